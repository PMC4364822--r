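test_that("fit reports are written completely and reproducibly", {
  set <- reconstructCombshell()
  cfg <- mcmcConfig(nChains = 2, nIter = 600, burnIn = 200, seed = 5)
  fit <- fitModel(set, "model3", cfg)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  writeFitReport(fit, dir1)
  writeFitReport(fitModel(set, "model3", cfg), dir2)
  for (f in c("draws.csv", "summary.csv", "dic.csv", "run-info.txt"))
    expect_true(file.exists(file.path(dir1, f)))
  ## identical config and seed give identical files
  expect_identical(readLines(file.path(dir1, "summary.csv")),
                   readLines(file.path(dir2, "summary.csv")))
  expect_identical(readLines(file.path(dir1, "draws.csv")),
                   readLines(file.path(dir2, "draws.csv")))
  ## the summary has the three pooled parameters of the no-seasonality model
  sm <- read.csv(file.path(dir1, "summary.csv"))
  expect_setequal(sm$parameter, c("S", "Pcl", "Pcd", "deviance"))
  ## the seed and config hash are stamped
  info <- readLines(file.path(dir1, "run-info.txt"))
  expect_true(any(grepl("seed: 5", info)))
  expect_true(any(grepl("config-hash: [0-9a-f]{8}", info)))
})

test_that("dead-exclusive fits report no dead-detection parameter", {
  set <- reconstructCombshell()
  fit4 <- fitModel(set, "model4",
                   mcmcConfig(nChains = 2, nIter = 600, burnIn = 200, seed = 5))
  expect_false("Pcd" %in% fit4$summary$parameter)
  expect_setequal(setdiff(fit4$summary$parameter, "deviance"), c("S", "Pcl"))
})

test_that("comparison tables split the dead-exclusive family", {
  mk <- function(name, dic, dead)
    new("DicResult", dbar = dic, dhat = dic, pD = 0, dic = dic,
        modelName = name, includesDead = dead, focus = "observation")
  fits <- list(mk("model1", 76.7, TRUE), mk("model3", 76.3, TRUE),
               mk("model4", 70.2, FALSE), mk("model4-1", 69.1, FALSE))
  path <- file.path(withr::local_tempdir(), "compare.csv")
  paths <- writeComparisonTable(fits, path)
  expect_length(paths, 2L)
  main <- read.csv(path)
  expect_equal(main$model, c("model3", "model1"))
  other <- read.csv(sub("\\.csv$", "-dead-excluded.csv", path))
  expect_equal(other$model, c("model4-1", "model4"))
})

test_that("recovery reports round-trip to CSV", {
  tr <- simTruth(S = 0.95, Pcl = 0.85, Pcd = 0.4, seed = 1,
                 cohorts = cohortTable(1L, 30L))
  rep <- parameterRecovery(tr, "model3", nReplicates = 2,
                           config = mcmcConfig(nChains = 2, nIter = 800,
                                               burnIn = 300, seed = 2))
  path <- file.path(withr::local_tempdir(), "recovery.csv")
  writeRecoveryReport(rep, path)
  back <- read.csv(path)
  expect_equal(back$parameter, c("S", "Pcl", "Pcd"))
  reps <- read.csv(sub("\\.csv$", "-replicates.csv", path))
  expect_equal(nrow(reps), 2L)
})

test_that("run configurations are read from YAML with defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("histories: h.csv", "calendar: cal.csv", "model: model2",
               "mcmc:", "  nIter: 1000", "  burnIn: 200", "  seed: 7"), path)
  cfg <- readRunConfig(path)
  expect_equal(cfg$model, "model2")
  expect_equal(cfg$config@nIter, 1000L)
  expect_equal(cfg$config@seed, 7L)
  expect_equal(cfg$config@nChains, 3L)  # default
})
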