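test_that("degenerate simulation regimes behave deterministically", {
  d <- combshellDesign()
  ## certain survival and detection: every post-release cell is a detection
  sim <- simulateHistories(simTruth(S = 1, Pcl = 1, Pcd = 0.5, seed = 1))
  cm <- codes(sim)
  post <- col(cm) >= matrix(releaseOccasions(sim), nrow(cm), ncol(cm))
  expect_true(all(cm[post] == 1L))
  expect_true(all(cm[!post] == -1L))
  ## certain immediate death, invisible shells: zeros after release
  tr0 <- simTruth(S = 0, Pcl = 0.9, Pcd = 0, seed = 2)
  cm0 <- codes(simulateHistories(tr0))
  rel <- matrix(releaseOccasions(simulateHistories(tr0)), nrow(cm0), ncol(cm0))
  expect_true(all(cm0[col(cm0) > rel] == 0L))
  ## reproducibility given the seed
  expect_identical(codes(simulateHistories(simTruth(seed = 9))),
                   codes(simulateHistories(simTruth(seed = 9))))
})

test_that("detection frequency among alive occasions matches the truth", {
  ## with S = 1 everyone stays alive, so every post-release cell is a
  ## Bernoulli(Pcl) trial
  tr <- simTruth(S = 1, Pcl = 0.98, Pcd = 0.5, seed = 3,
                 cohorts = cohortTable(1L, 3000L))
  cm <- codes(simulateHistories(tr))
  trials <- sum(col(cm) > 1)
  hits <- sum(cm[, -1] == 1L)
  se <- sqrt(0.98 * 0.02 / trials)
  expect_lt(abs(hits / trials - 0.98), 3 * se)
})

test_that("simulated column tallies match their closed-form expectations", {
  d <- combshellDesign()
  S <- 0.97; Pcl <- 0.9
  tr <- simTruth(spec = modelSpec("model4"), S = S, Pcl = Pcl, seed = 4,
                 cohorts = cohortTable(1:5, c(1150, 1400, 1900, 450, 100)))
  cm <- codes(simulateHistories(tr))
  ages <- agesMonths(d$calendar)
  rel <- releaseOccasions(simulateHistories(tr))
  for (k in c(3, 5, 8)) {
    expHits <- sum(vapply(seq_along(rel), function(i) {
      if (rel[i] >= k) return(0)
      Pcl * S^(ages[k] - ages[rel[i]])
    }, numeric(1)))
    hits <- sum(cm[, k] == 1L & rel < k)
    expect_lt(abs(hits - expHits), 3 * sqrt(expHits))
  }
})

test_that("hierarchical truth draws individual parameters around the mean", {
  spec <- modelSpec("model3-1")
  tr <- simTruth(spec = spec, S = 0.9, Pcl = 0.8, Pcd = 0.4,
                 sigmaS = 0.02, sigmaPcl = 0.05, sigmaPcd = 0.1, seed = 5,
                 cohorts = cohortTable(1L, 500L))
  sim <- simulateHistories(tr)
  expect_s4_class(sim, "CaptureHistorySet")
  ## with S = 0.9 over 27.5 months most individuals die; dead recoveries at
  ## Pcd = 0.4 must appear, and the set still validates
  expect_gt(sum(codes(sim) == 2L), 0)
  expect_true(validObject(sim))
})

test_that("parameter recovery reports bias and coverage per parameter", {
  tr <- simTruth(S = 0.95, Pcl = 0.85, Pcd = 0.4, seed = 6,
                 cohorts = cohortTable(1:5, c(23, 28, 38, 9, 1)))
  rep <- parameterRecovery(tr, "model3", nReplicates = 3,
                           config = mcmcConfig(nChains = 2, nIter = 1200,
                                               burnIn = 400, seed = 20))
  expect_s4_class(rep, "RecoveryReport")
  expect_equal(rep@table$parameter, c("S", "Pcl", "Pcd"))
  expect_true(all(rep@table$coverage >= 0 & rep@table$coverage <= 1))
  expect_equal(rep@nReplicates, 3L)
  expect_length(rep@seeds, 3L)
  ## posterior means land near the truth even in a 3-replicate smoke run
  expect_lt(abs(rep@table$bias[rep@table$parameter == "Pcl"]), 0.1)
})

test_that("uninformative dead-recovery data return the Pcd prior mean", {
  ## no deaths can occur, so the Pcd posterior equals its Uniform(0, 1) prior
  tr <- simTruth(S = 1, Pcl = 0.9, Pcd = 0, seed = 7,
                 cohorts = cohortTable(1L, 40L))
  sim <- simulateHistories(tr)
  fit <- runChains(sim, "model3", mcmcConfig(nChains = 2, nIter = 3000,
                                             burnIn = 1000, seed = 8))
  sm <- summarizePosterior(fit)
  expect_equal(sm$mean[sm$parameter == "Pcd"], 0.5, tolerance = 0.03)
})
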