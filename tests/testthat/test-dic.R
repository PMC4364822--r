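test_that("observation deviance matches hand computations and is additive", {
  cal <- tinyCalendar2()
  spec <- modelSpec("model4")
  hs <- historySet("1 0", 1, cal)
  lat <- initLatentStates(hs, spec)  # alive, undetected
  ## one Bernoulli observation with p = 0.5
  expect_equal(modelDeviance(hs, lat, paramState(spec, 0.9, 0.5), spec),
               -2 * log(0.5))
  ## perfect detection of a fully detected animal
  hs2 <- historySet("1 1", 1, cal)
  expect_equal(modelDeviance(hs2, initLatentStates(hs2, spec),
                             paramState(spec, 0.9, 1), spec), 0)
  ## additivity over individuals
  both <- historySet(c("1 0", "1 1"), c(1, 1), cal)
  p <- paramState(spec, 0.9, 0.6)
  expect_equal(modelDeviance(both, initLatentStates(both, spec), p, spec),
               modelDeviance(hs, lat, p, spec) +
                 modelDeviance(hs2, initLatentStates(hs2, spec), p, spec))
  ## impossible observation
  badLat <- list(L = rbind(c(1L, 0L)), D = rbind(c(0L, 0L)))
  expect_equal(modelDeviance(hs2, badLat, p, spec), Inf)
  ## the complete focus adds the transition terms
  expect_equal(modelDeviance(hs2, initLatentStates(hs2, spec), p, spec,
                             focus = "complete"),
               modelDeviance(hs2, initLatentStates(hs2, spec), p, spec) -
                 2 * log(0.9))
})

test_that("DIC identities hold exactly on real fits", {
  set <- reconstructCombshell()
  for (preset in c("model3", "model4")) {
    fit <- fitModel(set, preset,
                    mcmcConfig(nChains = 2, nIter = 1500, burnIn = 500,
                               seed = 3))
    r <- fit$dic
    expect_identical(r@dic, r@dbar + r@pD)
    expect_identical(r@pD, r@dbar - r@dhat)
    expect_equal(r@dbar, mean(devianceTrace(fit$draws)))
    expect_equal(r@includesDead, preset == "model3")
  }
})

test_that("a degenerate posterior has zero effective parameters", {
  cal <- tinyCalendar4()
  spec <- modelSpec("model4")
  hs <- historySet(c("1 1 1 1", "1 1 1"), c(1, 2), cal)
  p <- paramState(spec, S = 0.9, Pcl = 0.8)
  lat <- initLatentStates(hs, spec)
  d0 <- modelDeviance(hs, lat, p, spec)
  nKeep <- 100
  draws <- makeDraws(list(S = matrix(0.9, nKeep, 2), Pcl = matrix(0.8, nKeep, 2)),
                     devTrace = matrix(d0, nKeep, 2), spec = spec)
  draws@aliveFreq <- matrix(1, 2, 4)  # everyone alive throughout, certainly
  r <- dic(draws, hs)
  expect_equal(r@pD, 0)
  expect_equal(r@dic, r@dbar)
})

test_that("the 5/10-unit support rules are applied", {
  mk <- function(name, dic, dead = TRUE)
    new("DicResult", dbar = dic - 1, dhat = dic - 2, pD = 1, dic = dic,
        modelName = name, includesDead = dead, focus = "observation")
  tab <- compareModels(list(mk("a", 70), mk("b", 73), mk("c", 77), mk("d", 85)))
  expect_equal(tab$model, c("a", "b", "c", "d"))
  expect_equal(tab$delta, c(0, 3, 7, 15))
  expect_equal(as.character(tab$support),
               c("well-supported", "well-supported", "less-supported",
                 "excluded"))
  ## a single model is trivially well supported
  one <- compareModels(mk("solo", 50))
  expect_equal(one$delta, 0)
  expect_equal(as.character(one$support), "well-supported")
  ## dead-inclusive and dead-exclusive specs are never ranked together
  expect_error(compareModels(list(mk("a", 70), mk("m4", 69, dead = FALSE))),
               "cannot be ranked together")
})
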