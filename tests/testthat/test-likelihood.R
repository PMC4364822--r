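test_that("interval survival is a power of monthly survival", {
  expect_equal(intervalSurvival(1, 8.5), 1)
  expect_equal(intervalSurvival(0.5, 1), 0.5)
  expect_equal(intervalSurvival(0.999, 2), 0.998001)
  expect_error(intervalSurvival(1.2, 1), "S must")
  expect_error(intervalSurvival(0.9, 0), "dt must")
})

test_that("prior log-density matches closed forms", {
  spec <- modelSpec("model3")
  expect_equal(priorLogdensity(paramState(spec, 0.5, 0.7, 0.2), spec), 0)
  expect_equal(priorLogdensity(paramState(spec, 0.5, 0.7, 0.2) |>
                                 (\(p) {p@S <- 1.2; p})(), spec), -Inf)
  ## truncated normal at its mode, mu = 0.5, sigma = 0.1
  h <- modelSpec("model2-1")
  p <- paramState(h, S = 0.9, Pcl = 0.9, Pcd = 0.5, sigmaPcd = 0.1, n = 1,
                  Pcdi = matrix(0.5, 1, 1))
  z <- pnorm(1, 0.5, 0.1) - pnorm(0, 0.5, 0.1)
  expect_equal(priorLogdensity(p, h),
               log(1 / h@priorSdUpper) + dnorm(0.5, 0.5, 0.1, log = TRUE) - log(z))
})

test_that("complete-data log-likelihood matches hand computations", {
  cal <- tinyCalendar2()
  spec <- modelSpec("model4")
  hs <- historySet("1 1", 1, cal)
  lat <- initLatentStates(hs, spec)
  ## certain survival and detection
  expect_equal(completeDataLoglik(hs, lat, paramState(spec, 1, 1), spec), 0)
  ## survive (0.8) then detect (0.9) over one month: ln 0.72
  expect_equal(completeDataLoglik(hs, lat, paramState(spec, 0.8, 0.9), spec),
               log(0.72))
  ## a live detection where the latent state says dead is impossible
  dead <- list(L = rbind(c(1L, 0L)), D = rbind(c(0L, 1L)))
  expect_equal(completeDataLoglik(hs, dead, paramState(spec, 0.8, 0.9), spec),
               -Inf)
})

test_that("small marginals match enumeration-by-hand", {
  cal <- tinyCalendar2()  # dt = 1
  S <- 0.8; p <- 0.7; pd <- 0.4
  m4 <- modelSpec("model4")
  m3 <- modelSpec("model3")
  ## detected alive at the single recapture occasion: one path
  expect_equal(marginalLoglik(historySet("1 1", 1, cal), paramState(m4, S, p), m4),
               log(S * p))
  ## not detected, no dead submodel: survive-and-miss or die
  expect_equal(marginalLoglik(historySet("1 0", 1, cal), paramState(m4, S, p), m4),
               log(S * (1 - p) + (1 - S)))
  ## not detected, dead submodel: the dead path also misses the shell
  expect_equal(marginalLoglik(historySet("1 0", 1, cal),
                              paramState(m3, S, p, pd), m3),
               log(S * (1 - p) + (1 - S) * (1 - pd)))
  ## recovered dead: die then find the shell
  expect_equal(marginalLoglik(historySet("1 2", 1, cal),
                              paramState(m3, S, p, pd), m3),
               log((1 - S) * pd))
})

test_that("death-time marginal equals the brute-force latent sum", {
  cal <- tinyCalendar4()
  hs <- historySet(c("1 1 0 1", "1 0 2", "1 0 0 0", "1"),
                   c(1, 2, 1, 4), cal)
  set.seed(71)
  for (preset in c("model1", "model2", "model3", "model4")) {
    spec <- modelSpec(preset)
    specSingle <- modelSpec(preset, shellPersistence = "single_occasion")
    for (rep in 1:5) {
      p <- paramState(spec, S = runif(2, 0.6, 0.99), Pcl = runif(2, 0.3, 0.95),
                      Pcd = runif(2, 0.1, 0.9))
      a <- marginalLoglik(hs, p, spec)
      b <- enumerateMarginalLoglik(hs, p, spec)
      expect_equal(a, b, tolerance = 1e-12)
      pS <- paramState(specSingle, S = runif(2, 0.6, 0.99),
                       Pcl = runif(2, 0.3, 0.95), Pcd = runif(2, 0.1, 0.9))
      expect_equal(marginalLoglik(hs, pS, specSingle),
                   enumerateMarginalLoglik(hs, pS, specSingle),
                   tolerance = 1e-12)
    }
  }
  expect_error(enumerateMarginalLoglik(
    simulateHistories(simTruth(seed = 1)), paramState(modelSpec("model3")),
    modelSpec("model3")), "too large")
})

test_that("hierarchical marginals also match the latent sum", {
  cal <- tinyCalendar4()
  hs <- historySet(c("1 1 0 1", "1 0 0"), c(1, 2), cal)
  spec <- modelSpec("model3-1")
  set.seed(5)
  p <- paramState(spec, S = 0.9, Pcl = 0.7, Pcd = 0.4,
                  sigmaS = 0.05, sigmaPcl = 0.05, sigmaPcd = 0.05, n = 2,
                  Si = matrix(runif(2, 0.7, 0.95), 2),
                  Pcli = matrix(runif(2, 0.5, 0.9), 2),
                  Pcdi = matrix(runif(2, 0.2, 0.6), 2))
  expect_equal(marginalLoglik(hs, p, spec),
               enumerateMarginalLoglik(hs, p, spec), tolerance = 1e-12)
})

test_that("the unit-interval single-season limit matches the CJS formula", {
  cal <- unitCalendar(6)
  expect_true(all(intervalSeason(cal) == intervalSeason(cal)[1]))
  spec <- modelSpec("model4")
  S <- 0.85; p <- 0.6
  ## detected at occasions 2..3 after release at 1, never seen again
  hs <- historySet("1 1 1 0 0 0", 1, cal)
  expect_equal(marginalLoglik(hs, paramState(spec, S, p), spec),
               log(cjsNeverSeenAgain(S, p, nDetected = 2, nAfter = 3)))
  ## release only, never seen
  hs2 <- historySet("1 0 0 0 0 0", 1, cal)
  expect_equal(marginalLoglik(hs2, paramState(spec, S, p), spec),
               log(cjsNeverSeenAgain(S, p, 0, 5)))
})

test_that("the likelihood is exchangeable within cohorts", {
  cal <- tinyCalendar4()
  texts <- c("1 1 0 1", "1 0 1 1", "1 1 1 1")
  spec <- modelSpec("model3")
  p <- paramState(spec, 0.9, 0.8, 0.3)
  a <- marginalLoglik(historySet(texts, c(1, 1, 1), cal), p, spec)
  b <- marginalLoglik(historySet(texts[c(3, 1, 2)], c(1, 1, 1), cal), p, spec)
  expect_equal(a, b)
})
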