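test_that("detection counts on the reconstruction give the known tallies", {
  set <- reconstructCombshell()
  spec <- modelSpec("model3")
  ## the minimal-miss latent completion: each unobserved death happens right
  ## after the last detection, leaving only the two temporary misses at risk
  cm <- codes(set)
  lastDet <- apply(cm == 1L, 1, function(x) max(which(x)))
  deathOcc <- ifelse(rowSums(cm == 2L) > 0L, 5L,
                     ifelse(lastDet < 8L, lastDet + 1L, 9L))
  lat <- latentFromDeathTimes(deathOcc, set, spec)
  ct <- detectionCounts(lat, set, spec, 1, "live")
  expect_equal(ct[["successes"]], 543)
  expect_equal(ct[["trials"]] - ct[["successes"]], 2)
  ## conjugate full-conditional mean 544/547
  set.seed(1)
  draws <- replicate(4000, updateDetection(lat, set, spec, 1, "live"))
  expect_equal(mean(draws), 544 / 547, tolerance = 0.001)
})

test_that("detection updates fall back to the prior with no trials", {
  cal <- tinyCalendar4()
  spec <- modelSpec("model3")
  hs <- historySet(c("1 1 1 1"), 1, cal)
  lat <- initLatentStates(hs, spec)  # nobody dead: no dead-detection trials
  expect_equal(unname(detectionCounts(lat, hs, spec, 1, "dead")),
               c(0, 0))
  set.seed(2)
  draws <- replicate(4000, updateDetection(lat, hs, spec, 1, "dead"))
  expect_lt(abs(mean(draws) - 0.5), 3 * sqrt(1 / 12 / 4000) + 0.005)
})

test_that("all-success detection trials give the Beta(m + 1, 1) mean", {
  cal <- unitCalendar(5)
  spec <- modelSpec("model4")
  hs <- historySet(c("1 1 1 1 1", "1 1 1 1"), c(1, 2), cal)
  lat <- initLatentStates(hs, spec)
  m <- detectionCounts(lat, hs, spec, 1, "live")[["trials"]]  # 7, all successes
  expect_equal(m, 7)
  set.seed(3)
  draws <- replicate(6000, updateDetection(lat, hs, spec, 1, "live"))
  expect_equal(mean(draws), (m + 1) / (m + 2), tolerance = 0.004)
})

test_that("the survival block targets its full conditional", {
  cal <- unitCalendar(5)
  spec <- modelSpec("model4")
  ## all transitions survived; exposure E mussel-months => posterior S^E
  hs <- historySet(c("1 1 1 1 1", "1 1 1 1 1"), c(1, 1), cal)
  lat <- initLatentStates(hs, spec)
  E <- 8
  set.seed(4)
  s <- 0.5
  chain <- numeric(20000)
  for (i in seq_along(chain)) {
    s <- updateSurvival(lat, cal, spec, 1, s, proposalSd = 0.8)
    chain[i] <- s
  }
  chain <- chain[-(1:1000)]
  expect_equal(mean(chain), (E + 1) / (E + 2), tolerance = 0.01)
  ## with no at-risk transitions the chain samples the Uniform(0, 1) prior
  hs0 <- historySet("1", 5, cal)
  lat0 <- initLatentStates(hs0, spec)
  set.seed(5)
  s <- 0.5
  chain0 <- numeric(20000)
  for (i in seq_along(chain0)) {
    s <- updateSurvival(lat0, cal, spec, 1, s, proposalSd = 2)
    chain0[i] <- s
  }
  expect_equal(mean(chain0[-(1:1000)]), 0.5, tolerance = 0.03)
})

test_that("seeded runs are exactly reproducible and draws stay in range", {
  set <- reconstructCombshell()
  cfg <- mcmcConfig(nChains = 2, nIter = 400, burnIn = 100, thin = 2, seed = 42)
  a <- runChains(set, "model3", cfg)
  b <- runChains(set, "model3", cfg)
  expect_identical(drawsArray(a), drawsArray(b))
  expect_identical(devianceTrace(a), devianceTrace(b))
  expect_equal(dim(drawsArray(a)), c(150L, 2L, 3L))
  expect_true(all(drawsArray(a) >= 0 & drawsArray(a) <= 1))
  expect_equal(paramNames(a), c("S", "Pcl", "Pcd"))
})

test_that("posterior means match a grid-quadrature oracle on a small instance", {
  cal <- tinyCalendar4()
  spec <- modelSpec("model4")
  hs <- historySet(c("1 1 0 1", "1 0 1 0", "1 1 1 1"), c(1, 1, 1), cal)
  oracle <- gridPosteriorMeans(hs, spec, nGrid = 200)
  fit <- runChains(hs, spec, mcmcConfig(nChains = 3, nIter = 6000,
                                        burnIn = 1500, seed = 2))
  sm <- summarizePosterior(fit)
  expect_lt(abs(sm$mean[sm$parameter == "S"] - oracle[["S"]]), 0.01)
  expect_lt(abs(sm$mean[sm$parameter == "Pcl"] - oracle[["Pcl"]]), 0.01)
})

test_that("uninformative data return the hierarchical prior", {
  ## no deaths observed: the dead-detection family has a flat likelihood, so
  ## its individual values, hypermean and SD must sample their joint prior
  cal <- unitCalendar(4)
  spec <- modelSpec("model2-1", seasonalPcd = FALSE)
  hs <- historySet(rep("1 1 1 1", 4), rep(1, 4), cal)
  fit <- runChains(hs, spec, mcmcConfig(nChains = 3, nIter = 6000,
                                        burnIn = 1500, seed = 11))
  sm <- summarizePosterior(fit)
  expect_lt(abs(sm$mean[sm$parameter == "mu_Pcd"] - 0.5), 0.05)
  expect_lt(abs(sm$mean[sm$parameter == "sigma_Pcd"] - 0.25), 0.05)
  expect_lt(abs(mean(fit@individualMeans$Pcdi) - 0.5), 0.05)
})

test_that("a vanishing random-effect SD pins individuals to the hypermean", {
  cal <- unitCalendar(4)
  spec <- modelSpec("model2-1", seasonalPcd = FALSE)
  hs <- historySet(rep("1 1 1 1", 3), rep(1, 3), cal)
  p <- paramState(spec, S = 0.9, Pcl = 0.9, Pcd = 0.4, sigmaPcd = 1e-10, n = 3)
  lat <- initLatentStates(hs, spec)
  set.seed(7)
  for (i in 1:20) p <- updateHierarchical(lat, hs, p, spec)
  expect_lt(max(abs(p@Pcdi - p@Pcd)), 1e-6)
})

test_that("hierarchical updates keep detailed balance against the prior", {
  ## flat likelihood, sigma free: after many sweeps the individual values
  ## of a two-individual system remain exchangeable and inside [0, 1]
  cal <- unitCalendar(4)
  spec <- modelSpec("model2-1", seasonalPcd = FALSE)
  hs <- historySet(rep("1 1 1 1", 2), rep(1, 2), cal)
  p <- paramState(spec, S = 0.9, Pcl = 0.9, Pcd = 0.5, sigmaPcd = 0.2, n = 2,
                  Pcdi = matrix(c(0.4, 0.6), 2, 1))
  lat <- initLatentStates(hs, spec)
  set.seed(8)
  mus <- replicate(3000, {
    p <<- updateHierarchical(lat, hs, p, spec)
    p@Pcd
  })
  expect_true(all(mus > 0 & mus < 1))
  ## the hypermean posterior is symmetric around 0.5 under the flat
  ## likelihood; consecutive sweeps are autocorrelated, hence the wide band
  expect_lt(abs(mean(mus) - 0.5), 0.1)
})
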