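test_that("history strings parse to coded rows and back", {
  ## a mussel first captured at occasions 2 and 3, again at 5, 6 and 8
  row <- parseHistory("0 1 1 0 1 1 0 1 0", 1, 9)
  expect_equal(which(row == 1L), c(2L, 3L, 5L, 6L, 8L))
  expect_equal(formatHistory(row, 1), "0 1 1 0 1 1 0 1 0")

  ## release at the last occasion gives a single-entry record
  row1 <- parseHistory("1", 5, 5)
  expect_equal(row1, c(rep(-1L, 4), 1L))

  ## cells after a dead recovery become post-recovery markers
  row2 <- parseHistory("1 0 2 0", 2, 5)
  expect_equal(row2, c(-1L, 1L, 0L, 2L, 3L))
  expect_equal(formatHistory(row2, 2), "1 0 2 0")

  expect_error(parseHistory("1 2 1", 1), "live detection after dead recovery")
  expect_error(parseHistory("1 2 0 2", 1), "more than one dead recovery")
  expect_error(parseHistory("1 x 0", 1), "tokens")
})

test_that("capture-history sets validate their invariants", {
  cal <- tinyCalendar4()
  ## release cell must be a detection
  expect_error(captureHistorySet(rbind(c(0L, 1L, 1L, 1L)), 1L, cal) |>
                 validObject(), "invalid")
  ## no live detection after a dead recovery
  expect_error(captureHistorySet(rbind(c(1L, 2L, 1L, 0L)), 1L, cal) |>
                 validObject(), "invalid")
  ## pre-release cells must be marked as such
  expect_error(captureHistorySet(rbind(c(0L, 1L, 1L, 1L)), 2L, cal) |>
                 validObject(), "invalid")
  ok <- captureHistorySet(rbind(parseHistory("1 0 2", 2, 4)), 2L, cal)
  expect_s4_class(ok, "CaptureHistorySet")
})

test_that("capture-history files round-trip and reject bad input", {
  set <- reconstructCombshell()
  path <- withr::local_tempfile(fileext = ".csv")
  writeHistories(set, path)
  back <- readHistories(path, calendar(set))
  expect_identical(codes(back), codes(set))
  expect_identical(releaseOccasions(back), releaseOccasions(set))

  ## duplicate ids
  df <- read.csv(path, colClasses = "character")
  df$id[2] <- df$id[1]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path2, row.names = FALSE, quote = FALSE)
  expect_error(readHistories(path2, calendar(set)), "duplicate")

  ## a detection before the declared release occasion
  df <- read.csv(path, colClasses = "character")
  df$release_occasion[1] <- "2"
  path3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path3, row.names = FALSE, quote = FALSE)
  expect_error(readHistories(path3, calendar(set)), "invalid")
})

test_that("the canonical reconstruction reproduces the published tallies", {
  set <- reconstructCombshell()
  agg <- combshellAggregates()
  tall <- tabulateCounts(set)
  expect_identical(tall@released, agg@released)
  expect_identical(tall@liveRecaptured, agg@liveRecaptured)
  expect_identical(tall@deadRecaptured, agg@deadRecaptured)
  expect_equal(nIndividuals(set), 99L)

  ## exactly one dead recovery, at occasion 5
  expect_equal(which(colSums(codes(set) == 2L) > 0), 5L)
  expect_equal(sum(codes(set) == 2L), 1L)

  ## the two temporary misses sit at occasions 3 and 4; every other zero cell
  ## belongs to an individual never seen again
  cm <- codes(set)
  seenLater <- t(apply(cm == 1L, 1, function(x) rev(cummax(rev(x)))))
  tempMiss <- which(cm == 0L & seenLater == 1L, arr.ind = TRUE)
  expect_equal(sort(tempMiss[, "col"]), c(3L, 4L))

  ## five individuals terminate dead: one recovered, four never seen again
  lastDet <- apply(cm == 1L, 1, function(x) max(which(x)))
  gone <- sum(lastDet < 8L & rowSums(cm == 2L) == 0L)
  expect_equal(gone, 4L)
  expect_equal(sum(rowSums(cm == 2L) > 0L), 1L)
})

test_that("reconstruction is deterministic down to the written file", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeHistories(reconstructCombshell(), p1)
  writeHistories(reconstructCombshell(), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("tabulate after reconstruct is the identity on consistent counts", {
  d <- combshellDesign()
  ## aggregates arising from simulated data are consistent by construction
  for (seed in 1:5) {
    tr <- simTruth(S = 0.93, Pcl = 0.85, Pcd = 0.5, seed = seed,
                   cohorts = cohortTable(1:5, c(12, 10, 8, 5, 3)))
    sim <- simulateHistories(tr)
    agg <- tabulateCounts(sim)
    rec <- reconstructHistories(agg, d$calendar, cohortTable(1:5, c(12, 10, 8, 5, 3)))
    expect_identical(tabulateCounts(rec)@liveRecaptured, agg@liveRecaptured)
    expect_identical(tabulateCounts(rec)@deadRecaptured, agg@deadRecaptured)
    expect_identical(tabulateCounts(rec)@released, agg@released)
  }
})

test_that("inconsistent aggregates are rejected with the offending occasion", {
  d <- combshellDesign()
  expect_error(aggregateCounts(c(5L, rep(0L, 7)), c(0L, 6L, rep(0L, 6)),
                               integer(8)) |> validObject(),
               "cumulative releases")
  bad <- aggregateCounts(c(5L, rep(0L, 7)), c(0L, 5L, 5L, rep(0L, 5)),
                         c(0L, 0L, 1L, rep(0L, 5)))
  expect_error(reconstructHistories(bad, d$calendar,
                                    cohortTable(1L, 5L)),
               "occasion [0-9]")
})

test_that("an empty set tallies to zero", {
  cal <- tinyCalendar4()
  empty <- captureHistorySet(matrix(integer(0), 0, 4), integer(0), cal)
  tall <- tabulateCounts(empty)
  expect_equal(tall@released, integer(4))
  expect_equal(tall@liveRecaptured, integer(4))
})

test_that("perfect detection without mortality tallies the full at-risk pool", {
  tr <- simTruth(S = 1, Pcl = 1, Pcd = 0, seed = 1,
                 cohorts = cohortTable(c(1L, 2L), c(6L, 4L)))
  sim <- simulateHistories(tr)
  tall <- tabulateCounts(sim)
  prior <- c(0L, cumsum(tall@released)[-8])
  expect_equal(tall@liveRecaptured[-1], prior[-1])
})
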