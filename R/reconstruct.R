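#' @include capture.R
NULL

#' Reconstruct a canonical capture-history set from aggregate counts
#'
#' Individual capture histories are rarely published; this builds one
#' deterministic completion of the per-occasion release / live-recapture /
#' dead-recovery tallies under a minimal-miss rule:
#'
#' * each dead recovery at occasion c is attributed to a death in the
#'   immediately preceding interval (c-1, c];
#' * the number of at-risk live individuals carried into each occasion is the
#'   smallest one consistent with all later counts (backward induction), so a
#'   live-detection deficit becomes a temporary miss (a 0 with later
#'   detections) only when later counts require the individual alive, and a
#'   permanent disappearance (an unrecovered death, 0s to the end) otherwise;
#' * misses and deaths are assigned chronologically to the lowest-index
#'   individuals of the earliest eligible cohort, each event to an individual
#'   with no previous event while one is available.
#'
#' Under the non-hierarchical likelihoods individuals within a cohort are
#' exchangeable, so only the pattern counts matter; the fixed assignment makes
#' the reconstruction deterministic (identical inputs give identical files).
#' Because the completion contains the fewest possible non-detections, posterior
#' detection estimates from it are upper bounds for the unpublished data.
#'
#' @param aggregates an [AggregateCounts-class].
#' @param calendar an [OccasionCalendar-class] (K occasions).
#' @param cohorts a [CohortTable-class]; per-occasion release sums must match
#'   `aggregates`.
#' @return a [CaptureHistorySet-class] whose [tabulateCounts()] equals
#'   `aggregates`.
#' @export
reconstructHistories <- function(aggregates, calendar, cohorts) {
  K <- nOccasions(calendar)
  R <- aggregates@released
  l <- aggregates@liveRecaptured
  m <- aggregates@deadRecaptured
  if (length(R) != K) stop("aggregates and calendar disagree on occasion count")
  relByOcc <- vapply(seq_len(K), function(k)
    sum(cohorts@cohortSize[cohorts@releaseOccasion == k]), numeric(1))
  if (!all(relByOcc == R))
    stop("cohort table release counts do not match the aggregates")
  if (m[1L] > 0L)
    stop("reconstruction error at occasion 1: dead recovery before any interval")

  ## Backward pass: minimal at-risk live count needed at each occasion.
  ## need[k] individuals (released before k) must be alive at k so that every
  ## later live count and dead-recovery donor can be supplied.
  need <- integer(K)
  need[K] <- l[K]
  if (K >= 2L) for (k in (K - 1L):1L)
    need[k] <- max(l[k], need[k + 1L] + m[k + 1L] - R[k])
  need <- pmax(need, 0L)

  ## Forward pass: unrecovered deaths u[k] in each interval (k-1, k] make the
  ## realized at-risk count equal need[k]; a negative u flags inconsistency.
  alive <- 0L  # at-risk (previously released, alive) entering occasion k
  u <- integer(K)
  for (k in seq_len(K)[-1L]) {
    pool <- alive + R[k - 1L]
    u[k] <- pool - m[k] - need[k]
    if (u[k] < 0L)
      stop("reconstruction error at occasion ", k,
           ": counts need more live individuals than were released")
    alive <- need[k]
  }
  miss <- need - l  # temporary misses per occasion (>= 0 by construction)

  ## Assignment: individuals ordered by cohort then index; events
  ## chronologically, each to the lowest-index alive event-free individual.
  ord <- order(cohorts@releaseOccasion)
  rel <- rep(cohorts@releaseOccasion[ord], cohorts@cohortSize[ord])
  n <- length(rel)
  deathOcc <- rep(NA_integer_, n)   # first occasion at which dead
  recovered <- logical(n)
  missAt <- vector("list", n)
  hasEvent <- logical(n)
  pick <- function(k, exclude = integer(0)) {
    cand <- which(is.na(deathOcc) & rel < k)
    cand <- setdiff(cand, exclude)
    if (!length(cand)) stop("reconstruction error at occasion ", k,
                            ": no eligible individual")
    free <- cand[!hasEvent[cand]]
    if (length(free)) free[1L] else cand[1L]
  }
  for (k in seq_len(K)[-1L]) {
    ## deaths in (k-1, k] first: they decide who is alive at occasion k
    for (e in seq_len(m[k])) {         # recovered deaths
      i <- pick(k)
      deathOcc[i] <- k; recovered[i] <- TRUE; hasEvent[i] <- TRUE
    }
    for (e in seq_len(u[k])) {         # unrecovered deaths
      i <- pick(k)
      deathOcc[i] <- k; hasEvent[i] <- TRUE
    }
    missedNow <- integer(0)            # distinct individuals per occasion
    for (e in seq_len(miss[k])) {      # temporary misses at occasion k
      i <- pick(k, exclude = missedNow)
      missAt[[i]] <- c(missAt[[i]], k)
      hasEvent[i] <- TRUE
      missedNow <- c(missedNow, i)
    }
  }

  codesM <- matrix(CODE_PRE, n, K)
  for (i in seq_len(n)) {
    d <- if (is.na(deathOcc[i])) K + 1L else deathOcc[i]
    for (k in rel[i]:K) {
      codesM[i, k] <-
        if (k < d) (if (k %in% missAt[[i]]) CODE_NONE else CODE_LIVE)
        else if (recovered[i]) (if (k == d) CODE_DEAD else CODE_POST)
        else CODE_NONE
    }
  }
  set <- captureHistorySet(codesM, rel, calendar)
  tall <- tabulateCounts(set)
  stopifnot(identical(tall@liveRecaptured, l), identical(tall@deadRecaptured, m))
  set
}

#' Reconstruct the Powell River combshell capture histories
#'
#' Applies [reconstructHistories()] to the published aggregates
#' ([combshellAggregates()]) under the study design ([combshellDesign()]):
#' 99 individuals over 8 occasions, with two temporary misses (occasions 3 and
#' 4), one dead recovery at occasion 5, and four unrecovered deaths.
#'
#' @return a [CaptureHistorySet-class].
#' @export
reconstructCombshell <- function() {
  d <- combshellDesign()
  reconstructHistories(combshellAggregates(), d$calendar, d$cohorts)
}
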