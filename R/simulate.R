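#' @include dic.R
NULL

## Normal(mu, sigma) truncated to [0, 1], by inverse-CDF sampling.
.rtnorm01 <- function(n, mu, sigma) {
  lo <- stats::pnorm(0, mu, sigma); hi <- stats::pnorm(1, mu, sigma)
  stats::qnorm(stats::runif(n, lo, hi), mu, sigma)
}

#' Generating conditions for the capture-history simulator
#'
#' Defaults emulate the Powell River combshell release: five staggered cohorts
#' of 23, 28, 38, 9 and 1 individuals over the eight-occasion calendar, with
#' monthly survival 0.998, live detection 0.98 and dead detection 0.4 under
#' the pooled-parameter dead-inclusive model.  These emulate the study regime;
#' they are not field estimates.
#'
#' @param spec generating [ModelSpec-class].
#' @param calendar an [OccasionCalendar-class].
#' @param cohorts a [CohortTable-class].
#' @param S,Pcl,Pcd generating values (hypermeans under hierarchical specs),
#'   recycled per season.
#' @param sigmaS,sigmaPcl,sigmaPcd random-effect SDs for hierarchical specs.
#' @param seed simulation seed.
#' @return a [SimTruth-class].
#' @export
simTruth <- function(spec = modelSpec("model3"),
                     calendar = combshellDesign()$calendar,
                     cohorts = combshellDesign()$cohorts,
                     S = 0.998, Pcl = 0.98, Pcd = 0.4,
                     sigmaS = 0.01, sigmaPcl = 0.01, sigmaPcd = 0.05,
                     seed = 1L) {
  params <- paramState(spec, S = S, Pcl = Pcl, Pcd = Pcd, sigmaS = sigmaS,
                       sigmaPcl = sigmaPcl, sigmaPcd = sigmaPcd,
                       n = sum(cohorts@cohortSize))
  new("SimTruth", params = params, calendar = calendar, cohorts = cohorts,
      spec = spec, seed = as.integer(seed))
}

#' Simulate capture histories under the generative model
#'
#' Each individual is alive at release; over each interval it survives with
#' probability `S^dt` (its own value under hierarchical truth); while alive it
#' is detected with probability `Pcl`; once dead its shell is detectable with
#' probability `Pcd` per occasion (for as long as `shellPersistence` allows),
#' the first dead detection is coded 2 and the individual is censored
#' afterwards.  Reproducible given the seed.
#'
#' @param truth a [SimTruth-class].
#' @param seed overrides `truth@seed` when given.
#' @return a [CaptureHistorySet-class].
#' @export
simulateHistories <- function(truth, seed = NULL) {
  set.seed(if (is.null(seed)) truth@seed else as.integer(seed))
  spec <- truth@spec
  cal <- truth@calendar
  K <- nOccasions(cal)
  ord <- order(truth@cohorts@releaseOccasion)
  r <- rep(truth@cohorts@releaseOccasion[ord], truth@cohorts@cohortSize[ord])
  n <- length(r)
  seas <- .famSeasons(spec, cal)
  pick <- function(fam, hier, sigma) {
    mu <- slot(truth@params, fam)
    ns <- length(mu)
    if (!hier) return(matrix(rep(mu, each = n), n, ns))
    vapply(seq_len(ns), function(s) .rtnorm01(n, mu[s], sigma), numeric(n))
  }
  Sv <- pick("S", spec@hierS, truth@params@sigmaS)
  Pclv <- pick("Pcl", spec@hierPcl, truth@params@sigmaPcl)
  Pcdv <- if (spec@includeDeadSubmodel)
    pick("Pcd", spec@hierPcd, truth@params@sigmaPcd) else NULL
  codesM <- matrix(CODE_PRE, n, K)
  codesM[cbind(seq_len(n), r)] <- CODE_LIVE
  alive <- rep(TRUE, n)
  shell <- rep(FALSE, n)   # shell currently detectable
  censored <- rep(FALSE, n)
  for (k in 2:K) {
    inStudy <- r < k
    ## survival over interval (k-1, k]
    sNow <- Sv[, seas$S[k - 1L]]
    surv <- stats::runif(n) < sNow^cal@deltaT[k - 1L]
    newlyDead <- inStudy & alive & !surv
    alive[newlyDead] <- FALSE
    if (spec@includeDeadSubmodel) {
      shell[newlyDead] <- TRUE
    }
    ## live detections
    det <- stats::runif(n) < Pclv[, seas$Pcl[k]]
    liveRows <- inStudy & alive & !censored
    codesM[liveRows, k] <- ifelse(det[liveRows], CODE_LIVE, CODE_NONE)
    ## dead recoveries
    deadRows <- inStudy & !alive & !censored
    if (spec@includeDeadSubmodel) {
      found <- stats::runif(n) < Pcdv[, seas$Pcd[k]]
      rec <- deadRows & shell & found
      codesM[rec, k] <- CODE_DEAD
      codesM[deadRows & !rec, k] <- CODE_NONE
      censored[rec] <- TRUE
      shell[rec] <- FALSE
      if (spec@shellPersistence == "single_occasion") shell[newlyDead] <- FALSE
    } else {
      codesM[deadRows, k] <- CODE_NONE
    }
  }
  ## post-recovery cells (censored rows were left untouched inside the loop)
  for (i in which(apply(codesM == CODE_DEAD, 1L, any))) {
    c0 <- which(codesM[i, ] == CODE_DEAD)
    if (c0 < K) codesM[i, (c0 + 1L):K] <- CODE_POST
  }
  captureHistorySet(codesM, r, cal)
}

#' Simulate-fit-summarize parameter recovery
#'
#' Simulates `nReplicates` datasets under `truth` (seeds `truth@seed + 1`,
#' `+2`, ...), fits `specToFit` to each by [runChains()], and reports the bias
#' of posterior means and the empirical 95 percent credible-interval coverage
#' for every population parameter shared between the generating and fitted
#' specs.  Replicates whose worst parameter Rhat exceeds `rhatMax` are flagged,
#' excluded with a warning, and listed in the report.
#'
#' @param truth a [SimTruth-class].
#' @param specToFit a [ModelSpec-class] or preset name.
#' @param nReplicates number of replicates (>= 1).
#' @param config an [McmcConfig-class] for each fit.
#' @param rhatMax convergence threshold (default 1.05).
#' @return a [RecoveryReport-class].
#' @export
parameterRecovery <- function(truth, specToFit = truth@spec, nReplicates = 20L,
                              config = mcmcConfig(nIter = 4000L, burnIn = 1000L),
                              rhatMax = 1.05) {
  if (is.character(specToFit)) specToFit <- modelSpec(specToFit)
  nReplicates <- as.integer(nReplicates)
  truthVals <- .flattenParams(truth@params, truth@spec)
  names(truthVals) <- specParamNames(truth@spec)
  fitNames <- specParamNames(specToFit)
  common <- intersect(names(truthVals), fitNames)
  seeds <- truth@seed + seq_len(nReplicates)
  est <- lo <- hi <- matrix(NA_real_, nReplicates, length(common),
                            dimnames = list(NULL, common))
  excluded <- integer(0)
  for (rep in seq_len(nReplicates)) {
    setRep <- simulateHistories(truth, seed = seeds[rep])
    cfg <- mcmcConfig(config@nChains, config@nIter, config@burnIn,
                      config@thin, config@seed + rep, config@proposalSd,
                      config@adapt)
    fit <- runChains(setRep, specToFit, cfg)
    sm <- summarizePosterior(fit)
    sm <- sm[sm$parameter %in% common, , drop = FALSE]
    if (any(sm$rhat > rhatMax, na.rm = TRUE)) {
      warning("replicate ", rep, " excluded: Rhat above ", rhatMax)
      excluded <- c(excluded, rep)
      next
    }
    est[rep, sm$parameter] <- sm$mean
    lo[rep, sm$parameter] <- sm$q2.5
    hi[rep, sm$parameter] <- sm$q97.5
  }
  used <- setdiff(seq_len(nReplicates), excluded)
  tab <- do.call(rbind, lapply(common, function(p) {
    tv <- truthVals[[p]]
    data.frame(parameter = p, truth = tv,
               postMean = mean(est[used, p]),
               bias = mean(est[used, p]) - tv,
               coverage = mean(lo[used, p] <= tv & tv <= hi[used, p]),
               covered = sum(lo[used, p] <= tv & tv <= hi[used, p]),
               nUsed = length(used), stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  new("RecoveryReport", table = tab, nReplicates = nReplicates,
      seeds = as.integer(seeds), excluded = excluded)
}
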