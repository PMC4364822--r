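#' @include design-data.R
NULL

#' MCMC run configuration
#'
#' Defaults suit the non-hierarchical variants (3 chains of 20,000 with 5,000
#' burn-in, no thinning).  Hierarchical variants mix more slowly; 3 x 60,000
#' with 10,000 burn-in and thin 10 is a reasonable desk-scale choice, always
#' subject to the Rhat <= 1.05 convergence check reported by
#' [summarizePosterior()].
#'
#' @param nChains chains (>= 2 for Gelman-Rubin diagnostics).
#' @param nIter iterations per chain.
#' @param burnIn discarded initial iterations.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param seed base seed; chain c is seeded with `seed + c - 1`.
#' @param proposalSd initial logit/log-scale random-walk SD.
#' @param adapt adapt proposal scales toward 20-50 percent acceptance during
#'   burn-in, frozen afterwards (preserving detailed balance for retained
#'   draws).
#' @return an [McmcConfig-class].
#' @export
mcmcConfig <- function(nChains = 3L, nIter = 20000L, burnIn = 5000L,
                       thin = 1L, seed = 1L, proposalSd = 0.5, adapt = TRUE) {
  new("McmcConfig", nChains = as.integer(nChains), nIter = as.integer(nIter),
      burnIn = as.integer(burnIn), thin = as.integer(thin),
      seed = as.integer(seed), proposalSd = proposalSd, adapt = isTRUE(adapt))
}

## One logit-scale random-walk Metropolis step against logtarget.
.metropolisLogit <- function(current, lsd, logtarget) {
  z <- stats::qlogis(current)
  zp <- z + stats::rnorm(1L, 0, exp(lsd))
  prop <- stats::plogis(zp)
  la <- logtarget(prop) - logtarget(current) +
    log(prop) + log1p(-prop) - log(current) - log1p(-current)
  if (is.finite(la) && log(stats::runif(1L)) < la) list(value = prop, acc = 1L)
  else list(value = current, acc = 0L)
}

## Full-conditional log target for a population survival value of season s.
.survTarget <- function(expo, dieDts) {
  function(S) {
    if (S <= 0 || S >= 1) return(-Inf)
    .xmul(expo, log(S)) + sum(log1p(-S^dieDts))
  }
}

#' Conjugate and Metropolis parameter updates
#'
#' `detectionCounts` tallies the Bernoulli trials of a detection probability
#' given latent states: live trials are post-release occasions with `L = 1`
#' in the given occasion-season (successes are live detections; the release
#' detection is conditioned on and not counted), dead trials are occasions
#' with `D = 1` (successes are dead recoveries).  `updateDetection` draws the
#' conjugate `Beta(1 + successes, 1 + failures)` full conditional of a
#' non-hierarchical detection probability.  `updateSurvival` performs one
#' logit-scale random-walk Metropolis step against the full conditional of a
#' non-hierarchical monthly survival rate, whose likelihood is
#' `prod Bern(L_k | L_{k-1} S^dt_k)` over the intervals of the given
#' interval-season.  All use R's global random number stream.
#'
#' @param latent a [LatentStateMatrix-class] consistent with `histories`.
#' @param histories a [CaptureHistorySet-class].
#' @param spec a [ModelSpec-class] (non-hierarchical for the parameter being
#'   updated).
#' @param season season index (1 = summer, 2 = winter; use 1 for pooled
#'   parameters).
#' @param which `"live"` (Pcl) or `"dead"` (Pcd).
#' @param cal an [OccasionCalendar-class].
#' @param current current survival value in (0, 1).
#' @param proposalSd logit-scale random-walk SD.
#' @return `detectionCounts`: `c(successes =, trials =)`;
#'   `updateDetection` and `updateSurvival`: one numeric draw.
#' @export
detectionCounts <- function(latent, histories, spec, season = 1L,
                            which = c("live", "dead")) {
  which <- match.arg(which)
  histories <- .applySpecToHistories(histories, spec)
  cm <- histories@codes
  n <- nrow(cm); K <- ncol(cm)
  seas <- .famSeasons(spec, calendar(histories))
  if (which == "live") {
    sIdx <- matrix(seas$Pcl, n, K, byrow = TRUE)
    atRisk <- latent@L == 1L & col(cm) > matrix(histories@releaseOccasion, n, K) &
      sIdx == season & (cm == CODE_LIVE | cm == CODE_NONE)
    succ <- sum(atRisk & cm == CODE_LIVE)
  } else {
    if (!spec@includeDeadSubmodel) stop("the spec has no dead submodel")
    sIdx <- matrix(seas$Pcd, n, K, byrow = TRUE)
    atRisk <- latent@D == 1L & sIdx == season &
      (cm == CODE_DEAD | cm == CODE_NONE)
    succ <- sum(atRisk & cm == CODE_DEAD)
  }
  c(successes = succ, trials = sum(atRisk))
}

#' @rdname detectionCounts
#' @export
updateDetection <- function(latent, histories, spec, season = 1L,
                            which = c("live", "dead")) {
  ct <- detectionCounts(latent, histories, spec, season, which)
  stats::rbeta(1L, 1 + ct[["successes"]], 1 + ct[["trials"]] - ct[["successes"]])
}

#' @rdname detectionCounts
#' @export
updateSurvival <- function(latent, cal, spec, season = 1L, current,
                           proposalSd = 0.5) {
  seasS <- if (spec@seasonalS) cal@intervalSeason else rep(1L, length(cal@deltaT))
  L <- latent@L
  expo <- 0; dieDts <- numeric(0)
  for (k in seq_len(ncol(L))[-1L]) {
    if (seasS[k - 1L] != season) next
    atRisk <- L[, k - 1L] == 1L
    surv <- atRisk & L[, k] == 1L
    expo <- expo + sum(surv) * cal@deltaT[k - 1L]
    dieDts <- c(dieDts, rep(cal@deltaT[k - 1L], sum(atRisk & L[, k] == 0L)))
  }
  .metropolisLogit(current, log(proposalSd), .survTarget(expo, dieDts))$value
}

## ---- hierarchical family updates (shared by runChains and the exported
## ---- updateHierarchical) ------------------------------------------------

## Per-individual log-likelihood factors as functions of one family's values.
.hierLiks <- function(dd, cnt, fam, s) {
  switch(fam,
    S = {
      expoI <- cnt$expoI[[s]]
      dieHere <- cnt$died & !is.na(cnt$dieSeason) & cnt$dieSeason == s
      dts <- ifelse(dieHere, cnt$dieDt, NA_real_)
      function(x) {
        ll <- .xmul(expoI, log(x))
        ll[dieHere] <- ll[dieHere] + log1p(-x[dieHere]^dts[dieHere])
        ll
      }
    },
    Pcl = {
      det <- cnt$detI[[s]]; mis <- cnt$misI[[s]]
      function(x) .xmul(det, log(x)) + .xmul(mis, log1p(-x))
    },
    Pcd = {
      succ <- cnt$pcdSuccI[[s]]; fail <- cnt$pcdFailI[[s]]
      function(x) .xmul(succ, log(x)) + .xmul(fail, log1p(-x))
    })
}

## Vectorized Metropolis update of one hierarchical family (all individuals,
## all seasons), then the hypermeans and the shared SD.
.updateHierFamily <- function(dd, cnt, params, spec, fam, tune, track = NULL) {
  slotI <- paste0(fam, "i")
  xi <- slot(params, slotI)
  mu <- slot(params, fam)
  sigma <- slot(params, paste0("sigma", fam))
  ns <- ncol(xi)
  for (s in seq_len(ns)) {
    lik <- .hierLiks(dd, cnt, fam, s)
    x <- xi[, s]
    z <- stats::qlogis(x)
    zp <- z + stats::rnorm(length(x), 0, exp(tune[[paste0(fam, "i")]]))
    xp <- stats::plogis(zp)
    la <- lik(xp) - lik(x) +
      .dtnorm01(xp, mu[s], sigma) - .dtnorm01(x, mu[s], sigma) +
      log(xp) + log1p(-xp) - log(x) - log1p(-x)
    acc <- is.finite(la) & log(stats::runif(length(x))) < la
    xi[acc, s] <- xp[acc]
    if (!is.null(track)) .track(track, paste0(fam, "i"), mean(acc))
    ## hypermean: Uniform(0,1) prior, truncated-normal terms
    muTarget <- function(m) sum(.dtnorm01(xi[, s], m, sigma))
    st <- .metropolisLogit(mu[s], tune[[paste0("mu", fam)]], muTarget)
    mu[s] <- st$value
    if (!is.null(track)) .track(track, paste0("mu", fam), st$acc)
  }
  ## shared SD: Uniform(0, priorSdUpper) prior, log-scale random walk
  sigTarget <- function(g) {
    if (g <= 0 || g >= spec@priorSdUpper) return(-Inf)
    sum(vapply(seq_len(ns), function(s) sum(.dtnorm01(xi[, s], mu[s], g)),
               numeric(1)))
  }
  lg <- log(sigma) + stats::rnorm(1L, 0, exp(tune[[paste0("sigma", fam)]]))
  gp <- exp(lg)
  la <- sigTarget(gp) - sigTarget(sigma) + log(gp) - log(sigma)
  accS <- is.finite(la) && log(stats::runif(1L)) < la
  if (accS) sigma <- gp
  if (!is.null(track)) .track(track, paste0("sigma", fam), as.integer(accS))
  slot(params, slotI) <- xi
  slot(params, fam) <- mu
  slot(params, paste0("sigma", fam)) <- sigma
  params
}

.track <- function(env, name, rate) {
  env$num[[name]] <- (env$num[[name]] %||% 0) + rate
  env$den[[name]] <- (env$den[[name]] %||% 0) + 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One sweep of the hierarchical parameter blocks
#'
#' Updates every per-individual parameter of the hierarchical families by
#' logit-scale Metropolis against (individual likelihood x truncated-normal
#' prior), then the hypermeans against their truncated-normal terms and
#' Uniform(0, 1) priors, and the shared SDs against Uniform(0,
#' `priorSdUpper`).
#'
#' @inheritParams updateLatentStates
#' @param proposalSd random-walk SD used for every block.
#' @return the updated [ParamState-class].
#' @export
updateHierarchical <- function(latent, histories, params, spec,
                               proposalSd = 0.5) {
  histories <- .applySpecToHistories(histories, spec)
  dd <- .designData(histories, spec)
  cnt <- .countsFromDeaths(dd, deathTimesFromLatent(latent), spec)
  tune <- list()
  for (fam in c("S", "Pcl", "Pcd"))
    for (blk in c(paste0(fam, "i"), paste0("mu", fam), paste0("sigma", fam)))
      tune[[blk]] <- log(proposalSd)
  for (fam in c("S", "Pcl", "Pcd")) {
    if (!slot(spec, paste0("hier", fam))) next
    params <- .updateHierFamily(dd, cnt, params, spec, fam, tune)
  }
  params
}

## ---- deviance from sufficient counts ------------------------------------

.obsLoglikFromCounts <- function(dd, cnt, params, spec) {
  ll <- 0
  for (s in seq_len(dd$nsPcl)) {
    if (spec@hierPcl) {
      ll <- ll + sum(.xmul(cnt$detI[[s]], log(params@Pcli[, s])) +
                       .xmul(cnt$misI[[s]], log1p(-params@Pcli[, s])))
    } else {
      ll <- ll + .xmul(sum(cnt$detI[[s]]), log(params@Pcl[s])) +
        .xmul(sum(cnt$misI[[s]]), log1p(-params@Pcl[s]))
    }
  }
  if (spec@includeDeadSubmodel) for (s in seq_len(dd$nsPcd)) {
    if (spec@hierPcd) {
      ll <- ll + sum(.xmul(cnt$pcdSuccI[[s]], log(params@Pcdi[, s])) +
                       .xmul(cnt$pcdFailI[[s]], log1p(-params@Pcdi[, s])))
    } else {
      ll <- ll + .xmul(sum(cnt$pcdSuccI[[s]]), log(params@Pcd[s])) +
        .xmul(sum(cnt$pcdFailI[[s]]), log1p(-params@Pcd[s]))
    }
  }
  ll
}

.transLoglikFromCounts <- function(dd, cnt, params, spec) {
  ll <- 0
  for (s in seq_len(dd$nsS)) {
    dieHere <- cnt$died & cnt$dieSeason == s
    if (spec@hierS) {
      ll <- ll + sum(.xmul(cnt$expoI[[s]], log(params@Si[, s])))
      if (any(dieHere))
        ll <- ll + sum(log1p(-params@Si[dieHere, s]^cnt$dieDt[dieHere]))
    } else {
      ll <- ll + .xmul(sum(cnt$expoI[[s]]), log(params@S[s]))
      if (any(dieHere))
        ll <- ll + sum(log1p(-params@S[s]^cnt$dieDt[dieHere]))
    }
  }
  ll
}

## ---- the main sampler ----------------------------------------------------

.initParams <- function(spec, n) {
  ns <- function(seasonal) if (seasonal) 2L else 1L
  S <- stats::runif(ns(spec@seasonalS), 0.5, 0.99)
  Pcl <- stats::runif(ns(spec@seasonalPcl), 0.3, 0.95)
  Pcd <- stats::runif(ns(spec@seasonalPcd), 0.1, 0.9)
  paramState(spec, S = S, Pcl = Pcl, Pcd = Pcd,
             sigmaS = stats::runif(1, 0.01, spec@priorSdUpper / 2),
             sigmaPcl = stats::runif(1, 0.01, spec@priorSdUpper / 2),
             sigmaPcd = stats::runif(1, 0.01, spec@priorSdUpper / 2),
             n = n)
}

#' Run the data-augmentation MCMC sampler
#'
#' Each iteration performs a full sweep: an exact Gibbs draw of every
#' individual's latent death time (enumerating the monotone alive-path
#' support), conjugate Beta draws for non-hierarchical detection
#' probabilities, logit-scale random-walk Metropolis for survival rates, and
#' Metropolis sweeps for hierarchical families (individual values, hypermeans,
#' shared SDs).  Proposal scales adapt during burn-in only.  Chains run
#' sequentially with seeds `seed + chain - 1`; runs are exactly reproducible.
#'
#' @param histories a [CaptureHistorySet-class].
#' @param spec a [ModelSpec-class] or preset name.
#' @param config an [McmcConfig-class].
#' @param devianceFocus deviance recorded per retained draw:
#'   `"observation"` (observation layer only, default) or `"complete"`.
#' @return a [PosteriorDraws-class].
#' @export
runChains <- function(histories, spec, config = mcmcConfig(),
                      devianceFocus = c("observation", "complete")) {
  devianceFocus <- match.arg(devianceFocus)
  if (is.character(spec)) spec <- modelSpec(spec)
  histories <- .applySpecToHistories(histories, spec)
  dd <- .designData(histories, spec)
  n <- dd$n; K <- dd$K
  pn <- specParamNames(spec)
  nKeep <- (config@nIter - config@burnIn) %/% config@thin
  draws <- array(NA_real_, c(nKeep, config@nChains, length(pn)),
                 dimnames = list(NULL, NULL, pn))
  devTrace <- matrix(NA_real_, nKeep, config@nChains)
  laCount <- matrix(0, n, K)  # tallies of the last-alive occasion
  indivSum <- list(Si = NULL, Pcli = NULL, Pcdi = NULL)
  track <- new.env(); track$num <- list(); track$den <- list()
  hierFams <- c("S", "Pcl", "Pcd")[c(spec@hierS, spec@hierPcl, spec@hierPcd)]

  for (chain in seq_len(config@nChains)) {
    set.seed(config@seed + chain - 1L)
    params <- .initParams(spec, n)
    tune <- list()
    for (s in seq_len(dd$nsS)) tune[[paste0("S", s)]] <- log(config@proposalSd)
    for (fam in hierFams)
      for (blk in c(paste0(fam, "i"), paste0("mu", fam), paste0("sigma", fam)))
        tune[[blk]] <- log(config@proposalSd)
    batch <- new.env(); batch$num <- list(); batch$den <- list()
    batchNo <- 0L

    for (iter in seq_len(config@nIter)) {
      deathOcc <- .sampleDeathTimes(dd, params, spec)
      cnt <- .countsFromDeaths(dd, deathOcc, spec)
      inBurn <- iter <= config@burnIn
      rec <- if (inBurn) NULL else track
      ## survival
      if (!spec@hierS) {
        for (s in seq_len(dd$nsS)) {
          dieDts <- cnt$dieDt[cnt$died & cnt$dieSeason == s]
          st <- .metropolisLogit(params@S[s], tune[[paste0("S", s)]],
                                 .survTarget(sum(cnt$expoI[[s]]), dieDts))
          params@S[s] <- st$value
          .track(batch, paste0("S", s), st$acc)
          if (!inBurn) .track(track, paste0("S", s), st$acc)
        }
      }
      ## live detection
      if (!spec@hierPcl) {
        for (s in seq_len(dd$nsPcl))
          params@Pcl[s] <- stats::rbeta(1L, 1 + sum(cnt$detI[[s]]),
                                        1 + sum(cnt$misI[[s]]))
      }
      ## dead detection
      if (spec@includeDeadSubmodel && !spec@hierPcd) {
        for (s in seq_len(dd$nsPcd))
          params@Pcd[s] <- stats::rbeta(1L, 1 + sum(cnt$pcdSuccI[[s]]),
                                        1 + sum(cnt$pcdFailI[[s]]))
      }
      ## hierarchical families
      for (fam in hierFams)
        params <- .updateHierFamily(dd, cnt, params, spec, fam, tune,
                                    track = if (inBurn) batch else track)
      ## proposal adaptation during burn-in
      if (config@adapt && inBurn && iter %% 50L == 0L) {
        batchNo <- batchNo + 1L
        for (blk in names(batch$den)) {
          rate <- batch$num[[blk]] / batch$den[[blk]]
          tune[[blk]] <- min(max(tune[[blk]] +
                                   (rate - 0.35) / sqrt(batchNo), -8), 3)
        }
        batch$num <- list(); batch$den <- list()
      }
      ## record
      if (!inBurn && (iter - config@burnIn) %% config@thin == 0L) {
        row <- (iter - config@burnIn) %/% config@thin
        draws[row, chain, ] <- .flattenParams(params, spec)
        obs <- .obsLoglikFromCounts(dd, cnt, params, spec)
        devTrace[row, chain] <- if (devianceFocus == "observation") -2 * obs
          else -2 * (obs + .transLoglikFromCounts(dd, cnt, params, spec))
        idx <- cbind(seq_len(n), pmin(deathOcc - 1L, K))
        laCount[idx] <- laCount[idx] + 1
        for (fam in hierFams) {
          slotI <- paste0(fam, "i")
          cur <- slot(params, slotI)
          indivSum[[slotI]] <- if (is.null(indivSum[[slotI]])) cur
            else indivSum[[slotI]] + cur
        }
      }
    }
  }
  totKeep <- nKeep * config@nChains
  indivMeans <- lapply(indivSum[!vapply(indivSum, is.null, logical(1))],
                       function(m) m / totKeep)
  acc <- mapply(function(a, b) a / b, track$num, track$den, SIMPLIFY = FALSE)
  new("PosteriorDraws", draws = draws, paramNames = pn, devianceTrace = devTrace,
      aliveFreq = .aliveFreqFromTallies(laCount, dd, totKeep),
      individualMeans = indivMeans, acceptance = acc, config = config,
      spec = spec, devianceFocus = devianceFocus)
}

## posterior P(alive at occasion k) per individual from last-alive tallies:
## P(alive at k) = P(lastAlive >= k); pre-release cells are 0.
.aliveFreqFromTallies <- function(laCount, dd, tot) {
  K <- dd$K
  freq <- t(apply(laCount[, K:1, drop = FALSE], 1L, cumsum))[, K:1, drop = FALSE] / tot
  for (i in seq_len(nrow(freq))) if (dd$r[i] > 1L)
    freq[i, seq_len(dd$r[i] - 1L)] <- 0
  freq
}
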