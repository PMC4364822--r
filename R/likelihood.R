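#' @include model.R
NULL

#' Interval survival probability
#'
#' Survival over an interval of `dt` months at monthly survival rate `S` is
#' `S^dt`; intervals need not be whole months.
#'
#' @param S monthly survival rate in `[0, 1]`.
#' @param dt interval length in months, `> 0`.
#' @return `S^dt`.
#' @examples
#' intervalSurvival(0.999, 2)  # 0.998001
#' @export
intervalSurvival <- function(S, dt) {
  if (any(S < 0 | S > 1)) stop("S must lie in [0, 1]")
  if (any(dt <= 0)) stop("dt must be positive")
  S^dt
}

## Normal(mu, sigma) truncated to [0, 1]; log density, -Inf outside support.
.dtnorm01 <- function(x, mu, sigma, log = TRUE) {
  z <- stats::pnorm(1, mu, sigma) - stats::pnorm(0, mu, sigma)
  ld <- ifelse(x < 0 | x > 1, -Inf, stats::dnorm(x, mu, sigma, log = TRUE) - log(z))
  if (log) ld else exp(ld)
}

#' Log prior density of a parameter state
#'
#' Population probabilities and hypermeans carry Uniform(0, 1) priors;
#' random-effect SDs Uniform(0, `priorSdUpper`); individual values a
#' Normal(hypermean, SD) truncated to `[0, 1]`.  Returns `-Inf` outside the
#' support rather than erroring, so samplers can reject invalid states.
#'
#' @param params a [ParamState-class].
#' @param spec a [ModelSpec-class].
#' @return the log prior density (an additive constant applies within the
#'   support of the uniform terms).
#' @export
priorLogdensity <- function(params, spec) {
  lp <- 0
  unifTerm <- function(x, upper = 1) {
    if (!length(x)) return(0)
    if (any(x < 0 | x > upper)) -Inf else -length(x) * log(upper)
  }
  lp <- lp + unifTerm(params@S) + unifTerm(params@Pcl) + unifTerm(params@Pcd)
  lp <- lp + unifTerm(params@sigmaS, spec@priorSdUpper) +
    unifTerm(params@sigmaPcl, spec@priorSdUpper) +
    unifTerm(params@sigmaPcd, spec@priorSdUpper)
  hierTerm <- function(x, mu, sigma) {
    if (!length(x)) return(0)
    sum(.dtnorm01(x, rep(mu, each = nrow(x)), sigma))
  }
  if (spec@hierS) lp <- lp + hierTerm(params@Si, params@S, params@sigmaS)
  if (spec@hierPcl) lp <- lp + hierTerm(params@Pcli, params@Pcl, params@sigmaPcl)
  if (spec@hierPcd) lp <- lp + hierTerm(params@Pcdi, params@Pcd, params@sigmaPcd)
  lp
}

## Parameter value for family fam ("S", "Pcl", "Pcd"), individual i, season s.
.pv <- function(params, spec, fam, i, s) {
  hier <- slot(spec, paste0("hier", if (fam == "S") "S" else fam))
  if (hier) slot(params, paste0(fam, "i"))[i, s]
  else slot(params, fam)[s]
}

## Shell-availability row implied by an alive row: D[k] = 1 while the shell is
## observable.  recoveredAt is the code-2 occasion or NA.
.deadAvailRow <- function(Lrow, r, K, recoveredAt, persistence) {
  D <- integer(K)
  post <- if (r < K) (r + 1L):K else integer(0)
  deadIdx <- post[Lrow[post] == 0L]
  if (!length(deadIdx)) return(D)
  d <- deadIdx[1L]
  if (persistence == "until_recovered") {
    last <- if (is.na(recoveredAt)) K else recoveredAt
    D[d:last] <- 1L
  } else {
    D[d] <- 1L
  }
  D
}

## Complete-data log-likelihood terms for one individual row.
## Returns c(trans, obs): transition terms and observation (O_l, O_d) terms.
.rowLoglik <- function(codeRow, Lrow, Drow, r, K, i, params, spec, seas, dt) {
  cens <- which(codeRow == CODE_DEAD)
  end <- if (length(cens)) cens[1L] else K
  trans <- 0; obs <- 0
  if (r >= end) return(c(trans = 0, obs = 0))
  for (k in (r + 1L):end) {
    sS <- .pv(params, spec, "S", i, seas$S[k - 1L])
    p <- Lrow[k - 1L] * sS^dt[k - 1L]
    trans <- trans + stats::dbinom(Lrow[k], 1L, p, log = TRUE)
    ol <- as.integer(codeRow[k] == CODE_LIVE)
    obs <- obs + stats::dbinom(ol, 1L, Lrow[k] * .pv(params, spec, "Pcl", i, seas$Pcl[k]),
                               log = TRUE)
    if (spec@includeDeadSubmodel) {
      od <- as.integer(codeRow[k] == CODE_DEAD)
      obs <- obs + stats::dbinom(od, 1L, Drow[k] * .pv(params, spec, "Pcd", i, seas$Pcd[k]),
                                 log = TRUE)
    }
  }
  c(trans = trans, obs = obs)
}

.latentMatrices <- function(latent) {
  if (is(latent, "LatentStateMatrix")) list(L = latent@L, D = latent@D)
  else latent
}

#' Complete-data log-likelihood given latent states
#'
#' The sum, over individuals and post-release occasions up to any dead
#' recovery, of the Bernoulli state-transition terms
#' `L[k] ~ Bern(L[k-1] * S^dt)`, the live-observation terms
#' `O_l[k] ~ Bern(L[k] * Pcl)` and, when the dead submodel is included, the
#' dead-observation terms `O_d[k] ~ Bern(D[k] * Pcd)`.  The release occasion
#' is conditioned on and contributes no terms.  Observations impossible under
#' the supplied latent states yield `-Inf` (not an error), so samplers can
#' reject uniformly.
#'
#' @param histories a [CaptureHistorySet-class].
#' @param latent a [LatentStateMatrix-class], or a plain `list(L =, D =)` of
#'   0/1 matrices.
#' @param params a [ParamState-class].
#' @param spec a [ModelSpec-class].
#' @return the complete-data log-likelihood.
#' @export
completeDataLoglik <- function(histories, latent, params, spec) {
  histories <- .applySpecToHistories(histories, spec)
  lm <- .latentMatrices(latent)
  cal <- calendar(histories)
  seas <- .famSeasons(spec, cal)
  K <- nOccasions(histories)
  total <- 0
  for (i in seq_len(nIndividuals(histories))) {
    tt <- .rowLoglik(histories@codes[i, ], lm$L[i, ], lm$D[i, ],
                     histories@releaseOccasion[i], K, i, params, spec, seas,
                     cal@deltaT)
    total <- total + sum(tt)
  }
  total
}

#' Deviance of the observed detections
#'
#' `-2` times the log-likelihood of the observation layer (the `O_l` and `O_d`
#' Bernoulli terms) conditional on latent states and parameters — the
#' stochastic-observed-node convention under which the state-transition terms
#' of fully latent nodes do not enter the deviance.  `focus = "complete"`
#' includes the transition terms as well; the choice shifts the deviance (and
#' DIC) by a data-dependent constant, so compare models under one focus only.
#'
#' @inheritParams completeDataLoglik
#' @param focus `"observation"` (default) or `"complete"`.
#' @return the deviance; `+Inf` when an observation is impossible under the
#'   latent states.
#' @export
modelDeviance <- function(histories, latent, params, spec,
                          focus = c("observation", "complete")) {
  focus <- match.arg(focus)
  histories <- .applySpecToHistories(histories, spec)
  lm <- .latentMatrices(latent)
  cal <- calendar(histories)
  seas <- .famSeasons(spec, cal)
  K <- nOccasions(histories)
  obs <- 0; trans <- 0
  for (i in seq_len(nIndividuals(histories))) {
    tt <- .rowLoglik(histories@codes[i, ], lm$L[i, ], lm$D[i, ],
                     histories@releaseOccasion[i], K, i, params, spec, seas,
                     cal@deltaT)
    obs <- obs + tt[["obs"]]; trans <- trans + tt[["trans"]]
  }
  if (focus == "observation") -2 * obs else -2 * (obs + trans)
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Observed-data log-likelihood by death-time marginalization
#'
#' Marginalizes the latent alive/dead trajectory analytically: because alive
#' states are non-increasing, each individual's latent path is indexed by its
#' death interval, so the observed-data likelihood is a sum over the death
#' times consistent with the record (including survival throughout).  Exact
#' for any model variant; linear in the number of occasions.
#'
#' @inheritParams completeDataLoglik
#' @return the observed-data log-likelihood.
#' @export
marginalLoglik <- function(histories, params, spec) {
  histories <- .applySpecToHistories(histories, spec)
  cal <- calendar(histories)
  seas <- .famSeasons(spec, cal)
  dt <- cal@deltaT
  K <- nOccasions(histories)
  single <- spec@shellPersistence == "single_occasion"
  total <- 0
  for (i in seq_len(nIndividuals(histories))) {
    row <- histories@codes[i, ]
    r <- histories@releaseOccasion[i]
    recAt <- which(row == CODE_DEAD)
    recovered <- length(recAt) == 1L
    cens <- if (recovered) recAt else K
    live <- which(row == CODE_LIVE)
    tlast <- max(live)
    ## cumulative pieces over occasions r+1 .. k
    survC <- 0; detC <- 0
    cumSurv <- numeric(K); cumDet <- numeric(K)  # index k = value through k
    cumSurv[r] <- 0; cumDet[r] <- 0
    if (r < K) for (k in (r + 1L):K) {
      sS <- .pv(params, spec, "S", i, seas$S[k - 1L])
      survC <- survC + dt[k - 1L] * log(sS)
      pcl <- .pv(params, spec, "Pcl", i, seas$Pcl[k])
      if (k <= cens && row[k] != CODE_DEAD)
        detC <- detC + if (row[k] == CODE_LIVE) log(pcl) else log1p(-pcl)
      cumSurv[k] <- survC; cumDet[k] <- detC
    }
    deadTail <- function(d) {  # shell-observation terms for death at occasion d
      if (!spec@includeDeadSubmodel) return(0)
      if (recovered) {
        pcdRec <- .pv(params, spec, "Pcd", i, seas$Pcd[cens])
        if (single) {
          if (d != cens) return(-Inf)
          return(log(pcdRec))
        }
        misses <- if (d <= cens - 1L) vapply(d:(cens - 1L), function(k)
          log1p(-.pv(params, spec, "Pcd", i, seas$Pcd[k])), numeric(1)) else numeric(0)
        sum(misses) + log(pcdRec)
      } else {
        if (single) return(log1p(-.pv(params, spec, "Pcd", i, seas$Pcd[d])))
        sum(vapply(d:K, function(k)
          log1p(-.pv(params, spec, "Pcd", i, seas$Pcd[k])), numeric(1)))
      }
    }
    cand <- numeric(0)
    dRange <- if (tlast + 1L <= cens) (tlast + 1L):cens else integer(0)
    for (d in dRange) {  # death in interval (d-1, d]
      sS <- .pv(params, spec, "S", i, seas$S[d - 1L])
      cand <- c(cand, cumSurv[d - 1L] + cumDet[d - 1L] +
                  log1p(-sS^dt[d - 1L]) + deadTail(d))
    }
    if (!recovered) cand <- c(cand, cumSurv[K] + cumDet[K])  # survived throughout
    total <- total + .logsumexp(cand)
  }
  total
}

#' Observed-data log-likelihood by brute-force latent enumeration
#'
#' Sums `exp(completeDataLoglik)` over every binary alive sequence for every
#' individual (invalid sequences contribute zero through their `-Inf`
#' transition terms), with shell availability implied by the alive path.  An
#' independent oracle for [marginalLoglik()]; cost is of order `n * 2^K`, so a
#' size guard refuses large instances.
#'
#' @inheritParams completeDataLoglik
#' @param maxCells refuse instances with `n * 2^K` above this bound\n#'   (default 2^14, i.e. a handful of individuals over a handful of occasions).
#' @return the observed-data log-likelihood.
#' @export
enumerateMarginalLoglik <- function(histories, params, spec, maxCells = 2^14) {
  histories <- .applySpecToHistories(histories, spec)
  cal <- calendar(histories)
  seas <- .famSeasons(spec, cal)
  K <- nOccasions(histories)
  n <- nIndividuals(histories)
  if (n * 2^K > maxCells)
    stop("instance too large to enumerate (n * 2^K = ", n * 2^K, ")")
  total <- 0
  for (i in seq_len(n)) {
    row <- histories@codes[i, ]
    r <- histories@releaseOccasion[i]
    recAt <- which(row == CODE_DEAD)
    recoveredAt <- if (length(recAt)) recAt[1L] else NA_integer_
    cens <- if (length(recAt)) recAt[1L] else K  # censored after recovery
    span <- cens - r
    terms <- numeric(0)
    for (mask in 0:(2^span - 1L)) {
      Lrow <- integer(K)
      Lrow[r] <- 1L
      if (span > 0L)
        Lrow[(r + 1L):cens] <- as.integer(intToBits(mask)[seq_len(span)] == 1)
      Drow <- .deadAvailRow(Lrow, r, K, recoveredAt, spec@shellPersistence)
      tt <- .rowLoglik(row, Lrow, Drow, r, K, i, params, spec, seas, cal@deltaT)
      terms <- c(terms, sum(tt))
    }
    total <- total + .logsumexp(terms)
  }
  total
}
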