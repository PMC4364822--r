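#' @include likelihood.R
NULL

#' Convert between death times and latent state matrices
#'
#' Because the alive state is non-increasing, an individual's latent
#' trajectory is fully indexed by its death occasion: the first occasion at
#' which it is dead, or `K + 1` if it survives the study.  `latentFromDeathTimes`
#' expands death occasions to the `L`/`D` matrices (shell availability per the
#' spec's `shellPersistence`); `deathTimesFromLatent` inverts it.
#'
#' @param deathOcc integer vector of death occasions (`K + 1` = survived).
#' @param histories a [CaptureHistorySet-class] (for release occasions and
#'   recovery records).
#' @param spec a [ModelSpec-class].
#' @param latent a [LatentStateMatrix-class].
#' @return `latentFromDeathTimes`: a [LatentStateMatrix-class];
#'   `deathTimesFromLatent`: an integer vector.
#' @export
latentFromDeathTimes <- function(deathOcc, histories, spec) {
  K <- nOccasions(histories)
  n <- nIndividuals(histories)
  r <- histories@releaseOccasion
  L <- matrix(0L, n, K); D <- matrix(0L, n, K)
  for (i in seq_len(n)) {
    d <- deathOcc[i]
    lastAlive <- min(d - 1L, K)
    L[i, r[i]:lastAlive] <- 1L
    if (d <= K) {
      recAt <- which(histories@codes[i, ] == CODE_DEAD)
      if (spec@shellPersistence == "until_recovered") {
        last <- if (length(recAt)) recAt[1L] else K
        D[i, d:last] <- 1L
      } else D[i, d] <- 1L
    }
  }
  new("LatentStateMatrix", L = L, D = D, releaseOccasion = r)
}

#' @rdname latentFromDeathTimes
#' @export
deathTimesFromLatent <- function(latent) {
  K <- ncol(latent@L)
  vapply(seq_len(nrow(latent@L)), function(i) {
    post <- (latent@releaseOccasion[i]):K
    dead <- post[latent@L[i, post] == 0L]
    if (length(dead)) dead[1L] else K + 1L
  }, integer(1))
}

#' Initialize latent states consistent with the observations
#'
#' Individuals are taken alive through their last live detection; recovered
#' individuals die in the interval immediately preceding the recovery;
#' unconstrained tails are filled alive.  Deterministic (the optional seed is
#' accepted for interface symmetry with the stochastic sampler steps).
#'
#' @param histories a [CaptureHistorySet-class].
#' @param spec a [ModelSpec-class].
#' @param seed ignored; initialization is deterministic.
#' @return a [LatentStateMatrix-class].
#' @export
initLatentStates <- function(histories, spec, seed = NULL) {
  histories <- .applySpecToHistories(histories, spec)
  K <- nOccasions(histories)
  deathOcc <- vapply(seq_len(nIndividuals(histories)), function(i) {
    recAt <- which(histories@codes[i, ] == CODE_DEAD)
    if (length(recAt)) recAt[1L] else K + 1L
  }, integer(1))
  latentFromDeathTimes(deathOcc, histories, spec)
}

#' Gibbs update of the latent alive/dead trajectories
#'
#' Resamples every individual's unobserved post-last-detection trajectory from
#' its exact full conditional by enumerating the monotone death-time support
#' (a categorical draw per individual); cells constrained by observations are
#' unchanged.  Uses R's global random number stream.
#'
#' @param latent current [LatentStateMatrix-class] (its observation-constrained
#'   cells determine nothing here; the draw is a fresh exact Gibbs sample).
#' @param histories a [CaptureHistorySet-class].
#' @param params a [ParamState-class].
#' @param spec a [ModelSpec-class].
#' @return a new [LatentStateMatrix-class].
#' @export
updateLatentStates <- function(latent, histories, params, spec) {
  histories <- .applySpecToHistories(histories, spec)
  dd <- .designData(histories, spec)
  deathOcc <- .sampleDeathTimes(dd, params, spec)
  latentFromDeathTimes(deathOcc, histories, spec)
}
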