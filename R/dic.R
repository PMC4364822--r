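#' @include diagnostics.R
NULL

## Rebuild a ParamState from pooled posterior means of the flattened draws
## (inverse of .flattenParams) plus the pooled means of individual values.
.unflattenParams <- function(vals, spec, n, indivMeans) {
  vals <- unname(vals)
  pos <- 0L
  take <- function(k) {
    out <- vals[pos + seq_len(k)]
    pos <<- pos + k
    out
  }
  ns <- function(seasonal) if (seasonal) 2L else 1L
  S <- take(ns(spec@seasonalS))
  sigmaS <- if (spec@hierS) take(1L) else numeric(0)
  Pcl <- take(ns(spec@seasonalPcl))
  sigmaPcl <- if (spec@hierPcl) take(1L) else numeric(0)
  Pcd <- numeric(0); sigmaPcd <- numeric(0)
  if (spec@includeDeadSubmodel) {
    Pcd <- take(ns(spec@seasonalPcd))
    if (spec@hierPcd) sigmaPcd <- take(1L)
  }
  empty <- matrix(numeric(0), 0L, 0L)
  new("ParamState", S = S, Pcl = Pcl, Pcd = Pcd,
      sigmaS = sigmaS, sigmaPcl = sigmaPcl, sigmaPcd = sigmaPcd,
      Si = indivMeans$Si %||% empty,
      Pcli = indivMeans$Pcli %||% empty,
      Pcdi = indivMeans$Pcdi %||% empty)
}

#' Deviance information criterion of a fitted model
#'
#' `dbar` is the mean of the recorded deviance trace; `dhat` plugs the pooled
#' posterior means of the parameters (and, for the latent-conditional
#' observation terms, the posterior-modal latent states, taken cell-wise from
#' the pooled alive frequencies) into the same deviance; then
#' `pD = dbar - dhat` and `DIC = dbar + pD` exactly.
#'
#' @param draws a [PosteriorDraws-class].
#' @param histories the [CaptureHistorySet-class] that was fitted.
#' @param spec the [ModelSpec-class] (default: the one stored in `draws`).
#' @return a [DicResult-class].
#' @export
dic <- function(draws, histories, spec = draws@spec) {
  if (!length(draws@devianceTrace) || anyNA(draws@devianceTrace))
    stop("no deviance trace available")
  histories <- .applySpecToHistories(histories, spec)
  dd <- .designData(histories, spec)
  dbar <- mean(draws@devianceTrace)
  means <- apply(draws@draws, 3L, mean)
  params <- .unflattenParams(means, spec, dd$n, draws@individualMeans)
  ## posterior-modal latent state, cell-wise; alive frequencies are monotone
  ## non-increasing per row, so the cell-wise mode is a valid monotone path
  lastAliveHat <- vapply(seq_len(dd$n), function(i) {
    alive <- which(draws@aliveFreq[i, ] >= 0.5)
    max(alive)
  }, integer(1))
  deathOccHat <- ifelse(lastAliveHat >= dd$K & !dd$recovered, dd$K + 1L,
                        lastAliveHat + 1L)
  cnt <- .countsFromDeaths(dd, deathOccHat, spec)
  obs <- .obsLoglikFromCounts(dd, cnt, params, spec)
  dhat <- if (draws@devianceFocus == "observation") -2 * obs
    else -2 * (obs + .transLoglikFromCounts(dd, cnt, params, spec))
  pD <- dbar - dhat
  new("DicResult", dbar = dbar, dhat = dhat, pD = pD, dic = dbar + pD,
      modelName = spec@name, includesDead = spec@includeDeadSubmodel,
      focus = draws@devianceFocus)
}

#' Rank fitted models by DIC with support categories
#'
#' Sorts by DIC and applies the 5/10-unit support rules: models within 5 DIC
#' units of the best are well supported, within 5-10 units substantially less
#' supported, and more than 10 units away definitely excluded.  Models fitted
#' with and without the dead-recovery data have different likelihoods, so
#' mixing dead-inclusive and dead-exclusive results in one ranking is an
#' error — compare the model 4 family separately.
#'
#' @param results a list of [DicResult-class] objects (one comparability
#'   group).
#' @return a data.frame sorted by DIC with columns `model`, `dic`, `dbar`,
#'   `pD`, `delta` and `support`.
#' @export
compareModels <- function(results) {
  if (is(results, "DicResult")) results <- list(results)
  if (!length(results)) stop("no model results to compare")
  stopifnot(all(vapply(results, is, logical(1), "DicResult")))
  incl <- vapply(results, function(r) r@includesDead, logical(1))
  if (length(unique(incl)) > 1L)
    stop("dead-inclusive and dead-exclusive models have different data ",
         "likelihoods and cannot be ranked together")
  foci <- unique(vapply(results, function(r) r@focus, character(1)))
  if (length(foci) > 1L)
    stop("all results must use the same deviance focus")
  df <- data.frame(
    model = vapply(results, function(r) r@modelName, character(1)),
    dic = vapply(results, function(r) r@dic, numeric(1)),
    dbar = vapply(results, function(r) r@dbar, numeric(1)),
    pD = vapply(results, function(r) r@pD, numeric(1)),
    stringsAsFactors = FALSE)
  df <- df[order(df$dic), , drop = FALSE]
  df$delta <- df$dic - df$dic[1L]
  df$support <- cut(df$delta, c(-Inf, 5, 10, Inf),
                    labels = c("well-supported", "less-supported", "excluded"))
  rownames(df) <- NULL
  df
}
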