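#' @include reconstruct.R
NULL

.presets <- list(
  "model1"   = list(seasonal = c(S = TRUE,  Pcl = TRUE,  Pcd = TRUE),  dead = TRUE,
                    hier = c(S = FALSE, Pcl = FALSE, Pcd = FALSE)),
  "model1-1" = list(seasonal = c(S = TRUE,  Pcl = TRUE,  Pcd = TRUE),  dead = TRUE,
                    hier = c(S = TRUE,  Pcl = TRUE,  Pcd = TRUE)),
  "model2"   = list(seasonal = c(S = FALSE, Pcl = FALSE, Pcd = TRUE),  dead = TRUE,
                    hier = c(S = FALSE, Pcl = FALSE, Pcd = FALSE)),
  "model2-1" = list(seasonal = c(S = FALSE, Pcl = FALSE, Pcd = TRUE),  dead = TRUE,
                    hier = c(S = FALSE, Pcl = FALSE, Pcd = TRUE)),
  "model3"   = list(seasonal = c(S = FALSE, Pcl = FALSE, Pcd = FALSE), dead = TRUE,
                    hier = c(S = FALSE, Pcl = FALSE, Pcd = FALSE)),
  "model3-1" = list(seasonal = c(S = FALSE, Pcl = FALSE, Pcd = FALSE), dead = TRUE,
                    hier = c(S = TRUE,  Pcl = TRUE,  Pcd = TRUE)),
  "model4"   = list(seasonal = c(S = FALSE, Pcl = FALSE, Pcd = FALSE), dead = FALSE,
                    hier = c(S = FALSE, Pcl = FALSE, Pcd = FALSE)),
  "model4-1" = list(seasonal = c(S = FALSE, Pcl = FALSE, Pcd = FALSE), dead = FALSE,
                    hier = c(S = TRUE,  Pcl = TRUE,  Pcd = FALSE))
)

#' Model variants of the joint live-recapture / dead-recovery model
#'
#' The eight presets combine three structural choices:
#'
#' * seasonality (summer/winter values) of monthly survival `S`, live
#'   detection `Pcl`, and dead detection `Pcd`: all three in model 1; only
#'   `Pcd` in model 2; none in models 3 and 4;
#' * the dead-recovery submodel: included everywhere except models 4/4-1,
#'   which drop the dead-mussel data entirely;
#' * truncated-normal individual random effects (`-1` variants): on all
#'   parameters of the corresponding base model except model 2-1, where only
#'   `Pcd` carries individual variation.
#'
#' @param name preset name (`"model1"`, `"model1-1"`, ..., `"model4-1"`), or a
#'   custom label when structural flags are given explicitly.
#' @param seasonalS,seasonalPcl,seasonalPcd,includeDeadSubmodel,hierS,hierPcl,hierPcd
#'   explicit structure, overriding the preset.
#' @param shellPersistence `"until_recovered"` (default: a dead individual's
#'   shell remains detectable at every later occasion until first recovered)
#'   or `"single_occasion"`.
#' @param priorSdUpper upper bound of the Uniform prior on random-effect SDs
#'   (default 0.5).
#' @return a [ModelSpec-class].
#' @examples
#' modelSpec("model3")
#' modelSpec("custom", seasonalS = TRUE, includeDeadSubmodel = FALSE)
#' @export
modelSpec <- function(name = "model3",
                      seasonalS = NULL, seasonalPcl = NULL, seasonalPcd = NULL,
                      includeDeadSubmodel = NULL,
                      hierS = NULL, hierPcl = NULL, hierPcd = NULL,
                      shellPersistence = "until_recovered",
                      priorSdUpper = 0.5) {
  p <- .presets[[name]]
  if (is.null(p)) {
    if (is.null(includeDeadSubmodel) && is.null(seasonalS) && is.null(hierS))
      stop("unknown model preset: ", name, " (presets: ",
           paste(names(.presets), collapse = ", "), ")")
    p <- list(seasonal = c(S = FALSE, Pcl = FALSE, Pcd = FALSE), dead = TRUE,
              hier = c(S = FALSE, Pcl = FALSE, Pcd = FALSE))
  }
  pickFlag <- function(x, def) if (is.null(x)) def else isTRUE(x)
  dead <- pickFlag(includeDeadSubmodel, p$dead)
  new("ModelSpec", name = name,
      seasonalS = pickFlag(seasonalS, p$seasonal[["S"]]),
      seasonalPcl = pickFlag(seasonalPcl, p$seasonal[["Pcl"]]),
      seasonalPcd = if (dead) pickFlag(seasonalPcd, p$seasonal[["Pcd"]]) else FALSE,
      includeDeadSubmodel = dead,
      hierS = pickFlag(hierS, p$hier[["S"]]),
      hierPcl = pickFlag(hierPcl, p$hier[["Pcl"]]),
      hierPcd = if (dead) pickFlag(hierPcd, p$hier[["Pcd"]]) else FALSE,
      shellPersistence = shellPersistence,
      priorSdUpper = priorSdUpper)
}

#' @rdname modelSpec
#' @export
modelPresets <- function() names(.presets)

.isHier <- function(spec) spec@hierS || spec@hierPcl || spec@hierPcd

.nSeason <- function(seasonal) if (seasonal) 2L else 1L

#' Construct a parameter state for a model specification
#'
#' Lengths follow the model specification: seasonal parameters have a summer
#' and a winter value, pooled parameters one.  For hierarchical parameters the `S`/`Pcl`/
#' `Pcd` slots hold the hypermeans, `sigma*` the shared random-effect SD, and
#' `Si`/`Pcli`/`Pcdi` the per-individual values (`n` rows; initialized at the
#' hypermean when not supplied).
#'
#' @param spec a [ModelSpec-class].
#' @param S,Pcl,Pcd population values or hypermeans (recycled per season).
#' @param sigmaS,sigmaPcl,sigmaPcd random-effect SDs (hierarchical parameters).
#' @param n number of individuals (needed for hierarchical specs).
#' @param Si,Pcli,Pcdi optional per-individual value matrices.
#' @return a [ParamState-class].
#' @export
paramState <- function(spec, S = 0.99, Pcl = 0.9, Pcd = 0.5,
                       sigmaS = 0.05, sigmaPcl = 0.05, sigmaPcd = 0.05,
                       n = 0L, Si = NULL, Pcli = NULL, Pcdi = NULL) {
  expand <- function(x, seasonal) rep_len(x, .nSeason(seasonal))
  S <- expand(S, spec@seasonalS)
  Pcl <- expand(Pcl, spec@seasonalPcl)
  Pcd <- if (spec@includeDeadSubmodel) expand(Pcd, spec@seasonalPcd) else numeric(0)
  indiv <- function(hier, mu, given) {
    if (!hier) return(matrix(numeric(0), 0L, 0L))
    if (!is.null(given)) return(matrix(as.numeric(given), nrow = n))
    matrix(rep(mu, each = n), nrow = n)
  }
  new("ParamState", S = S, Pcl = Pcl, Pcd = Pcd,
      sigmaS = if (spec@hierS) sigmaS else numeric(0),
      sigmaPcl = if (spec@hierPcl) sigmaPcl else numeric(0),
      sigmaPcd = if (spec@hierPcd) sigmaPcd else numeric(0),
      Si = indiv(spec@hierS, S, Si),
      Pcli = indiv(spec@hierPcl, Pcl, Pcli),
      Pcdi = indiv(spec@hierPcd, Pcd, Pcdi))
}

#' Parameter labels of the population-level draws of a model
#'
#' @param spec a [ModelSpec-class].
#' @return character vector of labels, e.g. `"S"`, `"Pcl[summer]"`, `"mu_S"`,
#'   `"sigma_S"`.
#' @export
specParamNames <- function(spec) {
  lab <- function(base, seasonal, hier) {
    base2 <- if (hier) paste0("mu_", base) else base
    out <- if (seasonal) paste0(base2, c("[summer]", "[winter]")) else base2
    if (hier) out <- c(out, paste0("sigma_", base))
    out
  }
  c(lab("S", spec@seasonalS, spec@hierS),
    lab("Pcl", spec@seasonalPcl, spec@hierPcl),
    if (spec@includeDeadSubmodel) lab("Pcd", spec@seasonalPcd, spec@hierPcd))
}

## Flatten the population-level values of a ParamState in specParamNames order.
.flattenParams <- function(params, spec) {
  c(params@S, if (spec@hierS) params@sigmaS,
    params@Pcl, if (spec@hierPcl) params@sigmaPcl,
    if (spec@includeDeadSubmodel) c(params@Pcd, if (spec@hierPcd) params@sigmaPcd))
}

## Season index vectors for each parameter family (all-1 when pooled).
.famSeasons <- function(spec, cal) {
  K <- nOccasions(cal)
  list(
    S = if (spec@seasonalS) cal@intervalSeason else rep(1L, K - 1L),
    Pcl = if (spec@seasonalPcl) cal@occasionSeason else rep(1L, K),
    Pcd = if (spec@seasonalPcd) cal@occasionSeason else rep(1L, K)
  )
}

## Dead-exclusive specs discard the dead-recovery records: code 2 and
## post-recovery cells become plain non-detections.
.applySpecToHistories <- function(set, spec) {
  if (spec@includeDeadSubmodel) return(set)
  cm <- set@codes
  cm[cm == CODE_DEAD | cm == CODE_POST] <- CODE_NONE
  captureHistorySet(cm, set@releaseOccasion, set@calendar, set@individualId)
}
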