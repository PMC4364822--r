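#' @import methods
NULL

setOldClass("Date")

## Integer codes used in capture-history matrices.  A release is recorded as a
## detection ("the 0th capture") but contributes no detection-probability term.
CODE_PRE <- -1L  # before the individual's release occasion
CODE_NONE <- 0L  # at risk, not detected
CODE_LIVE <- 1L  # detected alive
CODE_DEAD <- 2L  # recovered dead (shell found); individual censored afterwards
CODE_POST <- 3L  # after dead recovery

SEASON_SUMMER <- 1L
SEASON_WINTER <- 2L

#' OccasionCalendar: the sampling-occasion calendar of a staggered-entry design
#'
#' Holds the ordered occasion dates, the cohort age (months) at each occasion,
#' the inter-occasion intervals `deltaT` (months, taken as differences of the
#' age row rather than recomputed from dates), and a two-season labelling
#' (summer = 1, winter = 2) for both occasions and intervals.
#'
#' @slot dates ordered occasion dates (length K).
#' @slot agesMonths cohort age in months at each occasion (length K).
#' @slot deltaT months between adjacent occasions (length K - 1).
#' @slot occasionSeason season label per occasion, 1 = summer, 2 = winter.
#' @slot intervalSeason season label per interval (length K - 1).
#' @exportClass OccasionCalendar
setClass("OccasionCalendar",
  representation(
    dates = "Date",
    agesMonths = "numeric",
    deltaT = "numeric",
    occasionSeason = "integer",
    intervalSeason = "integer"
  )
)

setValidity("OccasionCalendar", function(object) {
  K <- length(object@dates)
  msg <- character()
  if (length(object@agesMonths) != K)
    msg <- c(msg, "agesMonths must have one entry per occasion")
  if (length(object@deltaT) != K - 1L)
    msg <- c(msg, "deltaT must have K - 1 entries")
  if (length(object@occasionSeason) != K || length(object@intervalSeason) != K - 1L)
    msg <- c(msg, "season labels must cover every occasion and interval")
  if (K >= 2L && any(diff(as.numeric(object@dates)) <= 0))
    msg <- c(msg, "occasion dates must be strictly increasing")
  if (any(object@deltaT <= 0))
    msg <- c(msg, "deltaT must be positive (zero-length interval)")
  if (any(abs(object@deltaT - diff(object@agesMonths)) > 1e-8))
    msg <- c(msg, "deltaT must equal successive differences of agesMonths")
  if (!all(c(object@occasionSeason, object@intervalSeason) %in% c(1L, 2L)))
    msg <- c(msg, "season labels must be 1 (summer) or 2 (winter)")
  if (length(msg)) msg else TRUE
})

#' CohortTable: release cohorts of a staggered-entry design
#'
#' @slot releaseOccasion occasion index at which each cohort was released.
#' @slot cohortSize number of individuals per cohort.
#' @exportClass CohortTable
setClass("CohortTable",
  representation(releaseOccasion = "integer", cohortSize = "integer")
)

setValidity("CohortTable", function(object) {
  msg <- character()
  if (length(object@releaseOccasion) != length(object@cohortSize))
    msg <- c(msg, "releaseOccasion and cohortSize must have equal length")
  if (any(object@cohortSize < 0L)) msg <- c(msg, "cohort sizes must be non-negative")
  if (any(object@releaseOccasion < 1L)) msg <- c(msg, "release occasions must be >= 1")
  if (length(msg)) msg else TRUE
})

#' CaptureHistorySet: coded detection matrix with per-individual releases
#'
#' One row per tagged individual, one column per sampling occasion.  Cell codes:
#' -1 before release (written `.` on file), 0 at risk but not detected, 1
#' detected alive (the release occasion itself is coded 1), 2 recovered dead,
#' 3 after a dead recovery (written `x` on file; the individual is censored).
#'
#' @slot codes integer matrix, n x K.
#' @slot releaseOccasion occasion index of each individual's release.
#' @slot individualId unique label per row.
#' @slot calendar the [OccasionCalendar-class] the columns refer to.
#' @exportClass CaptureHistorySet
setClass("CaptureHistorySet",
  representation(
    codes = "matrix",
    releaseOccasion = "integer",
    individualId = "character",
    calendar = "OccasionCalendar"
  )
)

setValidity("CaptureHistorySet", function(object) {
  codes <- object@codes
  n <- nrow(codes); K <- ncol(codes)
  msg <- character()
  if (length(object@releaseOccasion) != n || length(object@individualId) != n)
    msg <- c(msg, "releaseOccasion and individualId must have one entry per row")
  if (anyDuplicated(object@individualId))
    msg <- c(msg, "individual ids must be unique")
  if (length(object@calendar@dates) != K)
    msg <- c(msg, "calendar must have one occasion per column")
  if (!all(codes %in% c(CODE_PRE, CODE_NONE, CODE_LIVE, CODE_DEAD, CODE_POST)))
    msg <- c(msg, "codes must be in {-1, 0, 1, 2, 3}")
  if (n > 0L) {
    r <- object@releaseOccasion
    if (any(r < 1L | r > K)) {
      msg <- c(msg, "release occasions must be valid column indices")
    } else {
      bad <- integer()
      for (i in seq_len(n)) {
        row <- codes[i, ]
        ok <- TRUE
        if (r[i] > 1L && !all(row[seq_len(r[i] - 1L)] == CODE_PRE)) ok <- FALSE
        if (any(row[r[i]:K] == CODE_PRE)) ok <- FALSE
        if (row[r[i]] != CODE_LIVE) ok <- FALSE
        dead <- which(row == CODE_DEAD)
        if (length(dead) > 1L) ok <- FALSE
        if (length(dead) == 1L) {
          if (dead < K && !all(row[(dead + 1L):K] == CODE_POST)) ok <- FALSE
          if (dead == r[i]) ok <- FALSE
        }
        post <- which(row == CODE_POST)
        if (length(post) && (length(dead) == 0L || min(post) <= dead)) ok <- FALSE
        if (!ok) bad <- c(bad, i)
      }
      if (length(bad))
        msg <- c(msg, paste0("invalid capture-history rows: ",
                             paste(object@individualId[bad], collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' AggregateCounts: per-occasion release and recapture tallies
#'
#' The three numeric rows of a release/recapture summary table: individuals
#' released, live recaptures of previously released individuals, and dead
#' recoveries, per sampling occasion.
#'
#' @slot released releases per occasion.
#' @slot liveRecaptured live recaptures per occasion (releases at the same
#'   occasion are not counted; entry 1 is always 0 in a design with no earlier
#'   releases).
#' @slot deadRecaptured dead recoveries per occasion.
#' @exportClass AggregateCounts
setClass("AggregateCounts",
  representation(released = "integer", liveRecaptured = "integer",
                 deadRecaptured = "integer")
)

setValidity("AggregateCounts", function(object) {
  K <- length(object@released)
  msg <- character()
  if (length(object@liveRecaptured) != K || length(object@deadRecaptured) != K)
    msg <- c(msg, "the three count vectors must have equal length")
  if (any(c(object@released, object@liveRecaptured, object@deadRecaptured) < 0L))
    msg <- c(msg, "counts must be non-negative")
  prior <- c(0L, cumsum(object@released)[-K])
  if (any(object@liveRecaptured > prior))
    msg <- c(msg, "live recaptures cannot exceed cumulative releases before the occasion")
  if (length(msg)) msg else TRUE
})

#' ModelSpec: which parameters are seasonal, hierarchical, and whether dead
#' recoveries are modelled
#'
#' The eight named presets (`"model1"`, `"model1-1"`, `"model2"`, `"model2-1"`,
#' `"model3"`, `"model3-1"`, `"model4"`, `"model4-1"`) combine two-season
#' structure, the dead-recovery submodel, and truncated-normal individual
#' random effects; see [modelSpec()].
#'
#' @slot name preset or user label.
#' @slot seasonalS,seasonalPcl,seasonalPcd season-specific monthly survival /
#'   live-detection / dead-detection.
#' @slot includeDeadSubmodel whether dead recoveries contribute to the likelihood.
#' @slot hierS,hierPcl,hierPcd individual random effects on each parameter.
#' @slot shellPersistence `"until_recovered"` (a shell stays detectable until
#'   first recovered) or `"single_occasion"` (detectable only at the first
#'   occasion after death).
#' @slot priorSdUpper upper bound of the Uniform prior on random-effect SDs.
#' @exportClass ModelSpec
setClass("ModelSpec",
  representation(
    name = "character",
    seasonalS = "logical", seasonalPcl = "logical", seasonalPcd = "logical",
    includeDeadSubmodel = "logical",
    hierS = "logical", hierPcl = "logical", hierPcd = "logical",
    shellPersistence = "character",
    priorSdUpper = "numeric"
  )
)

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (!object@shellPersistence %in% c("until_recovered", "single_occasion"))
    msg <- c(msg, "shellPersistence must be 'until_recovered' or 'single_occasion'")
  if (!object@includeDeadSubmodel && (object@seasonalPcd || object@hierPcd))
    msg <- c(msg, "Pcd structure requires the dead submodel")
  if (object@priorSdUpper <= 0)
    msg <- c(msg, "priorSdUpper must be positive")
  if (length(msg)) msg else TRUE
})

#' ParamState: values of survival and detection parameters
#'
#' Population-level (or, for hierarchical parameters, hypermean) values of the
#' monthly survival rate `S`, live-detection probability `Pcl` and
#' dead-detection probability `Pcd`, each of length 1 (pooled) or 2
#' (summer, winter); random-effect SDs (length 1, shared across seasons); and
#' per-individual values (n x number-of-seasons matrices) for hierarchical
#' parameters.
#'
#' @slot S,Pcl,Pcd population values or hypermeans, by season.
#' @slot sigmaS,sigmaPcl,sigmaPcd random-effect SDs (length 0 when the
#'   parameter is not hierarchical).
#' @slot Si,Pcli,Pcdi per-individual values (0 x 0 when not hierarchical).
#' @exportClass ParamState
setClass("ParamState",
  representation(
    S = "numeric", Pcl = "numeric", Pcd = "numeric",
    sigmaS = "numeric", sigmaPcl = "numeric", sigmaPcd = "numeric",
    Si = "matrix", Pcli = "matrix", Pcdi = "matrix"
  )
)

setValidity("ParamState", function(object) {
  msg <- character()
  probs <- c(object@S, object@Pcl, object@Pcd,
             object@Si, object@Pcli, object@Pcdi)
  if (length(probs) && (any(probs < 0) || any(probs > 1)))
    msg <- c(msg, "all probabilities must lie in [0, 1]")
  sds <- c(object@sigmaS, object@sigmaPcl, object@sigmaPcd)
  if (length(sds) && any(sds < 0)) msg <- c(msg, "random-effect SDs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' LatentStateMatrix: augmented alive and shell-available indicators
#'
#' `L[i, k] = 1` while individual i is alive at occasion k (1 at release,
#' non-increasing afterwards); `D[i, k] = 1` while its shell is available for
#' dead recovery.  Cells before release are 0 in both.
#'
#' @slot L alive indicator matrix (integer 0/1).
#' @slot D dead-shell-available indicator matrix (integer 0/1).
#' @slot releaseOccasion per-individual release occasion.
#' @exportClass LatentStateMatrix
setClass("LatentStateMatrix",
  representation(L = "matrix", D = "matrix", releaseOccasion = "integer")
)

setValidity("LatentStateMatrix", function(object) {
  L <- object@L; D <- object@D; r <- object@releaseOccasion
  msg <- character()
  if (!identical(dim(L), dim(D)))
    msg <- c(msg, "L and D must have identical dimensions")
  if (length(r) != nrow(L))
    msg <- c(msg, "releaseOccasion must have one entry per row")
  if (!all(L %in% c(0L, 1L)) || !all(D %in% c(0L, 1L)))
    msg <- c(msg, "L and D must be 0/1")
  if (any(L == 1L & D == 1L))
    msg <- c(msg, "an individual cannot be alive and shell-available at once")
  if (nrow(L) > 0L && length(r) == nrow(L)) {
    K <- ncol(L)
    for (i in seq_len(nrow(L))) {
      seg <- L[i, r[i]:K]
      if (seg[1L] != 1L || any(diff(seg) > 0L))
        msg <- c(msg, sprintf("row %d: L must be 1 at release and non-increasing", i))
      if (r[i] > 1L && any(L[i, seq_len(r[i] - 1L)] == 1L))
        msg <- c(msg, sprintf("row %d: alive before release", i))
      if (any(D[i, seq_len(r[i])] == 1L))
        msg <- c(msg, sprintf("row %d: shell available at or before release", i))
    }
  }
  if (length(msg)) msg else TRUE
})

#' McmcConfig: chain lengths, thinning, seeding and proposal tuning
#'
#' @slot nChains number of independent chains (>= 2 for convergence diagnostics).
#' @slot nIter iterations per chain.
#' @slot burnIn discarded initial iterations per chain.
#' @slot thin keep-every interval applied after burn-in.
#' @slot seed base seed; chain c uses `seed + c - 1`.
#' @slot proposalSd initial logit-scale random-walk SD for Metropolis blocks.
#' @slot adapt adapt proposal SDs during burn-in (frozen afterwards).
#' @exportClass McmcConfig
setClass("McmcConfig",
  representation(nChains = "integer", nIter = "integer", burnIn = "integer",
                 thin = "integer", seed = "integer", proposalSd = "numeric",
                 adapt = "logical")
)

setValidity("McmcConfig", function(object) {
  msg <- character()
  if (object@nChains < 1L) msg <- c(msg, "nChains must be >= 1")
  if (object@burnIn >= object@nIter) msg <- c(msg, "burnIn must be < nIter")
  if (object@thin < 1L) msg <- c(msg, "thin must be >= 1")
  if (object@proposalSd <= 0) msg <- c(msg, "proposalSd must be positive")
  if (length(msg)) msg else TRUE
})

#' PosteriorDraws: retained MCMC output of a fitted model
#'
#' @slot draws array retained-iteration x chain x parameter.
#' @slot paramNames parameter labels (third array dimension).
#' @slot devianceTrace observation-layer deviance per retained iteration x chain.
#' @slot aliveFreq pooled posterior frequency of the alive state per
#'   individual x occasion (used for the plug-in latent state in DIC).
#' @slot individualMeans pooled posterior means of per-individual parameters
#'   (hierarchical specs), a named list of matrices.
#' @slot acceptance mean Metropolis acceptance rate per block per chain.
#' @slot config the [McmcConfig-class] used.
#' @slot spec the [ModelSpec-class] fitted.
#' @slot devianceFocus `"observation"` or `"complete"`; the focus under which
#'   `devianceTrace` was recorded.
#' @exportClass PosteriorDraws
setClass("PosteriorDraws",
  representation(
    draws = "array", paramNames = "character", devianceTrace = "matrix",
    aliveFreq = "matrix", individualMeans = "list", acceptance = "list",
    config = "McmcConfig", spec = "ModelSpec", devianceFocus = "character"
  )
)

setValidity("PosteriorDraws", function(object) {
  msg <- character()
  d <- dim(object@draws)
  if (length(d) != 3L) msg <- c(msg, "draws must be a 3-d array")
  else {
    if (d[3L] != length(object@paramNames))
      msg <- c(msg, "paramNames must match the third dimension of draws")
    if (!identical(dim(object@devianceTrace), d[1:2]))
      msg <- c(msg, "devianceTrace must be retained-iterations x chains")
    keep <- (object@config@nIter - object@config@burnIn) %/% object@config@thin
    if (d[1L] != keep)
      msg <- c(msg, "retained iterations must equal floor((nIter - burnIn)/thin)")
  }
  pn <- object@paramNames
  isProb <- !grepl("^sigma", pn)
  if (length(pn) && any(isProb)) {
    pd <- object@draws[, , isProb, drop = FALSE]
    if (any(pd < 0 | pd > 1)) msg <- c(msg, "probability draws must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' DicResult: deviance summaries of one fitted model
#'
#' `dic = dbar + pD` and `pD = dbar - dhat` hold exactly by construction.
#'
#' @slot dbar posterior mean deviance.
#' @slot dhat deviance at the posterior-mean parameters (and posterior-modal
#'   latent states).
#' @slot pD effective number of parameters, `dbar - dhat`.
#' @slot dic `dbar + pD`.
#' @slot modelName label.
#' @slot includesDead whether the dead-recovery data entered the likelihood
#'   (dead-inclusive and dead-exclusive fits are never ranked together).
#' @slot focus deviance focus, `"observation"` or `"complete"`.
#' @exportClass DicResult
setClass("DicResult",
  representation(dbar = "numeric", dhat = "numeric", pD = "numeric",
                 dic = "numeric", modelName = "character",
                 includesDead = "logical", focus = "character")
)

setValidity("DicResult", function(object) {
  msg <- character()
  if (abs(object@dic - (object@dbar + object@pD)) > 1e-8)
    msg <- c(msg, "dic must equal dbar + pD")
  if (abs(object@pD - (object@dbar - object@dhat)) > 1e-8)
    msg <- c(msg, "pD must equal dbar - dhat")
  if (length(msg)) msg else TRUE
})

#' SimTruth: generating conditions for the capture-history simulator
#'
#' @slot params generating [ParamState-class] (hypermeans and SDs for
#'   hierarchical specs).
#' @slot calendar occasion calendar.
#' @slot cohorts release cohorts.
#' @slot spec generating [ModelSpec-class].
#' @slot seed simulation seed.
#' @exportClass SimTruth
setClass("SimTruth",
  representation(params = "ParamState", calendar = "OccasionCalendar",
                 cohorts = "CohortTable", spec = "ModelSpec", seed = "integer")
)

setValidity("SimTruth", function(object) {
  K <- length(object@calendar@dates)
  if (any(object@cohorts@releaseOccasion > K))
    "cohort release occasions must lie within the calendar" else TRUE
})

#' RecoveryReport: simulate-fit-summarize parameter-recovery results
#'
#' @slot table per-parameter truth, mean posterior mean, bias and empirical
#'   95 percent credible-interval coverage across replicates.
#' @slot nReplicates replicates attempted.
#' @slot seeds per-replicate simulation seeds.
#' @slot excluded replicate indices excluded for failing the Rhat threshold.
#' @exportClass RecoveryReport
setClass("RecoveryReport",
  representation(table = "data.frame", nReplicates = "integer",
                 seeds = "integer", excluded = "integer")
)

setValidity("RecoveryReport", function(object) {
  msg <- character()
  if (object@nReplicates < 1L) msg <- c(msg, "at least one replicate is required")
  if (nrow(object@table) &&
      (any(object@table$coverage < 0, na.rm = TRUE) ||
       any(object@table$coverage > 1, na.rm = TRUE)))
    msg <- c(msg, "coverage must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
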