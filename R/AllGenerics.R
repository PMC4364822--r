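#' @include AllClasses.R
NULL

#' Accessors for pitmark classes
#'
#' Small accessor generics: number of occasions/individuals, the code matrix,
#' release occasions, ids, the calendar and its season labels, and the
#' retained parameter draws.
#'
#' @param object a pitmark object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nOccasions", function(object) standardGeneric("nOccasions"))
#' @rdname accessors
#' @export
setGeneric("nIndividuals", function(object) standardGeneric("nIndividuals"))
#' @rdname accessors
#' @export
setGeneric("codes", function(object) standardGeneric("codes"))
#' @rdname accessors
#' @export
setGeneric("releaseOccasions", function(object) standardGeneric("releaseOccasions"))
#' @rdname accessors
#' @export
setGeneric("individualIds", function(object) standardGeneric("individualIds"))
#' @rdname accessors
#' @export
setGeneric("calendar", function(object) standardGeneric("calendar"))
#' @rdname accessors
#' @export
setGeneric("deltaT", function(object) standardGeneric("deltaT"))
#' @rdname accessors
#' @export
setGeneric("agesMonths", function(object) standardGeneric("agesMonths"))
#' @rdname accessors
#' @export
setGeneric("occasionSeason", function(object) standardGeneric("occasionSeason"))
#' @rdname accessors
#' @export
setGeneric("intervalSeason", function(object) standardGeneric("intervalSeason"))
#' @rdname accessors
#' @export
setGeneric("occasionDates", function(object) standardGeneric("occasionDates"))
#' @rdname accessors
#' @export
setGeneric("paramNames", function(object) standardGeneric("paramNames"))
#' @rdname accessors
#' @export
setGeneric("drawsArray", function(object) standardGeneric("drawsArray"))
#' @rdname accessors
#' @export
setGeneric("devianceTrace", function(object) standardGeneric("devianceTrace"))

setMethod("nOccasions", "OccasionCalendar", function(object) length(object@dates))
setMethod("nOccasions", "CaptureHistorySet", function(object) ncol(object@codes))
setMethod("nIndividuals", "CaptureHistorySet", function(object) nrow(object@codes))
setMethod("codes", "CaptureHistorySet", function(object) object@codes)
setMethod("releaseOccasions", "CaptureHistorySet", function(object) object@releaseOccasion)
setMethod("individualIds", "CaptureHistorySet", function(object) object@individualId)
setMethod("calendar", "CaptureHistorySet", function(object) object@calendar)
setMethod("deltaT", "OccasionCalendar", function(object) object@deltaT)
setMethod("agesMonths", "OccasionCalendar", function(object) object@agesMonths)
setMethod("occasionSeason", "OccasionCalendar", function(object) object@occasionSeason)
setMethod("intervalSeason", "OccasionCalendar", function(object) object@intervalSeason)
setMethod("occasionDates", "OccasionCalendar", function(object) object@dates)
setMethod("paramNames", "PosteriorDraws", function(object) object@paramNames)
setMethod("drawsArray", "PosteriorDraws", function(object) object@draws)
setMethod("devianceTrace", "PosteriorDraws", function(object) object@devianceTrace)

setMethod("show", "OccasionCalendar", function(object) {
  K <- nOccasions(object)
  cat("OccasionCalendar with", K, "occasions spanning",
      sprintf("%.1f", object@agesMonths[K] - object@agesMonths[1]), "months\n")
  cat("  dates:", format(object@dates[1]), "...", format(object@dates[K]), "\n")
  cat("  deltaT (months):", paste(object@deltaT, collapse = ", "), "\n")
  cat("  occasion seasons:", paste(c("summer", "winter")[object@occasionSeason],
                                   collapse = ", "), "\n")
})

setMethod("show", "CohortTable", function(object) {
  cat("CohortTable:", length(object@cohortSize), "cohorts,",
      sum(object@cohortSize), "individuals\n")
  cat("  sizes:", paste(object@cohortSize, collapse = ", "),
      "at occasions", paste(object@releaseOccasion, collapse = ", "), "\n")
})

setMethod("show", "CaptureHistorySet", function(object) {
  cat("CaptureHistorySet:", nIndividuals(object), "individuals x",
      nOccasions(object), "occasions\n")
  cat("  live detections:", sum(object@codes == CODE_LIVE) - nIndividuals(object),
      "(after release); dead recoveries:", sum(object@codes == CODE_DEAD), "\n")
})

setMethod("show", "AggregateCounts", function(object) {
  cat("AggregateCounts over", length(object@released), "occasions\n")
  cat("  released:       ", paste(object@released, collapse = " "), "\n")
  cat("  live recaptured:", paste(object@liveRecaptured, collapse = " "), "\n")
  cat("  dead recaptured:", paste(object@deadRecaptured, collapse = " "), "\n")
})

setMethod("show", "ModelSpec", function(object) {
  seas <- c(if (object@seasonalS) "S", if (object@seasonalPcl) "Pcl",
            if (object@seasonalPcd) "Pcd")
  hier <- c(if (object@hierS) "S", if (object@hierPcl) "Pcl",
            if (object@hierPcd) "Pcd")
  cat("ModelSpec", sQuote(object@name), "\n")
  cat("  seasonal:", if (length(seas)) paste(seas, collapse = ", ") else "none", "\n")
  cat("  individual effects:", if (length(hier)) paste(hier, collapse = ", ") else "none", "\n")
  cat("  dead-recovery submodel:", object@includeDeadSubmodel,
      if (object@includeDeadSubmodel)
        paste0("(shell ", object@shellPersistence, ")") else "", "\n")
})

setMethod("show", "PosteriorDraws", function(object) {
  d <- dim(object@draws)
  cat("PosteriorDraws:", d[2], "chains x", d[1], "retained iterations,",
      d[3], "parameters\n")
  cat("  parameters:", paste(object@paramNames, collapse = ", "), "\n")
  cat("  model:", object@spec@name, "\n")
})

setMethod("show", "DicResult", function(object) {
  cat(sprintf("DicResult [%s]: DIC = %.2f (Dbar = %.2f, pD = %.2f, focus = %s)\n",
              object@modelName, object@dic, object@dbar, object@pD, object@focus))
})

setMethod("show", "RecoveryReport", function(object) {
  cat("RecoveryReport over", object@nReplicates, "replicates",
      if (length(object@excluded)) sprintf("(%d excluded)", length(object@excluded))
      else "", "\n")
  print(object@table, row.names = FALSE)
})
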