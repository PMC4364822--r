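#' @include AllGenerics.R
NULL

## Months counted as summer: June through October ("mussels grow rapidly");
## November through May is winter.  October appears at the boundary of both
## seasons, so the occasion/interval rules below make the assignment total.
.summerMonths <- 6:10

.seasonOfMonth <- function(month, summerMonths = .summerMonths) {
  ifelse(month %in% summerMonths, SEASON_SUMMER, SEASON_WINTER)
}

## Majority-month rule for an interval (a, b]: enumerate the calendar months
## from month(a) to month(b) inclusive (each occurrence counted), label each
## summer or winter, and take the majority; ties go to the season of the
## interval's terminal occasion.  Under this rule an interval starting in
## October is winter whenever it runs into November or later.
.intervalSeason <- function(a, b, summerMonths, tie = c("terminal", "summer", "winter")) {
  tie <- match.arg(tie)
  am <- as.POSIXlt(a); bm <- as.POSIXlt(b)
  i0 <- am$year * 12L + am$mon
  i1 <- bm$year * 12L + bm$mon
  months <- (i0:i1) %% 12L + 1L
  s <- .seasonOfMonth(months, summerMonths)
  nSummer <- sum(s == SEASON_SUMMER)
  nWinter <- sum(s == SEASON_WINTER)
  if (nSummer > nWinter) return(SEASON_SUMMER)
  if (nWinter > nSummer) return(SEASON_WINTER)
  switch(tie,
    terminal = .seasonOfMonth(bm$mon + 1L, summerMonths),
    summer = SEASON_SUMMER,
    winter = SEASON_WINTER)
}

#' Build an occasion calendar from dates and ages
#'
#' Inter-occasion intervals `deltaT` are taken from successive differences of
#' the age row (months), not recomputed from the calendar dates.  Occasions are
#' labelled summer when their month falls in `summerMonths` (June-October by
#' default, so an October occasion is a summer occasion); intervals are
#' labelled by the majority of calendar months they cover, with ties broken by
#' `tie` (default: the season of the interval's terminal occasion).
#'
#' @param dates occasion dates (`Date` or anything `as.Date` accepts), strictly
#'   increasing.
#' @param agesMonths cohort age in months at each occasion, strictly increasing.
#' @param summerMonths months (1-12) counted as summer.
#' @param tie tie-break for intervals covering equally many summer and winter
#'   months: `"terminal"`, `"summer"` or `"winter"`.
#' @return an [OccasionCalendar-class].
#' @examples
#' cal <- buildCalendar(as.Date(c("2009-07-01", "2009-10-07", "2010-06-25")),
#'                      c(24.5, 28, 36.5))
#' deltaT(cal)          # 3.5 8.5
#' intervalSeason(cal)  # summer, then winter (majority of Oct-Jun months)
#' @export
buildCalendar <- function(dates, agesMonths, summerMonths = .summerMonths,
                          tie = "terminal") {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("unparseable occasion dates")
  if (length(dates) != length(agesMonths))
    stop("dates and agesMonths must have the same length")
  if (length(dates) < 2L) stop("a calendar needs at least two occasions")
  if (any(diff(as.numeric(dates)) <= 0))
    stop("occasion dates must be strictly increasing")
  if (any(diff(agesMonths) <= 0))
    stop("ages must be strictly increasing (zero-length interval)")
  K <- length(dates)
  months <- as.POSIXlt(dates)$mon + 1L
  occSeason <- as.integer(.seasonOfMonth(months, summerMonths))
  intSeason <- vapply(seq_len(K - 1L), function(k)
    .intervalSeason(dates[k], dates[k + 1L], summerMonths, tie), integer(1))
  new("OccasionCalendar", dates = dates, agesMonths = as.numeric(agesMonths),
      deltaT = diff(as.numeric(agesMonths)), occasionSeason = occSeason,
      intervalSeason = as.integer(intSeason))
}

#' Construct a cohort table
#'
#' @param releaseOccasion occasion index of each cohort's release.
#' @param cohortSize number of individuals per cohort.
#' @return a [CohortTable-class].
#' @export
cohortTable <- function(releaseOccasion, cohortSize) {
  new("CohortTable", releaseOccasion = as.integer(releaseOccasion),
      cohortSize = as.integer(cohortSize))
}

#' The Powell River combshell release design
#'
#' The sampling design of the 2-year PIT-tag monitoring study of
#' laboratory-reared juvenile Cumberlandian combshell (*Epioblasma brevidens*)
#' released near Brooks Bridge, Powell River, Tennessee: eight sampling
#' occasions from 1 July 2009 to 12 October 2011 (27.5 months by the age row),
#' with five staggered release cohorts of 23, 28, 38, 9 and 1 individuals at
#' occasions 1-5.
#'
#' @return a list with elements `calendar` ([OccasionCalendar-class]) and
#'   `cohorts` ([CohortTable-class]).
#' @examples
#' d <- combshellDesign()
#' sum(deltaT(d$calendar))       # 27.5 months
#' sum(d$cohorts@cohortSize)     # 99 released
#' @export
combshellDesign <- function() {
  dates <- as.Date(c("2009-07-01", "2009-08-26", "2009-10-07", "2010-06-25",
                     "2010-10-11", "2011-05-10", "2011-08-17", "2011-10-12"))
  ages <- c(24.5, 26.5, 28, 36.5, 40, 47, 50, 52)
  list(calendar = buildCalendar(dates, ages),
       cohorts = cohortTable(1:5, c(23L, 28L, 38L, 9L, 1L)))
}

#' Read or write an occasion calendar as CSV
#'
#' Columns: `occasion`, `date` (ISO-8601), `age_months`, `season`.  Interval
#' seasons are recomputed from the dates with the given season rule on read.
#'
#' @param path file path.
#' @param cal an [OccasionCalendar-class].
#' @param summerMonths,tie season rule, as in [buildCalendar()].
#' @return `readCalendar` returns an [OccasionCalendar-class];
#'   `writeCalendar` returns `path` invisibly.
#' @export
readCalendar <- function(path, summerMonths = .summerMonths, tie = "terminal") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("occasion", "date", "age_months")
  if (!all(need %in% names(df)))
    stop("calendar file must have columns occasion, date, age_months")
  df <- df[order(df$occasion), ]
  buildCalendar(as.Date(df$date), df$age_months, summerMonths, tie)
}

#' @rdname readCalendar
#' @export
writeCalendar <- function(cal, path) {
  df <- data.frame(occasion = seq_len(nOccasions(cal)),
                   date = format(cal@dates, "%Y-%m-%d"),
                   age_months = cal@agesMonths,
                   season = c("summer", "winter")[cal@occasionSeason])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
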