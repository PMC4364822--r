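#' @include calendar.R
NULL

#' Construct a capture-history set
#'
#' @param codes integer matrix n x K with entries in -1 (pre-release), 0 (not
#'   detected), 1 (detected alive; required at the release occasion), 2
#'   (recovered dead, at most once per row) and 3 (post-recovery).
#' @param releaseOccasion per-individual release occasion index.
#' @param calendar the [OccasionCalendar-class] of the columns.
#' @param individualId unique row labels (default `ind001`, ...).
#' @return a validated [CaptureHistorySet-class].
#' @export
captureHistorySet <- function(codes, releaseOccasion, calendar,
                              individualId = NULL) {
  codes <- matrix(as.integer(codes), nrow = NROW(codes), ncol = NCOL(codes))
  n <- nrow(codes)
  if (is.null(individualId))
    individualId <- sprintf("ind%03d", seq_len(n))
  new("CaptureHistorySet", codes = codes,
      releaseOccasion = as.integer(releaseOccasion),
      individualId = as.character(individualId), calendar = calendar)
}

#' Parse and format single capture histories
#'
#' `parseHistory` turns a whitespace-separated string over `{0, 1, 2}` covering
#' occasions `releaseOccasion` through `releaseOccasion + length - 1` into a
#' coded row: pre-release cells are -1 and cells after a dead recovery are 3.
#' `formatHistory` is its inverse on the observed segment.
#'
#' @param text history string, e.g. `"1 1 0 1"`.
#' @param releaseOccasion occasion index of release.
#' @param nOccasions total number of occasions (default: inferred from the
#'   token count).
#' @return `parseHistory`: an integer vector of length `nOccasions`;
#'   `formatHistory`: a string.
#' @examples
#' parseHistory("1 0 2", 2, 4)   # -1 1 0 2
#' formatHistory(c(-1L, 1L, 0L, 2L), 2)  # "1 0 2"
#' @export
parseHistory <- function(text, releaseOccasion, nOccasions = NULL) {
  tokens <- strsplit(trimws(text), "\\s+")[[1]]
  if (!length(tokens)) stop("empty capture history")
  if (!all(tokens %in% c("0", "1", "2")))
    stop("capture-history tokens must be 0, 1 or 2: got ",
         paste(setdiff(tokens, c("0", "1", "2")), collapse = ", "))
  vals <- as.integer(tokens)
  releaseOccasion <- as.integer(releaseOccasion)
  if (releaseOccasion < 1L) stop("release occasion must be >= 1")
  if (is.null(nOccasions))
    nOccasions <- releaseOccasion + length(vals) - 1L
  if (releaseOccasion + length(vals) - 1L != nOccasions)
    stop("history length does not match the occasion span")
  dead <- which(vals == CODE_DEAD)
  if (length(dead) > 1L)
    stop("invalid history: more than one dead recovery")
  if (length(dead) == 1L && any(vals[seq_along(vals) > dead] == CODE_LIVE))
    stop("invalid history: live detection after dead recovery")
  if (length(dead) == 1L && dead < length(vals))
    vals[(dead + 1L):length(vals)] <- CODE_POST
  row <- c(rep(CODE_PRE, releaseOccasion - 1L), vals)
  as.integer(row)
}

#' @rdname parseHistory
#' @param row a coded row as produced by `parseHistory`.
#' @export
formatHistory <- function(row, releaseOccasion) {
  seg <- row[releaseOccasion:length(row)]
  if (any(seg == CODE_PRE)) stop("pre-release cell inside the observed segment")
  seg[seg == CODE_POST] <- CODE_NONE  # parseHistory re-marks cells after a 2
  paste(seg, collapse = " ")
}

.codeSymbols <- c(`-1` = ".", `0` = "0", `1` = "1", `2` = "2", `3` = "x")

#' Read and write capture-history CSV files
#'
#' The file has columns `id`, `release_occasion`, `o1` ... `oK` with cell
#' symbols `.` (pre-release), `0`, `1`, `2` and `x` (post-recovery).
#' `writeHistories` then `readHistories` is the identity on valid sets.
#'
#' @param path file path.
#' @param calendar the [OccasionCalendar-class] of the occasions; columns must
#'   match its length.
#' @param set a [CaptureHistorySet-class].
#' @return `readHistories` returns a validated [CaptureHistorySet-class];
#'   `writeHistories` returns `path` invisibly.
#' @export
readHistories <- function(path, calendar) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("id", "release_occasion") %in% names(df)))
    stop("capture-history file must have columns id and release_occasion")
  occCols <- grep("^o[0-9]+$", names(df), value = TRUE)
  occCols <- occCols[order(as.integer(sub("^o", "", occCols)))]
  K <- length(occCols)
  if (K != nOccasions(calendar))
    stop("file has ", K, " occasion columns but the calendar has ",
         nOccasions(calendar))
  if (anyDuplicated(df$id))
    stop("duplicate individual ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  sym <- as.matrix(df[, occCols, drop = FALSE])
  lut <- c(`.` = -1L, `0` = 0L, `1` = 1L, `2` = 2L, `x` = 3L)
  if (!all(sym %in% names(lut)))
    stop("unknown cell symbols: ", paste(unique(sym[!sym %in% names(lut)]),
                                         collapse = ", "))
  codes <- matrix(lut[sym], nrow = nrow(df))
  captureHistorySet(codes, as.integer(df$release_occasion), calendar,
                    individualId = df$id)
}

#' @rdname readHistories
#' @export
writeHistories <- function(set, path) {
  sym <- matrix(.codeSymbols[as.character(set@codes)], nrow = nIndividuals(set))
  df <- data.frame(id = set@individualId,
                   release_occasion = set@releaseOccasion,
                   stringsAsFactors = FALSE)
  occ <- as.data.frame(sym, stringsAsFactors = FALSE)
  names(occ) <- paste0("o", seq_len(nOccasions(set)))
  utils::write.csv(cbind(df, occ), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct aggregate per-occasion counts
#'
#' @param released,liveRecaptured,deadRecaptured integer vectors of equal
#'   length K (occasions).
#' @return an [AggregateCounts-class].
#' @export
aggregateCounts <- function(released, liveRecaptured, deadRecaptured) {
  new("AggregateCounts", released = as.integer(released),
      liveRecaptured = as.integer(liveRecaptured),
      deadRecaptured = as.integer(deadRecaptured))
}

#' Tally a capture-history set into per-occasion aggregate counts
#'
#' Releases per occasion, live recaptures of previously released individuals
#' (the release detection itself is not counted), and dead recoveries.
#'
#' @param set a [CaptureHistorySet-class].
#' @return an [AggregateCounts-class]; the inverse check for
#'   [reconstructHistories()].
#' @export
tabulateCounts <- function(set) {
  K <- nOccasions(set)
  r <- set@releaseOccasion
  released <- tabulate(r, nbins = K)
  live <- integer(K); dead <- integer(K)
  for (k in seq_len(K)) {
    live[k] <- sum(set@codes[, k] == CODE_LIVE & r < k)
    dead[k] <- sum(set@codes[, k] == CODE_DEAD)
  }
  aggregateCounts(released, live, dead)
}

#' The published per-occasion aggregates of the Powell River combshell study
#'
#' Releases (23, 28, 38, 9, 1 at occasions 1-5), live recaptures
#' (23, 50, 88, 97, 96, 95, 94 at occasions 2-8) and the single dead recovery
#' (occasion 5).
#'
#' @return an [AggregateCounts-class].
#' @export
combshellAggregates <- function() {
  aggregateCounts(released = c(23L, 28L, 38L, 9L, 1L, 0L, 0L, 0L),
                  liveRecaptured = c(0L, 23L, 50L, 88L, 97L, 96L, 95L, 94L),
                  deadRecaptured = c(0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L))
}
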