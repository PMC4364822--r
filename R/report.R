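#' @include simulate.R
NULL

## Short hash of a deparse()d object; stamped into report files so a run's
## outputs can be matched to its configuration.
.configHash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 900000011  # rolling polynomial hash
  sprintf("%08x", as.integer(h))
}

.runInfo <- function(dir, config, spec, extra = character()) {
  info <- c(sprintf("model: %s", spec@name),
            sprintf("seed: %d", config@seed),
            sprintf("chains: %d  iterations: %d  burn-in: %d  thin: %d",
                    config@nChains, config@nIter, config@burnIn, config@thin),
            sprintf("config-hash: %s",
                    .configHash(list(spec = spec@name, config = list(
                      config@nChains, config@nIter, config@burnIn,
                      config@thin, config@seed)))),
            extra)
  writeLines(info, file.path(dir, "run-info.txt"))
}

#' Fit a model variant to a capture-history set
#'
#' Convenience wrapper around [runChains()], [summarizePosterior()] and
#' [dic()]: one call returns the retained draws, the publication-style summary
#' table (posterior mean and SD per parameter by season), convergence
#' diagnostics and the DIC decomposition.  A fit whose worst parameter Rhat
#' exceeds `rhatMax` is flagged `converged = FALSE`; its summaries are still
#' returned.
#'
#' @param histories a [CaptureHistorySet-class].
#' @param model a [ModelSpec-class] or preset name (see [modelSpec()]).
#' @param config an [McmcConfig-class].
#' @param rhatMax convergence threshold for the flag (default 1.05).
#' @param devianceFocus passed to [runChains()].
#' @return a list with elements `draws` ([PosteriorDraws-class]), `summary`
#'   (data.frame), `dic` ([DicResult-class]), `converged` (logical) and
#'   `spec`.
#' @export
fitModel <- function(histories, model = "model3", config = mcmcConfig(),
                     rhatMax = 1.05,
                     devianceFocus = c("observation", "complete")) {
  spec <- if (is.character(model)) modelSpec(model) else model
  draws <- runChains(histories, spec, config, devianceFocus = devianceFocus)
  sm <- summarizePosterior(draws)
  res <- dic(draws, histories, spec)
  conv <- !any(sm$rhat > rhatMax, na.rm = TRUE)
  list(draws = draws, summary = sm, dic = res, converged = conv, spec = spec)
}

#' Write the files of one model fit
#'
#' Writes `draws.csv` (chain, iteration, one column per parameter, deviance),
#' `summary.csv` (the posterior summary with Rhat and ESS, marked
#' `NOT CONVERGED` when the Rhat threshold failed), `dic.csv`, and
#' `run-info.txt` (model, seed, run lengths, config hash, Metropolis
#' acceptance rates).
#'
#' @param fit a fit as returned by [fitModel()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeFitReport <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  draws <- fit$draws
  d <- dim(draws@draws)
  flat <- do.call(rbind, lapply(seq_len(d[2]), function(ch) {
    m <- draws@draws[, ch, , drop = FALSE]
    dim(m) <- c(d[1], d[3])
    colnames(m) <- draws@paramNames
    data.frame(chain = ch, iteration = seq_len(d[1]), m,
               deviance = draws@devianceTrace[, ch], check.names = FALSE)
  }))
  utils::write.csv(flat, file.path(dir, "draws.csv"), row.names = FALSE)
  sm <- fit$summary
  sm$converged <- ifelse(fit$converged, "yes", "NOT CONVERGED")
  utils::write.csv(sm, file.path(dir, "summary.csv"), row.names = FALSE)
  r <- fit$dic
  utils::write.csv(data.frame(model = r@modelName, dbar = r@dbar, dhat = r@dhat,
                              pD = r@pD, dic = r@dic, focus = r@focus),
                   file.path(dir, "dic.csv"), row.names = FALSE)
  accLines <- if (length(draws@acceptance))
    sprintf("acceptance %s: %.3f", names(draws@acceptance),
            unlist(draws@acceptance)) else character()
  .runInfo(dir, draws@config, fit$spec, accLines)
  invisible(dir)
}

#' Write a DIC comparison table
#'
#' One CSV per comparability group (dead-inclusive models versus the model 4
#' family), each sorted by DIC with delta and support categories.
#'
#' @param fits a list of fits from [fitModel()] (or [DicResult-class]
#'   objects); groups are split automatically.
#' @param path output CSV path; with two groups, the dead-exclusive table
#'   gains a `-dead-excluded` suffix.
#' @return the written paths, invisibly.
#' @export
writeComparisonTable <- function(fits, path) {
  dics <- lapply(fits, function(f) if (is(f, "DicResult")) f else f$dic)
  incl <- vapply(dics, function(r) r@includesDead, logical(1))
  paths <- character()
  if (any(incl)) {
    utils::write.csv(compareModels(dics[incl]), path, row.names = FALSE)
    paths <- c(paths, path)
  }
  if (any(!incl)) {
    p2 <- if (any(incl))
      sub("(\\.csv)?$", "-dead-excluded.csv", path)[1] else path
    utils::write.csv(compareModels(dics[!incl]), p2, row.names = FALSE)
    paths <- c(paths, p2)
  }
  invisible(paths)
}

#' Write a parameter-recovery report
#'
#' @param report a [RecoveryReport-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeRecoveryReport <- function(report, path) {
  utils::write.csv(report@table, path, row.names = FALSE)
  info <- sub("(\\.csv)?$", "-replicates.csv", path)[1]
  utils::write.csv(data.frame(replicate = seq_len(report@nReplicates),
                              seed = report@seeds,
                              excluded = seq_len(report@nReplicates) %in%
                                report@excluded),
                   info, row.names = FALSE)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' A single structured file with blocks `histories` (CSV path), `calendar`
#' (CSV path), `model` (preset name) and `mcmc` (`nChains`, `nIter`, `burnIn`,
#' `thin`, `seed`, `proposalSd`); missing MCMC fields fall back to
#' [mcmcConfig()] defaults.
#'
#' @param path YAML file path.
#' @return a list with elements `histories`, `calendar`, `model` (character)
#'   and `config` ([McmcConfig-class]).
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  m <- y$mcmc %||% list()
  cfg <- mcmcConfig(nChains = m$nChains %||% 3L, nIter = m$nIter %||% 20000L,
                    burnIn = m$burnIn %||% 5000L, thin = m$thin %||% 1L,
                    seed = m$seed %||% 1L,
                    proposalSd = m$proposalSd %||% 0.5)
  list(histories = y$histories, calendar = y$calendar,
       model = y$model %||% "model3", config = cfg)
}
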