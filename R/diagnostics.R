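#' @include mcmc.R
NULL

#' Gelman-Rubin potential scale reduction factor
#'
#' `sqrt(((n - 1)/n * W + B/n) / W)` with `W` the mean within-chain variance
#' and `B` the between-chain variance of chain means (times `n`).  Chains with
#' zero variance throughout (a degenerate posterior) return exactly 1.
#'
#' @param x a matrix (iterations x chains), or a [PosteriorDraws-class] (one
#'   value per parameter).
#' @param ... unused.
#' @return the potential scale reduction factor(s).
#' @export
setGeneric("gelmanRubin", function(x, ...) standardGeneric("gelmanRubin"))

#' @rdname gelmanRubin
#' @export
setMethod("gelmanRubin", "matrix", function(x, ...) {
  m <- ncol(x); n <- nrow(x)
  if (m < 2L) stop("Gelman-Rubin diagnostics need at least 2 chains")
  if (n < 10L) stop("Gelman-Rubin diagnostics need at least 10 draws per chain")
  W <- mean(apply(x, 2L, stats::var))
  B <- n * stats::var(colMeans(x))
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
})

#' @rdname gelmanRubin
#' @export
setMethod("gelmanRubin", "PosteriorDraws", function(x, ...) {
  out <- vapply(seq_along(x@paramNames), function(p) {
    m <- x@draws[, , p, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    gelmanRubin(m)
  }, numeric(1))
  names(out) <- x@paramNames
  out
})

#' Sample autocorrelation and effective sample size
#'
#' `autocorrelation` returns the sample autocorrelation at lags 0..`maxLag`;
#' a constant chain has no defined autocorrelation and is signalled as an
#' error.  `effectiveSampleSize` uses `n / (1 + 2 * sum(rho_k))` with the sum
#' truncated at the first negative autocorrelation, capped at `n`.
#'
#' @param x numeric vector of draws (one chain).
#' @param maxLag largest lag.
#' @return `autocorrelation`: numeric vector named by lag;
#'   `effectiveSampleSize`: a single count.
#' @export
autocorrelation <- function(x, maxLag = min(50L, length(x) - 1L)) {
  if (stats::var(x) == 0)
    stop("autocorrelation is undefined for a constant chain")
  ac <- stats::acf(x, lag.max = maxLag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  names(ac) <- 0:maxLag
  ac
}

#' @rdname autocorrelation
#' @export
effectiveSampleSize <- function(x, maxLag = min(200L, length(x) - 1L)) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)  # degenerate chain: no autocorrelation signal
  ac <- autocorrelation(x, maxLag)[-1L]
  neg <- which(ac < 0)
  if (length(neg)) ac <- ac[seq_len(neg[1L] - 1L)]
  min(n, n / (1 + 2 * sum(ac)))
}

#' Posterior summary table
#'
#' Pooled-chain mean, SD and 2.5/50/97.5 percent quantiles per parameter,
#' with the Gelman-Rubin statistic and effective sample size (summed over
#' chains) alongside; the deviance trace is summarized as an extra row.
#'
#' @param draws a [PosteriorDraws-class].
#' @return a data.frame with one row per parameter.
#' @export
summarizePosterior <- function(draws) {
  pn <- draws@paramNames
  one <- function(m, name) {
    pooled <- as.vector(m)
    q <- stats::quantile(pooled, c(0.025, 0.5, 0.975), names = FALSE)
    ess <- sum(apply(m, 2L, effectiveSampleSize))
    data.frame(parameter = name, mean = mean(pooled), sd = stats::sd(pooled),
               q2.5 = q[1], median = q[2], q97.5 = q[3],
               rhat = if (ncol(m) >= 2L) gelmanRubin(m) else NA_real_,
               ess = ess, stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_along(pn), function(p) {
    m <- draws@draws[, , p, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    one(m, pn[p])
  })
  rows <- c(rows, list(one(draws@devianceTrace, "deviance")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
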