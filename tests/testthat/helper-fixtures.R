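# Shared fixtures and independent oracles, built in code.

# A small two-occasion calendar with a one-month interval.
tinyCalendar2 <- function(dt = 1) {
  buildCalendar(as.Date(c("2010-01-15", "2010-02-15")), c(10, 10 + dt))
}

# Four occasions, mixed intervals (months): 1, 2, 1.5.
tinyCalendar4 <- function() {
  buildCalendar(as.Date(c("2010-01-15", "2010-02-15", "2010-04-15",
                          "2010-06-01")),
                c(10, 11, 13, 14.5))
}

# Calendar with unit intervals and a single season (all summer months).
unitCalendar <- function(K) {
  buildCalendar(as.Date("2010-06-01") + round(30.44 * (seq_len(K) - 1)),
                seq(10, by = 1, length.out = K))
}

historySet <- function(texts, release, cal) {
  K <- nOccasions(cal)
  codes <- do.call(rbind, Map(function(tx, r) parseHistory(tx, r, K),
                              texts, release))
  captureHistorySet(codes, as.integer(release), cal)
}

# Midpoint-rule grid posterior means of (S, Pcl) for a dead-exclusive spec,
# built on the observed-data likelihood.
gridPosteriorMeans <- function(hs, spec, nGrid = 200) {
  g <- seq(0.5 / nGrid, 1 - 0.5 / nGrid, length.out = nGrid)
  grid <- expand.grid(S = g, P = g)
  ll <- mapply(function(S, P)
    marginalLoglik(hs, paramState(spec, S = S, Pcl = P), spec),
    grid$S, grid$P)
  w <- exp(ll - max(ll)); w <- w / sum(w)
  c(S = sum(w * grid$S), Pcl = sum(w * grid$P))
}

# Textbook single-season Cormack-Jolly-Seber probability of a history that is
# never seen after its last detection, with unit intervals: chi recursion.
cjsNeverSeenAgain <- function(S, p, nDetected, nAfter) {
  chi <- 1
  for (j in seq_len(nAfter)) chi <- (1 - S) + S * (1 - p) * chi
  (S * p)^nDetected * chi
}

# Assemble a PosteriorDraws object from given per-parameter chains (a list of
# iteration x chain matrices) for exercising summaries and DIC identities.
makeDraws <- function(chains, devTrace = NULL, spec = modelSpec("model4")) {
  pn <- names(chains)
  nKeep <- nrow(chains[[1]]); nCh <- ncol(chains[[1]])
  a <- array(NA_real_, c(nKeep, nCh, length(pn)),
             dimnames = list(NULL, NULL, pn))
  for (p in seq_along(pn)) a[, , p] <- chains[[p]]
  if (is.null(devTrace)) devTrace <- matrix(0, nKeep, nCh)
  cfg <- mcmcConfig(nChains = nCh, nIter = nKeep, burnIn = 0L, seed = 1L)
  new("PosteriorDraws", draws = a, paramNames = pn, devianceTrace = devTrace,
      aliveFreq = matrix(numeric(0), 0, 0), individualMeans = list(),
      acceptance = list(), config = cfg, spec = spec,
      devianceFocus = "observation")
}
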