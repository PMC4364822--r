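#' @include latent.R
NULL

## Internal precomputation for the data-augmentation sampler.  Because alive
## states are monotone, the latent state of individual i is its death occasion
## d in {tlast_i + 1, ..., cens_i} or "survived"; everything the sampler needs
## is a function of d through cumulative per-season counts, so one n x K
## matrix of log-weights drives the exact latent Gibbs step, and sufficient
## counts for the parameter blocks are row lookups.  Column j of the weight
## matrix corresponds to lastAlive = j (death at j + 1; j = K means survived).

## count * logprob with the 0 * -Inf = 0 convention
.xmul <- function(count, logp) {
  out <- count * logp
  if (anyNA(out)) out[is.na(out) & count == 0] <- 0
  out
}

.designData <- function(histories, spec) {
  cm <- histories@codes
  n <- nrow(cm); K <- ncol(cm)
  r <- histories@releaseOccasion
  cal <- calendar(histories)
  seas <- .famSeasons(spec, cal)
  recAt <- apply(cm == CODE_DEAD, 1L, function(x) {
    w <- which(x); if (length(w)) w[1L] else NA_integer_
  })
  recovered <- !is.na(recAt)
  cens <- ifelse(recovered, recAt, K)
  tlast <- apply(cm == CODE_LIVE, 1L, function(x) max(which(x)))
  postRelease <- col(cm) > matrix(r, n, K)
  cumBySeason <- function(indicator, seasonIdx, s) {
    m <- indicator * (matrix(seasonIdx, n, K, byrow = TRUE) == s)
    t(apply(m, 1L, cumsum))
  }
  nsPcl <- max(seas$Pcl); nsPcd <- max(seas$Pcd); nsS <- max(seas$S)
  det1 <- (cm == CODE_LIVE) & postRelease
  mis1 <- (cm == CODE_NONE)  # only cells before death are counted, via lastAlive
  detc <- lapply(seq_len(nsPcl), function(s) cumBySeason(det1, seas$Pcl, s))
  missc <- lapply(seq_len(nsPcl), function(s) cumBySeason(mis1, seas$Pcl, s))
  EsS <- lapply(seq_len(nsS), function(s) {
    e <- cal@deltaT * (seas$S == s)
    c(0, 0, cumsum(e))  # length K + 1; entry k + 1 = exposure through occasion k
  })
  occPcd <- lapply(seq_len(nsPcd), function(s) c(0L, cumsum(seas$Pcd == s)))
  ## occPcd[[s]][k + 1] = number of occasions 1..k in Pcd-season s
  jIdx <- matrix(seq_len(K), n, K, byrow = TRUE)
  valid <- (jIdx >= matrix(tlast, n, K)) &
    ((jIdx + 1L <= matrix(cens, n, K)) |
       (jIdx == K & !matrix(recovered, n, K)))
  list(n = n, K = K, r = r, tlast = tlast, cens = cens, recovered = recovered,
       seas = seas, dtv = cal@deltaT, nsS = nsS, nsPcl = nsPcl, nsPcd = nsPcd,
       detc = detc, missc = missc, EsS = EsS, occPcd = occPcd, valid = valid)
}

## n x K log-weight matrix over lastAlive = column index.
.logWeights <- function(dd, params, spec) {
  n <- dd$n; K <- dd$K
  W <- matrix(0, n, K)
  ## survival of completed intervals
  for (s in seq_len(dd$nsS)) {
    A <- dd$EsS[[s]]  # length K + 1; A[k + 1] = exposure through occasion k
    expo <- matrix(A[2L:(K + 1L)], n, K, byrow = TRUE) - A[dd$r + 1L]
    logS <- if (spec@hierS) log(params@Si[, s]) else log(params@S[s])
    W <- W + .xmul(expo, logS)
  }
  ## death in interval (j, j + 1]
  if (K >= 2L) {
    cols <- seq_len(K - 1L)
    if (spec@hierS) {
      Dmat <- matrix(0, n, K - 1L)
      for (s in seq_len(dd$nsS)) {
        cs <- cols[dd$seas$S == s]
        if (length(cs))
          Dmat[, cs] <- log1p(-outer(params@Si[, s], dd$dtv[cs], `^`))
      }
      W[, cols] <- W[, cols] + Dmat
    } else {
      v <- log1p(-params@S[dd$seas$S]^dd$dtv)
      W[, cols] <- W[, cols] + matrix(v, n, K - 1L, byrow = TRUE)
    }
  }
  ## live detections and misses while alive
  for (s in seq_len(dd$nsPcl)) {
    lp <- if (spec@hierPcl) log(params@Pcli[, s]) else log(params@Pcl[s])
    lq <- if (spec@hierPcl) log1p(-params@Pcli[, s]) else log1p(-params@Pcl[s])
    W <- W + .xmul(dd$detc[[s]], lp) + .xmul(dd$missc[[s]], lq)
  }
  ## shell observation terms after death
  if (spec@includeDeadSubmodel) {
    single <- spec@shellPersistence == "single_occasion"
    if (!single) {
      eFail <- ifelse(dd$recovered, dd$cens - 1L, K)  # last shell-miss occasion
      for (s in seq_len(dd$nsPcd)) {
        O <- dd$occPcd[[s]]
        failCnt <- O[eFail + 1L] - matrix(O[(seq_len(K)) + 1L], n, K, byrow = TRUE)
        failCnt <- pmax(failCnt, 0)  # columns beyond eFail are masked anyway
        lq <- if (spec@hierPcd) log1p(-params@Pcdi[, s]) else log1p(-params@Pcd[s])
        W <- W + .xmul(failCnt, lq)
      }
    } else if (K >= 2L) {
      cols <- seq_len(K - 1L)
      nonrec <- !dd$recovered
      if (any(nonrec)) {
        if (spec@hierPcd) {
          for (s in seq_len(dd$nsPcd)) {
            cs <- cols[dd$seas$Pcd[cols + 1L] == s]
            if (length(cs))
              W[nonrec, cs] <- W[nonrec, cs] + log1p(-params@Pcdi[nonrec, s])
          }
        } else {
          v <- log1p(-params@Pcd[dd$seas$Pcd[cols + 1L]])
          W[nonrec, cols] <- W[nonrec, cols] +
            matrix(v, sum(nonrec), K - 1L, byrow = TRUE)
        }
      }
      ## recovered: shell observable only at the first occasion after death,
      ## so the recovery pins death to (cens - 1, cens]
      if (any(dd$recovered)) {
        rec <- which(dd$recovered)
        W[rec, ] <- -Inf
        ## re-add below via success term on the single valid column
      }
    }
    ## recovery success term
    if (any(dd$recovered)) {
      rec <- which(dd$recovered)
      sRec <- dd$seas$Pcd[dd$cens[rec]]
      lpRec <- if (spec@hierPcd) log(params@Pcdi[cbind(rec, sRec)])
               else log(params@Pcd[sRec])
      if (!single) {
        W[rec, ] <- W[rec, ] + lpRec
      } else {
        ## only column cens - 1 is feasible; overwrite it with the full weight
        for (idx in seq_along(rec)) {
          i <- rec[idx]; j <- dd$cens[i] - 1L
          w <- lpRec[idx]
          for (s in seq_len(dd$nsS)) {
            A <- dd$EsS[[s]]
            logS <- if (spec@hierS) log(params@Si[i, s]) else log(params@S[s])
            w <- w + .xmul(A[j + 1L] - A[dd$r[i] + 1L], logS)
          }
          w <- w + log1p(-(if (spec@hierS) params@Si[i, dd$seas$S[j]]
                           else params@S[dd$seas$S[j]])^dd$dtv[j])
          for (s in seq_len(dd$nsPcl)) {
            lp <- if (spec@hierPcl) log(params@Pcli[i, s]) else log(params@Pcl[s])
            lq <- if (spec@hierPcl) log1p(-params@Pcli[i, s]) else log1p(-params@Pcl[s])
            w <- w + .xmul(dd$detc[[s]][i, j], lp) + .xmul(dd$missc[[s]][i, j], lq)
          }
          W[i, j] <- w
        }
      }
    }
  }
  W[!dd$valid] <- -Inf
  W
}

## Exact Gibbs draw of death occasions (K + 1 = survived) via Gumbel-max.
.sampleDeathTimes <- function(dd, params, spec) {
  W <- .logWeights(dd, params, spec)
  G <- W - log(-log(matrix(stats::runif(dd$n * dd$K), dd$n, dd$K)))
  G[!is.finite(W)] <- -Inf
  lastAlive <- max.col(G, ties.method = "first")
  if (any(!is.finite(W[cbind(seq_len(dd$n), lastAlive)])))
    stop("zero-probability capture history under the current parameters")
  ifelse(lastAlive == dd$K & !dd$recovered, dd$K + 1L, lastAlive + 1L)
}

## Sufficient counts given sampled death occasions.
.countsFromDeaths <- function(dd, deathOcc, spec) {
  K <- dd$K
  lastAlive <- pmin(deathOcc - 1L, K)
  idx <- cbind(seq_len(dd$n), lastAlive)
  died <- deathOcc <= K
  detI <- lapply(dd$detc, function(m) m[idx])    # live-detection successes
  misI <- lapply(dd$missc, function(m) m[idx])   # live-detection failures
  expoI <- lapply(dd$EsS, function(A) A[lastAlive + 1L] - A[dd$r + 1L])
  dieOcc <- ifelse(died, deathOcc, NA_integer_)
  nDie <- tabulate(dieOcc[died], nbins = K)      # deaths by terminal occasion
  pcdFailI <- pcdSuccI <- NULL
  if (spec@includeDeadSubmodel) {
    single <- spec@shellPersistence == "single_occasion"
    pcdSuccI <- lapply(seq_len(dd$nsPcd), function(s)
      as.numeric(dd$recovered & dd$seas$Pcd[pmin(dd$cens, K)] == s))
    if (!single) {
      eFail <- ifelse(dd$recovered, dd$cens - 1L, K)
      pcdFailI <- lapply(seq_len(dd$nsPcd), function(s) {
        O <- dd$occPcd[[s]]
        out <- numeric(dd$n)
        out[died] <- pmax(O[eFail[died] + 1L] - O[deathOcc[died]], 0)
        out
      })
    } else {
      pcdFailI <- lapply(seq_len(dd$nsPcd), function(s) {
        out <- numeric(dd$n)
        w <- died & !dd$recovered
        out[w] <- as.numeric(dd$seas$Pcd[deathOcc[w]] == s)
        out
      })
    }
  }
  ## per-individual death-interval info for survival terms
  dieSeason <- ifelse(died, dd$seas$S[pmax(deathOcc - 1L, 1L)], NA_integer_)
  dieDt <- ifelse(died, dd$dtv[pmax(deathOcc - 1L, 1L)], NA_real_)
  list(lastAlive = lastAlive, died = died, nDie = nDie,
       detI = detI, misI = misI, expoI = expoI,
       pcdFailI = pcdFailI, pcdSuccI = pcdSuccI,
       dieSeason = dieSeason, dieDt = dieDt)
}
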