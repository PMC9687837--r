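# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no binary fixtures.

ECG5 <- c("NHB", "AHB", "MI", "HMI", "COVID")

# compact sheet used by most rendering tests
testSheetSpec <- function(...) {
  sheetSpec(widthPx = 320L, heightPx = 240L, minorGridSpacingPx = 4L,
            labelBandTopPx = 24L, labelBandBottomPx = 24L, ...)
}

# taller sheet used where trace morphology matters (training, separability)
morphSheetSpec <- function(...) {
  sheetSpec(widthPx = 448L, heightPx = 360L, minorGridSpacingPx = 4L,
            labelBandTopPx = 28L, labelBandBottomPx = 28L, ...)
}

# cached default-size sheet (rendering the full 2213 x 1572 page is the
# expensive part; share it across tests)
fullSheet <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- renderSheet("NHB", sheetSpec(seed = 5L))
    cache
  }
})

# ---- independent oracles ----

# exhaustive-search Otsu: maximise between-class variance over t = 0..255
bruteOtsu <- function(gray) {
  v <- as.integer(round(gray))
  best <- -Inf; bestT <- 0L
  for (t in 0:255) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    bcv <- (length(lo) / length(v)) * (length(hi) / length(v)) *
      (mean(lo) - mean(hi))^2
    if (bcv > best) { best <- bcv; bestT <- t }
  }
  bestT
}

# double-loop non-local means with the same padding/weight semantics as the
# implementation contract
bruteNlm <- function(img, patchSize, patchDistance, h) {
  pr <- (patchSize - 1L) %/% 2L; sr <- patchDistance; M <- pr + sr
  H <- nrow(img); W <- ncol(img)
  ri <- pmin(pmax(seq(1 - M, H + M), 1), H)
  ci <- pmin(pmax(seq(1 - M, W + M), 1), W)
  pad <- img[ri, ci]
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    pi <- i + M; pj <- j + M
    num <- 0; den <- 0
    for (dy in -sr:sr) for (dx in -sr:sr) {
      qi <- pi + dy; qj <- pj + dx
      D <- mean((pad[(pi - pr):(pi + pr), (pj - pr):(pj + pr)] -
                 pad[(qi - pr):(qi + pr), (qj - pr):(qj + pr)])^2)
      w <- exp(-D / h^2)
      num <- num + w * pad[qi, qj]; den <- den + w
    }
    out[i, j] <- num / den
  }
  out
}

# per-window SSIM with uniform window and sample covariance
bruteSsim <- function(a, b, window = 7L, K1 = 0.01, K2 = 0.03, L = 255) {
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  H <- nrow(a); W <- ncol(a)
  vals <- c()
  for (i in 1:(H - window + 1)) for (j in 1:(W - window + 1)) {
    wa <- as.vector(a[i:(i + window - 1), j:(j + window - 1)])
    wb <- as.vector(b[i:(i + window - 1), j:(j + window - 1)])
    mua <- mean(wa); mub <- mean(wb)
    va <- stats::var(wa); vb <- stats::var(wb); cab <- stats::cov(wa, wb)
    vals <- c(vals, ((2 * mua * mub + C1) * (2 * cab + C2)) /
                    ((mua^2 + mub^2 + C1) * (va + vb + C2)))
  }
  mean(vals)
}

# multiclass MCC from the covariance definition
bruteMcc <- function(m) {
  K <- nrow(m); s <- sum(m)
  num <- 0
  for (k in 1:K) for (l in 1:K) for (mm in 1:K)
    num <- num + m[k, k] * m[l, mm] - m[k, l] * m[mm, k]
  d1 <- 0; d2 <- 0
  for (k in 1:K) {
    d1 <- d1 + sum(m[k, ]) * sum(m[-k, ])
    d2 <- d2 + sum(m[, k]) * sum(m[, -k])
  }
  num / sqrt(d1 * d2)
}

# exact two-sided signed-rank p by full enumeration of sign patterns
bruteWilcoxP <- function(x, y) {
  d <- x - y; d <- d[d != 0]; n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  Ws <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(m))[1:n]
    Ws[m + 1] <- sum(r[signs == 1])
  }
  lo <- mean(Ws <= W + 1e-9); hi <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(lo, hi))
}

# AUC as the normalised Mann-Whitney U by brute pair counting
bruteAuc <- function(scorePos, scoreNeg) {
  wins <- 0
  for (p in scorePos) for (q in scoreNeg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(scorePos) * length(scoreNeg))
}

# ---- beat-aligned trace extraction (separability check) ----

stripProfile <- function(strip) {
  prof <- apply(strip, 2, function(col) if (any(col)) mean(which(col)) else NA)
  prof[is.na(prof)] <- stats::median(prof, na.rm = TRUE)
  prof <- -(prof - stats::median(prof))
  prof - stats::runmed(prof, 61)
}

# summary features of the beat-aligned mean trace pooled over all strips:
# Q/S depth, ST level, dominant T deflection, mean RR, RR variability
beatTraceStats <- function(sh, sp) {
  m <- sheetMasks(sh)$signal
  H <- nrow(m); W <- ncol(m)
  leadTop <- sp@labelBandTopPx + 1L
  nStrips <- sp@nLeadRows + 1L
  stripH <- (H - sp@labelBandTopPx - sp@labelBandBottomPx) %/% nStrips
  stripW <- W %/% sp@nLeadCols
  segs <- list(); rrs <- numeric()
  pre <- 20L; post <- 60L
  for (r in seq_len(nStrips)) {
    ncols <- if (r == nStrips) 1L else sp@nLeadCols
    for (cc in seq_len(ncols)) {
      x0 <- if (r == nStrips) 1L else (cc - 1L) * stripW + 1L
      x1 <- if (r == nStrips) W else cc * stripW
      rows <- (leadTop + (r - 1L) * stripH):(leadTop + r * stripH - 1L)
      prof <- stripProfile(m[rows, x0:x1])
      th <- 0.5 * stats::quantile(prof, 0.999)
      cand <- which(prof > th)
      pk <- integer()
      for (p in cand) if (!length(pk) || p - pk[length(pk)] > 25) pk <- c(pk, p)
      pk <- vapply(pk, function(p) {
        w <- max(1, p - 5):min(length(prof), p + 5); w[which.max(prof[w])]
      }, integer(1))
      if (length(pk) > 1) rrs <- c(rrs, diff(pk))
      pk <- pk[pk > pre & pk <= length(prof) - post]
      for (p in pk) segs[[length(segs) + 1L]] <- prof[(p - pre):(p + post)]
    }
  }
  if (length(segs) < 3 || length(rrs) < 3) return(NULL)
  mb <- rowMeans(do.call(cbind, segs))
  mb <- mb / max(abs(mb))
  c(q = min(mb[14:20]), s = min(mb[22:28]), st = mean(mb[29:39]),
    t = mb[which.max(abs(mb[41:56])) + 40], rr = mean(rrs),
    rrcv = stats::sd(rrs) / mean(rrs))
}

# random binary test image (0/255)
randomBinary <- function(h, w, pFg = 0.3) {
  matrix(ifelse(stats::runif(h * w) < pFg, 255, 0), h, w)
}
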