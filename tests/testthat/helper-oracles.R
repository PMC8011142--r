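# Independent reference implementations used as oracles. These follow the
# direct textbook formula for each quantity with their own code paths
# (explicit loops, brute-force DFT, sort-based quantiles) and stay
# independent of the package internals they check.

oracle_skewness <- function(v) {
  n <- length(v); m <- sum(v) / n
  m2 <- sum((v - m)^2) / n; m3 <- sum((v - m)^3) / n
  if (m2 == 0) 0 else m3 / m2^(3 / 2)
}

oracle_kurtosis <- function(v) {
  n <- length(v); m <- sum(v) / n
  m2 <- sum((v - m)^2) / n; m4 <- sum((v - m)^4) / n
  if (m2 == 0) 0 else m4 / m2^2 - 3
}

# linear-interpolation quantile (type 7) from first principles
oracle_quantile <- function(v, p) {
  s <- sort(v); n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# brute-force DFT: no fft() call
oracle_main_frequency <- function(v, fs) {
  n <- length(v)
  v <- v - sum(v) / n
  ks <- seq_len(n %/% 2)
  amp <- vapply(ks, function(k) {
    re <- sum(v * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(v * sin(-2 * pi * k * (0:(n - 1)) / n))
    2 / n * sqrt(re^2 + im^2)
  }, numeric(1))
  best <- which.max(amp)
  c(freq = ks[best] * fs / n, amplitude = amp[best])
}

# direct per-feature computation of the 78-feature catalogue
oracle_full_features <- function(bout) {
  s <- bout$samples
  n <- nrow(s)
  out <- c()
  for (a in 1:3) out <- c(out, sum(s[, a]) / n)
  for (a in 1:3) out <- c(out, sum((s[, a] - mean(s[, a]))^2) / (n - 1))
  for (a in 1:3) out <- c(out, sqrt(sum((s[, a] - mean(s[, a]))^2) / (n - 1)))
  for (a in 1:3) {
    m <- mean(s[, a])
    out <- c(out, if (m == 0) 0 else sd(s[, a]) / m)
  }
  for (a in 1:3) out <- c(out, oracle_skewness(s[, a]))
  for (a in 1:3) out <- c(out, oracle_kurtosis(s[, a]))
  for (a in 1:3) out <- c(out, max(s[, a]))
  for (a in 1:3) out <- c(out, min(s[, a]))
  for (a in 1:3) out <- c(out, max(s[, a]) - min(s[, a]))
  for (a in 1:3) out <- c(out, sqrt(sum(s[, a]^2)))
  prs <- list(c(1, 2), c(1, 3), c(2, 3))
  for (p in prs)
    out <- c(out, sum((s[, p[1]] - mean(s[, p[1]])) *
                        (s[, p[2]] - mean(s[, p[2]]))) / (n - 1))
  for (p in prs) {
    sa <- sd(s[, p[1]]); sb <- sd(s[, p[2]])
    out <- c(out, if (sa == 0 || sb == 0) 0
             else cov(s[, p[1]], s[, p[2]]) / (sa * sb))
  }
  for (p in prs) out <- c(out, mean(s[, p[1]]) - mean(s[, p[2]]))
  for (p in prs) out <- c(out, sd(s[, p[1]] - s[, p[2]]))
  stat <- matrix(rep(colMeans(s), each = n), n, 3)
  dyn <- s - stat
  for (a in 1:3) out <- c(out, var(stat[, a]))
  for (a in 1:3) out <- c(out, var(dyn[, a]))
  for (a in 1:3) out <- c(out, mean(abs(dyn[, a])))
  for (a in 1:3) out <- c(out, max(abs(dyn[, a])))
  out <- c(out, sum(abs(dyn)) / n)
  am <- bout$axis_map
  ms <- mean(s[, am[["surge"]]]); mw <- mean(s[, am[["sway"]]])
  mh <- mean(s[, am[["heave"]]])
  out <- c(out, atan2(ms, sqrt(mw^2 + mh^2)) * 180 / pi,
           atan2(mw, mh) * 180 / pi)
  for (a in 1:3) out <- c(out, mean(abs(diff(s[, a]))))
  for (a in 1:3) out <- c(out, if (n > 2) var(diff(s[, a])) else 0)
  mf <- sapply(1:3, function(a) oracle_main_frequency(s[, a], bout$fs))
  out <- c(out, mf[1, ], mf[2, ])
  for (q in c(0.25, 0.5, 0.75))
    for (a in 1:3) out <- c(out, oracle_quantile(s[, a], q))
  unname(out)
}

# step-by-step re-enactment of the correlation-pruning iteration
oracle_prune <- function(X, cutoff = 0.7) {
  X <- as.matrix(X)
  C <- suppressWarnings(abs(cor(X)))
  C[!is.finite(C)] <- 0
  diag(C) <- 0
  keep <- seq_len(ncol(X))
  repeat {
    if (length(keep) < 2L) break
    best <- c(NA, NA); mx <- -Inf
    for (ii in seq_along(keep)) for (jj in seq_along(keep)) {
      if (ii >= jj) next
      r <- C[keep[ii], keep[jj]]
      if (r > mx) { mx <- r; best <- c(keep[ii], keep[jj]) }
    }
    if (mx <= cutoff) break
    i <- best[1]; j <- best[2]
    mi <- mean(C[i, setdiff(keep, i)])
    mj <- mean(C[j, setdiff(keep, j)])
    drop <- if (mi > mj) i else if (mj > mi) j else max(i, j)
    keep <- setdiff(keep, drop)
  }
  colnames(X)[keep]
}
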