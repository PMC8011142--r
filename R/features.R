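#' Static / dynamic decomposition of a bout
#'
#' Splits the raw triaxial signal into a static (gravitational, posture)
#' component and a dynamic (movement) component with
#' `static + dynamic = raw` elementwise. The static component is a
#' centred running mean of the raw signal; with the default
#' `window = NULL` the window is the whole bout, i.e. the static
#' component is the per-axis bout mean. Shorter windows (e.g. a 2-s
#' running mean) can be set per dataset via `acc_config(static_window=)`.
#'
#' @param bout An [acc_bout()].
#' @param window Running-mean window length in records, or `NULL` for the
#'   whole bout. Windows are truncated at the bout edges.
#' @return List with matrices `static` and `dynamic` (same shape as
#'   `bout$samples`).
#' @export
static_dynamic_decompose <- function(bout, window = NULL) {
  stopifnot(inherits(bout, "acc_bout"))
  raw <- bout$samples
  n <- nrow(raw)
  if (is.null(window) || window >= n) {
    static <- matrix(rep(colMeans(raw), each = n), n, 3L,
                     dimnames = dimnames(raw))
  } else {
    half <- (window - 1L) %/% 2L
    static <- raw
    cs <- rbind(0, apply(raw, 2L, cumsum))
    for (i in seq_len(n)) {
      lo <- max(1L, i - half)
      hi <- min(n, i + (window - 1L - half))
      static[i, ] <- (cs[hi + 1L, ] - cs[lo, ]) / (hi - lo + 1L)
    }
  }
  list(static = static, dynamic = raw - static)
}

#' Overall dynamic body acceleration (ODBA)
#'
#' The per-sample sum of absolute dynamic acceleration over the three
#' axes, averaged over the bout. Using the mean (rather than the sum)
#' makes the value comparable across bout lengths. ODBA is a standard
#' proxy for movement intensity and energy expenditure.
#'
#' @inheritParams static_dynamic_decompose
#' @return ODBA in g (non-negative scalar).
#' @export
compute_odba <- function(bout, window = NULL) {
  d <- static_dynamic_decompose(bout, window)$dynamic
  mean(abs(d[, 1L]) + abs(d[, 2L]) + abs(d[, 3L]))
}

#' Device pitch and roll from the mean gravity vector
#'
#' Posture angles derived from the per-axis bout means, interpreted
#' through the bout's axis map: pitch is the rotation about the lateral
#' (sway) axis, `atan2(mean_surge, sqrt(mean_sway^2 + mean_heave^2))`;
#' roll is the rotation about the longitudinal (surge) axis,
#' `atan2(mean_sway, mean_heave)`. Both are reported in degrees.
#'
#' @param bout An [acc_bout()].
#' @return Named numeric `c(pitch=, roll=)` in degrees. A zero mean
#'   vector (no gravity information) gives both angles 0 with a warning.
#' @export
compute_pitch_roll <- function(bout) {
  stopifnot(inherits(bout, "acc_bout"))
  m <- colMeans(bout$samples)
  am <- bout$axis_map
  ms <- m[[am[["surge"]]]]; mw <- m[[am[["sway"]]]]; mh <- m[[am[["heave"]]]]
  if (ms == 0 && mw == 0 && mh == 0) {
    warning("zero mean acceleration vector; pitch and roll undefined, returning 0",
            call. = FALSE)
    return(c(pitch = 0, roll = 0))
  }
  c(pitch = atan2(ms, sqrt(mw^2 + mh^2)) * 180 / pi,
    roll = atan2(mw, mh) * 180 / pi)
}

#' Dominant spectral component of one axis
#'
#' Discrete Fourier transform of the mean-removed signal; the main
#' frequency is the non-DC bin with the largest amplitude (ties broken
#' toward the lowest frequency) and the amplitude is that bin's
#' magnitude scaled by `2/N`, so a unit sinusoid at an exact bin scores
#' amplitude 1 g.
#'
#' @param axis_signal Numeric vector (length >= 2), one axis of a bout.
#' @param fs Sampling frequency in Hz.
#' @return Named numeric `c(freq=, amplitude=)`; a constant signal
#'   returns the first non-DC bin frequency with amplitude 0.
#' @export
compute_main_frequency <- function(axis_signal, fs) {
  n <- length(axis_signal)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  sp <- fft(axis_signal - mean(axis_signal))
  k <- seq_len(n %/% 2L)                  # non-DC bins up to Nyquist
  amp <- 2 / n * Mod(sp[k + 1L])
  best <- which.max(amp)                  # first max = lowest frequency
  c(freq = k[best] * fs / n, amplitude = amp[best])
}

# moment helpers: population moments; zero-variance axes yield 0, never
# NaN, so classifiers always receive finite inputs
moment_skewness <- function(v) {
  m2 <- mean((v - mean(v))^2)
  if (m2 == 0) return(0)
  mean((v - mean(v))^3) / m2^1.5
}
moment_kurtosis <- function(v) {
  m2 <- mean((v - mean(v))^2)
  if (m2 == 0) return(0)
  mean((v - mean(v))^4) / m2^2 - 3
}
safe_cv <- function(v) {
  m <- mean(v)
  if (m == 0) 0 else sd(v) / m
}
safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)
}

#' The full feature catalogue
#'
#' Names and group membership of the 78 per-bout summary statistics, in
#' computation order: 10 per-axis statistics (30), 4 per-axis-pair
#' statistics (12), static/dynamic decomposition features (13), posture
#' angles (2), successive-difference statistics (6), spectral features
#' (6) and per-axis quartiles (9).
#'
#' @return Data frame with columns `name` and `group`.
#' @export
feature_catalogue <- function() {
  ax <- c("x", "y", "z")
  pr <- c("xy", "xz", "yz")
  per_axis <- function(stats, suffixes = ax)
    as.vector(t(outer(stats, suffixes, paste, sep = "_")))
  nm <- per_axis(c("mean", "var", "sd", "cv", "skew", "kurt", "max",
                   "min", "range", "norm"))
  nm <- c(nm, per_axis(c("cov", "cor", "meandiff", "sddiff"), pr))
  nm <- c(nm, per_axis(c("statvar", "dynvar", "meandba", "maxdba")),
          "odba")
  nm <- c(nm, "pitch", "roll")
  nm <- c(nm, per_axis(c("meandl", "vardl")))
  nm <- c(nm, per_axis(c("mainfreq", "mainamp")))
  nm <- c(nm, per_axis(c("q25", "q50", "q75")))
  grp <- c(rep("per-axis statistics", 30L),
           rep("axis-pair statistics", 12L),
           rep("static/dynamic", 13L),
           rep("posture angles", 2L),
           rep("successive differences", 6L),
           rep("spectral", 6L),
           rep("quartiles", 9L))
  data.frame(name = nm, group = grp)
}

#' Compute the full 78-feature vector of a bout
#'
#' Per axis: mean, variance, standard deviation, coefficient of
#' variation, skewness, excess kurtosis, maximum, minimum, range and
#' Euclidean norm. Per axis pair: covariance, Pearson correlation, mean
#' difference and standard deviation of the difference. From the
#' static/dynamic decomposition: static and dynamic variance, mean and
#' maximum absolute dynamic acceleration per axis, and ODBA. Pitch and
#' roll in degrees. Per axis: mean absolute successive difference and
#' variance of the signed successive differences, main frequency (Hz)
#' and its amplitude (g), and the 25/50/75% quartiles.
#'
#' Variance and SD use the n-1 denominator; skewness and kurtosis are
#' moment ratios (excess kurtosis); quartiles use linear interpolation
#' (type 7). Zero-variance axes yield 0 for CV, skewness, kurtosis and
#' correlations so the vector is always finite.
#'
#' @inheritParams static_dynamic_decompose
#' @return Named numeric vector of length 78, in [feature_catalogue()]
#'   order.
#' @export
compute_full_features <- function(bout, window = NULL) {
  stopifnot(inherits(bout, "acc_bout"))
  s <- bout$samples
  ax <- list(x = s[, 1L], y = s[, 2L], z = s[, 3L])
  out <- numeric(0)
  for (f in list(mean = mean, var = var, sd = sd, cv = safe_cv,
                 skew = moment_skewness, kurt = moment_kurtosis,
                 max = max, min = min,
                 range = function(v) max(v) - min(v),
                 norm = function(v) sqrt(sum(v^2)))) {
    out <- c(out, vapply(ax, f, numeric(1)))
  }
  pairs <- list(xy = c(1L, 2L), xz = c(1L, 3L), yz = c(2L, 3L))
  for (f in list(cov = function(a, b) cov(a, b),
                 cor = safe_cor,
                 meandiff = function(a, b) mean(a - b),
                 sddiff = function(a, b) sd(a - b))) {
    out <- c(out, vapply(pairs, function(p) f(s[, p[1L]], s[, p[2L]]),
                         numeric(1)))
  }
  dec <- static_dynamic_decompose(bout, window)
  out <- c(out,
           apply(dec$static, 2L, var),
           apply(dec$dynamic, 2L, var),
           colMeans(abs(dec$dynamic)),
           apply(abs(dec$dynamic), 2L, max),
           mean(rowSums(abs(dec$dynamic))))
  out <- c(out, compute_pitch_roll(bout))
  dl <- apply(s, 2L, diff)
  if (is.null(dim(dl))) dl <- matrix(dl, 1L)   # 2-record bout
  out <- c(out, colMeans(abs(dl)),
           if (nrow(dl) > 1L) apply(dl, 2L, var) else rep(0, 3L))
  mf <- vapply(ax, compute_main_frequency, numeric(2), fs = bout$fs)
  out <- c(out, mf[1L, ], mf[2L, ])
  for (q in c(0.25, 0.5, 0.75))
    out <- c(out, vapply(ax, quantile, numeric(1), probs = q,
                         names = FALSE, type = 7))
  names(out) <- feature_catalogue()$name
  out
}

#' Simplified placement-specific feature set
#'
#' The reduced feature sets used for on-board calculation. For back,
#' collar and leg placements the surge and heave axes are the main
#' movement axes: the set is their means and standard deviations plus
#' ODBA (5 features). For ear placements (ruminants) only the heave axis
#' is used, plus ODBA and the main frequency of the heave axis, which
#' picks up jaw movement (4 features). Each value equals its full-set
#' counterpart; features are named after the underlying file axis so the
#' sub-vector identity with [compute_full_features()] holds by name.
#'
#' @inheritParams static_dynamic_decompose
#' @param placement One of `"back"`, `"collar"`, `"leg"`, `"ear"`.
#' @return Named numeric vector of length 5 (back/collar/leg) or 4 (ear).
#' @export
compute_simplified_features <- function(bout, placement, window = NULL) {
  stopifnot(inherits(bout, "acc_bout"))
  prof <- placement_profile(placement)
  am <- bout$axis_map
  su <- am[["surge"]]; he <- am[["heave"]]
  s <- bout$samples
  if (identical(prof$primary_axes, c("surge", "heave"))) {
    out <- c(mean(s[, su]), sd(s[, su]), mean(s[, he]), sd(s[, he]),
             compute_odba(bout, window))
    names(out) <- c(paste0(c("mean_", "sd_"), su),
                    paste0(c("mean_", "sd_"), he), "odba")
  } else {
    out <- c(mean(s[, he]), sd(s[, he]), compute_odba(bout, window),
             compute_main_frequency(s[, he], bout$fs)[["freq"]])
    names(out) <- c(paste0(c("mean_", "sd_"), he), "odba",
                    paste0("mainfreq_", he))
  }
  out
}

#' Placement profile for the simplified feature set
#'
#' @param placement One of `"back"`, `"collar"`, `"leg"`, `"ear"`.
#' @return List with `placement`, `primary_axes` and
#'   `include_main_frequency`.
#' @export
placement_profile <- function(placement) {
  if (length(placement) != 1L ||
      !placement %in% c("back", "collar", "leg", "ear"))
    stop("unknown placement: must be back, collar, leg or ear",
         call. = FALSE)
  if (placement == "ear")
    list(placement = placement, primary_axes = "heave",
         include_main_frequency = TRUE)
  else
    list(placement = placement, primary_axes = c("surge", "heave"),
         include_main_frequency = FALSE)
}

#' Feature table for a list of bouts
#'
#' Applies [compute_full_features()] or [compute_simplified_features()]
#' to each bout and assembles a data frame with one row per bout.
#'
#' @param bouts List of [acc_bout()] objects.
#' @param set `"full"` (78 features) or `"simplified"`.
#' @param placement Required when `set = "simplified"`.
#' @param window Static-decomposition window (see
#'   [static_dynamic_decompose()]).
#' @return Data frame with columns `bout_id`, `label`, then one column
#'   per feature.
#' @export
feature_table <- function(bouts, set = c("full", "simplified"),
                          placement = NULL, window = NULL) {
  set <- match.arg(set)
  stopifnot(length(bouts) >= 1L)
  rows <- lapply(bouts, function(b) {
    if (set == "full") compute_full_features(b, window)
    else compute_simplified_features(b, placement, window)
  })
  feat <- do.call(rbind, rows)
  labs <- vapply(bouts, function(b) b$label, character(1))
  cbind(data.frame(bout_id = seq_along(bouts), label = labs,
                   stringsAsFactors = FALSE),
        as.data.frame(feat))
}
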