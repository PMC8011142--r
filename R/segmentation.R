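#' Construct a bout
#'
#' A bout is a fixed-length, single-behaviour segment of triaxial ACC
#' samples: the unit of feature calculation and classification.
#'
#' @param samples Numeric matrix with columns `x,y,z`, one row per record,
#'   values in g.
#' @param fs Sampling frequency in Hz.
#' @param label Behaviour category, or `NA` if unlabelled.
#' @param source_offset Index (0-based) of the bout's first sample in the
#'   parent series.
#' @param axis_map Body-axis mapping, as in [acc_config()].
#' @return An object of class `"acc_bout"`.
#' @export
acc_bout <- function(samples, fs, label = NA_character_, source_offset = 0L,
                     axis_map = c(surge = "x", sway = "y", heave = "z")) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L)
    stop("bout samples must have 3 columns (x,y,z)", call. = FALSE)
  colnames(samples) <- c("x", "y", "z")
  if (!all(is.finite(samples)))
    stop("bout samples must be finite", call. = FALSE)
  if (nrow(samples) < 2L)
    stop("a bout needs at least 2 records", call. = FALSE)
  check_axis_map(axis_map)
  structure(list(samples = samples, fs = fs,
                 label = as.character(label),
                 source_offset = as.integer(source_offset),
                 axis_map = axis_map),
            class = "acc_bout")
}

#' @export
print.acc_bout <- function(x, ...) {
  cat(sprintf("ACC bout: %d records at %g Hz, label: %s, offset: %d\n",
              nrow(x$samples), x$fs,
              ifelse(is.na(x$label), "<none>", x$label), x$source_offset))
  invisible(x)
}

#' Number of ACC records in a bout of given duration
#'
#' Loggers report burst durations in seconds; the record count is the
#' duration times the sampling rate, rounded to the nearest integer
#' (e.g. 3.8 s at 10.54 Hz gives 40 records).
#'
#' @param duration_s Bout duration in seconds (> 0).
#' @param fs Sampling frequency in Hz (> 0).
#' @return Integer record count.
#' @examples
#' bout_records_for(3.8, 10.54) # 40
#' bout_records_for(9.1, 3.3)   # 30
#' @export
bout_records_for <- function(duration_s, fs) {
  if (any(duration_s <= 0) || any(fs <= 0))
    stop("duration_s and fs must be positive", call. = FALSE)
  as.integer(round(duration_s * fs))
}

#' Segment an ACC series into fixed-length single-behaviour bouts
#'
#' Cuts the series into consecutive non-overlapping windows of
#' `config$bout_len_records` records starting at the first sample; a
#' trailing partial window is discarded. A window is retained as a bout
#' only if every one of its samples carries the same behaviour label;
#' windows spanning a label switch or containing unlabelled time are
#' pruned, mirroring the standard practice of dropping bouts that
#' reflect more than one behaviour.
#'
#' @param series An [acc_series()].
#' @param labels A [label_intervals()] data frame (or `NULL` for fully
#'   unlabelled data, in which case every full window is pruned).
#' @param config An [acc_config()] supplying the bout length and axis map.
#' @return A list with elements `bouts` (list of [acc_bout()]) and
#'   `pruned_count` (number of full windows dropped for label impurity).
#'   `length(bouts) + pruned_count` equals the number of full windows.
#' @export
segment_series <- function(series, labels, config) {
  stopifnot(inherits(series, "acc_series"), inherits(config, "acc_config"))
  L <- config$bout_len_records
  n <- nrow(series)
  if (n < L) {
    warning("series shorter than one bout; returning no bouts",
            call. = FALSE)
    return(list(bouts = list(), pruned_count = 0L))
  }
  n_win <- n %/% L
  lab <- label_at(labels, series$t)
  bouts <- vector("list", n_win)
  kept <- 0L
  for (w in seq_len(n_win)) {
    idx <- ((w - 1L) * L + 1L):(w * L)
    wl <- lab[idx]
    if (!anyNA(wl) && length(unique(wl)) == 1L) {
      kept <- kept + 1L
      bouts[[kept]] <- acc_bout(
        as.matrix(series[idx, c("x", "y", "z")]),
        fs = attr(series, "fs"), label = wl[1L],
        source_offset = (w - 1L) * L,
        axis_map = config$axis_map)
    }
  }
  list(bouts = bouts[seq_len(kept)], pruned_count = n_win - kept)
}
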