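#' Dataset configuration
#'
#' Describes how a deployment recorded ACC data and how it should be
#' processed downstream: sampling frequency, bout length, sensor range,
#' raw storage width, tracker placement and the behaviour catalogue.
#' The placement determines which simplified feature set applies (see
#' [placement_profile()]), and `axis_map` records which file column
#' corresponds to which body axis (surge = longitudinal, sway = lateral,
#' heave = vertical).
#'
#' @param fs Sampling frequency in Hz.
#' @param bout_len_records Number of ACC records per bout (>= 2).
#' @param placement Tracker attachment, one of `"back"`, `"collar"`,
#'   `"leg"`, `"ear"`.
#' @param behaviours Character vector of behaviour category names.
#' @param sensor_range_g Sensor full-scale range in g (samples outside
#'   `[-range, range]` trigger a warning on read).
#' @param bytes_per_value Storage width of one raw axis value in bytes
#'   (typical loggers pack 12-bit samples into 2 bytes).
#' @param axis_map Named character vector mapping body axes to file
#'   columns, a permutation of `c(surge=, sway=, heave=)` over
#'   `"x","y","z"`.
#' @param static_window Optional window length (records, odd) for the
#'   centred running mean used to estimate static acceleration; `NULL`
#'   means the whole bout (static = per-axis bout mean).
#'
#' @return An object of class `"acc_config"`.
#' @examples
#' acc_config(fs = 10.54, bout_len_records = 40, placement = "back")
#' @export
acc_config <- function(fs, bout_len_records,
                       placement = c("back", "collar", "leg", "ear"),
                       behaviours = character(),
                       sensor_range_g = 4, bytes_per_value = 2,
                       axis_map = c(surge = "x", sway = "y", heave = "z"),
                       static_window = NULL) {
  placement <- match.arg(placement)
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  bout_len_records <- as.integer(bout_len_records)
  if (bout_len_records < 2L)
    stop("bout_len_records must be >= 2", call. = FALSE)
  if (bytes_per_value < 1)
    stop("bytes_per_value must be >= 1", call. = FALSE)
  check_axis_map(axis_map)
  if (!is.null(static_window)) {
    static_window <- as.integer(static_window)
    stopifnot(static_window >= 1L)
  }
  structure(list(fs = fs, bout_len_records = bout_len_records,
                 placement = placement, behaviours = as.character(behaviours),
                 sensor_range_g = sensor_range_g,
                 bytes_per_value = bytes_per_value,
                 axis_map = axis_map, static_window = static_window),
            class = "acc_config")
}

check_axis_map <- function(axis_map) {
  if (!setequal(names(axis_map), c("surge", "sway", "heave")) ||
      !setequal(axis_map, c("x", "y", "z")))
    stop("axis_map must map {surge, sway, heave} onto {x, y, z}",
         call. = FALSE)
  invisible(axis_map)
}

#' @export
print.acc_config <- function(x, ...) {
  cat("ACC dataset configuration\n")
  cat(sprintf("  fs: %g Hz, bout length: %d records (%.2f s)\n",
              x$fs, x$bout_len_records, x$bout_len_records / x$fs))
  cat(sprintf("  placement: %s, range: +/- %g g, %d bytes/value\n",
              x$placement, x$sensor_range_g, x$bytes_per_value))
  cat(sprintf("  axis map: surge=%s sway=%s heave=%s\n",
              x$axis_map[["surge"]], x$axis_map[["sway"]],
              x$axis_map[["heave"]]))
  if (length(x$behaviours))
    cat("  behaviours:", paste(x$behaviours, collapse = ", "), "\n")
  invisible(x)
}

#' Read a dataset configuration from a YAML file
#'
#' Keys mirror the arguments of [acc_config()]; `axis_map` is given as a
#' mapping `surge: x` etc.
#'
#' @param path Path to a YAML file.
#' @return An `"acc_config"`.
#' @export
read_acc_config <- function(path) {
  y <- yaml::read_yaml(path)
  am <- if (is.null(y$axis_map)) c(surge = "x", sway = "y", heave = "z")
        else unlist(y$axis_map)
  acc_config(fs = y$fs, bout_len_records = y$bout_len_records,
             placement = y$placement %||% "back",
             behaviours = y$behaviours %||% character(),
             sensor_range_g = y$sensor_range_g %||% 4,
             bytes_per_value = y$bytes_per_value %||% 2,
             axis_map = am, static_window = y$static_window)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a triaxial acceleration series
#'
#' A uniformly sampled triaxial stream. Time is seconds from stream
#' start; values are in g (1 g = 9.8 m/s^2).
#'
#' @param t Sample times in seconds, strictly increasing and uniformly
#'   spaced at `1/fs`.
#' @param x,y,z Acceleration in g along the three sensor axes.
#' @param fs Sampling frequency in Hz.
#' @param axis_map Body-axis to column mapping (see [acc_config()]).
#' @return A data frame of class `"acc_series"` with columns `t,x,y,z`
#'   and attributes `fs` and `axis_map`.
#' @export
acc_series <- function(t, x, y, z, fs,
                       axis_map = c(surge = "x", sway = "y", heave = "z")) {
  stopifnot(length(t) == length(x), length(x) == length(y),
            length(y) == length(z))
  if (anyNA(t) || anyNA(x) || anyNA(y) || anyNA(z))
    stop("acc_series values must be finite (no NA)", call. = FALSE)
  if (!all(is.finite(c(x, y, z))))
    stop("acc_series values must be finite", call. = FALSE)
  if (length(t) > 1L) {
    dt <- diff(t)
    if (any(dt <= 0))
      stop("sample times must be strictly increasing", call. = FALSE)
    if (any(abs(dt - 1 / fs) > 1e-4 / fs))
      stop("inter-sample spacing must equal 1/fs", call. = FALSE)
  }
  check_axis_map(axis_map)
  structure(data.frame(t = t, x = x, y = y, z = z),
            fs = fs, axis_map = axis_map,
            class = c("acc_series", "data.frame"))
}

#' @export
print.acc_series <- function(x, ...) {
  cat(sprintf("ACC series: %d samples at %g Hz (%.1f s)\n",
              nrow(x), attr(x, "fs"), nrow(x) / attr(x, "fs")))
  print(head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Read a raw ACC stream from delimited text
#'
#' Expects a comma-delimited file with header `t,x,y,z`: time in seconds
#' from stream start and the three acceleration axes in g. Rows must be
#' in strictly increasing time order. Samples outside the configured
#' sensor range raise a warning but are kept.
#'
#' @param path Path to the CSV file.
#' @param config An [acc_config()]; supplies `fs`, the sensor range and
#'   the axis map.
#' @return An [acc_series()].
#' @export
read_acc_csv <- function(path, config) {
  stopifnot(inherits(config, "acc_config"))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("ACC file must have columns t,x,y,z; found: ",
         paste(names(df), collapse = ","), call. = FALSE)
  df <- df[need]
  for (cn in need) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("malformed value in column '%s' at data line %d of %s",
                   cn, bad[1L], path), call. = FALSE)
    df[[cn]] <- v
  }
  if (nrow(df) > 1L && any(diff(df$t) <= 0))
    stop("time column is not strictly increasing in ", path, call. = FALSE)
  rng <- config$sensor_range_g
  n_out <- sum(abs(df$x) > rng | abs(df$y) > rng | abs(df$z) > rng)
  if (n_out > 0)
    warning(sprintf("%d sample(s) outside +/- %g g sensor range (kept)",
                    n_out, rng), call. = FALSE)
  acc_series(df$t - df$t[1L], df$x, df$y, df$z, fs = config$fs,
             axis_map = config$axis_map)
}

#' Write an ACC stream to delimited text
#'
#' Inverse of [read_acc_csv()]; values round-trip to at least six decimal
#' places.
#'
#' @param series An [acc_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_acc_csv <- function(series, path) {
  stopifnot(inherits(series, "acc_series"))
  df <- as.data.frame(series)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct behaviour label intervals
#'
#' Ground-truth observation intervals. A sample at time `t` carries the
#' label of the interval with `t_start <= t < t_end` (half-open), so
#' adjacent intervals never double-label a sample. Intervals are sorted
#' by start time and must not overlap.
#'
#' @param t_start,t_end Interval bounds in seconds (`t_start < t_end`).
#' @param label Behaviour category per interval.
#' @return A data frame of class `"label_intervals"` sorted by `t_start`.
#' @export
label_intervals <- function(t_start, t_end, label) {
  stopifnot(length(t_start) == length(t_end),
            length(t_end) == length(label))
  if (any(!is.finite(t_start)) || any(!is.finite(t_end)))
    stop("interval bounds must be finite", call. = FALSE)
  if (any(t_start >= t_end))
    stop("every interval must satisfy t_start < t_end", call. = FALSE)
  o <- order(t_start)
  t_start <- t_start[o]; t_end <- t_end[o]; label <- as.character(label)[o]
  if (length(t_start) > 1L && any(t_start[-1L] < t_end[-length(t_end)]))
    stop("label intervals must not overlap", call. = FALSE)
  structure(data.frame(t_start = t_start, t_end = t_end, label = label),
            class = c("label_intervals", "data.frame"))
}

#' Read behaviour label intervals from delimited text
#'
#' Expects a comma-delimited file with header `t_start,t_end,label`.
#' Intervals are validated (positive length, pairwise non-overlapping)
#' and returned sorted by start time.
#'
#' @param path Path to the CSV file.
#' @return A [label_intervals()] data frame.
#' @export
read_labels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_start", "t_end", "label")
  if (!all(need %in% names(df)))
    stop("label file must have columns t_start,t_end,label", call. = FALSE)
  label_intervals(as.numeric(df$t_start), as.numeric(df$t_end), df$label)
}

#' @rdname read_labels
#' @param intervals A [label_intervals()] data frame.
#' @export
write_labels <- function(intervals, path) {
  stopifnot(inherits(intervals, "label_intervals"))
  write.csv(as.data.frame(intervals), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Label of each time point under the half-open [t_start, t_end) rule;
# NA_character_ for unlabelled time.
label_at <- function(intervals, t) {
  out <- rep(NA_character_, length(t))
  if (is.null(intervals) || nrow(intervals) == 0L) return(out)
  idx <- findInterval(t, intervals$t_start)
  ok <- idx >= 1L
  ok[ok] <- t[ok] < intervals$t_end[idx[ok]]
  out[ok] <- intervals$label[idx[ok]]
  out
}
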