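#' Uniformly sampled fNIRS time series
#'
#' Lightweight container for a uniformly sampled scalar signal. Every
#' signal handled by the package -- raw optical intensities converted to
#' optical densities, chromophore concentration changes, hemodynamic
#' response curves and stimulus encodings -- is carried in this form.
#'
#' @param values numeric vector of samples.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds (default 0).
#' @param units optional character label for the sample units.
#'
#' @return An object of class `"fnirs_ts"`: a list with elements
#'   `values`, `fs`, `t0` and `units`.
#' @examples
#' x <- fnirs_ts(sin(2 * pi * 0.1 * seq(0, 10, by = 0.1)), fs = 10)
#' x
#' head(ts_times(x))
#' @export
fnirs_ts <- function(values, fs, t0 = 0, units = NULL) {
  if (!is.numeric(values) || length(values) < 1L)
    stop("'values' must be a non-empty numeric vector")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number (Hz)")
  structure(
    list(values = as.numeric(values), fs = as.numeric(fs),
         t0 = as.numeric(t0), units = units),
    class = "fnirs_ts"
  )
}

#' @export
length.fnirs_ts <- function(x) length(x$values)

#' Sample times of a time series
#'
#' @param x an [fnirs_ts] object.
#' @return numeric vector of sample times in seconds.
#' @export
ts_times <- function(x) {
  stopifnot(inherits(x, "fnirs_ts"))
  x$t0 + (seq_along(x$values) - 1) / x$fs
}

#' @export
print.fnirs_ts <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<fnirs_ts> %d samples @ %.4g Hz, t = [%.3f, %.3f] s\n",
              n, x$fs, x$t0, x$t0 + (n - 1) / x$fs))
  if (!is.null(x$units)) cat("  units:", x$units, "\n")
  cat("  range: [", format(min(x$values), digits = 5), ", ",
      format(max(x$values), digits = 5), "]\n", sep = "")
  invisible(x)
}

# internal: check two series share grid (sampling rate + length; t0 too)
check_aligned <- function(a, b, what = "series") {
  stopifnot(inherits(a, "fnirs_ts"), inherits(b, "fnirs_ts"))
  if (length(a$values) != length(b$values))
    stop(what, " differ in length (", length(a$values), " vs ",
         length(b$values), ")")
  if (abs(a$fs - b$fs) > 1e-9 * max(a$fs, b$fs))
    stop(what, " differ in sampling rate (", a$fs, " vs ", b$fs, " Hz)")
  if (abs(a$t0 - b$t0) > 1e-9)
    stop(what, " differ in time origin")
  invisible(TRUE)
}

#' Resample a time series onto a new uniform grid
#'
#' Linear interpolation onto a uniform grid with the requested sampling
#' rate spanning the same time interval as the input. Used to bring
#' signals acquired at the instrument rate (1.81 Hz) onto the 0.01 s
#' analysis grid (100 Hz). Linear interpolation is exact on piecewise
#' linear signals and introduces no ringing.
#'
#' @param x an [fnirs_ts] object with at least 2 samples.
#' @param target_fs target sampling rate in Hz (> 0).
#' @return an [fnirs_ts] at the new rate.
#' @examples
#' slow <- fnirs_ts(seq(0, 10, length.out = 20), fs = 1.81)
#' fast <- resample_to(slow, 100)
#' fast$fs
#' @export
resample_to <- function(x, target_fs) {
  stopifnot(inherits(x, "fnirs_ts"))
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0)
    stop("'target_fs' must be a single positive number (Hz)")
  if (length(x$values) < 2L)
    stop("cannot resample a series with fewer than 2 samples")
  t_old <- ts_times(x)
  t_new <- seq(x$t0, t_old[length(t_old)], by = 1 / target_fs)
  y <- stats::approx(t_old, x$values, xout = t_new, method = "linear")$y
  fnirs_ts(y, fs = target_fs, t0 = x$t0, units = x$units)
}

#' Read / write a single-channel signal CSV
#'
#' The on-disk format is a two-column CSV with header `time_s,value`,
#' uniformly sampled. The sampling rate is inferred from the median time
#' step on read.
#'
#' @param path file path.
#' @return `read_signal_csv` returns an [fnirs_ts]; `write_signal_csv`
#'   returns `path` invisibly.
#' @export
read_signal_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(d)))
    stop("expected columns 'time_s' and 'value' in ", path)
  dt <- diff(d$time_s)
  if (length(dt) < 1L) stop("need at least 2 samples in ", path)
  step <- stats::median(dt)
  if (any(abs(dt - step) > 1e-6 * max(step, 1)))
    stop("time grid in ", path, " is not uniform")
  fnirs_ts(d$value, fs = 1 / step, t0 = d$time_s[1])
}

#' @param x an [fnirs_ts] object.
#' @rdname read_signal_csv
#' @export
write_signal_csv <- function(x, path) {
  stopifnot(inherits(x, "fnirs_ts"))
  utils::write.csv(data.frame(time_s = ts_times(x), value = x$values),
                   path, row.names = FALSE)
  invisible(path)
}
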