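# Canonical double-gamma hemodynamic response: kernel, stimulus
# encoding, convolution, and attribute extraction.

#' Shape parameters of the double-gamma HRF kernel
#'
#' The canonical haemodynamic impulse response is a difference of two
#' gamma densities: a positive main response and a delayed undershoot
#' attenuated by a fixed factor of 6. `alpha1`/`beta1` are the shape
#' (delay) and rate (dispersion, 1/s) of the response, `alpha2`/`beta2`
#' those of the undershoot. The defaults peak near 5 s and settle by
#' 25-30 s, the physiologically expected timing.
#'
#' @param alpha1 delay of the response (shape, > 1 so h(0) = 0).
#' @param alpha2 delay of the undershoot (shape, > 1).
#' @param beta1 dispersion of the response (rate, 1/s, > 0).
#' @param beta2 dispersion of the undershoot (rate, 1/s, >= 0; a rate of
#'   0 switches the undershoot term off).
#' @return an object of class `"hrf_params"`.
#' @examples
#' hrf_params()                 # canonical shape
#' hrf_params(alpha1 = 7, beta1 = 1.2)
#' @export
hrf_params <- function(alpha1 = 6, alpha2 = 16, beta1 = 1, beta2 = 1) {
  p <- c(alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1, beta2 = beta2)
  if (any(!is.finite(p))) stop("HRF parameters must be finite")
  if (alpha1 <= 1 || alpha2 <= 1)
    stop("'alpha1' and 'alpha2' must exceed 1 (so the kernel is 0 at t = 0)")
  if (beta1 <= 0) stop("'beta1' must be positive")
  if (beta2 < 0) stop("'beta2' must be non-negative")
  structure(as.list(p), class = "hrf_params")
}

#' @export
print.hrf_params <- function(x, ...) {
  cat(sprintf(
    "<hrf_params> response: shape %.3g, rate %.3g /s | undershoot: shape %.3g, rate %.3g /s\n",
    x$alpha1, x$beta1, x$alpha2, x$beta2))
  cat(sprintf("  nominal peak time (alpha1-1)/beta1 = %.2f s\n",
              (x$alpha1 - 1) / x$beta1))
  invisible(x)
}

#' Canonical double-gamma HRF kernel
#'
#' Samples the impulse response
#' \deqn{h(t) = \frac{t^{\alpha_1-1}\beta_1^{\alpha_1}e^{-\beta_1 t}}{\Gamma(\alpha_1)}
#'   - \frac{t^{\alpha_2-1}\beta_2^{\alpha_2}e^{-\beta_2 t}}{6\,\Gamma(\alpha_2)}}
#' on a uniform grid. Each term is a gamma density, so the main response
#' integrates to 1 and the undershoot to 1/6 regardless of the shape
#' parameters. The divisor 6 is a fixed constant of the canonical model,
#' not a free parameter.
#'
#' @param params an [hrf_params] object.
#' @param dt sample step in seconds (> 0; default 0.01).
#' @param duration kernel support in seconds (> 0; default 32, by which
#'   time the canonical response has settled).
#' @return an [fnirs_ts] holding the kernel samples on `[0, duration]`.
#' @examples
#' h <- canonical_hrf(hrf_params(), dt = 0.01)
#' ts_times(h)[which.max(h$values)]   # about 5 s
#' @export
canonical_hrf <- function(params = hrf_params(), dt = 0.01, duration = 32) {
  stopifnot(inherits(params, "hrf_params"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a single positive number (s)")
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("'duration' must be a single positive number (s)")
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = params$alpha1, rate = params$beta1)
  if (params$beta2 > 0)
    h <- h - stats::dgamma(t, shape = params$alpha2, rate = params$beta2) / 6
  fnirs_ts(h, fs = 1 / dt, t0 = 0)
}

#' Block-design stimulus train
#'
#' A set of non-overlapping task blocks within an experiment of a given
#' total length. Encoded as a unit boxcar for convolution with the HRF
#' kernel.
#'
#' @param onsets block onset times in seconds, strictly increasing.
#' @param durations block durations in seconds (recycled to the number
#'   of onsets).
#' @param total_length total experiment length in seconds.
#' @param label identifier for the train (e.g. `"St1"`).
#' @return an object of class `"stimulus_train"`.
#' @examples
#' stimulus_train(c(15, 45, 75, 105), 15, 135, "task")
#' @export
stimulus_train <- function(onsets, durations, total_length, label = "stim") {
  onsets <- as.numeric(onsets)
  durations <- rep_len(as.numeric(durations), length(onsets))
  if (length(onsets) < 1L) stop("need at least one block")
  if (any(!is.finite(onsets)) || any(!is.finite(durations)) ||
      any(durations <= 0))
    stop("onsets and durations must be finite, durations positive")
  if (is.unsorted(onsets, strictly = TRUE))
    stop("'onsets' must be strictly increasing")
  offs <- onsets + durations
  if (any(onsets < 0) || any(offs > total_length + 1e-9))
    stop("blocks must lie within [0, total_length]")
  if (length(onsets) > 1L && any(offs[-length(offs)] > onsets[-1] + 1e-9))
    stop("blocks must not overlap")
  structure(list(onsets = onsets, durations = durations,
                 total_length = as.numeric(total_length), label = label),
            class = "stimulus_train")
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat(sprintf("<stimulus_train> '%s': %d block(s), total %.4g s\n",
              x$label, length(x$onsets), x$total_length))
  for (i in seq_along(x$onsets))
    cat(sprintf("  [%g, %g] s\n", x$onsets[i], x$onsets[i] + x$durations[i]))
  invisible(x)
}

#' Encode a stimulus train as a unit boxcar series
#'
#' @param train a [stimulus_train].
#' @param fs sampling rate in Hz.
#' @return an [fnirs_ts] of 0/1 values; a sample at time t is 1 when t
#'   lies in `[onset, onset + duration)` of some block.
#' @export
encode_boxcar <- function(train, fs) {
  stopifnot(inherits(train, "stimulus_train"))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive number (Hz)")
  t <- seq(0, train$total_length, by = 1 / fs)
  u <- numeric(length(t))
  for (i in seq_along(train$onsets)) {
    on <- train$onsets[i]
    off <- on + train$durations[i]
    u[t >= on - 1e-12 & t < off - 1e-12] <- 1
  }
  fnirs_ts(u, fs = fs, t0 = 0)
}

#' Convolve a stimulus encoding with an HRF kernel
#'
#' Discrete convolution scaled by the sample step, truncated to the
#' length of the stimulus series, i.e. the sampled version of
#' `HRF(t) = (h * u)(t)`. Both series must share the sampling rate.
#'
#' @param u boxcar [fnirs_ts] from [encode_boxcar()].
#' @param h kernel [fnirs_ts] from [canonical_hrf()].
#' @return an [fnirs_ts] of the same length and grid as `u`.
#' @examples
#' u <- encode_boxcar(stimulus_train(10, 10, 50), fs = 10)
#' h <- canonical_hrf(hrf_params(), dt = 0.1)
#' r <- convolve_hrf(u, h)
#' @export
convolve_hrf <- function(u, h) {
  stopifnot(inherits(u, "fnirs_ts"), inherits(h, "fnirs_ts"))
  if (abs(u$fs - h$fs) > 1e-9 * max(u$fs, h$fs))
    stop("'u' and 'h' must share the same sampling rate")
  dt <- 1 / u$fs
  full <- stats::convolve(u$values, rev(h$values), type = "open") * dt
  fnirs_ts(full[seq_along(u$values)], fs = u$fs, t0 = u$t0)
}

#' Extract HRF attributes from a response curve
#'
#' Summarises a (reconstructed or fitted) response over one task window
#' into the attributes that DPF mis-specification is known to distort:
#'
#' * `baseline_offset`: mean over the pre-onset rest;
#' * `peak_value`, `time_to_peak`: global maximum over
#'   `[onset, offset + 10 s]` (delayed peaks are common, hence the 10 s
#'   grace window); ties broken at the earliest time;
#' * `fwhm`: full width at half maximum of the main response measured
#'   above the baseline, with half-maximum crossings located by linear
#'   interpolation between bracketing samples (`NA` when there is no
#'   positive response above baseline or a crossing is not bracketed);
#' * `undershoot_depth`: `max(0, baseline - min)` over the post-stimulus
#'   interval `(offset, end]`.
#'
#' @param x an [fnirs_ts] response curve.
#' @param task_window numeric length-2, task onset and offset in seconds;
#'   must lie within the series (with pre-onset samples available and the
#'   series extending past the offset).
#' @return a list of class `"hrf_attributes"` with elements `peak_value`,
#'   `time_to_peak`, `fwhm`, `undershoot_depth`, `baseline_offset`.
#' @export
hrf_attributes <- function(x, task_window) {
  stopifnot(inherits(x, "fnirs_ts"))
  if (length(task_window) != 2L || task_window[1] >= task_window[2])
    stop("'task_window' must be c(onset, offset) with onset < offset")
  t <- ts_times(x)
  on <- task_window[1]; off <- task_window[2]
  if (on <= t[1] || off >= t[length(t)])
    stop("task window must lie strictly inside the series span ",
         "(pre-onset rest and post-offset samples are required)")
  v <- x$values

  baseline <- mean(v[t < on])

  sel <- which(t >= on & t <= off + 10)
  ipk <- sel[which.max(v[sel])]   # which.max -> earliest tie
  peak <- v[ipk]
  tpk <- t[ipk]

  fwhm <- NA_real_
  amp <- peak - baseline
  if (amp > 0) {
    half <- baseline + amp / 2
    # walk left then right from the peak to the first sample below half,
    # interpolating the crossing linearly
    left <- NA_real_; right <- NA_real_
    i <- ipk
    while (i > 1 && v[i] >= half) i <- i - 1
    if (v[i] < half)
      left <- t[i] + (half - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
    j <- ipk
    n <- length(v)
    while (j < n && v[j] >= half) j <- j + 1
    if (v[j] < half)
      right <- t[j - 1] + (v[j - 1] - half) / (v[j - 1] - v[j]) *
        (t[j] - t[j - 1])
    if (is.finite(left) && is.finite(right)) fwhm <- right - left
  }

  post <- v[t > off]
  undershoot <- max(0, baseline - min(post))

  structure(list(peak_value = peak, time_to_peak = tpk, fwhm = fwhm,
                 undershoot_depth = undershoot, baseline_offset = baseline),
            class = "hrf_attributes")
}

#' @export
print.hrf_attributes <- function(x, ...) {
  cat("<hrf_attributes>\n")
  cat(sprintf("  peak %.4g at %.2f s | fwhm %s s | undershoot %.4g | baseline %.4g\n",
              x$peak_value, x$time_to_peak,
              ifelse(is.na(x$fwhm), "NA", sprintf("%.2f", x$fwhm)),
              x$undershoot_depth, x$baseline_offset))
  invisible(x)
}
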