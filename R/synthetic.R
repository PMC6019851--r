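# Synthetic fNIRS signal generator: baseline + scaled HRF + cardiac,
# respiratory and Mayer-wave sinusoids + Gaussian noise, under the
# block-design paradigms used in the analysis.

#' Baseline, activity and physiological-noise parameters
#'
#' Parameters of the optical signal model
#' `y(t) = a0 + a1 HRF(t) + ac sin(2 pi fc t) + ar sin(2 pi fr t) +
#'  am sin(2 pi fm t) + e(t)` with `e ~ N(0, noise_sd^2)`.
#' Defaults are physiologically plausible resting values inside the
#' fitting constraints: cardiac ~1 Hz (60 bpm), respiration 0.25 Hz
#' (15 breaths/min), Mayer waves ~0.095 Hz, modest nuisance amplitudes
#' relative to an activity strength of 6.
#'
#' @param a0 baseline (signal units).
#' @param a1 activity strength (gain on the convolved HRF).
#' @param ac,ar,am amplitudes of the cardiac, respiratory and Mayer
#'   sinusoids (>= 0).
#' @param fc,fr,fm their frequencies in Hz (> 0).
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (>= 0).
#' @return an object of class `"nuisance_params"`.
#' @examples
#' nuisance_params()                        # defaults
#' nuisance_params(noise_sd = 0)            # deterministic signal
#' @export
nuisance_params <- function(a0 = 2, a1 = 6, ac = 0.4, ar = 0.3, am = 0.3,
                            fc = 1.0, fr = 0.25, fm = 0.095,
                            noise_sd = 0.1) {
  p <- c(a0 = a0, a1 = a1, ac = ac, ar = ar, am = am,
         fc = fc, fr = fr, fm = fm, noise_sd = noise_sd)
  if (any(!is.finite(p))) stop("nuisance parameters must be finite")
  if (any(c(ac, ar, am) < 0)) stop("sinusoid amplitudes must be >= 0")
  if (any(c(fc, fr, fm) <= 0)) stop("sinusoid frequencies must be > 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(as.list(p), class = "nuisance_params")
}

#' @export
print.nuisance_params <- function(x, ...) {
  cat(sprintf("<nuisance_params> a0 %.3g, a1 %.3g | cardiac %.3g@%.3g Hz, resp %.3g@%.3g Hz, Mayer %.3g@%.3g Hz | noise sd %.3g\n",
              x$a0, x$a1, x$ac, x$fc, x$ar, x$fr, x$am, x$fm, x$noise_sd))
  invisible(x)
}

#' Block-design paradigm of the finger-tapping protocol
#'
#' 15 s initial rest followed by four trials of 15 s task + 15 s rest:
#' onsets at 15, 45, 75 and 105 s, total length 135 s.
#'
#' @return a [stimulus_train].
#' @export
task_paradigm <- function() {
  stimulus_train(onsets = c(15, 45, 75, 105), durations = 15,
                 total_length = 135, label = "task")
}

#' Built-in simulation stimulus patterns
#'
#' The five simulation patterns St1-St5 are boxcar trains built from a
#' common task duration: St1 one block; St2 two blocks with a 20 s gap;
#' St3 three blocks with 15 s gaps; St4 two blocks with a 10 s gap;
#' St5 a full-duration block then a half-duration block with a 15 s gap.
#' Each pattern is a list with `mult` (per-block duration multipliers)
#' and `gaps` (inter-block gaps in s); users may pass modified
#' definitions to [simulated_paradigm()].
#'
#' @return named list of pattern definitions.
#' @examples
#' names(stimulus_patterns())
#' @export
stimulus_patterns <- function() {
  list(
    St1 = list(mult = 1,           gaps = numeric(0)),
    St2 = list(mult = c(1, 1),     gaps = 20),
    St3 = list(mult = c(1, 1, 1),  gaps = c(15, 15)),
    St4 = list(mult = c(1, 1),     gaps = 10),
    St5 = list(mult = c(1, 0.5),   gaps = 15)
  )
}

#' Simulation paradigm: initial rest, stimulus train, terminal rest
#'
#' Builds the block design used for the simulated data sets: 10 s of
#' initial rest, the chosen stimulus pattern with activation blocks of
#' the given duration, then 30 s of terminal rest.
#'
#' @param task_s activation-block duration in seconds; the study grid is
#'   10, 20 or 30 s (other positive values are accepted with a warning).
#' @param pattern a pattern label from [stimulus_patterns()] or a
#'   pattern definition list with elements `mult` and `gaps`.
#' @param initial_rest,final_rest rest durations in seconds.
#' @return a [stimulus_train].
#' @examples
#' simulated_paradigm(20, "St1")    # 10 + 20 + 30 = 60 s
#' simulated_paradigm(10, "St3")
#' @export
simulated_paradigm <- function(task_s, pattern = "St1",
                               initial_rest = 10, final_rest = 30) {
  if (!is.numeric(task_s) || length(task_s) != 1L || task_s <= 0)
    stop("'task_s' must be a single positive duration (s)")
  if (!task_s %in% c(10, 20, 30))
    warning("task duration ", task_s,
            " s is outside the study grid {10, 20, 30} s")
  if (is.character(pattern)) {
    defs <- stimulus_patterns()
    if (!pattern %in% names(defs))
      stop("unknown stimulus pattern '", pattern, "'; available: ",
           paste(names(defs), collapse = ", "))
    label <- pattern
    pattern <- defs[[pattern]]
  } else {
    if (!is.list(pattern) || !all(c("mult", "gaps") %in% names(pattern)))
      stop("a custom pattern must be a list with elements 'mult' and 'gaps'")
    label <- "custom"
  }
  durs <- task_s * pattern$mult
  gaps <- pattern$gaps
  if (length(gaps) != length(durs) - 1L)
    stop("pattern must define one gap fewer than blocks")
  onsets <- initial_rest + c(0, cumsum(durs[-length(durs)] + gaps))
  total <- onsets[length(onsets)] + durs[length(durs)] + final_rest
  stimulus_train(onsets, durs, total, label = label)
}

#' Generate a synthetic fNIRS HbO signal
#'
#' Samples the optical signal model: baseline plus activity-scaled
#' convolved HRF plus the three physiological sinusoids plus Gaussian
#' noise, on a uniform grid at rate `fs` over the paradigm. Time enters
#' the sinusoids in seconds, so frequencies are in Hz. The sampling rate
#' must exceed twice the highest nuisance frequency, otherwise the
#' cardiac component would alias.
#'
#' @param hrf an [hrf_params] object (shape of the impulse response).
#' @param nuisance a [nuisance_params] object.
#' @param paradigm a [stimulus_train].
#' @param fs sampling rate in Hz.
#' @param seed optional integer; when given, the Gaussian noise is drawn
#'   reproducibly and two calls with identical arguments return
#'   identical signals.
#' @return an [fnirs_ts] over `[0, total_length]`.
#' @examples
#' y <- generate_signal(hrf_params(), nuisance_params(noise_sd = 0),
#'                      simulated_paradigm(20, "St1"), fs = 10)
#' @export
generate_signal <- function(hrf = hrf_params(), nuisance = nuisance_params(),
                            paradigm = task_paradigm(), fs = 100,
                            seed = NULL) {
  stopifnot(inherits(hrf, "hrf_params"),
            inherits(nuisance, "nuisance_params"),
            inherits(paradigm, "stimulus_train"))
  amps <- c(nuisance$ac, nuisance$ar, nuisance$am)
  freqs <- c(nuisance$fc, nuisance$fr, nuisance$fm)
  fmax <- if (any(amps > 0)) max(freqs[amps > 0]) else 0
  if (fs <= 2 * fmax)
    stop("sampling rate ", fs, " Hz is too low: it must exceed twice the ",
         "highest nuisance frequency (", fmax,
         " Hz) or the sinusoids alias")
  u <- encode_boxcar(paradigm, fs)
  h <- canonical_hrf(hrf, dt = 1 / fs)
  resp <- convolve_hrf(u, h)
  t <- ts_times(u)
  y <- nuisance$a0 + nuisance$a1 * resp$values +
    nuisance$ac * sin(2 * pi * nuisance$fc * t) +
    nuisance$ar * sin(2 * pi * nuisance$fr * t) +
    nuisance$am * sin(2 * pi * nuisance$fm * t)
  if (nuisance$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(length(y), 0, nuisance$noise_sd)
  }
  fnirs_ts(y, fs = fs, t0 = 0)
}

#' Deterministic part of the signal model
#'
#' The noise-free model prediction used both by the generator and as
#' the forward model inside the fit: baseline + a1 * (u * h) + the three
#' sinusoids. Exposed for residual checks and plotting.
#'
#' @inheritParams generate_signal
#' @return an [fnirs_ts].
#' @export
model_prediction <- function(hrf, nuisance, paradigm, fs) {
  nn <- nuisance
  nn$noise_sd <- 0
  class(nn) <- class(nuisance)
  generate_signal(hrf, nn, paradigm, fs)
}
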