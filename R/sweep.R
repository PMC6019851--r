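# DPF sweeps: reconstruct or refit the response across a range of DPF
# values and tabulate the HRF attributes of each curve.

task_window_of <- function(paradigm) {
  k <- length(paradigm$onsets)
  c(paradigm$onsets[1], paradigm$onsets[k] + paradigm$durations[k])
}

attrs_row <- function(attrs) {
  if (is.null(attrs))
    return(data.frame(peak_value = NA_real_, time_to_peak_s = NA_real_,
                      fwhm_s = NA_real_, undershoot_depth = NA_real_,
                      baseline_offset = NA_real_))
  data.frame(peak_value = attrs$peak_value,
             time_to_peak_s = attrs$time_to_peak,
             fwhm_s = attrs$fwhm,
             undershoot_depth = attrs$undershoot_depth,
             baseline_offset = attrs$baseline_offset)
}

#' Reconstruction sweep of a split over DPF values
#'
#' Reconstructs the HbO series from a sign-constrained split under each
#' DPF value in turn (varying one wavelength's DPF, holding the other
#' fixed) and extracts the HRF attributes of each reconstruction.
#'
#' @param split an [od_split].
#' @param paradigm the [stimulus_train] the series was generated under
#'   (defines the attribute windows).
#' @param dpf_values DPF values to sweep (default 3:8, the range over
#'   which the study compiles results).
#' @param vary which wavelength's DPF to vary, `"l1"` or `"l2"`.
#' @param fixed_dpf value held for the other wavelength; defaults to its
#'   implied true value.
#' @return a data frame with one row per DPF value: `label`, `case`,
#'   `dpf_l1`, `dpf_l2` and the five attribute columns.
#' @export
sweep_reconstruct <- function(split, paradigm, dpf_values = 3:8,
                              vary = c("l1", "l2"), fixed_dpf = NULL) {
  stopifnot(inherits(split, "od_split"), inherits(paradigm, "stimulus_train"))
  vary <- match.arg(vary)
  if (any(dpf_values <= 0)) stop("'dpf_values' must be positive")
  truth <- implied_true_dpf()
  if (is.null(fixed_dpf))
    fixed_dpf <- if (vary == "l1") truth[["dpf_l2"]] else truth[["dpf_l1"]]
  window <- task_window_of(paradigm)
  rows <- lapply(dpf_values, function(d) {
    d1 <- if (vary == "l1") d else fixed_dpf
    d2 <- if (vary == "l2") d else fixed_dpf
    rec <- reconstruct_under_dpf(split, d1, d2)
    at <- tryCatch(hrf_attributes(rec, window), error = function(e) NULL)
    cbind(data.frame(label = paradigm$label, case = split$case$label,
                     dpf_l1 = d1, dpf_l2 = d2), attrs_row(at))
  })
  do.call(rbind, rows)
}

#' Fit sweep over DPF values
#'
#' Refits the twelve-parameter model once per DPF value, varying one
#' wavelength's DPF and holding the other fixed, and extracts the HRF
#' attributes of each fitted activation curve (`a0 + a1 * HRF`). A fit
#' failure in one row is caught and reported as `NA` attributes; the
#' sweep continues.
#'
#' @param pair an [od_pair].
#' @param paradigm the [stimulus_train] matching the pair.
#' @param dpf_values DPF values to sweep (default 3:8).
#' @param vary `"l1"` or `"l2"`.
#' @param fixed_dpf DPF of the non-varied wavelength (default: the
#'   pair's own value for that wavelength).
#' @param ... further arguments to [fit_hrf()] (`n_restarts`, `seed`,
#'   `max_iter`, ...).
#' @return a data frame with one row per DPF value: `label`, `case`
#'   (`NA`), `dpf_l1`, `dpf_l2`, attribute columns, plus `j2` and
#'   `converged`.
#' @export
sweep_fit <- function(pair, paradigm, dpf_values = 3:8,
                      vary = c("l1", "l2"), fixed_dpf = NULL, ...) {
  stopifnot(inherits(pair, "od_pair"), inherits(paradigm, "stimulus_train"))
  vary <- match.arg(vary)
  if (any(dpf_values <= 0)) stop("'dpf_values' must be positive")
  if (is.null(fixed_dpf))
    fixed_dpf <- if (vary == "l1") pair$dpf_l2 else pair$dpf_l1
  window <- task_window_of(paradigm)
  rows <- lapply(dpf_values, function(d) {
    d1 <- if (vary == "l1") d else fixed_dpf
    d2 <- if (vary == "l2") d else fixed_dpf
    res <- tryCatch({
      fit <- fit_hrf(pair, paradigm, dpf_l1 = d1, dpf_l2 = d2, ...)
      act <- predict(fit, type = "activation")
      at <- tryCatch(hrf_attributes(act, window), error = function(e) NULL)
      cbind(attrs_row(at),
            data.frame(j2 = fit$j2, converged = fit$converged))
    }, error = function(e) {
      warning("fit failed at DPF ", d, " (", vary, "): ",
              conditionMessage(e))
      cbind(attrs_row(NULL), data.frame(j2 = NA_real_, converged = NA))
    })
    cbind(data.frame(label = paradigm$label, case = NA_character_,
                     dpf_l1 = d1, dpf_l2 = d2), res)
  })
  do.call(rbind, rows)
}
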