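# Age/wavelength models of the differential path-length factor (DPF).
# The DPF scales the source-detector separation to the mean optical path
# actually travelled by scattered NIR photons through scalp, skull and
# cortex; mis-specifying it biases every MBLL concentration estimate.

# published coefficient triples (intercept, slope, exponent) of the
# age-calibration at the four measured wavelengths
.dpf_calib <- list(
  `690` = c(5.38, 0.049, 0.877),
  `744` = c(5.11, 0.106, 0.723),
  `807` = c(4.99, 0.067, 0.814),
  `832` = c(4.67, 0.062, 0.819)
)

#' DPF from the per-wavelength age calibrations
#'
#' Evaluates the empirical age calibration of the differential
#' path-length factor at one of the four wavelengths for which the
#' calibration was measured (690, 744, 807, 832 nm). Each calibration
#' has the form `intercept + slope * age^exponent`, so the intercept is
#' the newborn (age 0) value.
#'
#' @param wavelength_nm one of 690, 744, 807 or 832 (nm).
#' @param age_years subject age in years (>= 0); may be a vector and may
#'   be fractional (the source cohort spans 1 day to 50 years).
#' @return dimensionless DPF value(s), one per age.
#' @seealso [dpf_general()] for the continuous age-wavelength surface.
#' @examples
#' dpf_calibrated(690, 0)    # newborn intercept, 5.38
#' dpf_calibrated(832, 25)
#' @export
dpf_calibrated <- function(wavelength_nm, age_years) {
  if (length(wavelength_nm) != 1L ||
      !as.character(wavelength_nm) %in% names(.dpf_calib))
    stop("'wavelength_nm' must be one of the calibrated wavelengths: ",
         "690, 744, 807, 832 nm")
  if (!is.numeric(age_years) || any(!is.finite(age_years)) ||
      any(age_years < 0))
    stop("'age_years' must be finite and >= 0")
  cf <- .dpf_calib[[as.character(wavelength_nm)]]
  cf[1] + cf[2] * age_years^cf[3]
}

#' DPF as a continuous function of age and wavelength
#'
#' Evaluates the published age-wavelength surface
#' \deqn{DPF(\lambda, A) = 223.3 + 0.05624 A^{0.8493}
#'   - 5.723\times 10^{-7}\lambda^3 + 0.001245\lambda^2 - 0.9025\lambda}
#' valid over the near-infrared window. The wavelength polynomial is
#' cubic, so the function refuses to extrapolate outside 650-900 nm, and
#' ages are restricted to 0-100 years.
#'
#' @param wavelength_nm wavelength in nm, within [650, 900]; vectorised.
#' @param age_years age in years, within [0, 100]; vectorised.
#' @return dimensionless DPF value(s).
#' @examples
#' dpf_general(807, 0)         # close to 5.0
#' dpf_general(c(760, 830), 28)
#' @export
dpf_general <- function(wavelength_nm, age_years) {
  if (!is.numeric(wavelength_nm) || any(!is.finite(wavelength_nm)) ||
      any(wavelength_nm < 650) || any(wavelength_nm > 900))
    stop("'wavelength_nm' must lie in the NIR window [650, 900] nm; ",
         "the cubic wavelength term is unsafe to extrapolate")
  if (!is.numeric(age_years) || any(!is.finite(age_years)) ||
      any(age_years < 0) || any(age_years > 100))
    stop("'age_years' must lie in [0, 100]")
  l <- wavelength_nm
  223.3 + 0.05624 * age_years^0.8493 -
    5.723e-7 * l^3 + 0.001245 * l^2 - 0.9025 * l
}
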