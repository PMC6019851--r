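# Sign-constrained decomposition of an HbO series into per-wavelength
# optical densities. Per sample the model
#   y(k) = 0.0375 * OD2(k) - 0.01644 * OD1(k)
# is one equation in two unknowns; the split picks, within the required
# sign quadrant, the minimum-norm point on that line (or, when the line
# misses the quadrant entirely, the quadrant point closest to it).

#' Sign-constraint cases for the optical-density split
#'
#' The four quadrant constraints under which the split is solved:
#' case1 both densities non-negative; case2 both non-positive;
#' case3 OD1 >= 0 and OD2 <= 0; case4 OD1 <= 0 and OD2 >= 0.
#' Because the reconstruction weights OD2 positively and OD1 negatively,
#' case3 can only produce non-positive output and case4 only
#' non-negative output; samples of the opposite sign are infeasible
#' under those cases. Constraints are non-strict so that the origin is
#' always admissible.
#'
#' @param label one of `"case1"`, `"case2"`, `"case3"`, `"case4"`.
#' @return an object of class `"sign_case"` with elements `label`,
#'   `sign_l1` and `sign_l2` (+1 or -1).
#' @examples
#' sign_case("case3")
#' @export
sign_case <- function(label = c("case1", "case2", "case3", "case4")) {
  label <- match.arg(label)
  s <- switch(label,
              case1 = c(1, 1), case2 = c(-1, -1),
              case3 = c(1, -1), case4 = c(-1, 1))
  structure(list(label = label, sign_l1 = s[1], sign_l2 = s[2]),
            class = "sign_case")
}

#' @export
print.sign_case <- function(x, ...) {
  cat(sprintf("<sign_case> %s: OD1 %s 0, OD2 %s 0\n", x$label,
              ifelse(x$sign_l1 > 0, ">=", "<="),
              ifelse(x$sign_l2 > 0, ">=", "<=")))
  invisible(x)
}

#' Split objective: squared misfit of an OD pair against an HbO series
#'
#' `J1 = sum_k (y(k) - 0.0375 OD2(k) + 0.01644 OD1(k))^2`, the cost the
#' sign-constrained split minimises. The constants are the fixed
#' calibration products of the 760/830 nm model.
#'
#' @param y target HbO [fnirs_ts].
#' @param pair an [od_pair] aligned with `y`.
#' @return non-negative scalar.
#' @export
j1_residual <- function(y, pair) {
  stopifnot(inherits(y, "fnirs_ts"), inherits(pair, "od_pair"))
  check_aligned(y, pair$od_l1, "series")
  r <- y$values - .SPLIT_L2 * pair$od_l2$values +
    .SPLIT_L1 * pair$od_l1$values
  sum(r^2)
}

#' Sign-constrained optical-density split of an HbO series
#'
#' For each sample, solves the one-equation / two-unknown problem
#' `0.0375 OD2 - 0.01644 OD1 = y(k)` for the minimum-norm `(OD1, OD2)`
#' inside the case's sign quadrant. The constrained minimiser is either
#' the unconstrained perpendicular-foot point (when it satisfies the
#' signs) or its projection onto an admissible axis. When the line does
#' not intersect the quadrant at all -- positive `y` under case3,
#' negative `y` under case4 -- the sample is infeasible; the split
#' returns the quadrant point closest to the line (the origin) and the
#' sample contributes `y(k)^2` to the residual.
#'
#' The solution is closed-form, deterministic and residual-optimal:
#' `residual_j1` is exactly the sum of `y^2` over infeasible samples and
#' 0 whenever every sample is feasible.
#'
#' @param y an [fnirs_ts] HbO series (finite values).
#' @param case a [sign_case] or a case label.
#' @return an object of class `"od_split"`: list with elements `pair`
#'   (an [od_pair] carrying the implied true DPFs), `residual_j1`,
#'   `infeasible_fraction`, `infeasible` (logical per sample), `case`
#'   and `y`.
#' @examples
#' y <- generate_signal(hrf_params(), nuisance_params(noise_sd = 0),
#'                      simulated_paradigm(10, "St1"), fs = 10)
#' s <- split_signal(y, "case1")
#' s$residual_j1              # 0: case1 is always feasible
#' @export
split_signal <- function(y, case = "case1") {
  stopifnot(inherits(y, "fnirs_ts"))
  if (any(!is.finite(y$values))) stop("'y' must be finite")
  if (!inherits(case, "sign_case")) case <- sign_case(case)
  c1 <- .SPLIT_L1; c2 <- .SPLIT_L2
  D <- c1^2 + c2^2
  v <- y$values
  s1 <- case$sign_l1; s2 <- case$sign_l2

  # unconstrained minimum-norm point on the line c2*b - c1*a = y
  a <- -c1 * v / D
  b <- c2 * v / D
  ok0 <- s1 * a >= 0 & s2 * b >= 0

  # axis candidates (one coordinate clamped to zero)
  a1_ok <- s2 * (v / c2) >= 0                 # (0, y/c2)
  a2_ok <- s1 * (-v / c1) >= 0                # (-y/c1, 0)
  use_a1 <- !ok0 & a1_ok                      # |y|/c2 < |y|/c1: prefer A1
  use_a2 <- !ok0 & !a1_ok & a2_ok
  a[use_a1] <- 0;               b[use_a1] <- v[use_a1] / c2
  a[use_a2] <- -v[use_a2] / c1; b[use_a2] <- 0

  infeasible <- !ok0 & !a1_ok & !a2_ok
  a[infeasible] <- 0
  b[infeasible] <- 0

  dpf <- implied_true_dpf()
  pair <- od_pair(fnirs_ts(a, y$fs, y$t0), fnirs_ts(b, y$fs, y$t0),
                  dpf_l1 = dpf[["dpf_l1"]], dpf_l2 = dpf[["dpf_l2"]])
  structure(list(pair = pair,
                 residual_j1 = sum(v[infeasible]^2),
                 infeasible_fraction = mean(infeasible),
                 infeasible = infeasible,
                 case = case, y = y),
            class = "od_split")
}

#' @export
print.od_split <- function(x, ...) {
  cat(sprintf("<od_split> %s: %d samples, J1 residual %.4g, %.1f%% infeasible\n",
              x$case$label, length(x$y$values), x$residual_j1,
              100 * x$infeasible_fraction))
  invisible(x)
}

#' Reconstruct the HbO series from a split under swept DPFs
#'
#' Applies the fixed-coefficient reconstruction ([reconstruct_hbo()]) to
#' the split optical densities with an arbitrary DPF pair. At the
#' implied true DPFs the reconstruction returns the original series on
#' every feasible sample; moving either DPF away from its true value
#' rescales the corresponding wavelength's contribution, which is the
#' distortion mechanism under study.
#'
#' @param split an [od_split].
#' @param dpf_l1,dpf_l2 DPFs to reconstruct under (> 0); defaults are
#'   the implied true values.
#' @return an [fnirs_ts].
#' @export
reconstruct_under_dpf <- function(split,
                                  dpf_l1 = implied_true_dpf()[["dpf_l1"]],
                                  dpf_l2 = implied_true_dpf()[["dpf_l2"]]) {
  stopifnot(inherits(split, "od_split"))
  reconstruct_hbo(split$pair$od_l1, split$pair$od_l2, dpf_l1, dpf_l2)
}
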