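# Twelve-parameter HRF + physiological-noise model estimated from a
# measured optical-density pair by multi-start Nelder-Mead under the
# box constraints C1-C12. The box is enforced through a smooth
# per-coordinate logistic bijection onto unconstrained space, so every
# simplex trial point maps to an interior parameter vector.

.PARAM_NAMES <- c("alpha1", "alpha2", "beta1", "beta2",
                  "a0", "a1", "ac", "ar", "am", "fc", "fr", "fm")

#' Box constraints of the HRF + nuisance fit
#'
#' The twelve free parameters and their bounds: the four double-gamma
#' shape parameters, baseline `a0`, activity strength `a1`, the three
#' sinusoid amplitudes and the three sinusoid frequencies (Hz). The
#' frequency boxes encode physiology: cardiac 0.5-1.5 Hz, respiratory
#' 0.2-0.3 Hz, Mayer 0.09-0.1 Hz.
#'
#' @return a 12 x 2 matrix with rownames the parameter names and
#'   columns `lower`, `upper`.
#' @examples
#' hrf_constraint_box()
#' @export
hrf_constraint_box <- function() {
  m <- rbind(
    alpha1 = c(2, 10),
    alpha2 = c(6, 20),
    beta1  = c(0.5, 2),
    beta2  = c(0, 1.5),
    a0     = c(0, 20),
    a1     = c(0, 15),
    ac     = c(0, 2),
    ar     = c(0, 2),
    am     = c(0, 2),
    fc     = c(0.5, 1.5),
    fr     = c(0.2, 0.3),
    fm     = c(0.09, 0.1)
  )
  colnames(m) <- c("lower", "upper")
  m
}

# logistic bijection box <-> R^12 (interior-only: bounds map to +-Inf)
.box_to_z <- function(theta, box) {
  stats::qlogis((theta - box[, 1]) / (box[, 2] - box[, 1]))
}
.z_to_box <- function(z, box) {
  box[, 1] + (box[, 2] - box[, 1]) * stats::plogis(z)
}

# fast closure computing the model curve for a fixed paradigm/grid;
# reused by j2_cost, fit_hrf and predict. Because the stimulus encoding
# is a unit boxcar, the discrete convolution u * h equals a difference
# of cumulative sums of the kernel per task block -- exact and O(n),
# which keeps the optimiser's inner loop cheap.
.make_model_fun <- function(paradigm, fs, kernel_duration = 32) {
  u <- encode_boxcar(paradigm, fs)
  t <- ts_times(u)
  dt <- 1 / fs
  n <- length(u$values)
  tk <- seq(0, kernel_duration, by = dt)
  nk <- length(tk)
  d <- diff(c(0, u$values))
  a_idx <- which(d == 1)              # first sample of each block
  b_idx <- which(d == -1) - 1L        # last sample of each block
  if (length(b_idx) < length(a_idx)) b_idx <- c(b_idx, n)
  i <- seq_len(n)
  hi_idx <- lapply(a_idx, function(a) pmin(pmax(i - a + 1L, 0L), nk) + 1L)
  lo_idx <- lapply(b_idx, function(b) pmin(pmax(i - b, 0L), nk) + 1L)
  two_pi_t <- 2 * pi * t
  function(p) {
    h <- stats::dgamma(tk, shape = p[["alpha1"]], rate = p[["beta1"]])
    if (p[["beta2"]] > 0)
      h <- h - stats::dgamma(tk, shape = p[["alpha2"]],
                             rate = p[["beta2"]]) / 6
    cs <- c(0, cumsum(h))
    resp <- numeric(n)
    for (j in seq_along(a_idx))
      resp <- resp + (cs[hi_idx[[j]]] - cs[lo_idx[[j]]])
    p[["a0"]] + p[["a1"]] * (resp * dt) +
      p[["ac"]] * sin(two_pi_t * p[["fc"]]) +
      p[["ar"]] * sin(two_pi_t * p[["fr"]]) +
      p[["am"]] * sin(two_pi_t * p[["fm"]])
  }
}

# reconstruction target from an OD pair under given DPFs, on the
# paradigm grid (lengths must agree)
.fit_target <- function(pair, dpf_l1, dpf_l2) {
  reconstruct_hbo(pair$od_l1, pair$od_l2, dpf_l1, dpf_l2)
}

#' Fit objective: squared misfit of the model against the OD pair
#'
#' `J2 = sum_k (model(k) - y(k))^2` where the model is the noise-free
#' signal model (baseline + a1 * convolved HRF + three sinusoids) built
#' from the parameter vector, and `y` is the HbO series reconstructed
#' from the optical-density pair by the fixed-coefficient combination
#' under the supplied DPFs. The cost is defined for any finite parameter
#' vector; the box only constrains the optimiser.
#'
#' @param params named numeric vector with elements
#'   `alpha1, alpha2, beta1, beta2, a0, a1, ac, ar, am, fc, fr, fm`.
#' @param pair an [od_pair].
#' @param paradigm a [stimulus_train] matching the pair's grid.
#' @param dpf_l1,dpf_l2 DPFs used to reconstruct the target (> 0);
#'   default to the pair's own DPFs.
#' @param fs sampling rate in Hz; defaults to the pair's rate.
#' @return non-negative scalar.
#' @export
j2_cost <- function(params, pair, paradigm,
                    dpf_l1 = pair$dpf_l1, dpf_l2 = pair$dpf_l2,
                    fs = pair$od_l1$fs) {
  stopifnot(inherits(pair, "od_pair"), inherits(paradigm, "stimulus_train"))
  params <- params[.PARAM_NAMES]
  if (any(is.na(params)))
    stop("'params' must be a named vector containing: ",
         paste(.PARAM_NAMES, collapse = ", "))
  target <- .fit_target(pair, dpf_l1, dpf_l2)
  model <- .make_model_fun(paradigm, fs)
  m <- model(params)
  if (length(m) != length(target$values))
    stop("paradigm grid (", length(m), " samples) does not match the ",
         "OD pair (", length(target$values), " samples)")
  sum((m - target$values)^2)
}

#' Fit the HRF + physiological-noise model to an optical-density pair
#'
#' Estimates the twelve free parameters of the optical signal model by
#' minimising [j2_cost()] under the box constraints
#' ([hrf_constraint_box()]). The box is mapped to unconstrained space by
#' a per-coordinate logistic bijection and the transformed objective is
#' minimised with the Nelder-Mead simplex (standard reflection /
#' expansion / contraction / shrink coefficients 1, 2, 0.5, 0.5) from
#' `n_restarts` starting points drawn uniformly inside the box. Within
#' each restart the simplex is re-initialised at its own optimum up to
#' `n_cycles` times, which counters premature simplex collapse in twelve
#' dimensions. The best restart is returned; all randomness is governed
#' by `seed`.
#'
#' @param pair an [od_pair] (the measurement).
#' @param paradigm a [stimulus_train] whose grid at `fs` matches the
#'   pair's length.
#' @param dpf_l1,dpf_l2 DPFs under which the HbO target is
#'   reconstructed; default to the pair's DPFs.
#' @param fs sampling rate in Hz (defaults to the pair's).
#' @param n_restarts number of random starting points (default 20).
#' @param seed integer seed for the starting points.
#' @param max_iter Nelder-Mead iteration cap per cycle (default 5000).
#' @param ftol relative convergence tolerance on the simplex cost spread
#'   (default 1e-8).
#' @param n_cycles maximum simplex re-initialisations per restart.
#' @return an object of class `"hrf_fit"` with components
#'   `coefficients` (named length-12 vector inside the box), `j2`,
#'   `fitted.values`, `residuals`, `target`, `paradigm`, `fs`,
#'   `dpf_l1`, `dpf_l2`, `start_costs`, `n_restarts_used`,
#'   `n_iterations`, `converged` and `seed`. Standard methods are
#'   available: [coef()], [fitted()], [residuals()], [predict.hrf_fit()],
#'   [plot.hrf_fit()], [simulate.hrf_fit()], [summary.hrf_fit()],
#'   [deviance()].
#' @examples
#' \donttest{
#' y <- generate_signal(hrf_params(), nuisance_params(noise_sd = 0),
#'                      simulated_paradigm(20, "St1"), fs = 10)
#' pair <- split_signal(y, "case1")$pair
#' fit <- fit_hrf(pair, simulated_paradigm(20, "St1"),
#'                n_restarts = 8, seed = 1)
#' coef(fit)
#' summary(fit)
#' }
#' @export
fit_hrf <- function(pair, paradigm,
                    dpf_l1 = pair$dpf_l1, dpf_l2 = pair$dpf_l2,
                    fs = pair$od_l1$fs,
                    n_restarts = 20, seed = 1,
                    max_iter = 5000, ftol = 1e-8, n_cycles = 3) {
  stopifnot(inherits(pair, "od_pair"), inherits(paradigm, "stimulus_train"))
  if (n_restarts < 1) stop("'n_restarts' must be >= 1")
  box <- hrf_constraint_box()
  target <- .fit_target(pair, dpf_l1, dpf_l2)
  model <- .make_model_fun(paradigm, fs)
  yv <- target$values
  if (length(model(stats::setNames(rowMeans(box), .PARAM_NAMES))) !=
      length(yv))
    stop("paradigm grid does not match the OD pair length")

  obj_z <- function(z) {
    m <- model(.z_to_box(z, box))
    sum((m - yv)^2)
  }

  set.seed(seed)
  starts <- matrix(stats::runif(n_restarts * nrow(box), box[, 1], box[, 2]),
                   nrow = n_restarts, byrow = TRUE,
                   dimnames = list(NULL, .PARAM_NAMES))

  best <- NULL
  start_costs <- numeric(n_restarts)
  total_iter <- 0L
  for (r in seq_len(n_restarts)) {
    z <- .box_to_z(starts[r, ], box)
    cost <- obj_z(z)
    start_costs[r] <- cost
    conv_ok <- FALSE
    for (cyc in seq_len(n_cycles)) {
      opt <- stats::optim(z, obj_z, method = "Nelder-Mead",
                          control = list(maxit = max_iter, reltol = ftol))
      total_iter <- total_iter + opt$counts[["function"]]
      improved <- cost - opt$value
      z <- opt$par
      cost <- opt$value
      conv_ok <- opt$convergence == 0
      if (improved <= ftol * (abs(cost) + ftol)) break
    }
    if (is.null(best) || cost < best$j2)
      best <- list(j2 = cost, z = z, converged = conv_ok, restart = r)
  }

  theta <- stats::setNames(.z_to_box(best$z, box), .PARAM_NAMES)
  fitted_v <- model(theta)
  structure(list(
    coefficients = theta,
    j2 = best$j2,
    fitted.values = fnirs_ts(fitted_v, fs, target$t0),
    residuals = yv - fitted_v,
    target = target,
    paradigm = paradigm,
    fs = fs,
    dpf_l1 = dpf_l1, dpf_l2 = dpf_l2,
    start_costs = start_costs,
    best_restart = best$restart,
    n_restarts_used = n_restarts,
    n_iterations = total_iter,
    converged = best$converged,
    seed = seed,
    call = match.call()
  ), class = "hrf_fit")
}

#' @export
print.hrf_fit <- function(x, digits = 4, ...) {
  cat("Box-constrained HRF + nuisance fit (Nelder-Mead, ",
      x$n_restarts_used, " restarts)\n\n", sep = "")
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("\nJ2 = %.6g over %d samples (DPF pair %.4g / %.4g); %s\n",
              x$j2, length(x$target$values), x$dpf_l1, x$dpf_l2,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.hrf_fit <- function(object, ...) object$coefficients

#' @export
fitted.hrf_fit <- function(object, ...) object$fitted.values$values

#' @export
residuals.hrf_fit <- function(object, ...) object$residuals

#' @export
deviance.hrf_fit <- function(object, ...) object$j2

#' Predict model components from a fitted HRF model
#'
#' @param object an `"hrf_fit"`.
#' @param type `"response"` for the full deterministic model,
#'   `"activation"` for baseline + activity (`a0 + a1 * HRF`), or
#'   `"nuisance"` for the three sinusoids alone.
#' @param ... unused.
#' @return an [fnirs_ts] on the fit grid.
#' @export
predict.hrf_fit <- function(object,
                            type = c("response", "activation", "nuisance"),
                            ...) {
  type <- match.arg(type)
  p <- object$coefficients
  if (type == "response") return(object$fitted.values)
  q <- p
  if (type == "activation") q[c("ac", "ar", "am")] <- 0
  if (type == "nuisance")  { q["a0"] <- 0; q["a1"] <- 0 }
  model <- .make_model_fun(object$paradigm, object$fs)
  fnirs_ts(model(q), object$fs, object$target$t0)
}

#' Summary of a fitted HRF model
#'
#' Reports the coefficient table against its box (flagging estimates
#' within 1% of a bound), the final cost, the residual RMS, and the HRF
#' attributes of the fitted activation curve over the first-to-last task
#' window.
#'
#' @param object an `"hrf_fit"`.
#' @param ... unused.
#' @return an object of class `"summary.hrf_fit"`.
#' @export
summary.hrf_fit <- function(object, ...) {
  box <- hrf_constraint_box()
  w <- box[, 2] - box[, 1]
  near <- (object$coefficients - box[, 1] < 0.01 * w) |
    (box[, 2] - object$coefficients < 0.01 * w)
  tab <- data.frame(estimate = object$coefficients,
                    lower = box[, 1], upper = box[, 2],
                    at_bound = near)
  act <- predict(object, type = "activation")
  pr <- object$paradigm
  window <- c(pr$onsets[1],
              pr$onsets[length(pr$onsets)] + pr$durations[length(pr$durations)])
  attrs <- tryCatch(hrf_attributes(act, window), error = function(e) NULL)
  structure(list(coefficients = tab, j2 = object$j2,
                 rmse = sqrt(mean(object$residuals^2)),
                 attributes = attrs, converged = object$converged,
                 n = length(object$target$values),
                 n_restarts = object$n_restarts_used),
            class = "summary.hrf_fit")
}

#' @export
print.summary.hrf_fit <- function(x, digits = 4, ...) {
  cat("Box-constrained HRF + nuisance fit\n\n")
  print(cbind(round(x$coefficients[, 1:3], digits),
              at_bound = x$coefficients$at_bound))
  cat(sprintf("\nJ2 = %.6g, residual RMS = %.4g over %d samples (%s, %d restarts)\n",
              x$j2, x$rmse, x$n,
              if (x$converged) "converged" else "not converged",
              x$n_restarts))
  if (!is.null(x$attributes)) {
    cat("\nFitted activation attributes:\n")
    print(x$attributes)
  }
  invisible(x)
}

#' Plot a fitted HRF model
#'
#' Target series, fitted model and the activation component on one
#' panel, with task blocks shaded.
#'
#' @param x an `"hrf_fit"`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.hrf_fit <- function(x, ...) {
  t <- ts_times(x$target)
  yl <- range(x$target$values, x$fitted.values$values)
  graphics::plot(t, x$target$values, type = "l", col = "grey50",
                 xlab = "time (s)", ylab = "HbO (signal units)",
                 ylim = yl, ...)
  pr <- x$paradigm
  for (i in seq_along(pr$onsets))
    graphics::rect(pr$onsets[i], yl[1], pr$onsets[i] + pr$durations[i],
                   yl[2], col = grDevices::adjustcolor("steelblue", 0.1),
                   border = NA)
  graphics::lines(t, x$fitted.values$values, col = "firebrick", lwd = 2)
  act <- predict(x, type = "activation")
  graphics::lines(t, act$values, col = "darkgreen", lty = 2)
  graphics::legend("topright", c("target", "fitted", "activation"),
                   col = c("grey50", "firebrick", "darkgreen"),
                   lty = c(1, 1, 2), lwd = c(1, 2, 1), bty = "n")
  invisible(x)
}

#' Simulate replicate series from a fitted HRF model
#'
#' Draws `nsim` replicates of the deterministic fitted model plus
#' Gaussian noise. The noise standard deviation defaults to the residual
#' RMS of the fit.
#'
#' @param object an `"hrf_fit"`.
#' @param nsim number of replicates.
#' @param seed optional integer seed.
#' @param noise_sd noise standard deviation (default: residual RMS).
#' @param ... unused.
#' @return a data frame with one column per replicate (`sim_1`, ...),
#'   `nrow` equal to the series length; the sample times are attached as
#'   attribute `"time_s"`.
#' @export
simulate.hrf_fit <- function(object, nsim = 1, seed = NULL,
                             noise_sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise_sd)) noise_sd <- sqrt(mean(object$residuals^2))
  m <- object$fitted.values$values
  out <- as.data.frame(
    vapply(seq_len(nsim),
           function(i) m + stats::rnorm(length(m), 0, noise_sd),
           numeric(length(m))))
  names(out) <- paste0("sim_", seq_len(nsim))
  attr(out, "time_s") <- ts_times(object$fitted.values)
  out
}
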