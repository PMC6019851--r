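# fits in this file are kept small (short paradigm, 10 Hz grid, few
# restarts); the fuller recovery experiment lives in test-acceptance.R

make_pair_from <- function(y) split_signal(y, "case1")$pair

test_that("the constraint box carries the twelve printed bounds", {
  box <- hrf_constraint_box()
  expect_equal(dim(box), c(12, 2))
  expect_equal(box["alpha1", ], c(lower = 2, upper = 10))
  expect_equal(box["fm", ], c(lower = 0.09, upper = 0.1))
  expect_true(all(box[, 2] > box[, 1]))
})

test_that("J2 is zero at the generating parameters and positive away from them", {
  paradigm <- simulated_paradigm(20, "St1")
  truth <- c(alpha1 = 6, alpha2 = 16, beta1 = 1, beta2 = 1,
             a0 = 3, a1 = 5, ac = 0.5, ar = 0.4, am = 0.2,
             fc = 1.1, fr = 0.25, fm = 0.095)
  y <- generate_signal(hrf_params(6, 16, 1, 1),
                       nuisance_params(a0 = 3, a1 = 5, ac = 0.5, ar = 0.4,
                                       am = 0.2, fc = 1.1, fr = 0.25,
                                       fm = 0.095, noise_sd = 0),
                       paradigm, fs = 10)
  pair <- make_pair_from(y)
  expect_equal(j2_cost(truth, pair, paradigm), 0, tolerance = 1e-16)
  # quadratic in a1: any perturbation strictly increases the cost
  for (d in c(-0.5, 0.3, 1)) {
    pert <- truth; pert["a1"] <- truth["a1"] + d
    expect_gt(j2_cost(pert, pair, paradigm), 1e-3)
  }
  # zero model against a zero target
  zero_pair <- od_pair(fnirs_ts(numeric(601), 10), fnirs_ts(numeric(601), 10),
                       6, 6)
  zeros <- truth; zeros[c("a0", "a1", "ac", "ar", "am")] <- 0
  expect_equal(j2_cost(zeros, zero_pair, paradigm), 0)
  expect_error(j2_cost(truth[-1], pair, paradigm), "named")
})

test_that("the box bijection is an interior-preserving inverse pair", {
  box <- hrf_constraint_box()
  set.seed(4)
  for (i in 1:20) {
    theta <- runif(12, box[, 1], box[, 2])
    z <- fnirsdpf:::.box_to_z(theta, box)
    back <- fnirsdpf:::.z_to_box(z, box)
    expect_equal(unname(back), theta, tolerance = 1e-9)
  }
  wild <- fnirsdpf:::.z_to_box(c(-50, 50, rep(0, 10)), box)
  expect_true(all(wild >= box[, 1] & wild <= box[, 2]))
})

test_that("the fit recovers generating parameters from a clean signal", {
  paradigm <- simulated_paradigm(20, "St1")
  nz <- nuisance_params(a0 = 4, a1 = 7, ac = 0.8, ar = 0.6, am = 0.5,
                        fc = 0.9, fr = 0.24, fm = 0.093, noise_sd = 0)
  y <- generate_signal(hrf_params(), nz, paradigm, fs = 10)
  pair <- make_pair_from(y)
  fit <- fit_hrf(pair, paradigm, n_restarts = 8, seed = 31, max_iter = 3000)
  est <- coef(fit)
  expect_lt(abs(est[["a1"]] - 7) / 7, 0.05)
  expect_lt(abs(est[["fc"]] - 0.9), 0.005)
  expect_lt(abs(est[["fr"]] - 0.24), 0.005)
  expect_lt(abs(est[["fm"]] - 0.093), 0.005)
  # all parameters inside the box, optimum below every start
  box <- hrf_constraint_box()
  expect_true(all(est >= box[, 1] & est <= box[, 2]))
  expect_true(all(fit$j2 <= fit$start_costs))
})

test_that("fitting a constant series recovers the baseline with no activity", {
  paradigm <- simulated_paradigm(10, "St1")
  n <- length(encode_boxcar(paradigm, 10)$values)
  # constant target 5: od2/dpf2 * 0.2170 = 5
  pair <- od_pair(fnirs_ts(numeric(n), 10),
                  fnirs_ts(rep(5 / 0.2170, n), 10),
                  dpf_l1 = 6, dpf_l2 = 1)
  fit <- fit_hrf(pair, paradigm, n_restarts = 6, seed = 8, max_iter = 2000)
  est <- coef(fit)
  expect_equal(est[["a0"]], 5, tolerance = 0.02)
  h <- canonical_hrf(hrf_params(est[["alpha1"]], est[["alpha2"]],
                                est[["beta1"]], est[["beta2"]]), dt = 0.1)
  expect_lt(est[["a1"]] * max(abs(h$values)), 0.05)
})

test_that("the fit is deterministic for a fixed seed", {
  y <- make_clean_signal(task_s = 10, fs = 10)
  pair <- make_pair_from(y)
  paradigm <- simulated_paradigm(10, "St1")
  f1 <- fit_hrf(pair, paradigm, n_restarts = 3, seed = 5, max_iter = 800)
  f2 <- fit_hrf(pair, paradigm, n_restarts = 3, seed = 5, max_iter = 800)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$j2, f2$j2)
  expect_identical(f1$start_costs, f2$start_costs)
})

test_that("hrf_fit objects support the standard modelling methods", {
  y <- make_clean_signal(task_s = 10, fs = 10)
  pair <- make_pair_from(y)
  paradigm <- simulated_paradigm(10, "St1")
  fit <- fit_hrf(pair, paradigm, n_restarts = 4, seed = 2, max_iter = 2000)

  expect_named(coef(fit), rownames(hrf_constraint_box()))
  expect_length(fitted(fit), length(y$values))
  expect_equal(fitted(fit) + residuals(fit), y$values, tolerance = 1e-8)
  expect_equal(deviance(fit), sum(residuals(fit)^2), tolerance = 1e-10)

  full <- predict(fit, "response")
  act <- predict(fit, "activation")
  nui <- predict(fit, "nuisance")
  expect_equal(full$values, fitted(fit))
  expect_equal(act$values + nui$values, full$values, tolerance = 1e-10)

  s <- summary(fit)
  expect_s3_class(s, "summary.hrf_fit")
  expect_equal(nrow(s$coefficients), 12)
  expect_output(print(fit), "J2")
  expect_output(print(s), "residual RMS")

  sims <- simulate(fit, nsim = 3, seed = 1, noise_sd = 0.1)
  expect_equal(dim(sims), c(length(y$values), 3))
  expect_false(identical(sims$sim_1, sims$sim_2))
  sd_err <- sd(sims$sim_1 - fitted(fit))
  expect_equal(sd_err, 0.1, tolerance = 0.03)

  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("sweep_fit tabulates one row per DPF value and flags failures", {
  y <- make_clean_signal(task_s = 10, fs = 10)
  pair <- make_pair_from(y)
  paradigm <- simulated_paradigm(10, "St1")
  tab <- sweep_fit(pair, paradigm, dpf_values = c(3, 5.5, 8), vary = "l2",
                   n_restarts = 3, seed = 12, max_iter = 1500)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$dpf_l2, c(3, 5.5, 8))
  expect_true(all(tab$dpf_l1 == pair$dpf_l1))
  expect_true(all(is.finite(tab$peak_value)))
  # target scales down as dpf_l2 grows (positive od2): peaks follow
  expect_true(all(diff(tab$peak_value) < 0))
  expect_error(sweep_fit(pair, paradigm, dpf_values = c(-1, 3)), "positive")
})
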