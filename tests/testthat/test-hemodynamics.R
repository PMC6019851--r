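test_that("double-gamma kernel matches its closed form and vanishes at t = 0", {
  p <- hrf_params(alpha1 = 6, alpha2 = 16, beta1 = 1, beta2 = 1)
  h <- canonical_hrf(p, dt = 0.01, duration = 32)
  t <- ts_times(h)
  expect_identical(h$values[1], 0)
  # direct evaluation of the formula at a few interior points
  ref <- t^5 * exp(-t) / gamma(6) - t^15 * exp(-t) / (6 * gamma(16))
  expect_equal(h$values, ref, tolerance = 1e-12)
  # mode of the response gamma is (alpha1 - 1) / beta1 = 5 s
  expect_equal(t[which.max(h$values)], 5, tolerance = 0.05)
})

test_that("the response term is a normalised gamma density for any valid shape", {
  for (ab in list(c(6, 1), c(3, 0.7), c(9, 1.8))) {
    p <- hrf_params(alpha1 = ab[1], beta1 = ab[2], beta2 = 0)
    h <- canonical_hrf(p, dt = 0.01, duration = 60)
    expect_equal(sum(h$values) * 0.01, 1, tolerance = 1e-2)
  }
})

test_that("kernel construction validates its inputs", {
  expect_error(canonical_hrf(hrf_params(), dt = 0), "dt")
  expect_error(canonical_hrf(hrf_params(), duration = -1), "duration")
  expect_error(hrf_params(alpha1 = 1), "alpha")
  expect_error(hrf_params(beta1 = 0), "beta1")
})

test_that("convolution with a unit-mass impulse reproduces the kernel", {
  dt <- 0.1
  h <- canonical_hrf(hrf_params(), dt = dt, duration = 30)
  u <- fnirs_ts(c(1 / dt, numeric(400)), fs = 1 / dt)
  out <- convolve_hrf(u, h)
  expect_equal(out$values[seq_along(h$values)], h$values, tolerance = 1e-9)
  # zero input -> zero output
  z <- fnirs_ts(numeric(401), fs = 1 / dt)
  expect_equal(max(abs(convolve_hrf(z, h)$values)), 0)
})

test_that("convolution is linear and rejects mismatched rates", {
  dt <- 0.1
  h <- canonical_hrf(hrf_params(), dt = dt)
  set.seed(11)
  u1 <- fnirs_ts(rbinom(300, 1, 0.3), fs = 1 / dt)
  u2 <- fnirs_ts(rbinom(300, 1, 0.3), fs = 1 / dt)
  u12 <- fnirs_ts(u1$values + u2$values, fs = 1 / dt)
  expect_equal(convolve_hrf(u12, h)$values,
               convolve_hrf(u1, h)$values + convolve_hrf(u2, h)$values,
               tolerance = 1e-10)
  expect_error(convolve_hrf(fnirs_ts(1:10, fs = 5), h), "sampling rate")
})

test_that("a boxcar response peaks later and wider than the impulse response", {
  dt <- 0.01
  h <- canonical_hrf(hrf_params(), dt = dt)
  train <- stimulus_train(10, 10, 60)
  u <- encode_boxcar(train, 1 / dt)
  # independent brute-force discrete convolution on a coarse copy
  dtc <- 0.1
  hc <- canonical_hrf(hrf_params(), dt = dtc)
  uc <- encode_boxcar(train, 1 / dtc)
  n <- length(uc$values)
  brute <- sapply(seq_len(n), function(i) {
    m <- seq_len(i)
    k <- i - m + 1
    ok <- k <= length(hc$values)
    sum(uc$values[m[ok]] * hc$values[k[ok]]) * dtc
  })
  expect_equal(convolve_hrf(uc, hc)$values, brute, tolerance = 1e-9)
  out <- convolve_hrf(u, h)
  t_peak_box <- ts_times(out)[which.max(out$values)]
  t_peak_imp <- ts_times(h)[which.max(h$values)]
  expect_gt(t_peak_box, t_peak_imp)
  # width above half maximum is larger for the boxcar response
  w <- function(x) {
    half <- max(x$values) / 2
    diff(range(ts_times(x)[x$values >= half]))
  }
  expect_gt(w(out), w(h))
})

test_that("stimulus trains validate ordering, overlap and bounds", {
  expect_error(stimulus_train(c(10, 5), 2, 30), "increasing")
  expect_error(stimulus_train(c(0, 5), 10, 30), "overlap")
  expect_error(stimulus_train(10, 30, 30), "within")
  tr <- stimulus_train(c(0, 10), c(10, 5), 30)  # touching blocks allowed
  expect_length(tr$onsets, 2)
})

test_that("attribute extraction matches the canonical impulse response", {
  h <- canonical_hrf(hrf_params(), dt = 0.01, duration = 32)
  # treat the kernel as a response to a task over [0.5, 6] s: pre-onset
  # baseline is essentially 0, the peak is the gamma mode at 5 s
  at <- hrf_attributes(h, c(0.5, 6))
  expect_equal(at$time_to_peak, 5, tolerance = 0.05)
  expect_gt(at$fwhm, 0)
  expect_gt(at$undershoot_depth, 0)     # the undershoot dips below 0
  expect_equal(at$baseline_offset, 0, tolerance = 1e-4)
})

test_that("attributes are translation-equivariant; constants are degenerate", {
  y <- make_clean_signal(task_s = 20)
  window <- c(10, 30)
  a <- hrf_attributes(y, window)
  yc <- fnirs_ts(y$values + 3, y$fs, y$t0)
  b <- hrf_attributes(yc, window)
  expect_equal(b$peak_value, a$peak_value + 3)
  expect_equal(b$baseline_offset, a$baseline_offset + 3)
  expect_equal(b$time_to_peak, a$time_to_peak)
  expect_equal(b$fwhm, a$fwhm)
  expect_equal(b$undershoot_depth, a$undershoot_depth)
  # constant series: no response, no undershoot
  cst <- fnirs_ts(rep(4, 400), fs = 10)
  ac <- hrf_attributes(cst, c(10, 20))
  expect_equal(ac$peak_value - ac$baseline_offset, 0)
  expect_equal(ac$undershoot_depth, 0)
  expect_true(is.na(ac$fwhm))
})

test_that("attribute extraction rejects windows outside the series", {
  y <- make_clean_signal()
  expect_error(hrf_attributes(y, c(-5, 10)), "inside")
  expect_error(hrf_attributes(y, c(10, 500)), "inside")
  expect_error(hrf_attributes(y, c(20, 10)), "onset < offset")
})

test_that("fwhm is located by interpolation on an analytic triangle", {
  # triangular pulse rising over [10, 15], falling over [15, 20]:
  # baseline (t < 10) is 0, so the half-maximum crossings sit at exactly
  # t = 12.5 and 17.5 and the fwhm is 5 s
  t <- seq(0, 40, by = 0.5)
  v <- pmax(0, 1 - abs(t - 15) / 5)
  at <- hrf_attributes(fnirs_ts(v, fs = 2), c(10, 18))
  expect_equal(at$fwhm, 5, tolerance = 1e-9)
  expect_equal(at$peak_value, 1)
  expect_equal(at$time_to_peak, 15)
})
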