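test_that("split objective J1 reproduces its fixed constants", {
  one <- fnirs_ts(1, fs = 10)
  zero <- fnirs_ts(0, fs = 10)
  # y = 0, od1 = 0, od2 = 1: residual is (-0.0375)^2
  expect_equal(j1_residual(zero, od_pair(zero, one, 1, 1)), 0.0375^2)
  # y = 0, od1 = 1, od2 = 0: residual is 0.01644^2
  expect_equal(j1_residual(zero, od_pair(one, zero, 1, 1)), 0.01644^2)
  expect_equal(j1_residual(zero, od_pair(zero, zero, 1, 1)), 0)
  expect_error(j1_residual(fnirs_ts(1:3, 10), od_pair(one, one, 1, 1)),
               "length")
})

test_that("single-sample splits match the closed-form projection", {
  # y = 1 under case4: minimum-norm point on the line inside quadrant
  s <- split_signal(fnirs_ts(1, fs = 10), "case4")
  expect_equal(s$pair$od_l1$values, -9.806, tolerance = 1e-3)
  expect_equal(s$pair$od_l2$values, 22.369, tolerance = 1e-4)
  expect_equal(0.0375 * s$pair$od_l2$values -
                 0.01644 * s$pair$od_l1$values, 1, tolerance = 1e-12)
  expect_equal(s$residual_j1, 0)
  # y = -1 under case4 is sign-impossible: replacement (0, 0)
  s2 <- split_signal(fnirs_ts(-1, fs = 10), "case4")
  expect_equal(s2$pair$od_l1$values, 0)
  expect_equal(s2$pair$od_l2$values, 0)
  expect_equal(s2$infeasible_fraction, 1)
  expect_equal(s2$residual_j1, 1)
  # y = 0 maps to the origin under every case
  for (cs in paste0("case", 1:4)) {
    s0 <- split_signal(fnirs_ts(0, fs = 10), cs)
    expect_equal(s0$pair$od_l1$values, 0)
    expect_equal(s0$pair$od_l2$values, 0)
    expect_equal(s0$residual_j1, 0)
  }
})

test_that("closed-form split agrees with the brute-force enumeration oracle", {
  set.seed(17)
  y <- fnirs_ts(round(runif(50, -2, 2), 2), fs = 10)
  for (cs in paste0("case", 1:4)) {
    case <- sign_case(cs)
    s <- split_signal(y, cs)
    for (k in seq_along(y$values)) {
      o <- oracle_split_sample(y$values[k], case$sign_l1, case$sign_l2)
      norm_impl <- sqrt(s$pair$od_l1$values[k]^2 + s$pair$od_l2$values[k]^2)
      norm_orac <- sqrt(o$a^2 + o$b^2)
      expect_lt(abs(norm_impl - norm_orac), 1e-3)
      r_impl <- (y$values[k] - 0.0375 * s$pair$od_l2$values[k] +
                   0.01644 * s$pair$od_l1$values[k])^2
      r_orac <- (y$values[k] - 0.0375 * o$b + 0.01644 * o$a)^2
      expect_lt(abs(r_impl - r_orac), 1e-6)
      expect_equal(s$infeasible[k], !o$feasible)
    }
  }
})

test_that("residual J1 is exactly the infeasible mass and zero when feasible", {
  y <- make_clean_signal()                       # strictly positive signal
  for (cs in c("case1", "case2", "case4")) {
    s <- split_signal(y, cs)
    expect_equal(s$infeasible_fraction, 0, label = cs)
    expect_equal(s$residual_j1, 0, label = cs)
    expect_equal(j1_residual(y, s$pair), 0, tolerance = 1e-20, label = cs)
  }
  s3 <- split_signal(y, "case3")                 # all positive -> infeasible
  expect_equal(s3$infeasible_fraction, 1)
  expect_equal(s3$residual_j1, sum(y$values^2))
  expect_equal(j1_residual(y, s3$pair), s3$residual_j1)
})

test_that("split solutions honour their sign constraints", {
  set.seed(23)
  y <- fnirs_ts(rnorm(200), fs = 10)
  for (cs in paste0("case", 1:4)) {
    case <- sign_case(cs)
    s <- split_signal(y, cs)
    expect_true(all(case$sign_l1 * s$pair$od_l1$values >= 0), label = cs)
    expect_true(all(case$sign_l2 * s$pair$od_l2$values >= 0), label = cs)
  }
})

test_that("cases 3 and 4 partition a mixed-sign signal by sign", {
  t <- seq(0, 20, by = 0.1)
  y <- fnirs_ts(sin(2 * pi * 0.1 * t), fs = 10)   # takes both signs
  s3 <- split_signal(y, "case3")
  s4 <- split_signal(y, "case4")
  r3 <- reconstruct_under_dpf(s3)
  r4 <- reconstruct_under_dpf(s4)
  neg <- y$values < 0
  pos <- y$values > 0
  # case3 reproduces only the non-positive part, case4 only the
  # non-negative part
  expect_equal(r3$values[neg], y$values[neg], tolerance = 1e-10)
  expect_true(all(abs(r3$values[pos]) < 1e-12))
  expect_equal(r4$values[pos], y$values[pos], tolerance = 1e-10)
  expect_true(all(abs(r4$values[neg]) < 1e-12))
  # and stay sign-bounded for any DPFs in the swept range
  for (d1 in c(3, 8)) for (d2 in c(3, 8)) {
    expect_true(all(reconstruct_under_dpf(s3, d1, d2)$values <= 1e-12))
    expect_true(all(reconstruct_under_dpf(s4, d1, d2)$values >= -1e-12))
  }
})

test_that("reconstruction at the implied true DPFs returns the original signal", {
  y <- make_clean_signal(task_s = 30, pattern = "St2")
  for (cs in c("case1", "case2")) {
    s <- split_signal(y, cs)
    rec <- reconstruct_under_dpf(s)
    expect_equal(rec$values, y$values, tolerance = 1e-12, label = cs)
  }
})

test_that("case-2 reconstructions translate downward as dpf_l1 rises", {
  y <- make_clean_signal()
  s <- split_signal(y, "case2")        # od_l1 carries the negative weight
  expect_true(all(s$pair$od_l1$values <= 0))
  recs <- lapply(3:8, function(d) reconstruct_under_dpf(s, dpf_l1 = d))
  for (i in 1:5) {
    dif <- recs[[i + 1]]$values - recs[[i]]$values
    expect_true(all(dif <= 1e-12))
    expect_true(any(dif < -1e-6))      # strictly lower where od_l1 < 0
  }
})
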