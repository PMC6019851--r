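# shared fixtures, built in code

# a clean noise-free HbO signal on a short simulation paradigm
make_clean_signal <- function(task_s = 20, pattern = "St1", fs = 10,
                              a0 = 2, a1 = 6) {
  generate_signal(hrf_params(),
                  nuisance_params(a0 = a0, a1 = a1, ac = 0, ar = 0, am = 0,
                                  noise_sd = 0),
                  simulated_paradigm(task_s, pattern), fs = fs)
}

# extinction table with a well-conditioned 2x2 (arbitrary plausible values)
make_coeffs <- function() {
  mbll_coefficients(eps_hbo_l1 = 1.4866, eps_hbr_l1 = 3.8437,
                    eps_hbo_l2 = 2.3216, eps_hbr_l2 = 1.7913,
                    separation_cm = 3)
}

# split-target constants (duplicated here so tests do not read package
# internals): y = C2 * od2 - C1 * od1
SPLIT_C1 <- 0.01644
SPLIT_C2 <- 0.0375

# independent per-sample split oracle: enumerate the line inside the
# quadrant on a fine grid; if the quadrant misses the line, scan the
# quadrant for the point closest to the line (ties broken by norm)
oracle_split_sample <- function(y, s1, s2) {
  # the feasible minimum-norm point can lie as far out as |y| / C1
  r <- abs(y) / SPLIT_C1 + 1
  a_grid <- seq(-r, r, by = 5e-4)
  b <- (y + SPLIT_C1 * a_grid) / SPLIT_C2
  keep <- (s1 * a_grid >= 0) & (s2 * b >= 0)
  if (any(keep)) {
    a <- a_grid[keep]; b <- b[keep]
    i <- which.min(a^2 + b^2)
    return(list(a = a[i], b = b[i], feasible = TRUE))
  }
  # line misses the quadrant: scan near the origin for the closest point
  # (distance to the line grows with the norm, so a small window suffices)
  a2 <- s1 * seq(0, 5, by = 0.02)
  b2 <- s2 * seq(0, 5, by = 0.02)
  g <- expand.grid(a = a2, b = b2)
  resid <- abs(SPLIT_C2 * g$b - SPLIT_C1 * g$a - y)
  cand <- which(resid < min(resid) + 1e-12)
  i <- cand[which.min(g$a[cand]^2 + g$b[cand]^2)]
  list(a = g$a[i], b = g$b[i], feasible = FALSE)
}
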