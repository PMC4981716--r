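test_that("Henry's-law equilibrium O2 is linear and matches hand values", {
  g <- gas_params(50, kH = 1.08)
  expect_equal(equilibrium_O2(g, 0), 0)
  expect_equal(equilibrium_O2(g, 0.78), 842.4)
  expect_equal(signif(equilibrium_O2(g, 0.78), 2), 840)
  expect_equal(equilibrium_O2(g, 0.02), 21.6)
  # linearity: f(a+b) = f(a) + f(b) - f(0)
  for (i in 1:10) {
    set.seed(i); ab <- runif(2)
    expect_equal(equilibrium_O2(g, sum(ab)),
                 sum(equilibrium_O2(g, ab)) - equilibrium_O2(g, 0))
  }
})

test_that("qO2 from the O2 balance matches hand arithmetic and scaling", {
  g <- gas_params(0.83, kla_units = "per_min", pO2_in = 0)
  # (0.2*8 + 49.8*8) umol L-1 h-1 over 0.036 g L-1 -> 11.1 mmol h-1 g-1
  rec <- data.frame(D = 0.2, O2_uM = 8, x = 0.036)
  expect_equal(compute_qO2(rec, g), (0.2 * 8 + 49.8 * 8) / 0.036 / 1000)
  expect_equal(round(compute_qO2(rec, g), 1), 11.1)
  # equilibrium with in-gas and inflow: no net flux
  g2 <- gas_params(49.8, kH = 1.08, pO2_in = 0.2, O2_in = 1.08 * 0.2 * 1000)
  rec2 <- data.frame(D = 0.1, O2_uM = 1.08 * 0.2 * 1000, x = 0.04)
  expect_equal(compute_qO2(rec2, g2), 0)
  # doubling biomass at fixed fluxes halves the specific rate
  expect_equal(compute_qO2(data.frame(D = 0.2, O2_uM = 8, x = 0.072), g),
               compute_qO2(rec, g) / 2)
  # net consumption is a value, not an error
  g3 <- gas_params(49.8, pO2_in = 0.2)
  expect_lt(compute_qO2(data.frame(D = 0.1, O2_uM = 10, x = 0.04), g3), 0)
  expect_error(compute_qO2(data.frame(D = 0.2, O2_uM = 8, x = 0), g),
               "positive")
})

test_that("kla unit tags give identical results once converted", {
  per_min <- gas_params(0.83, kla_units = "per_min")
  per_h <- gas_params(49.8, kla_units = "per_h")
  expect_equal(per_min$kla, 49.8)
  rec <- data.frame(D = 0.2, O2_uM = 8, x = 0.036)
  expect_identical(compute_qO2(rec, per_min), compute_qO2(rec, per_h))
})

test_that("carbon-mole biomass rate is mu * 1000 / 24.59", {
  expect_equal(compute_qX(0), 0)
  expect_equal(compute_qX(0.20), 0.20 * 1000 / 24.59)
  expect_equal(round(compute_qX(0.20), 2), 8.13)
  expect_equal(round(compute_qX(0.07), 2), 2.85)
  mu <- seq(0, 0.3, by = 0.03)
  expect_true(all(diff(compute_qX(mu)) > 0))
  expect_equal(compute_qX(2 * mu), 2 * compute_qX(mu))
})

test_that("per-regime Q equals the closed-form OLS slope", {
  qO2 <- c(0, 2, 4, 6, 8, 10)
  expect_equal(
    photosynthetic_quotient(qO2, 1.3 * qO2, rep("lim", 6))$Q, 1.3)
  expect_equal(
    photosynthetic_quotient(c(0, 10), c(0, 6), rep("sat", 2))$Q, 0.6)
  for (s in 1:10) {
    set.seed(s)
    x <- runif(8, 0, 10); y <- 1.1 * x + rnorm(8, 0, 0.4)
    r <- sample(c("a", "b"), 8, replace = TRUE)
    got <- photosynthetic_quotient(x, y, r)
    for (reg in unique(r)) {
      i <- r == reg
      if (sum(i) >= 2)
        expect_equal(got$Q[got$regime == reg],
                     ols_slope_oracle(x[i], y[i]))
    }
    noi <- photosynthetic_quotient(x, y, r, intercept = FALSE)
    for (reg in unique(r)) {
      i <- r == reg
      if (sum(i) >= 2)
        expect_equal(noi$Q[noi$regime == reg],
                     ols_slope_oracle(x[i], y[i], intercept = FALSE))
    }
  }
})

test_that("degenerate regimes are flagged without a slope", {
  got <- photosynthetic_quotient(c(1, 2, 3, 3), c(1, 2, 9, 9),
                                 c("a", "b", "b", "b"))
  expect_true(got$flagged[got$regime == "a"])   # single point
  expect_true(is.na(got$Q[got$regime == "a"]))
  got2 <- photosynthetic_quotient(c(5, 5, 5), c(1, 2, 3), rep("z", 3))
  expect_true(got2$flagged)                     # zero qO2 variance
})

test_that("noisy Q estimates are unbiased within OLS sampling error", {
  est <- vapply(1:500, function(s) {
    set.seed(s)
    x <- seq(1, 10, length.out = 6)
    y <- 1.3 * x + rnorm(6, 0, 0.2)
    photosynthetic_quotient(x, y, rep("lim", 6))$Q
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 1.3), 3 * se)
})

test_that("steady state requires <=3% channel variation and 5 residence times", {
  const <- list(OD730 = rep(0.082, 4), pH = rep(7.5, 4), O2 = rep(8, 4))
  expect_true(detect_steady_state(const, 6)$steady)
  # a 12.5% OD step breaks continuity
  step <- list(OD730 = c(0.080, 0.090), pH = rep(7.5, 2))
  got <- detect_steady_state(step, 6)
  expect_false(got$steady)
  expect_false(got$channels[["OD730"]])
  expect_true(got$channels[["pH"]])
  # threshold is inclusive: exactly 3.0% variation passes
  v <- c(1, 1); v[2] <- (1 + 0.03 / 2) / (1 - 0.03 / 2)  # |diff|/mean = 3%
  excl <- list(a = v, b = rep(2, 2))
  expect_true(detect_steady_state(excl, 5)$steady)
  # too few residence times fails even with constant channels
  expect_false(detect_steady_state(const, 4.9)$steady)
  # empty channel is indeterminate, reported per channel
  ind <- detect_steady_state(list(a = rep(1, 3), b = numeric(0)), 6)
  expect_false(ind$steady)
  expect_true(is.na(ind$channels[["b"]]))
})

test_that("simulated records satisfy the O2 balance round trip", {
  for (s in 1:5) {
    set.seed(s)
    cf <- turbidostat_sim_config(
      Rmax_mu = runif(1, 0.05, 0.3), Ik = runif(1, 80, 400),
      noise_cv = 0, n_replicates = 1L, seed = s)
    ss <- simulate_steady_states(cf)
    got <- compute_qO2(ss, cf$gas)
    expect_lt(max(abs(got - ss$truth_qO2) / ss$truth_qO2), 1e-9)
  }
})
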