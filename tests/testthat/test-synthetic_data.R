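test_that("noise-free steady states lie exactly on the light-response curve", {
  cf <- turbidostat_sim_config(noise_cv = 0, n_replicates = 1L,
                               irradiance_grid = c(33, 164, 820))
  ss <- simulate_steady_states(cf)
  expect_equal(ss$mu[ss$Ii == 164], 0.20 * (1 - exp(-1)))
  # saturating limit at Ii = 5 Ik
  expect_lt(abs(ss$mu[ss$Ii == 820] - 0.20) / 0.20, 0.01)
  # turbidostat identity: dilution equals growth
  expect_identical(ss$D, ss$mu)
  # finite beta attenuates the rate
  cfb <- turbidostat_sim_config(beta = 500, noise_cv = 0,
                                n_replicates = 1L,
                                irradiance_grid = c(33, 164, 820))
  ssb <- simulate_steady_states(cfb)
  expect_equal(ssb$mu[ssb$Ii == 164],
               0.20 * (1 - exp(-1)) * exp(-164 / 500))
})

test_that("simulated tables are deterministic for a fixed seed", {
  a <- simulate_steady_states(turbidostat_sim_config(seed = 42))
  b <- simulate_steady_states(turbidostat_sim_config(seed = 42))
  expect_identical(a, b)
  c2 <- simulate_steady_states(turbidostat_sim_config(seed = 43))
  expect_false(identical(a, c2))
  e1 <- simulate_expression(expression_sim_config(
    n_genes = c(10L, 10L), seed = 42))
  e2 <- simulate_expression(expression_sim_config(
    n_genes = c(10L, 10L), seed = 42))
  expect_identical(e1, e2)
})

test_that("simulated dissolved O2 satisfies the mass balance to 1e-12", {
  cf <- turbidostat_sim_config(noise_cv = 0, n_replicates = 1L)
  ss <- simulate_steady_states(cf)
  g <- cf$gas
  lhs <- 1000 * ss$truth_qO2 * ss$x
  rhs <- ss$D * (ss$O2_uM - g$O2_in) +
    g$kla * (ss$O2_uM - equilibrium_O2(g, g$pO2_in))
  expect_lt(max(abs(lhs - rhs) / lhs), 1e-12)
})

test_that("non-physical configurations report the offending irradiance", {
  # a net-consuming culture (negative yield) sparged O2-free drives the
  # balance below zero dissolved O2
  cf <- turbidostat_sim_config(
    irradiance_grid = c(500, 760), Q_lim = -0.5, Q_sat = -0.5,
    noise_cv = 0, n_replicates = 1L)
  expect_error(simulate_steady_states(cf), "500")
})

test_that("expression archetypes are exact at zero noise and RPKM positive", {
  ex <- simulate_expression(expression_sim_config(
    n_genes = c(5L, 5L, 5L, 5L), gene_noise_sd = 0, planted = NULL,
    n_null_categories = 0L, seed = 1))
  expect_true(all(ex$rpkm > 0))
  # pseudocount 0: RPKM is an exact 2^profile scaling, so standardization
  # inverts the mapping exactly
  z <- transform_standardize(ex$rpkm, pseudocount = 0)$matrix
  for (a in 1:4) {
    rows <- z[names(ex$truth_labels)[ex$truth_labels == a], , drop = FALSE]
    expect_lt(max(abs(sweep(rows, 2, ex$archetypes[a, ]))), 1e-9)
  }
  # the four archetypes are linearly independent across the conditions
  expect_equal(qr(ex$archetypes)$rank, 4L)
})

test_that("a fully planted category is significant downstream", {
  ex <- simulate_expression(expression_sim_config(
    n_genes = c(20L, 80L), gene_noise_sd = 0,
    planted = data.frame(category = "planted", level = "main_role",
                         cluster = 1L, fraction = 1.0, background = 0.05),
    n_null_categories = 0L, seed = 2))
  cluster <- names(ex$truth_labels)[ex$truth_labels == 1L]
  got <- fisher_enrichment(cluster, ex$annotations, names(ex$truth_labels))
  expect_lt(got$p_value[got$category == "planted"], 0.05)
})

test_that("fluorescence traces follow the four-phase protocol", {
  tr <- simulate_fluorescence_trace(0.5, noise_sd = 0, seed = 1)
  expect_identical(unique(tr$phase),
                   c("saturating_pulse", "far_red", "actinic", "dark"))
  expect_true(all(diff(tr$time_s) > 0))
  durs <- tapply(tr$time_s, tr$phase, function(t) diff(range(t)))
  # nominal durations 0.2 / 5 / 15 / 30 s at dt = 0.05
  expect_equal(as.numeric(durs[c("saturating_pulse", "far_red", "actinic",
                                 "dark")]),
               c(0.2, 5, 15, 30) - 0.05)
  dark <- tr[tr$phase == "dark", ]
  fit <- lm(dark$F ~ dark$time_s)
  expect_equal(unname(coef(fit)[2]), 0.5, tolerance = 1e-9)
  flat <- simulate_fluorescence_trace(0, noise_sd = 0, seed = 1)
  expect_equal(sd(flat$F[flat$phase == "dark"]), 0)
})

test_that("the synthetic bundle round-trips through the readers", {
  d <- withr::local_tempdir()
  write_synthetic_bundle(d, seed = 11)
  ss <- read_steady_state_table(file.path(d, "steady_states.tsv"))
  expect_true(all(c("Ii", "mu", "x", "O2_uM") %in% names(ss)))
  m <- read_expression_matrix(file.path(d, "expression_rpkm.tsv"))
  expect_equal(dim(m), c(2732L, 8L))
  cfg <- jsonlite::read_json(file.path(d, "config.json"),
                             simplifyVector = TRUE)
  expect_equal(cfg$seed, 11)
  # rewriting under the same seed is byte-identical
  d2 <- withr::local_tempdir()
  write_synthetic_bundle(d2, seed = 11)
  for (f in list.files(d))
    expect_identical(readLines(file.path(d, f)),
                     readLines(file.path(d2, f)))
})
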