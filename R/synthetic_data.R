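# Synthetic-data generators emulating the study's instrument outputs
# (bioreactor steady states, PAM traces, RPKM matrices, cell measurements)
# with known ground truth. Hidden ground-truth columns carry the prefix
# "truth_" and must never be read by estimators.

#' Turbidostat simulation configuration
#'
#' Defaults describe the fast-growing Synechococcus-like reference
#' condition set: mu_max 0.20 h-1, Ik 164 umol photons m-2 s-1, no
#' photoinhibition (beta = Inf), eight steady states spanning 33-760
#' umol photons m-2 s-1, OD730 setpoint 0.082 with 36 mg AFDW L-1 per
#' 0.082 OD, O2-free sparge gas (kla 0.83 min-1, kH 1.08 mM atm-1) and
#' 5% multiplicative measurement noise with triplicate records per
#' irradiance. The per-regime growth-to-photosynthesis yields
#' \code{Q_lim}/\code{Q_sat} (1.3 / 0.6 Cmmol per mmol O2) set the
#' simulated qO2 through qO2 = qX / Q(regime).
#'
#' @param Rmax_mu maximum specific growth rate, h-1.
#' @param Ik saturating irradiance, umol photons m-2 s-1.
#' @param beta inhibition threshold irradiance (Inf = no inhibition).
#' @param irradiance_grid incident irradiances (strictly positive).
#' @param Q_lim,Q_sat growth-to-photosynthesis yield in the
#'   light-limited / light-saturated regime (interpolated linearly in
#'   irradiance across the transitional band).
#' @param gas a [gas_params()] object.
#' @param setpoint_OD turbidostat OD730 setpoint.
#' @param od_to_biomass g AFDW L-1 per OD730 unit.
#' @param noise_cv coefficient(s) of variation of the multiplicative
#'   log-normal measurement noise: either a single value applied to all
#'   channels or a named vector with elements \code{mu}, \code{OD},
#'   \code{O2}. Defaults follow the per-channel measurement precisions
#'   of the reference condition set (5% on rates, 3.7% on OD730, 2% on
#'   the O2 electrode).
#' @param n_replicates records per irradiance.
#' @param delta transitional-band half width used to assign the true
#'   regime.
#' @param seed integer seed.
#' @return list of class \code{"turbidostat_sim_config"}.
#' @export
turbidostat_sim_config <- function(Rmax_mu = 0.20, Ik = 164, beta = Inf,
                                   irradiance_grid = c(33, 66, 98, 132,
                                                       164, 211, 395, 760),
                                   Q_lim = 1.3, Q_sat = 0.6,
                                   gas = gas_params(0.83, kla_units = "per_min"),
                                   setpoint_OD = 0.082,
                                   od_to_biomass = 0.036 / 0.082,
                                   noise_cv = c(mu = 0.05, OD = 0.037,
                                                O2 = 0.02),
                                   n_replicates = 3L,
                                   delta = 0.25,
                                   seed = 1L) {
  stopifnot(Rmax_mu > 0, Ik > 0, beta > 0, all(irradiance_grid > 0),
            Q_lim != 0, Q_sat != 0, inherits(gas, "gas_params"),
            setpoint_OD > 0, od_to_biomass > 0, all(noise_cv >= 0),
            n_replicates >= 1)
  if (length(noise_cv) == 1L)
    noise_cv <- c(mu = unname(noise_cv), OD = unname(noise_cv),
                  O2 = unname(noise_cv))
  stopifnot(all(c("mu", "OD", "O2") %in% names(noise_cv)))
  structure(as.list(environment()), class = "turbidostat_sim_config")
}

# multiplicative log-normal noise with unit mean and coefficient of
# variation cv (rates are positive, spread roughly proportional to mean)
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, -s2 / 2, sqrt(s2)))
}

#' Simulate irradiance-controlled turbidostat steady states
#'
#' For each irradiance the true specific growth rate is the
#' light-response model [light_response()] at the configured parameters;
#' the turbidostat identity sets the dilution rate D = mu at constant
#' OD. The true qO2 follows from the per-regime yield
#' (qO2 = qX / Q) and the dissolved O2 is the exact solution of the
#' steady-state O2 balance for that qO2:
#' \code{O2 = (1000*qO2*x + D*O2_in + kla*kH*pO2_in*1000) / (D + kla)}.
#' Measured columns carry multiplicative log-normal noise of the
#' configured CV; ground truth is stored in \code{truth_*} columns.
#'
#' @param config a [turbidostat_sim_config()].
#' @return data frame (one row per irradiance x replicate) with columns
#'   \code{organism}, \code{Ii}, \code{D}, \code{mu}, \code{OD730},
#'   \code{x}, \code{O2_uM}, \code{pH}, and hidden
#'   \code{truth_mu}, \code{truth_qO2}, \code{truth_Q},
#'   \code{truth_regime}.
#' @export
simulate_steady_states <- function(config) {
  stopifnot(inherits(config, "turbidostat_sim_config"))
  cf <- config
  set.seed(cf$seed)
  grid <- rep(cf$irradiance_grid, each = cf$n_replicates)
  mu_true <- light_response(grid, cf$Rmax_mu, cf$Ik, cf$beta)
  regime <- classify_regimes(grid, cf$Ik, cf$delta)
  # yield is Q_lim below the transitional band, Q_sat above it, and
  # interpolates linearly in Ii across the band (the physiological
  # transition is gradual, not a step)
  lo <- (1 - cf$delta) * cf$Ik
  hi <- (1 + cf$delta) * cf$Ik
  frac <- pmin(pmax((grid - lo) / (hi - lo), 0), 1)
  Q_true <- cf$Q_lim + frac * (cf$Q_sat - cf$Q_lim)
  qO2_true <- compute_qX(mu_true) / Q_true
  x_true <- cf$setpoint_OD * cf$od_to_biomass
  g <- cf$gas
  O2_true <- (1000 * qO2_true * x_true + mu_true * g$O2_in +
                g$kla * equilibrium_O2(g, g$pO2_in)) / (mu_true + g$kla)
  if (any(O2_true < 0))
    stop("non-physical configuration: negative dissolved O2 at Ii = ",
         paste(unique(grid[O2_true < 0]), collapse = ", "))
  n <- length(grid)
  mu_obs <- mu_true * lognormal_noise(n, cf$noise_cv[["mu"]])
  od_obs <- cf$setpoint_OD * lognormal_noise(n, cf$noise_cv[["OD"]])
  o2_obs <- O2_true * lognormal_noise(n, cf$noise_cv[["O2"]])
  data.frame(
    organism = "synthetic",
    Ii = grid,
    D = mu_obs,          # turbidostat: dilution tracks growth
    mu = mu_obs,
    OD730 = od_obs,
    x = od_obs * cf$od_to_biomass,
    O2_uM = o2_obs,
    pH = 7.5,
    truth_mu = mu_true,
    truth_qO2 = qO2_true,
    truth_Q = Q_true,
    truth_regime = regime)
}

#' Expression simulation configuration
#'
#' Defaults emulate the published transcriptome structure: 2,732
#' expressed genes split over four archetypal condition profiles
#' (809 monotone-up, 724 monotone-down, 648 minimum-at-transition,
#' 551 maximum-at-transition genes), gene-level Gaussian noise of sd 0.3
#' in standardized units, and a functional-annotation map with planted
#' enriched categories (a translation-like category concentrated in the
#' monotone-up cluster plus uniform null categories).
#'
#' @param n_genes integer vector, genes per archetype (length 4 for the
#'   four default shapes).
#' @param conditions condition labels (irradiances), >= 4; the archetype
#'   extremum sits at the condition nearest \code{Ik_transition}.
#' @param Ik_transition irradiance of the transitional steady state.
#' @param gene_noise_sd sd of gene-level noise (standardized units).
#' @param rpkm_scale positive multiplier mapping standardized profiles
#'   to RPKM (RPKM = rpkm_scale * 2^profile).
#' @param planted data frame of the enrichment plan: columns
#'   \code{category}, \code{level}, \code{cluster} (archetype index),
#'   \code{fraction} (of that cluster's genes carrying the category) and
#'   \code{background} (fraction of all other genes carrying it).
#' @param n_null_categories uniform non-enriched subrole categories.
#' @param null_fraction fraction of genes carrying each null category.
#' @param seed integer seed.
#' @return list of class \code{"expression_sim_config"}.
#' @export
expression_sim_config <- function(n_genes = c(809L, 724L, 648L, 551L),
                                  conditions = c(33, 66, 98, 132,
                                                 164, 211, 395, 760),
                                  Ik_transition = 164,
                                  gene_noise_sd = 0.3,
                                  rpkm_scale = 100,
                                  planted = data.frame(
                                    category = "translation",
                                    level = "main_role",
                                    cluster = 1L,
                                    fraction = 0.131,
                                    background = 0.019),
                                  n_null_categories = 5L,
                                  null_fraction = 0.05,
                                  seed = 1L) {
  stopifnot(all(n_genes >= 1), length(conditions) >= 4,
            gene_noise_sd >= 0, rpkm_scale > 0)
  structure(as.list(environment()), class = "expression_sim_config")
}

# The four archetype condition profiles, standardized to mean 0 / unit
# population sd: monotone-up, monotone-down, minimum-at-transition and
# maximum-at-transition, with the extremum at the transitional condition.
# The up/min shapes are piecewise-linear in condition index; their
# counterparts fall with mild curvature (power 1.3) so that the four
# shapes are linearly independent rather than exact mirror images.
archetype_profiles <- function(n_cond, i_trans) {
  stopifnot(n_cond >= 4, i_trans >= 2, i_trans <= n_cond - 1)
  idx <- seq_len(n_cond)
  vee <- abs(idx - i_trans)
  std <- function(p) (p - mean(p)) / sqrt(mean((p - mean(p))^2))
  rbind(up = std(idx), down = std(-(idx^1.3)),
        min_at_transition = std(vee),
        max_at_transition = std(-(vee^1.3)))
}

#' Simulate an RPKM expression matrix with planted cluster structure
#'
#' Each gene is its archetype profile plus i.i.d. Gaussian noise in
#' standardized units, mapped to positive RPKM as
#' \code{rpkm_scale * 2^profile} (so log2 + standardization downstream
#' recovers the shapes). The true archetype labels and an annotation map
#' with the planted enriched categories are returned alongside.
#'
#' @param config an [expression_sim_config()].
#' @return list: \code{rpkm} (genes x conditions matrix),
#'   \code{truth_labels} (named archetype index per gene),
#'   \code{archetypes} (archetype x condition matrix),
#'   \code{annotations} (gene/level/category data frame),
#'   \code{planted} (the plan).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  cf <- config
  set.seed(cf$seed)
  n_cond <- length(cf$conditions)
  i_trans <- which.min(abs(cf$conditions - cf$Ik_transition))
  i_trans <- min(max(i_trans, 2L), n_cond - 1L)
  arch <- archetype_profiles(n_cond, i_trans)
  n_arch <- length(cf$n_genes)
  stopifnot(n_arch <= nrow(arch))
  total <- sum(cf$n_genes)
  gene_ids <- sprintf("g%04d", seq_len(total))
  labels <- rep(seq_len(n_arch), cf$n_genes)
  names(labels) <- gene_ids
  prof <- arch[labels, , drop = FALSE] +
    matrix(stats::rnorm(total * n_cond, 0, cf$gene_noise_sd),
           total, n_cond)
  rpkm <- cf$rpkm_scale * 2^prof
  dimnames(rpkm) <- list(gene_ids, as.character(cf$conditions))

  # annotation map: planted enriched categories + uniform null categories
  ann <- list()
  if (!is.null(cf$planted) && nrow(cf$planted)) {
    for (i in seq_len(nrow(cf$planted))) {
      p <- cf$planted[i, ]
      inside <- gene_ids[labels == p$cluster]
      outside <- gene_ids[labels != p$cluster]
      carriers <- c(
        sample(inside, round(p$fraction * length(inside))),
        sample(outside, round(p$background * length(outside))))
      ann[[length(ann) + 1L]] <- data.frame(
        gene = carriers, level = p$level, category = p$category)
    }
  }
  if (cf$n_null_categories > 0) {
    for (j in seq_len(cf$n_null_categories)) {
      carriers <- sample(gene_ids, round(cf$null_fraction * total))
      ann[[length(ann) + 1L]] <- data.frame(
        gene = carriers, level = "subrole",
        category = sprintf("null_category_%02d", j))
    }
  }
  annotations <- if (length(ann)) do.call(rbind, ann)
                 else data.frame(gene = character(0), level = character(0),
                                 category = character(0))
  list(rpkm = rpkm, truth_labels = labels, archetypes = arch,
       annotations = annotations, planted = cf$planted)
}

#' Simulate a four-phase PAM fluorescence trace
#'
#' Reproduces the transient protocol: (i) a 200-ms saturating pulse,
#' (ii) 5 s of far-red light, (iii) 15 s of actinic light, (iv) 30 s of
#' darkness. The dark phase carries a linear post-illumination rise of
#' the configured slope (the cyclic-electron-flow proxy) plus Gaussian
#' noise.
#'
#' @param rcef_slope true dark-phase rise, fluorescence units s-1
#'   (finite).
#' @param noise_sd Gaussian noise sd on F (>= 0).
#' @param seed integer seed.
#' @param dt sampling interval, s.
#' @param levels named baseline fluorescence per phase.
#' @return data frame \code{time_s}, \code{F}, \code{phase} with
#'   attribute \code{truth_rcef}.
#' @export
simulate_fluorescence_trace <- function(rcef_slope, noise_sd = 0,
                                        seed = 1L, dt = 0.05,
                                        levels = c(saturating_pulse = 2.5,
                                                   far_red = 0.4,
                                                   actinic = 1.0,
                                                   dark = 0.8)) {
  stopifnot(is.finite(rcef_slope), noise_sd >= 0, dt > 0,
            all(PAM_PHASES %in% names(levels)))
  set.seed(seed)
  durs <- c(saturating_pulse = 0.2, far_red = 5, actinic = 15, dark = 30)
  segs <- lapply(PAM_PHASES, function(ph) {
    t_rel <- seq(0, durs[[ph]] - dt / 2, by = dt)
    f <- rep(levels[[ph]], length(t_rel))
    if (ph == "dark") f <- f + rcef_slope * t_rel
    data.frame(t_rel = t_rel, F = f, phase = ph)
  })
  offs <- cumsum(c(0, utils::head(durs, -1)))
  trace <- do.call(rbind, Map(function(s, o) {
    s$time_s <- s$t_rel + o; s$t_rel <- NULL; s
  }, segs, offs))
  trace <- trace[, c("time_s", "F", "phase")]
  trace$F <- trace$F + stats::rnorm(nrow(trace), 0, noise_sd)
  rownames(trace) <- NULL
  attr(trace, "truth_rcef") <- rcef_slope
  trace
}

#' Simulate a rapid light curve with known saturation parameters
#'
#' Generates (PAR, F, Fm') steps whose implied rETR follows the
#' saturating light-response curve with the given \code{rETRmax} and
#' \code{Ik} (so alpha_r = rETRmax/Ik), holding Fm' constant and backing
#' out F from the effective yield.
#'
#' @param rETRmax true asymptote (relative units).
#' @param Ik true saturating PAR.
#' @param PAR PAR steps, strictly increasing and positive.
#' @param Fm_prime constant maximal fluorescence.
#' @param noise_cv multiplicative noise CV on the yield (>= 0).
#' @param seed integer seed.
#' @return data frame \code{PAR}, \code{F}, \code{Fm_prime} with
#'   attributes \code{truth_rETRmax}, \code{truth_Ik}.
#' @export
simulate_rapid_light_curve <- function(rETRmax = 60, Ik = 120,
                                       PAR = c(25, 50, 100, 150, 250,
                                               400, 600, 900),
                                       Fm_prime = 1, noise_cv = 0,
                                       seed = 1L) {
  stopifnot(rETRmax > 0, Ik > 0, all(PAR > 0), all(diff(PAR) > 0),
            Fm_prime > 0, noise_cv >= 0)
  if (rETRmax / Ik > 1)
    stop("rETRmax/Ik > 1 implies yield > 1 at low PAR; not realisable")
  set.seed(seed)
  retr <- light_response(PAR, rETRmax, Ik)
  yield <- retr / PAR * lognormal_noise(length(PAR), noise_cv)
  yield <- pmin(yield, 1)
  out <- data.frame(PAR = PAR, F = Fm_prime * (1 - yield),
                    Fm_prime = Fm_prime)
  attr(out, "truth_rETRmax") <- rETRmax
  attr(out, "truth_Ik") <- Ik
  out
}

#' Simulate per-condition cell axis measurements
#'
#' Draws minor-axis diameters from a log-normal with the given CV and a
#' fixed aspect ratio distribution, scaled so the prolate-spheroid
#' volume is centred near each condition's target mean. Defaults follow
#' the microscopy conditions: mean volumes 3.23 / 4.84 / 9.69 um^3 at
#' 66 / 98 / 395 umol photons m-2 s-1 with 104 / 107 / 65 cells (the
#' low-light mean is set so the span is a ~3x expansion).
#'
#' @param mean_volumes named numeric: target mean volume (um^3) per
#'   condition label.
#' @param n_cells cells measured per condition (same length).
#' @param aspect_ratio mean major/minor diameter ratio.
#' @param cv coefficient of variation of the minor axis.
#' @param seed integer seed.
#' @return data frame \code{cell_id}, \code{a_um}, \code{b_um},
#'   \code{condition}.
#' @export
simulate_cell_measurements <- function(mean_volumes = c(`66` = 3.23,
                                                        `98` = 4.84,
                                                        `395` = 9.69),
                                       n_cells = c(104L, 107L, 65L),
                                       aspect_ratio = 1.8, cv = 0.15,
                                       seed = 1L) {
  stopifnot(length(mean_volumes) == length(n_cells),
            all(mean_volumes > 0), all(n_cells >= 1),
            aspect_ratio >= 1, cv >= 0)
  set.seed(seed)
  s2 <- log(1 + cv^2)
  rows <- Map(function(cond, V, n) {
    # E[a^2 b] = ratio * E[a^3] = ratio * a_med^3 * exp(4.5 s2) for
    # log-normal a; choose the median so the mean volume hits the target
    a_med <- (6 * V / (pi * aspect_ratio))^(1 / 3) / exp(1.5 * s2)
    a <- a_med * exp(stats::rnorm(n, 0, sqrt(s2)))
    b <- a * aspect_ratio
    data.frame(cell_id = sprintf("%s_c%03d", cond, seq_len(n)),
               a_um = a, b_um = b, condition = cond)
  }, names(mean_volumes), mean_volumes, n_cells)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a complete synthetic input bundle to disk
#'
#' Generates all pipeline inputs under one seed and writes them as
#' unit-tagged TSVs plus a JSON sidecar recording the generating
#' configuration: steady-state table, PAM trace, rapid light curve,
#' expression matrix, annotation map and cell measurements.
#'
#' @param dir output directory (created if needed).
#' @param seed master seed; stage seeds are derived from it.
#' @param turbidostat,expression optional configuration overrides.
#' @return invisibly, the list of written paths.
#' @export
write_synthetic_bundle <- function(dir, seed = 1L,
                                   turbidostat = NULL, expression = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(turbidostat)) turbidostat <- turbidostat_sim_config(seed = seed)
  if (is.null(expression)) expression <- expression_sim_config(seed = seed + 1L)
  ss <- simulate_steady_states(turbidostat)
  ex <- simulate_expression(expression)
  tr <- simulate_fluorescence_trace(0.5, noise_sd = 0.02, seed = seed + 2L)
  rlc <- simulate_rapid_light_curve(noise_cv = 0.02, seed = seed + 3L)
  cells <- simulate_cell_measurements(seed = seed + 4L)

  p <- function(f) file.path(dir, f)
  write_units_tsv(ss, p("steady_states.tsv"),
                  units = c(organism = "-", Ii = "umol_photons.m-2.s-1",
                            D = "h-1", mu = "h-1", OD730 = "-",
                            x = "g_AFDW.L-1", O2_uM = "uM", pH = "-",
                            truth_mu = "h-1", truth_qO2 = "mmol.h-1.g-1",
                            truth_Q = "Cmmol.mmol-1", truth_regime = "-"))
  expr_df <- data.frame(gene = rownames(ex$rpkm), ex$rpkm,
                        check.names = FALSE)
  write_units_tsv(expr_df, p("expression_rpkm.tsv"))
  write_units_tsv(ex$annotations, p("annotations.tsv"))
  write_units_tsv(data.frame(gene = names(ex$truth_labels),
                             truth_cluster = ex$truth_labels),
                  p("truth_expression_labels.tsv"))
  write_units_tsv(as.data.frame(tr), p("pam_trace.tsv"),
                  units = c(time_s = "s", F = "fluorescence", phase = "-"))
  write_units_tsv(as.data.frame(rlc), p("rapid_light_curve.tsv"),
                  units = c(PAR = "umol_photons.m-2.s-1",
                            F = "fluorescence", Fm_prime = "fluorescence"))
  write_units_tsv(cells, p("cell_measurements.tsv"),
                  units = c(cell_id = "-", a_um = "um", b_um = "um",
                            condition = "umol_photons.m-2.s-1"))
  sidecar <- list(seed = seed,
                  turbidostat = turbidostat[setdiff(names(turbidostat), "gas")],
                  gas = unclass(turbidostat$gas),
                  expression = expression[c("n_genes", "conditions",
                                            "gene_noise_sd", "rpkm_scale",
                                            "seed")],
                  truth_rcef = attr(tr, "truth_rcef"),
                  truth_rETRmax = attr(rlc, "truth_rETRmax"),
                  truth_Ik_rlc = attr(rlc, "truth_Ik"))
  jsonlite::write_json(sidecar, p("config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(dir = dir,
                 files = list.files(dir, full.names = TRUE)))
}
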