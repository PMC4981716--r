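# Canonical internal units: h-1, uM, g AFDW L-1, mmol h-1 g-1.

# assumed molecular weight of dry biomass, g AFDW per C-mol
CMOL_MASS_AFDW <- 24.59

#' Gas-liquid transfer parameters of the sparged photobioreactor
#'
#' @param kla lumped volumetric gas-liquid mass transfer coefficient; by
#'   default in h-1, set \code{kla_units = "per_min"} for min-1 (converted
#'   internally, e.g. 0.83 min-1 = 49.8 h-1).
#' @param kH Henry's-law partitioning coefficient for O2, mM atm-1.
#' @param pO2_in partial pressure of O2 in the in-gas, atm (0..1).
#' @param O2_in dissolved O2 of the inflowing medium, uM. Defaults to 0:
#'   medium equilibrated with O2-free sparge gas.
#' @param kla_units unit tag for \code{kla}.
#' @return Object of class \code{"gas_params"} with \code{kla} in h-1.
#' @export
gas_params <- function(kla, kH = 1.08, pO2_in = 0, O2_in = 0,
                       kla_units = c("per_h", "per_min")) {
  kla_units <- match.arg(kla_units)
  if (kla_units == "per_min") kla <- kla * 60
  stopifnot(kla > 0, kH > 0, pO2_in >= 0, pO2_in <= 1, O2_in >= 0)
  structure(list(kla = kla, kH = kH, pO2_in = pO2_in, O2_in = O2_in),
            class = "gas_params")
}

#' @export
print.gas_params <- function(x, ...) {
  cat(sprintf(
    "gas_params: kla = %.4g h-1, kH = %.4g mM atm-1, pO2_in = %.3g atm, O2_in = %.4g uM\n",
    x$kla, x$kH, x$pO2_in, x$O2_in))
  invisible(x)
}

#' Dissolved O2 in equilibrium with a gas phase (Henry's law)
#'
#' @param gas a [gas_params()] object (its \code{kH} is used).
#' @param pO2 O2 partial pressure, atm.
#' @return Equilibrium dissolved O2, uM (\code{kH * pO2}, mM converted
#'   to uM).
#' @export
equilibrium_O2 <- function(gas, pO2) {
  stopifnot(inherits(gas, "gas_params"), all(pO2 >= 0))
  gas$kH * pO2 * 1000
}

#' Net specific O2 production from the steady-state reactor mass balance
#'
#' The O2 balance over the liquid control volume at steady state gives,
#' in the production-positive convention implemented here,
#' \deqn{q_{O_2} x = D([O_2]-[O_2]_{in}) + k_La([O_2]-k_H p_{O_2,in})}
#' i.e. net photosynthetic O2 production sustains both the washout of
#' supersaturated liquid and the stripping flux to the sparge gas. (The
#' same balance is often written consumption-positive with both
#' differences reversed; only the sign differs.) A negative return value
#' means net consumption and is not an error.
#'
#' @param record data frame with columns \code{D} (dilution rate, h-1),
#'   \code{O2_uM} (dissolved O2, uM) and \code{x} (biomass, g AFDW L-1);
#'   extra columns are ignored. Vectorised over rows.
#' @param gas a [gas_params()] object.
#' @return \code{qO2} in mmol O2 h-1 g AFDW-1, one value per row.
#' @export
compute_qO2 <- function(record, gas) {
  stopifnot(inherits(gas, "gas_params"),
            all(c("D", "O2_uM", "x") %in% names(record)))
  if (any(record$x <= 0)) stop("biomass concentration x must be positive")
  O2 <- record$O2_uM
  flux_uM_h <- record$D * (O2 - gas$O2_in) +
    gas$kla * (O2 - equilibrium_O2(gas, gas$pO2_in))
  flux_uM_h / record$x / 1000
}

#' Net specific biomass production on a carbon-mole basis
#'
#' Converts the specific growth rate to Cmmol biomass h-1 g AFDW-1
#' assuming a dry-biomass molecular weight of 24.59 g AFDW per C-mol:
#' \code{qX = mu * 1000 / 24.59}.
#'
#' @param mu specific growth rate, h-1 (vectorised, >= 0).
#' @return \code{qX}, Cmmol h-1 g-1.
#' @export
compute_qX <- function(mu) {
  stopifnot(all(mu >= 0))
  mu * 1000 / CMOL_MASS_AFDW
}

#' Growth-to-photosynthesis yield (photosynthetic quotient) per regime
#'
#' Q is the ratio of the net rate of carbon fixation into biomass to the
#' net rate of oxygenic photosynthesis; per light regime it is estimated
#' as the ordinary-least-squares slope of \code{qX} on \code{qO2}
#' (with intercept by default; forcing the origin is available).
#'
#' @param qO2 net specific O2 production, mmol h-1 g-1.
#' @param qX net specific biomass production, Cmmol h-1 g-1.
#' @param regime regime label per point (e.g. from [classify_regimes()]).
#' @param intercept fit with an intercept (default) or through the origin.
#' @return data frame with one row per regime: \code{regime}, \code{Q}
#'   (slope), \code{se}, \code{n}, \code{flagged} (TRUE when a slope could
#'   not be estimated: fewer than 2 points or zero qO2 variance).
#' @export
photosynthetic_quotient <- function(qO2, qX, regime, intercept = TRUE) {
  stopifnot(length(qO2) == length(qX), length(qX) == length(regime))
  regs <- unique(regime)
  rows <- lapply(regs, function(r) {
    i <- regime == r
    n <- sum(i)
    if (n < 2 || stats::var(qO2[i]) == 0)
      return(data.frame(regime = r, Q = NA_real_, se = NA_real_,
                        n = n, flagged = TRUE))
    fm <- if (intercept) stats::lm(qX[i] ~ qO2[i])
          else stats::lm(qX[i] ~ qO2[i] + 0)
    cf <- suppressWarnings(summary(fm))$coefficients  # exact fits allowed
    k <- nrow(cf)  # slope is the last coefficient
    data.frame(regime = r, Q = cf[k, 1], se = cf[k, 2], n = n,
               flagged = FALSE)
  })
  do.call(rbind, rows)
}

#' Steady-state detection from reactor continuity criteria
#'
#' A culture is declared at physiological steady state when every
#' monitored channel (OD730, pH, dissolved O2, ...) shows at most 3%
#' relative variation between consecutive measurements over the
#' assessment window (inclusive threshold) and at least five reactor
#' residence times have elapsed. Relative variation between a
#' consecutive pair is |difference| / pair mean.
#'
#' @param channels named list of numeric vectors, one per monitored
#'   channel, time-ordered within the assessment window.
#' @param residence_times_elapsed number of residence times completed.
#' @param max_variation inclusive relative-variation threshold
#'   (default 0.03).
#' @param min_residence_times required residence times (default 5).
#' @return list: \code{steady} (logical), \code{channels} (named logical,
#'   NA for channels with < 2 values), \code{max_variation} (named numeric),
#'   \code{residence_ok}.
#' @export
detect_steady_state <- function(channels, residence_times_elapsed,
                                max_variation = 0.03,
                                min_residence_times = 5) {
  stopifnot(is.list(channels), length(channels) > 0,
            !is.null(names(channels)))
  per <- vapply(channels, function(v) {
    if (length(v) < 2) return(NA_real_)
    pairs <- abs(diff(v)) / ((utils::head(v, -1) + utils::tail(v, -1)) / 2)
    max(pairs)
  }, numeric(1))
  verdict <- per <= max_variation
  res_ok <- residence_times_elapsed >= min_residence_times
  list(steady = isTRUE(all(verdict)) && res_ok,
       channels = verdict,
       max_variation = per,
       residence_ok = res_ok)
}
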