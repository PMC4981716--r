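# PAM chlorophyll-fluorescence statistics.
# Protocol phases for transient traces, in measurement order:
PAM_PHASES <- c("saturating_pulse", "far_red", "actinic", "dark")

#' Relative electron transport rate
#'
#' \code{rETR = PAR * (Fm' - F) / Fm'}, i.e. PAR times the effective
#' quantum yield of PSII under actinic light. \code{F > Fm'} gives a
#' negative yield; the value is returned as-is and flagged (attribute
#' \code{"flagged"}), never clamped.
#'
#' @param PAR actinic photon flux, umol photons m-2 s-1 (>= 0).
#' @param F steady-state fluorescence under actinic light.
#' @param Fm_prime maximal fluorescence under actinic light (> 0).
#' @return rETR (relative units), with attribute \code{flagged} marking
#'   positions where \code{F > Fm_prime}.
#' @export
compute_rETR <- function(PAR, F, Fm_prime) {
  if (any(Fm_prime <= 0)) stop("Fm_prime must be positive")
  stopifnot(all(PAR >= 0))
  val <- PAR * (Fm_prime - F) / Fm_prime
  attr(val, "flagged") <- F > Fm_prime
  val
}

#' Rapid-light-curve parameters rETR_max and alpha_r
#'
#' Computes rETR at every PAR step of a rapid light curve and fits the
#' monotone saturating light-response submodel through
#' [fit_light_response()]. \code{rETRmax} is the fitted asymptote (the
#' observed maximum is also reported); \code{alpha_r}, the relative
#' maximal quantum yield of photochemistry, is the fitted initial slope
#' Rmax/Ik.
#'
#' @param rlc data frame with columns \code{PAR}, \code{F},
#'   \code{Fm_prime}; >= 4 PAR steps, PAR strictly increasing.
#' @return list: \code{rETRmax} (fitted), \code{rETRmax_observed},
#'   \code{alpha_r}, \code{Ik}, \code{fit} (the underlying
#'   \code{light_response_fit}), \code{rETR} (per step),
#'   \code{degenerate} (TRUE when all rETR are zero; no fit attempted).
#' @export
fit_rapid_light_curve <- function(rlc) {
  stopifnot(all(c("PAR", "F", "Fm_prime") %in% names(rlc)))
  if (nrow(rlc) < 4) stop("need at least 4 PAR steps")
  if (any(diff(rlc$PAR) <= 0)) stop("PAR must be strictly increasing")
  retr <- compute_rETR(rlc$PAR, rlc$F, rlc$Fm_prime)
  if (all(retr == 0))
    return(list(rETRmax = NA_real_, rETRmax_observed = 0,
                alpha_r = NA_real_, Ik = NA_real_, fit = NULL,
                rETR = retr, degenerate = TRUE))
  pos <- rlc$PAR > 0
  fit <- fit_light_response(rlc$PAR[pos], as.numeric(retr)[pos],
                            model = "saturating")
  list(rETRmax = fit$Rmax, rETRmax_observed = max(retr),
       alpha_r = fit$alpha, Ik = fit$Ik, fit = fit, rETR = retr,
       degenerate = FALSE)
}

#' Post-illumination fluorescence rise: cyclic electron flow proxy
#'
#' After actinic illumination stops, reduction of the plastoquinone pool
#' by stromal reductant raises fluorescence in the dark; the initial rate
#' of that rise is used as a relative proxy for cyclic electron transport
#' around PSI (rCEF). Implemented as the ordinary-least-squares slope of
#' F against time over the first \code{window} seconds of the dark phase.
#'
#' @param trace data frame with columns \code{time_s}, \code{F},
#'   \code{phase} (containing a \code{"dark"} phase with >= 3 samples).
#' @param window initial dark-phase window used for the slope, seconds.
#'   A window longer than the dark phase is truncated with a warning.
#' @return list: \code{rCEF} (fluorescence units s-1), \code{se},
#'   \code{n}, \code{window_used} (s).
#' @export
estimate_rCEF <- function(trace, window = 10) {
  stopifnot(all(c("time_s", "F", "phase") %in% names(trace)),
            window > 0)
  dark <- trace[trace$phase == "dark", , drop = FALSE]
  if (nrow(dark) < 3) stop("trace needs a dark phase with >= 3 samples")
  t_rel <- dark$time_s - min(dark$time_s)
  span <- max(t_rel)
  if (window > span) {
    warning(sprintf("window %.3g s exceeds dark phase (%.3g s); truncated",
                    window, span))
    window <- span
  }
  keep <- t_rel <= window
  if (sum(keep) < 3) keep <- seq_len(min(3L, nrow(dark)))
  fm <- stats::lm(dark$F[keep] ~ t_rel[keep])
  # noise-free traces trigger summary.lm's perfect-fit warning; such
  # inputs are legitimate here (zero-slope dark phases)
  cf <- suppressWarnings(summary(fm))$coefficients
  list(rCEF = cf[2, 1], se = cf[2, 2], n = sum(keep),
       window_used = max(t_rel[keep]))
}

#' Optimal (dark-adapted) quantum yield of PSII
#'
#' \code{Fv/Fm = (Fm - Fo)/Fm}. An \code{Fo > Fm} pair yields a negative
#' value, returned as-is and flagged.
#'
#' @param Fo minimal (dark-adapted) fluorescence.
#' @param Fm maximal fluorescence after a saturating pulse (> 0).
#' @return Fv/Fm, with attribute \code{flagged} where \code{Fo > Fm}.
#' @export
optimal_quantum_yield <- function(Fo, Fm) {
  if (any(Fm <= 0)) stop("Fm must be positive")
  val <- (Fm - Fo) / Fm
  attr(val, "flagged") <- Fo > Fm
  val
}
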