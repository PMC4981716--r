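#' Saturating / photoinhibition light-response model
#'
#' Evaluates the Platt-type irradiance response
#' \deqn{R = R_{max}\,[1 - \exp(-I_i/I_k)]\,\exp(-I_i/\beta)}
#' where \eqn{I_k} is the theoretical saturating irradiance and \eqn{\beta}
#' the irradiance threshold of photoinhibition (same units as \eqn{I_i}).
#' With \code{beta = Inf} the inhibition factor drops and the model reduces
#' to the Webb saturating exponential.
#'
#' @param Ii incident irradiance, umol photons m-2 s-1 (vectorised).
#' @param Rmax asymptotic rate in the units of the response (> 0).
#' @param Ik theoretical saturating irradiance (> 0).
#' @param beta photoinhibition threshold irradiance (> 0, may be \code{Inf}).
#' @return Model response at each \code{Ii}.
#' @seealso [fit_light_response()], [peak_irradiance()]
#' @export
light_response <- function(Ii, Rmax, Ik, beta = Inf) {
  stopifnot(is.numeric(Ii), Rmax > 0, Ik > 0, beta > 0)
  inhib <- if (is.infinite(beta)) 1 else exp(-Ii / beta)
  Rmax * (1 - exp(-Ii / Ik)) * inhib
}

#' Irradiance of the maximum of the light-response curve
#'
#' Setting the derivative of the model to zero gives the closed form
#' \eqn{I_{peak} = I_k \log(1 + \beta/I_k)}; infinite for the
#' monotone saturating submodel.
#'
#' @inheritParams light_response
#' @return Irradiance at which the modelled response peaks.
#' @export
peak_irradiance <- function(Ik, beta = Inf) {
  stopifnot(Ik > 0, beta > 0)
  if (is.infinite(beta)) return(Inf)
  Ik * log1p(beta / Ik)
}

#' Fit the light-response model by (weighted) nonlinear least squares
#'
#' Minimises \eqn{\sum_i w_i (R_i - model(I_i))^2} with
#' Levenberg-Marquardt iterations from multiple data-driven starts.
#' Weights are \eqn{1/sd_i^2} when per-point standard deviations are
#' supplied, otherwise 1. Both the full three-parameter model and the
#' monotone saturating submodel (\code{beta = Inf}) are fitted; under
#' \code{model = "auto"} the finite-\code{beta} model is retained only when
#' it lowers the weighted SSE significantly by an extra-sum-of-squares
#' F test at \code{f_alpha}, so saturating data are not assigned spurious
#' inhibition.
#'
#' Parameters are optimised on the log scale (all are positive scales)
#' inside wide data-driven box bounds (\code{Ik} within 20x of the
#' observed irradiance range, \code{Rmax} within 100x of the observed
#' maximum): outside those boxes only ratios such as Rmax/Ik are
#' identified and the optimiser can otherwise wander to degenerate
#' near-linear solutions. Standard errors come from the Jacobian of the
#' natural-scale model at the optimum.
#'
#' @param Ii irradiances (strictly positive, >= 4 distinct values for the
#'   full model, >= 3 for \code{model = "saturating"}).
#' @param R measured response at each irradiance.
#' @param sd optional per-point standard deviations for 1/sd^2 weighting.
#' @param model \code{"auto"} (F-test selection), \code{"saturating"}
#'   (force \code{beta = Inf}) or \code{"full"}.
#' @param n_starts number of multi-start jitters around the data-driven
#'   initial guesses.
#' @param f_alpha significance level of the model-selection F test.
#' @param start_seed seed for the deterministic start jitter.
#' @return An object of class \code{"light_response_fit"}: list with
#'   \code{Rmax}, \code{Ik}, \code{beta}, \code{alpha} (= Rmax/Ik, initial
#'   slope), \code{peak_Ii}, \code{se} (named vector), \code{sse},
#'   \code{model} (selected), \code{sse_saturating}, \code{sse_full},
#'   \code{f_p_value}, \code{converged}, \code{weights}, \code{n},
#'   \code{data} and \code{fitted}.
#' @export
fit_light_response <- function(Ii, R, sd = NULL,
                               model = c("auto", "saturating", "full"),
                               n_starts = 5, f_alpha = 0.05,
                               start_seed = 1L) {
  model <- match.arg(model)
  stopifnot(length(Ii) == length(R), all(Ii > 0))
  if (anyDuplicated(Ii) && length(unique(Ii)) < 3)
    stop("need at least 3 distinct irradiances")
  n <- length(Ii)
  min_n <- if (model == "saturating") 3L else 4L
  if (n < min_n)
    stop("need at least ", min_n, " points for the ", model, " fit")
  w <- if (is.null(sd)) rep(1, n) else {
    stopifnot(length(sd) == n, all(sd > 0))
    1 / sd^2
  }
  sw <- sqrt(w)

  resid_fun <- function(logp) {
    p <- exp(logp)
    beta <- if (length(p) == 3L) p[[3L]] else Inf
    sw * (R - light_response(Ii, p[[1L]], p[[2L]], beta))
  }
  # box bounds (log scale) keep the optimiser out of the degenerate
  # region Ik >> max(Ii), where Rmax/Ik is identified but neither factor is
  bound_lo <- log(c(Rmax = 1e-2 * max(R), Ik = min(Ii) / 20,
                    beta = max(Ii) / 20))
  bound_hi <- log(c(Rmax = 1e2 * max(R), Ik = 20 * max(Ii),
                    beta = 1e8 * max(Ii)))
  run_starts <- function(starts) {
    best <- NULL
    for (s in starts) {
      np <- length(s)
      ans <- tryCatch(
        minpack.lm::nls.lm(par = pmin(pmax(log(s), bound_lo[seq_len(np)]),
                                      bound_hi[seq_len(np)]),
                           fn = resid_fun,
                           lower = bound_lo[seq_len(np)],
                           upper = bound_hi[seq_len(np)],
                           control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(ans)) next
      sse <- sum(ans$fvec^2)
      if (is.null(best) || sse < best$sse)
        best <- list(par = exp(ans$par), sse = sse,
                     converged = ans$info %in% 1:4)
    }
    best
  }

  # data-driven starts: Rmax ~ max R; Ik ~ irradiance at half max
  Rmax0 <- max(R)
  if (Rmax0 <= 0) stop("response must contain positive values")
  half <- Rmax0 / 2
  above <- which(R >= half)
  Ik0 <- if (length(above)) max(min(Ii[above]), min(Ii)) else stats::median(Ii)
  jit <- function(k, amount = 0.3) {
    set.seed(start_seed)
    c(1, exp(stats::rnorm(k - 1, 0, amount)))
  }
  j <- jit(n_starts)
  sat_starts <- lapply(j, function(f) c(Rmax = Rmax0 * f, Ik = Ik0 / f))
  sat <- run_starts(sat_starts)
  if (is.null(sat)) stop("saturating-model fit failed from every start")

  full <- NULL
  if (model != "saturating") {
    beta0s <- c(2 * max(Ii), 1e4 * max(Ii))
    full_starts <- c(
      lapply(beta0s, function(b)
        c(Rmax = sat$par[[1L]], Ik = sat$par[[2L]], beta = b)),
      lapply(j[-1], function(f)
        c(Rmax = Rmax0 * f, Ik = Ik0 / f, beta = 2 * max(Ii) * f)))
    full <- run_starts(full_starts)
  }

  # extra-sum-of-squares test of finite beta against the nested submodel
  f_p <- NA_real_
  use_full <- FALSE
  if (!is.null(full)) {
    sse1 <- min(full$sse, sat$sse)  # nesting: full can always match the submodel
    full$sse <- sse1
    if (model == "full") {
      use_full <- TRUE
    } else if (n > 3L) {
      scale <- max(sat$sse, .Machine$double.eps * sum((sw * R)^2, 1))
      fstat <- ((sat$sse - sse1) / 1) / max(sse1 / (n - 3L),
                                            .Machine$double.eps * scale)
      f_p <- stats::pf(fstat, 1, n - 3L, lower.tail = FALSE)
      use_full <- is.finite(f_p) && f_p < f_alpha
    }
  }

  chosen <- if (use_full) full else sat
  Rmax <- chosen$par[[1L]]; Ik <- chosen$par[[2L]]
  beta <- if (use_full) chosen$par[[3L]] else Inf

  # natural-scale Jacobian -> asymptotic standard errors
  p_nat <- if (use_full) c(Rmax = Rmax, Ik = Ik, beta = beta)
           else c(Rmax = Rmax, Ik = Ik)
  Jf <- function(p) {
    b <- if (length(p) == 3L) p[[3L]] else Inf
    sw * light_response(Ii, p[[1L]], p[[2L]], b)
  }
  J <- tryCatch(numeric_jacobian(Jf, p_nat), error = function(e) NULL)
  se <- rep(NA_real_, length(p_nat)); names(se) <- names(p_nat)
  dof <- n - length(p_nat)
  if (!is.null(J) && dof > 0) {
    JtJ <- crossprod(J)
    cv <- tryCatch(solve(JtJ) * chosen$sse / dof, error = function(e) NULL)
    if (!is.null(cv)) se[] <- sqrt(pmax(diag(cv), 0))
  }

  out <- list(
    Rmax = Rmax, Ik = Ik, beta = beta,
    alpha = Rmax / Ik,
    peak_Ii = peak_irradiance(Ik, beta),
    se = se,
    sse = chosen$sse,
    model = if (use_full) "full" else "saturating",
    sse_saturating = sat$sse,
    sse_full = if (is.null(full)) NA_real_ else full$sse,
    f_p_value = f_p,
    converged = chosen$converged,
    weights = w, n = n,
    data = data.frame(Ii = Ii, R = R,
                      sd = if (is.null(sd)) NA_real_ else sd),
    fitted = light_response(Ii, Rmax, Ik, beta))
  class(out) <- "light_response_fit"
  out
}

# central-difference Jacobian; relative step on each parameter
numeric_jacobian <- function(f, p, rel_h = 1e-6) {
  f0 <- f(p)
  J <- matrix(NA_real_, length(f0), length(p))
  for (i in seq_along(p)) {
    h <- rel_h * max(abs(p[[i]]), 1)
    if (!is.finite(h) || is.infinite(p[[i]])) { J[, i] <- 0; next }
    up <- p; up[[i]] <- p[[i]] + h
    dn <- p; dn[[i]] <- p[[i]] - h
    J[, i] <- (f(up) - f(dn)) / (2 * h)
  }
  J
}

#' @export
print.light_response_fit <- function(x, ...) {
  cat("Light-response fit (", x$model, " model, n = ", x$n, ")\n", sep = "")
  cat(sprintf("  Rmax  = %.4g (se %.3g)\n", x$Rmax, x$se[["Rmax"]]))
  cat(sprintf("  Ik    = %.4g (se %.3g)\n", x$Ik, x$se[["Ik"]]))
  if (is.finite(x$beta))
    cat(sprintf("  beta  = %.4g (se %.3g)\n", x$beta, x$se[["beta"]]))
  else cat("  beta  = Inf (no inhibition supported)\n")
  cat(sprintf("  alpha = Rmax/Ik = %.4g; peak at Ii = %.4g\n",
              x$alpha, x$peak_Ii))
  cat(sprintf("  weighted SSE = %.4g\n", x$sse))
  invisible(x)
}

#' Classify irradiances into light regimes around Ik
#'
#' The light-limited and light-saturated regimes are separated by a
#' transitional band of fractional half-width \code{delta} around the
#' theoretical saturating irradiance: \code{Ii < (1-delta)*Ik} is
#' light-limited, \code{Ii > (1+delta)*Ik} light-saturated, anything else
#' transitional.
#'
#' @param Ii irradiances to classify.
#' @param Ik theoretical saturating irradiance, or a
#'   \code{light_response_fit} from which it is taken.
#' @param delta fractional width of the transitional band (0 < delta < 1).
#' @return Character vector in
#'   \code{c("light-limited", "transitional", "light-saturated")}.
#' @export
classify_regimes <- function(Ii, Ik, delta = 0.25) {
  if (inherits(Ik, "light_response_fit")) Ik <- Ik$Ik
  stopifnot(Ik > 0, delta > 0, delta < 1)
  out <- rep("transitional", length(Ii))
  out[Ii < (1 - delta) * Ik] <- "light-limited"
  out[Ii > (1 + delta) * Ik] <- "light-saturated"
  out
}
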