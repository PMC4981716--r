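#' Cell volume from confocal axis measurements
#'
#' Treats the cell as a prolate spheroid with minor-axis diameter
#' \code{a} (two equal equatorial axes) and major-axis diameter \code{b}:
#' \deqn{V = \frac{\pi}{6} a^2 b}
#' (semi-axes a/2, a/2, b/2). The formula is sometimes quoted as
#' \eqn{(4/3)\pi a^2 b} with a, b still called diameters; that form only
#' holds if a and b are semi-axes and is 8x larger when fed diameters.
#' It is available as \code{formula = "as_printed"} for comparison; the
#' diameter-consistent form is the default and is what reproduces
#' micrometre-scale cell volumes of a few um^3.
#'
#' @param a minor-axis diameter, um (> 0; vectorised).
#' @param b major-axis diameter, um (> 0). Pairs with \code{a > b} are
#'   swapped with a warning.
#' @param formula \code{"diameter"} (default, pi/6 a^2 b) or
#'   \code{"as_printed"} (4/3 pi a^2 b).
#' @return volume, um^3.
#' @export
ellipsoid_volume <- function(a, b, formula = c("diameter", "as_printed")) {
  formula <- match.arg(formula)
  stopifnot(length(a) == length(b))
  if (any(a <= 0) || any(b <= 0)) stop("axis diameters must be positive")
  swap <- a > b
  if (any(swap)) {
    warning(sum(swap), " measurement(s) had minor axis > major axis; swapped")
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  }
  coef <- if (formula == "diameter") pi / 6 else 4 * pi / 3
  coef * a^2 * b
}

#' Per-condition cell-volume summaries and fold changes
#'
#' @param measurements data frame with columns \code{a_um}, \code{b_um}
#'   and \code{condition} (one group per steady state, e.g. the incident
#'   irradiance); optionally \code{cell_id}.
#' @param formula passed to [ellipsoid_volume()].
#' @return list: \code{summary} data frame (condition, n, mean_um3,
#'   sd_um3 — sample sd, \code{NA} at n = 1) ordered by condition, and
#'   \code{fold_change}, the matrix of mean-volume ratios
#'   (row condition / column condition).
#' @export
summarize_volumes <- function(measurements, formula = "diameter") {
  stopifnot(all(c("a_um", "b_um", "condition") %in% names(measurements)),
            nrow(measurements) >= 1)
  v <- ellipsoid_volume(measurements$a_um, measurements$b_um,
                        formula = formula)
  grp <- split(v, measurements$condition)
  sm <- data.frame(
    condition = names(grp),
    n = vapply(grp, length, integer(1)),
    mean_um3 = vapply(grp, mean, numeric(1)),
    sd_um3 = vapply(grp, function(x)
      if (length(x) > 1) stats::sd(x) else NA_real_, numeric(1)),
    row.names = NULL)
  fc <- outer(sm$mean_um3, sm$mean_um3, "/")
  dimnames(fc) <- list(sm$condition, sm$condition)
  list(summary = sm, fold_change = fc)
}
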