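#' Decompose tissue surface tension into cell-scale tensions
#'
#' Under the differential interfacial tension hypothesis, the tissue surface
#' tension of a cohesive aggregate balances the cortical tension at the
#' cell-medium interface, `T_CM`, against the effective cell-cell tension
#' `2 T_CC - J_CC` (doubled cell-cell cortical tension minus the
#' intercellular adhesion energy):
#' \deqn{\gamma = T_{CM} - \tfrac{1}{2}(2 T_{CC} - J_{CC}),}
#' while force balance at the three-phase cell/cell/medium contact line ties
#' the same combination to the local contact angle `alpha` between the free
#' surfaces of two neighbouring cells:
#' \deqn{2 T_{CM}\cos(\alpha/2) = 2 T_{CC} - J_{CC}.}
#' Eliminating between the two gives the closed forms returned here,
#' \deqn{T_{CM} = \frac{\gamma}{1 - \cos(\alpha/2)},\qquad
#'       2T_{CC} - J_{CC} = \frac{2\gamma\cos(\alpha/2)}{1 - \cos(\alpha/2)}.}
#' Only the combination `2 T_CC - J_CC` is identifiable; the adhesion energy
#' and the cell-cell cortical tension are never separated.
#'
#' @param gamma Tissue surface tension (mN/m), `> 0`.
#' @param alpha Cell-cell contact angle in degrees, in `(0, 180]`;
#'   180 degrees means fully spread, flat surface cells.
#' @return Object of class `interfacial_tensions` with `gamma`, `alpha`,
#'   `T_CM` and `T_CC_eff` (= `2 T_CC - J_CC`), all tensions in mN/m.
#' @examples
#' decompose_tensions(gamma = 20, alpha = 120)  # T_CM = 40, T_CC_eff = 40
#' @export
decompose_tensions <- function(gamma, alpha) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    stop("gamma must be a single finite positive tension (mN/m)")
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha))
    stop("alpha must be a single finite angle in degrees")
  if (alpha > 180)
    stop("contact angle alpha exceeds 180 degrees: out of the physical domain")
  if (alpha <= 0)
    stop("contact angle alpha must be positive")
  ca <- cos(alpha / 2 * pi / 180)
  denom <- 1 - ca
  if (denom < 1e-12)
    stop("alpha -> 0: cos(alpha/2) -> 1, tensions diverge; a vanishing ",
         "contact angle is outside the measurable regime")
  structure(list(
    gamma = gamma, alpha = alpha,
    T_CM = gamma / denom,
    T_CC_eff = 2 * gamma * ca / denom
  ), class = "interfacial_tensions")
}

#' Summarize a set of measured cell-cell contact angles
#'
#' Arithmetic mean, sample standard deviation and count of junction angles
#' measured over the spheroid surface. The decomposition into tensions is
#' then done at the mean angle per condition.
#'
#' @param angles Numeric vector of contact angles in degrees, each in
#'   `(0, 180]`.
#' @return Object of class `angle_summary`: `mean_alpha`, `sd_alpha`
#'   (0 for a single angle), `n`.
#' @examples
#' summarize_angles(c(90, 110))  # mean 100, sd ~14.14
#' @export
summarize_angles <- function(angles) {
  if (!is.numeric(angles) || length(angles) == 0L)
    stop("angles must be a non-empty numeric vector (degrees)")
  bad <- which(!is.finite(angles) | angles <= 0 | angles > 180)
  if (length(bad))
    stop("angle out of (0, 180] degrees at index ", bad[1L],
         " (value ", angles[bad[1L]], ")")
  structure(list(
    mean_alpha = mean(angles),
    sd_alpha = if (length(angles) > 1L) stats::sd(angles) else 0,
    n = length(angles)
  ), class = "angle_summary")
}

#' @export
print.interfacial_tensions <- function(x, ...) {
  cat(sprintf(
    "Interfacial tensions at alpha = %g deg, gamma = %g mN/m:\n  T_CM = %.4g mN/m, 2T_CC - J_CC = %.4g mN/m\n",
    x$alpha, x$gamma, x$T_CM, x$T_CC_eff))
  invisible(x)
}

#' @export
print.angle_summary <- function(x, ...) {
  cat(sprintf("Contact angles: mean %.2f deg, sd %.2f deg, n = %d\n",
              x$mean_alpha, x$sd_alpha, x$n))
  invisible(x)
}
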