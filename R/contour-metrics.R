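#' Build a contour from planar points
#'
#' Ordered planar points (x, z) in micrometres, as extracted from a
#' cryosection or side-profile micrograph.
#'
#' @param x,z Numeric coordinate vectors of equal length (um).
#' @return Object of class `contour_points`: data frame with columns
#'   `x_um`, `z_um`.
#' @export
contour_points <- function(x, z) {
  if (!is.numeric(x) || !is.numeric(z) || length(x) != length(z))
    stop("x and z must be numeric vectors of equal length")
  if (any(!is.finite(x)) || any(!is.finite(z)))
    stop("contour coordinates must be finite")
  structure(data.frame(x_um = as.numeric(x), z_um = as.numeric(z)),
            class = c("contour_points", "data.frame"))
}

#' Least-squares circle fit to a contour
#'
#' Geometric least-squares circle: minimizes the sum of squared orthogonal
#' distances `(|p_i - center| - r)^2`. The algebraic Kasa fit provides the
#' starting point, refined by Levenberg-Marquardt on (center, radius).
#' Exact on noiseless data (residual machine-zero on points lying on a
#' circle, including the circumscribed circle of three non-collinear
#' points).
#'
#' @param contour A [contour_points()] object or a two-column matrix/data
#'   frame of (x, z) in um.
#' @return List with `cx_um`, `cz_um`, `r_um`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 21)[-21]
#' fit_circle(contour_points(100 * cos(th), 100 * sin(th)))
#' @export
fit_circle <- function(contour) {
  p <- .as_contour(contour)
  n <- nrow(p)
  if (n < 3L) stop("circle fitting needs at least 3 points")
  x <- p$x_um; z <- p$z_um
  # collinearity guard via the rank of centred coordinates
  M <- cbind(x - mean(x), z - mean(z))
  sv <- svd(M, nu = 0, nv = 0)$d
  if (sv[2] <= 1e-10 * max(sv[1], 1))
    stop("degenerate circle fit: contour points are collinear")
  # Kasa algebraic fit: x^2 + z^2 = 2 cx x + 2 cz z + (r^2 - cx^2 - cz^2)
  A <- cbind(2 * x, 2 * z, 1)
  b <- x^2 + z^2
  sol <- qr.solve(A, b)
  cx <- sol[1]; cz <- sol[2]
  r <- sqrt(sol[3] + cx^2 + cz^2)
  # geometric refinement (Levenberg-Marquardt on orthogonal residuals)
  res <- minpack.lm::nls.lm(
    par = c(cx = cx, cz = cz, r = r),
    fn = function(par) sqrt((x - par[1])^2 + (z - par[2])^2) - par[3],
    control = minpack.lm::nls.lm.control(maxiter = 200))
  par <- res$par
  list(cx_um = unname(par[1]), cz_um = unname(par[2]), r_um = unname(par[3]))
}

#' Root-mean-squared roughness of a contour about a circular arc
#'
#' Fits a circular arc to the contour (unless a reference arc is supplied)
#' and computes, for each point, the signed distance `z_i` to the arc, then
#' \deqn{R_q = \sqrt{\tfrac{1}{N}\sum_i z_i^2}.}
#' The smaller `Rq`, the smoother the spheroid surface. Residuals are
#' evaluated only at the provided points; the arc is never extrapolated.
#'
#' @param contour A [contour_points()] object (or coercible).
#' @param arc Optional fixed reference arc, a list with `cx_um`, `cz_um`,
#'   `r_um`; when omitted the least-squares arc of [fit_circle()] is used.
#' @return Object of class `roughness_result`: `Rq_um`, `cx_um`, `cz_um`,
#'   `r_um`, `residuals_um` (signed, positive outside the arc), `n`.
#' @examples
#' th <- seq(0, pi, length.out = 200)
#' ct <- contour_points(500 * cos(th), 500 * sin(th))
#' roughness_rq(ct)$Rq_um  # 0
#' @export
roughness_rq <- function(contour, arc = NULL) {
  p <- .as_contour(contour)
  if (is.null(arc)) arc <- fit_circle(p)
  if (!all(c("cx_um", "cz_um", "r_um") %in% names(arc)))
    stop("arc must supply cx_um, cz_um, r_um")
  zi <- sqrt((p$x_um - arc$cx_um)^2 + (p$z_um - arc$cz_um)^2) - arc$r_um
  structure(list(
    Rq_um = sqrt(mean(zi^2)),
    cx_um = arc$cx_um, cz_um = arc$cz_um, r_um = arc$r_um,
    residuals_um = zi, n = nrow(p)
  ), class = "roughness_result")
}

.as_contour <- function(contour) {
  if (inherits(contour, "contour_points")) return(contour)
  if (is.matrix(contour)) contour <- as.data.frame(contour)
  if (is.data.frame(contour) && ncol(contour) >= 2L) {
    nm <- names(contour)
    if (all(c("x_um", "z_um") %in% nm))
      return(contour_points(contour$x_um, contour$z_um))
    return(contour_points(contour[[1L]], contour[[2L]]))
  }
  stop("cannot interpret contour input; supply contour_points() or two columns")
}

#' @export
print.roughness_result <- function(x, ...) {
  cat(sprintf("Roughness Rq = %.3g um about arc r = %.4g um (n = %d points)\n",
              x$Rq_um, x$r_um, x$n))
  invisible(x)
}
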