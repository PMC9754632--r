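#' Shape parameters of the flattened-drop forward model
#'
#' The equilibrium profile of a spheroid flattened by a uniform body force is
#' governed by the axisymmetric Young-Laplace equation in Bashforth-Adams
#' arc-length form. Two physical parameters fix the shape: the capillary
#' parameter `c = f/gamma` (body-force density over surface tension, 1/m^2)
#' and the apex mean curvature `b` (1/m), which carries the apex pressure
#' jump `2*gamma*b`.
#'
#' @param c Capillary parameter (1/m^2), `>= 0`. `c = 0` gives a sphere.
#' @param b Apex mean curvature (1/m), `> 0`.
#' @param step Dimensionless arc-length step of the integrator, relative to
#'   the internal length scale `min(1/b, 1/sqrt(c))`. Default `1e-3`.
#' @return An object of class `shape_params`.
#' @export
shape_params <- function(c, b, step = 1e-3) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c < 0)
    stop("capillary parameter c must be a single finite number >= 0 (1/m^2)")
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0)
    stop("apex curvature b must be a single finite positive number (1/m)")
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0)
    stop("step must be a single finite positive number")
  if (step > 0.05)
    stop("step too large to resolve the apex region (require step <= 0.05)")
  structure(list(c = as.numeric(c), b = as.numeric(b), step = as.numeric(step)),
            class = "shape_params")
}

# internal length scale: apex radius or capillary length, whichever is smaller,
# so sphere-like and puddle-like regimes are both resolved by the same
# dimensionless step
.length_scale <- function(c, b) 1 / sqrt(max(b^2, c))

#' Integrate an equilibrium Young-Laplace profile
#'
#' Integrates the arc-length form of the axisymmetric Young-Laplace equation
#' under a uniform downward body force,
#' \deqn{dx/ds = \cos\phi,\quad dz/ds = \sin\phi,\quad
#'       d\phi/ds = (2b + c z) - \sin\phi/x,}
#' from the apex (`x = z = phi = 0`, with the analytic apex limit
#' `dphi/ds = b`) until the tangent angle reaches 180 degrees, the
#' non-wetting contact condition. `z` is measured from the apex downward,
#' toward the magnet ("heavy sessile drop" orientation).
#'
#' Integration is a fixed-step classical Runge-Kutta scheme (order 4) on the
#' nondimensionalized system, with a series start at the apex and bisection
#' localization of the terminal angle. The volume of revolution is accumulated
#' as an auxiliary state, so all metrics converge at the integrator's order.
#'
#' @param params A [shape_params()] object.
#' @param keep_path Keep the sampled profile path? Default `TRUE`. Fitting
#'   loops set this to `FALSE` and use only the scalar metrics.
#' @param s_max Arc-length budget in units of the internal length scale;
#'   integration failing to reach 180 degrees within it is an error.
#' @return An object of class `shape_solution`: list with `params`, metric
#'   fields `h`, `w`, `V`, `L_model` (SI units), and when `keep_path` is
#'   `TRUE` vectors `s`, `x`, `z`, `phi` (m, m, m, rad).
#' @examples
#' R <- 530e-6
#' sol <- integrate_profile(shape_params(c = 0, b = 1 / R))
#' profile_metrics(sol)  # sphere: h = w = 2R, V = 4/3 pi R^3
#' @export
integrate_profile <- function(params, keep_path = TRUE, s_max = 1e4) {
  stopifnot(inherits(params, "shape_params"))
  Ls <- .length_scale(params$c, params$b)
  raw <- .ba_integrate(bhat = params$b * Ls, bo = params$c * Ls^2,
                       step = params$step, s_max = s_max,
                       keep_path = keep_path)
  sol <- list(params = params,
              h = raw$h * Ls, w = raw$w * Ls, V = raw$V * Ls^3,
              L_model = raw$L * Ls, s_end = raw$s_end * Ls)
  if (keep_path) {
    sol$s <- raw$s * Ls
    sol$x <- raw$x * Ls
    sol$z <- raw$z * Ls
    sol$phi <- raw$phi
  }
  structure(sol, class = "shape_solution")
}

#' Scalar metrics of an integrated profile
#'
#' Height `h` (final depth at 180 degrees contact), width `w = 2 max x`,
#' volume of revolution `V` (closed by the contact disc), and the model
#' contact radius `L_model` (radial coordinate where the tangent angle
#' reaches 180 degrees). `L_model` is a by-product of the shape solve and is
#' never used for elasticity; the Hertz modulus uses the measured contact
#' radius.
#'
#' @param sol A `shape_solution` from [integrate_profile()].
#' @return Object of class `profile_metrics`: list with `h`, `w`, `V`,
#'   `L_model` in SI units (m, m, m^3, m).
#' @export
profile_metrics <- function(sol) {
  if (!inherits(sol, "shape_solution"))
    stop("profile_metrics() needs a terminated shape_solution")
  structure(list(h = sol$h, w = sol$w, V = sol$V, L_model = sol$L_model),
            class = "profile_metrics")
}

#' Pointwise Laplace-balance residual of a solution
#'
#' Recomputes the mean curvature `dphi/ds + sin(phi)/x` from the stored path
#' by central finite differences and compares it with the pressure term
#' `2b + c z`. The maximum relative residual (scaled by `2b`) is a diagnostic
#' of integration quality, independent of the ODE right-hand side used to
#' produce the path.
#'
#' @param sol A `shape_solution` with a stored path.
#' @param trim Number of samples dropped at each end, where one-sided
#'   differences and the apex 0/0 limit would dominate. Default 5.
#' @return Maximum over the profile of `|curvature - (2b + c z)| / (2b)`.
#' @export
laplace_residual <- function(sol, trim = 5L) {
  stopifnot(inherits(sol, "shape_solution"))
  if (is.null(sol[["s"]]))
    stop("solution was integrated with keep_path = FALSE; no path to check")
  n <- length(sol[["s"]])
  if (n < 2L * trim + 5L) stop("path too short for a residual check")
  i <- (trim + 1L):(n - trim)
  dphi <- (sol$phi[i + 1L] - sol$phi[i - 1L]) / (sol$s[i + 1L] - sol$s[i - 1L])
  curv <- dphi + sin(sol$phi[i]) / sol$x[i]
  p <- 2 * sol$params$b + sol$params$c * sol$z[i]
  max(abs(curv - p)) / (2 * sol$params$b)
}

#' Solve for the profile of a given volume at fixed capillary parameter
#'
#' Root-finds on the apex curvature `b` so that the integrated volume of
#' revolution matches `V_target`, parameterizing the shape family by the
#' capillary parameter alone — the form in which the inverse tension fit
#' explores candidate surface tensions at conserved spheroid volume.
#'
#' @param c Capillary parameter (1/m^2), `>= 0`.
#' @param V_target Target volume (m^3), `> 0`.
#' @param step Dimensionless integrator step, as in [shape_params()].
#' @param tol Relative volume tolerance. Default `1e-9` (comfortably inside
#'   the documented 1e-6 contract).
#' @param keep_path Passed on to [integrate_profile()] for the returned
#'   solution.
#' @return A `shape_solution` whose volume matches `V_target` to `tol`.
#' @examples
#' R <- 530e-6
#' sol <- solve_shape_for_volume(c = 0, V_target = 4 / 3 * pi * R^3)
#' sol$params$b * R  # 1: the zero-force solution is the sphere of radius R
#' @export
solve_shape_for_volume <- function(c, V_target, step = 1e-3, tol = 1e-9,
                                   keep_path = TRUE) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c < 0)
    stop("capillary parameter c must be a single finite number >= 0")
  if (!is.numeric(V_target) || length(V_target) != 1L ||
      !is.finite(V_target) || V_target <= 0)
    stop("V_target must be a single finite positive volume (m^3)")
  R0 <- (3 * V_target / (4 * pi))^(1 / 3)
  vol_of <- function(logb) {
    integrate_profile(shape_params(c, exp(logb), step), keep_path = FALSE)$V
  }
  # V(b) is strictly decreasing; bracket log b around the sphere guess 1/R0
  lo <- log(1 / R0) - 1
  hi <- log(1 / R0) + 1
  for (k in 1:40) {
    if (vol_of(lo) > V_target) break
    lo <- lo - 1
    if (k == 40) stop("root bracket failure in solve_shape_for_volume (c = ",
                      c, ", V_target = ", V_target, "): b lower bound")
  }
  for (k in 1:40) {
    if (vol_of(hi) < V_target) break
    hi <- hi + 1
    if (k == 40) stop("root bracket failure in solve_shape_for_volume (c = ",
                      c, ", V_target = ", V_target, "): b upper bound")
  }
  r <- stats::uniroot(function(lb) vol_of(lb) - V_target, c(lo, hi),
                      tol = .Machine$double.eps^0.5)
  # polish on relative volume error with the secant until inside tol
  b <- exp(r$root)
  sol <- integrate_profile(shape_params(c, b, step), keep_path = keep_path)
  for (k in 1:30) {
    rel <- (sol$V - V_target) / V_target
    if (abs(rel) < tol) break
    # dV/db ~ -3V/b near any solution family member (dimensional scaling)
    b <- b * (1 + rel / 3)
    sol <- integrate_profile(shape_params(c, b, step), keep_path = keep_path)
  }
  if (abs(sol$V - V_target) / V_target >= 1e-6)
    stop("volume solve failed to converge (c = ", c, ", V_target = ",
         V_target, ")")
  sol
}

#' @export
print.shape_solution <- function(x, ...) {
  cat("Young-Laplace shape solution (c =", format(x$params$c, digits = 4),
      "m^-2, b =", format(x$params$b, digits = 4), "m^-1)\n")
  cat(sprintf("  h = %.2f um, w = %.2f um, V = %.4g um^3, L_model = %.2f um\n",
              x$h * 1e6, x$w * 1e6, x$V * 1e18, x$L_model * 1e6))
  invisible(x)
}

#' @export
print.profile_metrics <- function(x, ...) {
  cat(sprintf("Profile metrics: h = %.2f um, w = %.2f um, V = %.4g um^3, L_model = %.2f um\n",
              x$h * 1e6, x$w * 1e6, x$V * 1e18, x$L_model * 1e6))
  invisible(x)
}

#' Export a profile path as a data frame
#'
#' @param sol A `shape_solution` with stored path.
#' @return `data.frame` with columns `s_m`, `x_m`, `z_m`, `phi_rad`.
#' @export
profile_as_data_frame <- function(sol) {
  stopifnot(inherits(sol, "shape_solution"))
  if (is.null(sol[["s"]])) stop("no stored path (keep_path = FALSE)")
  data.frame(s_m = sol$s, x_m = sol$x, z_m = sol$z, phi_rad = sol$phi)
}
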