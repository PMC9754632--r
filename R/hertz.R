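#' Young's modulus from the contact-zone radius (Hertz theory)
#'
#' When a soft elastic sphere of radius `R` is pressed onto a plate by a
#' uniform body-force density `f`, Hertz contact theory relates its Young's
#' modulus to the radius `L` of the flattened contact zone:
#' \deqn{E = (1 - \sigma^2)\,\pi f R^4 / L^3,}
#' with Poisson ratio `sigma` (1/2 for an incompressible tissue, giving a
#' prefactor of `3/4 pi f R^4 / L^3`).
#'
#' @param R Initial spheroid radius (um).
#' @param L Contact-zone radius (um), measured on the image — never the
#'   model contact radius of the Laplace fit.
#' @param ctx A [magnetic_context()].
#' @param sigma Poisson ratio, default `1/2`.
#' @param w_um Optional measured width; `L > w/2` is geometrically
#'   impossible and triggers a warning.
#' @return Object of class `elasticity_result` with `E` (Pa), `sigma`,
#'   `L_um`, `R_um`, `f`.
#' @examples
#' ctx <- magnetic_context(250, 170)
#' young_modulus(R = 530, L = 429.3, ctx = ctx)  # ~100 Pa
#' @export
young_modulus <- function(R, L, ctx, sigma = 0.5, w_um = NULL) {
  stopifnot(inherits(ctx, "magnetic_context"))
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
    stop("R must be a single finite positive radius (um)")
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("contact radius L must be a single finite positive length (um); ",
         "L = 0 has no defined modulus")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0 || sigma >= 1)
    stop("Poisson ratio sigma must lie in [0, 1)")
  if (!is.null(w_um) && L > w_um / 2)
    warning("contact radius L exceeds half the measured width; ",
            "geometrically impossible landmark set")
  f <- force_density(ctx)
  R_m <- R * 1e-6
  L_m <- L * 1e-6
  E <- (1 - sigma^2) * pi * f * R_m^4 / L_m^3
  structure(list(E = E, sigma = sigma, L_um = L, R_um = R, f = f),
            class = "elasticity_result")
}

#' Contact radius implied by a Young's modulus
#'
#' Algebraic inverse of [young_modulus()]:
#' `L = [(1 - sigma^2) pi f R^4 / E]^(1/3)`. Used to build synthetic
#' fixtures with a known ground-truth modulus.
#'
#' @param E Young's modulus (Pa), `> 0`.
#' @param R Initial radius (um).
#' @param ctx A [magnetic_context()].
#' @param sigma Poisson ratio, default `1/2`.
#' @return Contact radius L in um.
#' @examples
#' contact_radius_for_modulus(100, 530, magnetic_context(250, 170))  # ~429 um
#' @export
contact_radius_for_modulus <- function(E, R, ctx, sigma = 0.5) {
  stopifnot(inherits(ctx, "magnetic_context"))
  if (!is.numeric(E) || length(E) != 1L || !is.finite(E) || E <= 0)
    stop("E must be a single finite positive modulus (Pa)")
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
    stop("R must be a single finite positive radius (um)")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0 || sigma >= 1)
    stop("Poisson ratio sigma must lie in [0, 1)")
  f <- force_density(ctx)
  R_m <- R * 1e-6
  ((1 - sigma^2) * pi * f * R_m^4 / E)^(1 / 3) * 1e6
}

#' @export
print.elasticity_result <- function(x, ...) {
  cat(sprintf("Hertz elasticity: E = %.4g Pa (R = %g um, L = %g um, sigma = %g)\n",
              x$E, x$R_um, x$L_um, x$sigma))
  invisible(x)
}
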