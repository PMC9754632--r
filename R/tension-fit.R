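#' Measured landmarks of a flattened spheroid profile
#'
#' The inverse tension fit consumes three scalar landmarks pointed on the
#' side-profile images: height `h` and width `w` of the flattened spheroid,
#' and the initial (undeformed) radius `R` which fixes the conserved volume
#' `V = 4/3 pi R^3`. The contact-zone radius `L`, when pointed, is carried
#' along for the Hertz modulus. All lengths are stored in micrometres.
#'
#' @param h Height of the flattened profile.
#' @param w Width of the flattened profile.
#' @param R Initial spheroid radius; exactly one of `R` or `V` is required.
#' @param V Spheroid volume (um^3 when `units = "um"`).
#' @param L Contact-zone radius (optional).
#' @param units Unit of the supplied lengths, `"um"` (default) or `"m"`.
#' @return Object of class `landmark_set` with fields `h_um`, `w_um`,
#'   `V_um3`, `R_um` (NA when volume was given directly) and `L_um`.
#' @examples
#' landmark_set(h = 700, w = 1250, R = 530)
#' @export
landmark_set <- function(h, w, R = NULL, V = NULL, L = NULL, units = c("um", "m")) {
  units <- match.arg(units)
  k <- if (units == "m") 1e6 else 1
  chk <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop("landmark ", nm, " must be a single finite positive length")
    as.numeric(x) * k
  }
  h <- chk(h, "h"); w <- chk(w, "w")
  if (h > w * (1 + 1e-9))
    stop("landmarks violate h <= w: a flattened drop is wider than tall")
  if (is.null(R) && is.null(V)) stop("supply either R or V")
  if (!is.null(R)) {
    R <- chk(R, "R")
    V <- 4 / 3 * pi * R^3
  } else {
    if (!is.numeric(V) || length(V) != 1L || !is.finite(V) || V <= 0)
      stop("landmark V must be a single finite positive volume")
    V <- as.numeric(V) * k^3
    R <- NA_real_
  }
  if (!is.null(L)) L <- chk(L, "L") else L <- NA_real_
  structure(list(h_um = h, w_um = w, V_um3 = V, R_um = R, L_um = L),
            class = "landmark_set")
}

#' Surface tension from a fitted capillary parameter
#'
#' `gamma = f / c`, reported in mN/m.
#'
#' @param c Capillary parameter (1/m^2), `> 0`.
#' @param ctx A [magnetic_context()].
#' @return Surface tension in mN/m.
#' @examples
#' gamma_from_c(2.024e6, magnetic_context(250, 170))  # ~21 mN/m
#' @export
gamma_from_c <- function(c, ctx) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    stop("capillary parameter must be a single positive number")
  stopifnot(inherits(ctx, "magnetic_context"))
  force_density(ctx) / c * 1000
}

# quadratic-error objective: equal-weight squared relative errors on h, w, V
.landmark_objective <- function(logb, logc, lm, step) {
  sol <- tryCatch(
    integrate_profile(shape_params(exp(logc), exp(logb), step),
                      keep_path = FALSE),
    error = function(e) NULL)
  if (is.null(sol)) return(1e10)
  ((sol$h * 1e6 - lm$h_um) / lm$h_um)^2 +
    ((sol$w * 1e6 - lm$w_um) / lm$w_um)^2 +
    ((sol$V * 1e18 - lm$V_um3) / lm$V_um3)^2
}

#' Fit the capillary parameter and surface tension to profile landmarks
#'
#' Inverse problem of magnetic-force tensiometry: find the capillary
#' parameter `c` (and apex curvature `b`) whose equilibrium Young-Laplace
#' profile minimizes the quadratic error — the equal-weight sum of squared
#' relative errors — on the measured height `h`, width `w`, and volume `V`,
#' then convert `c` to surface tension via `gamma = f / c`.
#'
#' The optimizer is Nelder-Mead over `(log b, log c)`, seeded from a coarse
#' log-grid pre-scan in `c` spanning gamma from 0.5 to 500 mN/m at
#' volume-matched `b`. The log parameterization enforces positivity without
#' constraints.
#'
#' @param landmarks A [landmark_set()].
#' @param ctx A [magnetic_context()].
#' @param gamma_init Initial surface-tension guess (mN/m). Default 10.
#' @param noise_bound_um Assumed pointing error on the landmarks (um);
#'   measured flattening `2R - h` below twice this bound triggers an
#'   identifiability warning, and below the bound itself the fit is refused
#'   as out of measurable range. Default 5.
#' @param step Integrator step for the forward model.
#' @param maxit Nelder-Mead iteration cap. Default 500.
#' @param reltol Relative convergence tolerance of the objective. Default 1e-8.
#' @return Object of class `tension_result`: `c` (1/m^2), `gamma` (mN/m),
#'   `b` (1/m), `residual` (final objective), `converged`, `warnings`
#'   (character vector), `E_Pa` slot left `NA` for the pipeline to fill.
#' @examples
#' ctx <- magnetic_context(250, 170)
#' truth <- solve_shape_for_volume(c = ctx$f / 21e-3,
#'                                 V_target = 4 / 3 * pi * (530e-6)^3)
#' lm <- landmark_set(h = truth$h * 1e6, w = truth$w * 1e6, R = 530)
#' fit_capillary(lm, ctx)$gamma  # recovers ~21 mN/m
#' @export
fit_capillary <- function(landmarks, ctx, gamma_init = 10,
                          noise_bound_um = 5, step = 1e-3,
                          maxit = 500, reltol = 1e-8) {
  stopifnot(inherits(landmarks, "landmark_set"), inherits(ctx, "magnetic_context"))
  if (!is.numeric(gamma_init) || gamma_init <= 0)
    stop("gamma_init must be positive (mN/m)")
  f <- force_density(ctx)
  warns <- character()

  # identifiability: flattening must exceed the pointing noise
  R_eff_um <- if (is.finite(landmarks$R_um)) landmarks$R_um else
    (3 * landmarks$V_um3 / (4 * pi))^(1 / 3)
  flattening_um <- 2 * R_eff_um - landmarks$h_um
  if (flattening_um < noise_bound_um)
    stop("out of measurable range: flattening 2R - h = ",
         signif(flattening_um, 3), " um is below the pointing noise (",
         noise_bound_um, " um); surface tension is unbounded for an ",
         "undeformed sphere")
  if (flattening_um < 2 * noise_bound_um)
    warns <- c(warns, sprintf(
      "weak identifiability: flattening %.3g um < twice the pointing noise (%g um)",
      flattening_um, 2 * noise_bound_um))

  V_m3 <- landmarks$V_um3 * 1e-18
  lm <- landmarks

  # coarse pre-scan over c (gamma grid 0.5..500 mN/m) at volume-matched b
  gamma_grid <- sort(unique(c(
    exp(seq(log(0.5), log(500), length.out = 13)), gamma_init)))
  scan <- lapply(gamma_grid, function(g) {
    cc <- f / (g * 1e-3)
    sol <- tryCatch(
      solve_shape_for_volume(cc, V_m3, step = step, keep_path = FALSE),
      error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    list(logb = log(sol$params$b), logc = log(cc),
         obj = .landmark_objective(log(sol$params$b), log(cc), lm, step))
  })
  scan <- Filter(Negate(is.null), scan)
  if (!length(scan)) stop("pre-scan failed over the whole gamma grid")
  best <- scan[[which.min(vapply(scan, `[[`, numeric(1), "obj"))]]

  opt <- stats::optim(
    par = c(best$logb, best$logc),
    fn = function(p) .landmark_objective(p[1], p[2], lm, step),
    method = "Nelder-Mead",
    control = list(maxit = maxit, reltol = reltol))
  if (opt$convergence != 0 && opt$value > best$obj)
    stop("capillary fit did not converge; final residual ", opt$value)
  if (opt$convergence != 0)
    warns <- c(warns, "Nelder-Mead hit the iteration cap; best point returned")

  cc <- exp(opt$par[2])
  structure(list(
    c = cc,
    gamma = gamma_from_c(cc, ctx),
    b = exp(opt$par[1]),
    residual = opt$value,
    converged = opt$convergence == 0,
    iterations = opt$counts[["function"]],
    warnings = warns,
    ctx = ctx,
    landmarks = landmarks
  ), class = "tension_result")
}

#' @export
print.tension_result <- function(x, ...) {
  cat(sprintf("Surface tension fit: gamma = %.3g mN/m (c = %.4g m^-2)\n",
              x$gamma, x$c))
  cat(sprintf("  residual = %.3g, converged = %s\n", x$residual, x$converged))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
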