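#' Configuration of the synthetic-fixture generators
#'
#' Defaults reproduce the reference experimental regime: spheroids of 530 um
#' radius magnetized at Mv = 250 A/m in a 170 T/m gradient (force density
#' 4.25e4 N/m^3, the midpoint of the accessible 2.5e4-8.5e4 N/m^3 range),
#' surface tension 21 mN/m and Young's modulus 100 Pa (the reference
#' flattened-spheroid condition), pointing noise of up to 5 um on the
#' landmarks, and a blebbistatin-style dose design of 0-160 uM with 8
#' replicates and 10% relative response noise.
#'
#' @param seed Integer seed fixing all pseudo-randomness of the generators.
#' @param gamma Ground-truth surface tension (mN/m).
#' @param E Ground-truth Young's modulus (Pa).
#' @param ctx A [magnetic_context()].
#' @param R Initial spheroid radius (um).
#' @param pointing_noise Half-width of the uniform pointing error (um);
#'   the plausible experimental range is 2-5.
#' @param n_replicates Replicates per dose in dose-response tables.
#' @param doses Dose set (uM).
#' @param response_cv Relative (Gaussian) response noise in dose-response
#'   tables.
#' @return Object of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L,
                           gamma = 21,
                           E = 100,
                           ctx = magnetic_context(Mv = 250, gradB = 170),
                           R = 530,
                           pointing_noise = 5,
                           n_replicates = 8L,
                           doses = c(0, 1, 3, 10, 30, 80, 160),
                           response_cv = 0.1) {
  stopifnot(inherits(ctx, "magnetic_context"))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single integer")
  if (gamma <= 0 || E <= 0 || R <= 0 || pointing_noise < 0)
    stop("gamma, E, R must be positive; pointing_noise >= 0")
  structure(list(
    seed = as.integer(seed), gamma = gamma, E = E, ctx = ctx, R = R,
    pointing_noise = pointing_noise, n_replicates = as.integer(n_replicates),
    doses = doses, response_cv = response_cv
  ), class = "fixture_config")
}

#' Generate a synthetic flattened-spheroid profile dataset
#'
#' Runs the forward Laplace model at `c = f/gamma` and the conserved volume
#' of an `R`-um sphere, reflects the half-profile into a closed contour,
#' perturbs the landmarks `h` and `w` (and optionally `L`) with independent
#' uniform pointing noise on `[-pointing_noise, +pointing_noise]`, and
#' derives the contact radius `L` from the ground-truth modulus `E` via the
#' inverse Hertz relation. Ground truth is embedded alongside.
#'
#' @param cfg A [fixture_config()].
#' @param n_points Number of contour samples of the half-profile.
#' @param noisy_L Also perturb the contact radius? Default `TRUE`.
#' @return List of class `profile_fixture`: `contour` ([contour_points()],
#'   um, image convention with z increasing downward from the apex),
#'   `landmarks` ([landmark_set()]), `truth` (list with `gamma`, `E`, `L_um`,
#'   `c`, `h_um`, `w_um`, `V_um3`), `manifest` (every generating parameter).
#' @export
make_profile_dataset <- function(cfg, n_points = 400L, noisy_L = TRUE) {
  stopifnot(inherits(cfg, "fixture_config"))
  set.seed(cfg$seed)
  f <- force_density(cfg$ctx)
  cc <- f / (cfg$gamma * 1e-3)
  V <- 4 / 3 * pi * (cfg$R * 1e-6)^3
  sol <- solve_shape_for_volume(cc, V)
  m <- profile_metrics(sol)

  idx <- unique(round(seq(1, length(sol$s), length.out = n_points)))
  xh <- sol$x[idx] * 1e6
  zh <- sol$z[idx] * 1e6
  contour <- contour_points(c(xh, -rev(xh)), c(zh, rev(zh)))

  L_true <- contact_radius_for_modulus(cfg$E, cfg$R, cfg$ctx)
  noise <- function() stats::runif(1, -cfg$pointing_noise, cfg$pointing_noise)
  h_um <- m$h * 1e6 + noise()
  w_um <- m$w * 1e6 + noise()
  L_um <- L_true + if (noisy_L) noise() else 0
  landmarks <- landmark_set(h = min(h_um, w_um), w = w_um, R = cfg$R,
                            L = max(L_um, 1e-3))

  truth <- list(gamma = cfg$gamma, E = cfg$E, L_um = L_true, c = cc,
                h_um = m$h * 1e6, w_um = m$w * 1e6, V_um3 = m$V * 1e18)
  manifest <- list(
    seed = cfg$seed, gamma_mN_per_m = cfg$gamma, E_Pa = cfg$E,
    Mv_A_per_m = cfg$ctx$Mv, gradB_T_per_m = cfg$ctx$gradB,
    R_um = cfg$R, pointing_noise_um = cfg$pointing_noise,
    noise_model = "uniform on [-bound, +bound], independent per landmark",
    n_points = n_points, noisy_L = noisy_L)
  structure(list(contour = contour, landmarks = landmarks, truth = truth,
                 manifest = manifest),
            class = "profile_fixture")
}

#' Generate a synthetic dose-response table
#'
#' Evaluates the Hill model on the configured dose set and multiplies each
#' response by `(1 + N(0, cv))`, `n_replicates` draws per dose.
#'
#' @param cfg A [fixture_config()] (supplies seed, doses, replicates, cv).
#' @param params Hill parameters: list with `Top`, `Bottom`, `IC50`,
#'   `HillSlope` (nonzero). Default mirrors the surface-tension inhibition
#'   reference curve (Top = 21 mN/m, Bottom = 2 mN/m, IC50 = 10 uM,
#'   HillSlope = -1).
#' @return `data.frame` with columns `dose_uM`, `response`, `replicate`.
#' @export
make_dose_dataset <- function(cfg,
                              params = list(Top = 21, Bottom = 2,
                                            IC50 = 10, HillSlope = -1)) {
  stopifnot(inherits(cfg, "fixture_config"))
  if (length(cfg$doses) == 0L) stop("empty dose set")
  if (params$HillSlope == 0) stop("degenerate Hill parameters: HillSlope = 0")
  set.seed(cfg$seed)
  mu <- hill_eval(cfg$doses, params)
  out <- do.call(rbind, lapply(seq_len(cfg$n_replicates), function(rep) {
    data.frame(dose_uM = cfg$doses,
               response = mu * (1 + stats::rnorm(length(mu), 0, cfg$response_cv)),
               replicate = rep)
  }))
  rownames(out) <- NULL
  out
}

#' Generate a noisy circular-arc contour for roughness testing
#'
#' `n` points on an arc of radius `r` with i.i.d. radial Gaussian offsets of
#' standard deviation `sigma_r`, seeded from the configuration.
#'
#' @param cfg A [fixture_config()] (supplies the seed).
#' @param r Arc radius (um), `> 0`.
#' @param sigma_r Radial noise standard deviation (um), `>= 0`.
#' @param n Number of points, `>= 3`.
#' @param span Angular span of the arc in radians (default `pi`, a
#'   half-circle as in a cryosection profile).
#' @return A [contour_points()] object.
#' @export
make_rough_contour <- function(cfg, r, sigma_r, n = 500L, span = pi) {
  stopifnot(inherits(cfg, "fixture_config"))
  if (!is.numeric(r) || r <= 0) stop("arc radius r must be positive")
  if (!is.numeric(sigma_r) || sigma_r < 0) stop("sigma_r must be >= 0")
  if (n < 3L) stop("need at least 3 contour points")
  set.seed(cfg$seed)
  th <- seq(0, span, length.out = n)
  ri <- r + stats::rnorm(n, 0, sigma_r)
  contour_points(ri * cos(th), ri * sin(th))
}

#' Write a fixture to a plain-text directory
#'
#' Serializes a `profile_fixture` as `contour.csv`, `landmarks.json`,
#' `truth.json`, `manifest.yaml` for consumption by the pipeline or CLI.
#'
#' @param fixture A `profile_fixture` from [make_profile_dataset()].
#' @param dir Target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(fixture, dir) {
  stopifnot(inherits(fixture, "profile_fixture"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(as.data.frame(fixture$contour),
                   file.path(dir, "contour.csv"), row.names = FALSE)
  write_landmarks_json(fixture$landmarks, file.path(dir, "landmarks.json"))
  jsonlite::write_json(fixture$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(fixture$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a fixture directory written by [write_fixture_dir()]
#'
#' @param dir Fixture directory.
#' @return A list with `contour`, `landmarks`, `truth`, `manifest` (the
#'   latter two `NULL` when absent, as for real measurement directories).
#' @export
read_fixture_dir <- function(dir) {
  if (!dir.exists(dir)) stop("fixture directory not found: ", dir)
  ct <- utils::read.csv(file.path(dir, "contour.csv"))
  lmp <- file.path(dir, "landmarks.json")
  trp <- file.path(dir, "truth.json")
  mfp <- file.path(dir, "manifest.yaml")
  list(
    contour = contour_points(ct$x_um, ct$z_um),
    landmarks = if (file.exists(lmp)) read_landmarks_json(lmp) else NULL,
    truth = if (file.exists(trp)) jsonlite::read_json(trp, simplifyVector = TRUE) else NULL,
    manifest = if (file.exists(mfp)) yaml::read_yaml(mfp) else NULL
  )
}
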