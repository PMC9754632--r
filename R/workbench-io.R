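#' Read and write the workbench file formats
#'
#' Plain-text formats tie the analysis stages together: contour CSV
#' (`x_um,z_um`), landmarks JSON (`{h_um, w_um, R_um?, V_um3?, L_um?}`),
#' angle CSV (`alpha_deg`), dose CSV (`dose_uM,response`), and a YAML run
#' configuration. Coordinates follow the image convention: x rightward,
#' z downward (toward the magnet), micrometres.
#'
#' @param path File path.
#' @return The parsed object (see the individual functions).
#' @name workbench-formats
NULL

#' @rdname workbench-formats
#' @export
read_contour_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("x_um", "z_um") %in% names(d)))
    stop("contour CSV must have columns x_um, z_um")
  contour_points(d$x_um, d$z_um)
}

#' @rdname workbench-formats
#' @param contour A [contour_points()] object.
#' @export
write_contour_csv <- function(contour, path) {
  utils::write.csv(as.data.frame(.as_contour(contour)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname workbench-formats
#' @export
read_landmarks_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$h_um) || is.null(j$w_um))
    stop("landmarks JSON must supply h_um and w_um")
  has_R <- !is.null(j$R_um) && is.finite(j$R_um)
  landmark_set(h = j$h_um, w = j$w_um,
               R = if (has_R) j$R_um else NULL,
               V = if (!has_R) j$V_um3 else NULL,
               L = if (!is.null(j$L_um) && is.finite(j$L_um)) j$L_um else NULL)
}

#' @rdname workbench-formats
#' @param landmarks A [landmark_set()] object.
#' @export
write_landmarks_json <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  jsonlite::write_json(unclass(landmarks), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname workbench-formats
#' @export
read_angles_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!"alpha_deg" %in% names(d))
    stop("angle CSV must have a column alpha_deg")
  d$alpha_deg
}

#' @rdname workbench-formats
#' @export
read_dose_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("dose_uM", "response") %in% names(d)))
    stop("dose CSV must have columns dose_uM, response")
  d
}

#' Run configuration
#'
#' Physical and processing parameters shared by the pipeline stages.
#'
#' @param Mv_A_per_m Magnetization per unit volume (A/m).
#' @param gradB_T_per_m Field gradient (T/m).
#' @param B_T Field magnitude (T), informational.
#' @param pixel_size_um Pixel size for image inputs (um/pixel).
#' @param sigma_poisson Poisson ratio for the Hertz modulus. Default 0.5.
#' @param gamma_init_mN_per_m Initial tension guess of the capillary fit.
#' @param noise_bound_um Assumed landmark pointing error (um). Default 5.
#' @return Object of class `run_config`.
#' @export
run_config <- function(Mv_A_per_m, gradB_T_per_m, B_T = NA_real_,
                       pixel_size_um = 1, sigma_poisson = 0.5,
                       gamma_init_mN_per_m = 10, noise_bound_um = 5) {
  ctx <- magnetic_context(Mv_A_per_m, gradB_T_per_m, B_T)
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (gamma_init_mN_per_m <= 0) stop("gamma_init_mN_per_m must be positive")
  if (noise_bound_um < 0) stop("noise_bound_um must be >= 0")
  structure(list(
    Mv_A_per_m = Mv_A_per_m, gradB_T_per_m = gradB_T_per_m, B_T = B_T,
    pixel_size_um = pixel_size_um, sigma_poisson = sigma_poisson,
    gamma_init_mN_per_m = gamma_init_mN_per_m,
    noise_bound_um = noise_bound_um, ctx = ctx
  ), class = "run_config")
}

#' @rdname workbench-formats
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$Mv_A_per_m) || is.null(y$gradB_T_per_m))
    stop("config YAML must supply Mv_A_per_m and gradB_T_per_m")
  args <- y[intersect(names(y), names(formals(run_config)))]
  do.call(run_config, args)
}

#' @rdname workbench-formats
#' @param config A [run_config()] object.
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  y <- unclass(config)
  y$ctx <- NULL
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Extract profile landmarks from a closed contour
#'
#' Automated replacement for on-screen pointing: height is the z extent,
#' width the x extent, and the contact radius `L` the half-chord of the
#' run of points within a tolerance band of the substrate line (the maximum
#' z, since z increases downward toward the magnet).
#'
#' @param contour A [contour_points()] object (closed or near-closed,
#'   `N >= 10`).
#' @param substrate_tol_um Band half-width below the deepest point counted
#'   as substrate contact (um). Default 2.
#' @param R_um Optional initial radius to attach for the volume.
#' @return A [landmark_set()] (with `V` from `R_um` when given, else from
#'   the x-z extents assuming the contour bounds an undeformed-volume
#'   equivalent is not attempted — `R` is required downstream for fitting).
#'   The extraction tolerance is attached as attribute
#'   `substrate_tol_um`.
#' @export
landmarks_from_contour <- function(contour, substrate_tol_um = 2, R_um = NULL) {
  p <- .as_contour(contour)
  if (nrow(p) < 10L)
    stop("insufficient coverage: need at least 10 contour points")
  # angular coverage, measured about the best-fit circle center, must span
  # at least a half turn; an open arc shorter than that cannot bound h and w
  ctr <- tryCatch(fit_circle(p), error = function(e)
    stop("insufficient coverage: ", conditionMessage(e)))
  ang <- sort(atan2(p$z_um - ctr$cz_um, p$x_um - ctr$cx_um))
  gaps <- diff(c(ang, ang[1L] + 2 * pi))
  if (2 * pi - max(gaps) < pi)
    stop("insufficient coverage: open contour spans less than 180 degrees")
  h <- diff(range(p$z_um))
  w <- diff(range(p$x_um))
  zmax <- max(p$z_um)
  contact <- p$x_um[p$z_um >= zmax - substrate_tol_um]
  L <- diff(range(contact)) / 2
  lm <- landmark_set(h = min(h, w), w = w,
                     R = R_um, V = if (is.null(R_um)) 4 / 3 * pi * (w / 2)^2 * (h / 2) else NULL,
                     L = if (L > 0) L else NULL)
  attr(lm, "substrate_tol_um") <- substrate_tol_um
  lm
}

#' Extract a contour from a grayscale mask image (convenience plumbing)
#'
#' Optional image front-end replacing manual pointing: Otsu threshold,
#' largest connected component, boundary trace. Off the main path — all
#' core analyses consume contours or landmarks directly. Requires the
#' EBImage package.
#'
#' @param img Numeric matrix in `[0, 1]` (grayscale) or logical mask.
#' @param pixel_size_um Pixel size (um/pixel).
#' @return A [contour_points()] object in um.
#' @export
contour_from_mask <- function(img, pixel_size_um = 1) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("contour_from_mask requires the EBImage package")
  if (!is.matrix(img)) stop("img must be a matrix")
  m <- if (is.logical(img)) img * 1 else {
    thr <- EBImage::otsu(EBImage::Image(img))
    (img > thr) * 1
  }
  lab <- EBImage::bwlabel(EBImage::Image(m))
  tab <- table(as.integer(EBImage::imageData(lab)))
  tab <- tab[names(tab) != "0"]
  if (!length(tab)) stop("no foreground component found")
  keep <- as.integer(names(tab)[which.max(tab)])
  oc <- EBImage::ocontour(EBImage::Image((EBImage::imageData(lab) == keep) * 1))[[1L]]
  contour_points(oc[, 1L] * pixel_size_um, oc[, 2L] * pixel_size_um)
}

#' Run the tensiometry pipeline over a batch of spheroids
#'
#' For each record, fits the surface tension from the landmarks, computes
#' the Hertz modulus when a contact radius is present, and decomposes the
#' tension into cell-scale components when contact angles are supplied.
#' Per-spheroid failures are captured in the record, never fatal to the
#' batch.
#'
#' @param config A [run_config()].
#' @param inputs A list of input records; each a list with `landmarks` (a
#'   [landmark_set()]) and optionally `angles` (numeric degrees) and `id`.
#'   A `profile_fixture` or a fixture directory path is also accepted per
#'   record.
#' @return Object of class `pipeline_result`: `records` (one per input,
#'   each with `gamma_mN_per_m`, `c_per_m2`, `E_Pa`, `residual`,
#'   `warnings`, possibly `T_CM_mN_per_m`/`T_CC_eff_mN_per_m`, or `error`),
#'   `summary` (min/median/max of gamma and E over successful records),
#'   and `provenance` (config echo + package version).
#' @export
run_pipeline <- function(config, inputs) {
  stopifnot(inherits(config, "run_config"))
  if (!is.list(inputs) || length(inputs) == 0L)
    stop("empty input set: nothing to analyse")
  records <- lapply(seq_along(inputs), function(i) {
    rec <- inputs[[i]]
    out <- list(id = if (is.character(rec)) rec
                else if (!is.null(rec$id)) rec$id else i)
    tryCatch({
      if (is.character(rec)) rec <- read_fixture_dir(rec)
      if (inherits(rec, "profile_fixture")) rec <- list(landmarks = rec$landmarks)
      lm <- rec$landmarks
      if (is.null(lm)) stop("record has no landmarks")
      fit <- fit_capillary(lm, config$ctx,
                           gamma_init = config$gamma_init_mN_per_m,
                           noise_bound_um = config$noise_bound_um)
      out$gamma_mN_per_m <- fit$gamma
      out$c_per_m2 <- fit$c
      out$residual <- fit$residual
      out$warnings <- fit$warnings
      if (is.finite(lm$L_um) && is.finite(lm$R_um)) {
        el <- young_modulus(lm$R_um, lm$L_um, config$ctx,
                            sigma = config$sigma_poisson, w_um = lm$w_um)
        out$E_Pa <- el$E
      } else out$E_Pa <- NA_real_
      if (!is.null(rec$angles)) {
        ang <- summarize_angles(rec$angles)
        dt <- decompose_tensions(fit$gamma, ang$mean_alpha)
        out$T_CM_mN_per_m <- dt$T_CM
        out$T_CC_eff_mN_per_m <- dt$T_CC_eff
        out$mean_alpha_deg <- ang$mean_alpha
        out$sd_alpha_deg <- ang$sd_alpha
        out$n_angles <- ang$n
      }
      out
    }, error = function(e) {
      out$error <- conditionMessage(e)
      out
    })
  })
  ok <- Filter(function(r) is.null(r$error), records)
  gam <- vapply(ok, function(r) r$gamma_mN_per_m, numeric(1))
  Es <- vapply(ok, function(r) r$E_Pa, numeric(1))
  summ <- list(
    n = length(records), n_ok = length(ok),
    gamma_mN_per_m = if (length(gam)) list(min = min(gam), median = stats::median(gam),
                                           max = max(gam)) else NULL,
    E_Pa = if (any(is.finite(Es))) list(min = min(Es, na.rm = TRUE),
                                        median = stats::median(Es, na.rm = TRUE),
                                        max = max(Es, na.rm = TRUE)) else NULL)
  structure(list(records = records, summary = summ,
                 provenance = list(
                   package = "magtensio",
                   version = as.character(utils::packageVersion("magtensio")),
                   config = unclass(config)[setdiff(names(config), "ctx")])),
            class = "pipeline_result")
}

#' @rdname workbench-formats
#' @param result A `pipeline_result`.
#' @export
write_results_json <- function(result, path) {
  stopifnot(inherits(result, "pipeline_result"))
  jsonlite::write_json(list(schema = "magtensio/results/v1",
                            records = result$records,
                            summary = result$summary,
                            provenance = result$provenance),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Tensiometry pipeline: %d spheroids (%d analysed)\n",
              x$summary$n, x$summary$n_ok))
  g <- x$summary$gamma_mN_per_m
  if (!is.null(g))
    cat(sprintf("  gamma (mN/m): min %.3g / median %.3g / max %.3g\n",
                g$min, g$median, g$max))
  e <- x$summary$E_Pa
  if (!is.null(e))
    cat(sprintf("  E (Pa):       min %.3g / median %.3g / max %.3g\n",
                e$min, e$median, e$max))
  invisible(x)
}
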