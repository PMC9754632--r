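test_that("landmarks extracted from a circle contour describe an undeformed sphere", {
  th <- seq(0, 2 * pi, length.out = 201)[-201]
  ct <- contour_points(500 * cos(th), 500 * sin(th))
  lm <- landmarks_from_contour(ct, R_um = 500)
  expect_equal(lm$h_um, 1000, tolerance = 1e-6)
  expect_equal(lm$w_um, 1000, tolerance = 1e-6)
  expect_lt(ifelse(is.finite(lm$L_um), lm$L_um, 0), 100)  # near-point contact
})

test_that("landmarks from a forward-model contour match the profile metrics", {
  fx <- make_profile_dataset(fixture_config(seed = 1, pointing_noise = 0),
                             n_points = 2000)
  lm <- landmarks_from_contour(fx$contour, R_um = 530)
  expect_equal(lm$h_um, fx$truth$h_um, tolerance = 1e-3)
  expect_equal(lm$w_um, fx$truth$w_um, tolerance = 1e-3)
  # contact half-chord approximates the model contact radius to the
  # substrate band tolerance
  expect_lt(abs(lm$L_um - fx$truth$w_um / 2) / (fx$truth$w_um / 2), 1)
})

test_that("sparse or open contours are refused", {
  expect_error(landmarks_from_contour(contour_points(1:5, 1:5 * 2)),
               "insufficient coverage")
  th <- seq(0, pi / 4, length.out = 50)  # quarter arc: < 180 deg coverage
  expect_error(landmarks_from_contour(contour_points(cos(th), sin(th))),
               "insufficient coverage")
})

test_that("the mask extractor traces a synthetic disk to its known radius", {
  skip_if_not_installed("EBImage")
  n <- 101
  xy <- expand.grid(i = 1:n, j = 1:n)
  disk <- matrix(as.numeric((xy$i - 51)^2 + (xy$j - 51)^2 <= 30^2), n, n)
  ct <- contour_from_mask(disk, pixel_size_um = 2)
  f <- fit_circle(ct)
  expect_equal(f$r_um, 30 * 2, tolerance = 0.05)
  lm <- landmarks_from_contour(ct, R_um = 60)
  expect_equal(lm$w_um, 120, tolerance = 0.05)
})

test_that("file formats round-trip to 12 significant digits", {
  dir <- withr::local_tempdir()
  lm <- landmark_set(h = 843.4013579246, w = 1142.9351234567, R = 530,
                     L = 429.2987654321)
  p <- file.path(dir, "lm.json")
  write_landmarks_json(lm, p)
  back <- read_landmarks_json(p)
  expect_equal(back$h_um, lm$h_um, tolerance = 1e-12)
  expect_equal(back$L_um, lm$L_um, tolerance = 1e-12)

  ct <- contour_points(c(1.123456789012, 2), c(3, 4.987654321098))
  pc <- file.path(dir, "ct.csv")
  write_contour_csv(ct, pc)
  expect_equal(read_contour_csv(pc)$x_um, ct$x_um, tolerance = 1e-12)

  cfg <- run_config(Mv_A_per_m = 250, gradB_T_per_m = 170, B_T = 0.53,
                    gamma_init_mN_per_m = 12.5)
  py <- file.path(dir, "cfg.yaml")
  write_config_yaml(cfg, py)
  cfg2 <- read_config_yaml(py)
  expect_equal(cfg2$Mv_A_per_m, cfg$Mv_A_per_m)
  expect_equal(cfg2$gamma_init_mN_per_m, cfg$gamma_init_mN_per_m)
  expect_equal(cfg2$ctx$f, cfg$ctx$f)
})

test_that("the pipeline analyses a batch of 8 fixtures against embedded truth", {
  cfg <- run_config(Mv_A_per_m = 250, gradB_T_per_m = 170)
  fixtures <- lapply(1:8, function(s)
    make_profile_dataset(fixture_config(seed = s)))
  res <- run_pipeline(cfg, fixtures)
  expect_length(res$records, 8)
  expect_equal(res$summary$n_ok, 8)
  for (i in 1:8) {
    rec <- res$records[[i]]
    truth <- fixtures[[i]]$truth
    expect_lt(abs(rec$gamma_mN_per_m - truth$gamma) / truth$gamma, 0.25)
    expect_lt(abs(rec$E_Pa - truth$E) / truth$E, 0.25)
  }
  expect_true(all(c("min", "median", "max") %in%
                    names(res$summary$gamma_mN_per_m)))
  # results serialize to JSON
  dir <- withr::local_tempdir()
  pr <- file.path(dir, "results.json")
  write_results_json(res, pr)
  j <- jsonlite::read_json(pr, simplifyVector = TRUE)
  expect_equal(j$summary$n_ok, 8)
})

test_that("per-spheroid failures are recorded without aborting the batch", {
  cfg <- run_config(Mv_A_per_m = 250, gradB_T_per_m = 170)
  good <- make_profile_dataset(fixture_config(seed = 1))
  bad <- list(landmarks = landmark_set(h = 1060, w = 1060, R = 530))
  res <- run_pipeline(cfg, list(good, bad))
  expect_equal(res$summary$n_ok, 1)
  expect_match(res$records[[2]]$error, "out of measurable range")
  expect_error(run_pipeline(cfg, list()), "empty input set")
})

test_that("tension decomposition joins the pipeline when angles are present", {
  cfg <- run_config(Mv_A_per_m = 250, gradB_T_per_m = 170)
  fx <- make_profile_dataset(fixture_config(seed = 2))
  rec <- list(landmarks = fx$landmarks, angles = c(150, 160, 170, 155))
  res <- run_pipeline(cfg, list(rec))
  r <- res$records[[1]]
  expect_equal(r$mean_alpha_deg, mean(c(150, 160, 170, 155)))
  expect_equal(r$T_CM_mN_per_m - r$T_CC_eff_mN_per_m / 2, r$gamma_mN_per_m,
               tolerance = 1e-9)
})
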