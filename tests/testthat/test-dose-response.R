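truth_params <- list(Top = 21, Bottom = 2, IC50 = 10, HillSlope = -1)

test_that("hill_eval matches hand-computed values and limits", {
  p <- list(Top = 22, Bottom = 2, IC50 = 10, HillSlope = 1)
  expect_equal(hill_eval(30, p), 17)               # 2 + 20/(1 + 1/3)
  expect_equal(hill_eval(10, p), 12)               # midpoint at X = IC50
  expect_equal(hill_eval(p$IC50, truth_params),
               (truth_params$Top + truth_params$Bottom) / 2)
  expect_equal(hill_eval(0, p), p$Bottom)          # X = 0 limit, slope > 0
  expect_equal(hill_eval(0, truth_params), truth_params$Top)  # slope < 0
  expect_equal(hill_eval(1e12, p), p$Top, tolerance = 1e-9)   # asymptote
  expect_error(hill_eval(10, list(Top = 1, Bottom = 0, IC50 = 10,
                                  HillSlope = 0)), "HillSlope")
  expect_error(hill_eval(-1, p), ">= 0")
})

test_that("hill_eval is monotone in dose", {
  X <- c(0.01, 0.1, 1, 10, 100, 1000)
  expect_true(all(diff(hill_eval(X, truth_params)) < 0))   # inhibition
  inc <- list(Top = 21, Bottom = 2, IC50 = 10, HillSlope = 1)
  expect_true(all(diff(hill_eval(X, inc)) > 0))
})

test_that("noise-free data recover the generating parameters", {
  d <- rep(c(0.5, 1, 3, 10, 30, 80, 160), each = 2)
  fit <- fit_hill(d, hill_eval(d, truth_params))
  expect_equal(fit$Top, truth_params$Top, tolerance = 1e-6)
  expect_equal(fit$Bottom, truth_params$Bottom, tolerance = 1e-6)
  expect_equal(fit$IC50, truth_params$IC50, tolerance = 1e-6)
  expect_equal(fit$HillSlope, truth_params$HillSlope, tolerance = 1e-6)
})

test_that("zero-dose points are included via the analytic limit", {
  d <- c(0, 1, 3, 10, 30, 80, 160)
  fit <- fit_hill(d, hill_eval(d, truth_params))
  expect_equal(fit$IC50, truth_params$IC50, tolerance = 1e-6)
})

test_that("the fit is invariant to pair order and returns the canonical gauge", {
  cfg <- fixture_config(seed = 21)
  tab <- make_dose_dataset(cfg)
  f1 <- fit_hill(tab$dose_uM, tab$response)
  idx <- sample(nrow(tab))
  f2 <- fit_hill(tab$dose_uM[idx], tab$response[idx])
  expect_equal(f1$IC50, f2$IC50, tolerance = 1e-8)
  expect_gte(f1$Top, f1$Bottom)  # canonical parameterization
  # the mirrored gauge describes the identical curve
  X <- c(0.5, 2, 10, 50, 150)
  mirrored <- list(Top = f1$Bottom, Bottom = f1$Top, IC50 = f1$IC50,
                   HillSlope = -f1$HillSlope)
  expect_equal(hill_eval(X, mirrored), hill_eval(X, f1), tolerance = 1e-12)
})

test_that("median IC50 bias stays below 10% over noisy replicates", {
  ic50 <- vapply(1:60, function(s) {
    tab <- make_dose_dataset(fixture_config(seed = s))
    fit_hill(tab$dose_uM, tab$response)$IC50
  }, numeric(1))
  expect_lt(abs(stats::median(ic50) - truth_params$IC50) / truth_params$IC50,
            0.10)
})

test_that("bootstrap percentiles bracket the IC50 on replicated designs", {
  tab <- make_dose_dataset(fixture_config(seed = 8))
  set.seed(1)
  fit <- fit_hill(tab$dose_uM, tab$response, n_boot = 60)
  expect_length(fit$IC50_boot, 60)
  expect_lt(fit$IC50_ci[1], fit$IC50)
  expect_gt(fit$IC50_ci[2], fit$IC50)
  expect_lt(fit$IC50_ci[1], 10)   # interval covers the generating value
  expect_gt(fit$IC50_ci[2], 10)
})

test_that("degenerate designs are refused", {
  expect_error(fit_hill(c(1, 2, 3), c(1, 2, 3)), "4 distinct doses")
  expect_error(fit_hill(c(1, 1, 2, 2, 3, 3), c(1, 1, 2, 2, 3, 3)),
               "4 distinct doses")
  expect_error(fit_hill(c(1, 2, 3, 4, 5), rep(7, 5)), "unidentifiable")
})

test_that("racemic-to-active IC50 conversion is a plain rescaling", {
  expect_equal(active_ic50(10, 0.6), 6)
  expect_equal(active_ic50(7, 0.57), 3.99)
  expect_equal(active_ic50(12.3, 1), 12.3)
  expect_error(active_ic50(10, 0), "active_fraction")
  expect_error(active_ic50(10, 1.2), "active_fraction")
  expect_error(active_ic50(-1, 0.5), "ic50_racemic")
})
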