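test_that("force density is Mv * grad(B) and rejects invalid contexts", {
  expect_equal(force_density(magnetic_context(500, 170)), 8.5e4)
  expect_equal(force_density(magnetic_context(250, 170)), 4.25e4)
  expect_equal(force_density(magnetic_context(150, 170)), 2.55e4)
  expect_error(magnetic_context(0, 170), "invalid magnetic context")
  expect_error(magnetic_context(250, -1), "invalid magnetic context")
  expect_error(magnetic_context(NA, 170), "invalid magnetic context")
})

test_that("zero body force reproduces a sphere to 1e-6 relative", {
  R <- ref_R_m
  sol <- integrate_profile(shape_params(c = 0, b = 1 / R))
  m <- profile_metrics(sol)
  expect_equal(m$h, 2 * R, tolerance = 1e-6)
  expect_equal(m$w, 2 * R, tolerance = 1e-6)
  expect_equal(m$V, 4 / 3 * pi * R^3, tolerance = 1e-6)
  # sphere closure: h = w and V = (pi/6) h^3
  expect_equal(m$V, pi / 6 * m$h^3, tolerance = 1e-6)
  expect_lt(m$L_model, 1e-3 * R)  # point contact
})

test_that("solution geometry satisfies the stated profile invariants", {
  sol <- integrate_profile(shape_params(c = 2e6, b = 2000))
  expect_equal(sol$x[1], 0)
  expect_equal(sol$z[1], 0)
  expect_equal(sol$phi[1], 0)
  expect_true(all(diff(sol$phi) > 0))            # phi strictly increasing
  expect_true(all(diff(sol$z) >= 0))             # z non-decreasing
  expect_true(all(sol$x >= 0))
  expect_equal(sol$phi[length(sol$phi)], pi, tolerance = 1e-12)
  expect_equal(sol$z[length(sol$z)], sol$h)
  m <- profile_metrics(sol)
  expect_gte(m$w, 2 * m$L_model)                 # max x dominates final x
  expect_lt(m$h, m$w)                            # flattened
})

test_that("pointwise Laplace curvature balance holds along the profile", {
  sol <- integrate_profile(shape_params(c = 2e6, b = 2000))
  expect_lt(laplace_residual(sol), 1e-5)
  # residual shrinks with the step (finite-difference check is 2nd order)
  sol2 <- integrate_profile(shape_params(c = 2e6, b = 2000, step = 5e-4))
  expect_lt(laplace_residual(sol2), laplace_residual(sol))
})

test_that("metrics converge at the integrator's 4th order under step halving", {
  m <- lapply(c(2e-2, 1e-2, 5e-3), function(st)
    integrate_profile(shape_params(2e6, 2000, st), keep_path = FALSE))
  for (f in c("h", "w", "V")) {
    r <- (m[[1]][[f]] - m[[2]][[f]]) / (m[[2]][[f]] - m[[3]][[f]])
    expect_gt(r, 8)   # a 4th-order scheme gives ~16; allow headroom
    expect_lt(r, 32)
  }
  # at the default step the metrics are already converged far below 1e-6
  f1 <- integrate_profile(shape_params(2e6, 2000, 1e-3), keep_path = FALSE)
  f2 <- integrate_profile(shape_params(2e6, 2000, 5e-4), keep_path = FALSE)
  for (f in c("h", "w", "V"))
    expect_lt(abs(f1[[f]] - f2[[f]]) / abs(f2[[f]]), 1e-9)
})

test_that("independent stiff-solver integration reproduces the profile metrics", {
  skip_if_not_installed("deSolve")
  b <- 2000; cc <- 2e6
  rhs <- function(s, y, p) {
    sphi <- sin(y[3])
    list(c(cos(y[3]), sphi, (2 * b + cc * y[2]) - sphi / y[1],
           pi * y[1]^2 * sphi))
  }
  s0 <- 1e-9
  y0 <- c(x = s0, z = b * s0^2 / 2, phi = b * s0, V = 0)
  out <- deSolve::lsodar(y = y0, times = c(s0, 1), func = rhs,
                         rootfunc = function(s, y, p) y[3] - pi,
                         rtol = 1e-10, atol = 1e-14)
  end <- out[nrow(out), ]
  mine <- integrate_profile(shape_params(cc, b), keep_path = FALSE)
  expect_equal(unname(end[["z"]]), mine$h, tolerance = 1e-7)
  expect_equal(unname(end[["V"]]), mine$V, tolerance = 1e-7)
  expect_equal(unname(end[["x"]]), mine$L_model, tolerance = 1e-6)
})

test_that("volume solve hits the target volume and flattens the sphere", {
  sol0 <- solve_shape_for_volume(c = 0, V_target = ref_V_m3, keep_path = FALSE)
  expect_equal(sol0$params$b, 1 / ref_R_m, tolerance = 1e-5)
  cc <- 2.024e6
  sol <- solve_shape_for_volume(cc, ref_V_m3, keep_path = FALSE)
  expect_lt(abs(sol$V - ref_V_m3) / ref_V_m3, 1e-6)
  expect_lt(sol$h, 2 * ref_R_m)  # strictly flattened vs the c = 0 sphere
})

test_that("h decreases and w increases with the capillary parameter at fixed volume", {
  grid <- c(0, 1e5, 1e6, 1e7)
  sols <- lapply(grid, solve_shape_for_volume, V_target = ref_V_m3,
                 keep_path = FALSE)
  h <- vapply(sols, `[[`, numeric(1), "h")
  w <- vapply(sols, `[[`, numeric(1), "w")
  expect_true(all(diff(h) < 0))
  expect_true(all(diff(w) > 0))
})

test_that("large drops approach the non-wetting puddle height 2/sqrt(c)", {
  cc <- 1e6
  V <- ref_V_m3 * 1000  # Bond ~ 28, already in the puddle regime
  sol <- solve_shape_for_volume(cc, V, keep_path = FALSE)
  expect_equal(sol$h, 2 / sqrt(cc), tolerance = 0.05)
  # closer to the asymptote at larger Bond
  sol2 <- solve_shape_for_volume(cc, V * 10, keep_path = FALSE)
  expect_lt(abs(sol2$h - 2 / sqrt(cc)), abs(sol$h - 2 / sqrt(cc)))
})

test_that("solutions are scale invariant: lengths x lambda, c / lambda^2", {
  lam <- 3.7
  a <- integrate_profile(shape_params(2e6, 2000), keep_path = FALSE)
  b <- integrate_profile(shape_params(2e6 / lam^2, 2000 / lam),
                         keep_path = FALSE)
  expect_equal(b$h, a$h * lam, tolerance = 1e-10)
  expect_equal(b$w, a$w * lam, tolerance = 1e-10)
  expect_equal(b$V, a$V * lam^3, tolerance = 1e-10)
})

test_that("invalid shape parameters and unterminated profiles are rejected", {
  expect_error(shape_params(c = -1, b = 100), "c must be")
  expect_error(shape_params(c = 1, b = 0), "b must be")
  expect_error(shape_params(c = 1, b = 100, step = 0.5), "step too large")
  expect_error(integrate_profile(shape_params(2e6, 2000), s_max = 0.1),
               "never reached")
  sol <- integrate_profile(shape_params(2e6, 2000), keep_path = FALSE)
  expect_error(laplace_residual(sol), "keep_path")
})
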