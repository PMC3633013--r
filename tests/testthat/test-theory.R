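test_that("motility coefficient reproduces the published values", {
  # M = (v t_free)^2 / (6 (t_free + t_pause)) against printed two-decimal M
  expect_equal(motility_coefficient(model_params(0.5, 2.0, 18.8)), 94.25,
               tolerance = 0.005 / 94.25)
  expect_equal(motility_coefficient(model_params(0.5, 2.5, 16.6)), 95.68,
               tolerance = 0.005 / 95.68)
  expect_equal(motility_coefficient(model_params(0.25, 2.0, 17.6)), 91.78,
               tolerance = 0.005 / 91.78)
  expect_equal(motility_coefficient(model_params(0.75, 1.5, 23.8)), 94.41,
               tolerance = 0.005 / 94.41)
  # the M-degenerate companion triplet, identical up to rounding
  expect_equal(motility_coefficient(degenerate_twin()),
               motility_coefficient(best_fit()), tolerance = 3e-4)
  # ideal-chain limit t_pause = 0: M = v^2 t_free / 6
  expect_equal(motility_coefficient(model_params(0, 3, 10)), 100 * 3 / 6)
})

test_that("single-particle square displacement is flat in pauses, quadratic in runs", {
  p <- best_fit()
  M <- motility_coefficient(p)
  # tau inside the pause: no growth beyond the completed cycles
  expect_equal(msd_single(2 * p$t_run, 0.3, p), 2 * M * 2 * p$t_run)
  expect_equal(msd_single(0, 0.5, p), 0)
  # one minute into a run: (v^2/3) * 1^2
  expect_equal(msd_single(0, p$t_pause + 1, p), 18.8^2 / 3)
  # approaching a full cycle recovers 2 M t_run (continuity across cycles)
  expect_equal(msd_single(0, p$t_run - 1e-9, p), 2 * M * p$t_run,
               tolerance = 1e-6)
  # dims scaling and the domain checks
  expect_equal(msd_single(p$t_run, 0, p, dims = 3),
               3 * msd_single(p$t_run, 0, p))
  expect_error(msd_single(1.3, 0, p), "multiple")
  expect_error(msd_single(p$t_run, p$t_run, p), "tau")
})

test_that("ensemble MSD follows the phase-averaged closed form", {
  p <- best_fit()
  M <- motility_coefficient(p)   # (18.8 * 2)^2 / 15
  expect_equal(msd_ensemble(0, p), 0)
  # linear branch: 2 M t - 2 M t_free / 3
  expect_equal(msd_ensemble(60, p), 2 * M * 60 - 2 * M * 2 / 3)
  # cubic branch at t = 1 (< t_free): u = 1/2
  u <- 0.5
  expect_equal(msd_ensemble(1, p),
               2 * M * 1 - 2 * M * 2 * (u^3 / 3 - u^2 + u))
  expect_equal(msd_ensemble(1, p), 78.54, tolerance = 1e-4)
  # continuity at the branch point and zero slope at zero
  expect_equal(msd_ensemble(p$t_free, p),
               2 * M * p$t_free - 2 * M * p$t_free / 3, tolerance = 1e-9)
  eps <- 1e-6
  expect_lt(msd_ensemble(eps, p) / eps, 1e-3)  # slope -> 0 at t = 0
  expect_equal(msd_ensemble(10, p, dims = 3), 3 * msd_ensemble(10, p))
  expect_error(msd_ensemble(-1, p), ">= 0")
})

test_that("linear MSD coefficients have two degrees of freedom", {
  p <- best_fit()
  co <- msd_linear_coeffs(p)
  expect_equal(unname(co["alpha"]), 188.5, tolerance = 1e-4)
  expect_equal(unname(co["beta"]), -125.67, tolerance = 1e-4)
  # beta/alpha = -t_free/3 identically
  for (pp in list(model_params(0, 1, 10), model_params(1.5, 2, 18.8),
                  model_params(0.75, 1.5, 23.8))) {
    co2 <- msd_linear_coeffs(pp)
    expect_equal(unname(co2["beta"] / co2["alpha"]), -pp$t_free / 3)
  }
  # doubling t_pause while rescaling v_free to keep M leaves (alpha, beta)
  p2 <- model_params(2 * p$t_pause, p$t_free,
                     p$v_free * sqrt((p$t_free + 2 * p$t_pause) /
                                       (p$t_free + p$t_pause)))
  expect_equal(motility_coefficient(p2), motility_coefficient(p))
  expect_equal(msd_linear_coeffs(p2), co)
})

test_that("squared confinement ratio matches its closed form and limits", {
  p0 <- model_params(0, 2, 18.8)
  expect_equal(sq_confinement(0, p0), 1 / 3)
  expect_equal(sq_confinement(p0$t_free, p0), 2 / 9)
  expect_lt(sq_confinement(1e6, p0), 1e-5)
  # monotonically non-increasing
  tt <- seq(0, 20, by = 0.1)
  expect_true(all(diff(sq_confinement(tt, p0)) <= 1e-12))
  # consistency with Def: E[D^2]/(t^2 v^2) (independent route via MSD)
  for (t in c(0.5, 1, 2, 5, 30))
    expect_equal(sq_confinement(t, p0),
                 msd_ensemble(t, p0) / (t^2 * p0$v_free^2),
                 tolerance = 1e-12)
  # nonzero pause refused unless explicitly allowed
  expect_error(sq_confinement(1, best_fit()), "t_pause")
  expect_equal(sq_confinement(1, best_fit(), allow_pause = TRUE),
               msd_ensemble(1, best_fit()) / (1 * 18.8^2))
})

test_that("normalized squared confinement converges to t_free/3", {
  p0 <- model_params(0, 2, 18.8)
  expect_equal(normalized_sq_confinement(1e7, p0), 2 / 3, tolerance = 1e-6)
  expect_equal(normalized_sq_confinement(p0$t_free, p0), 2 * (2 / 9))
  # t >= t_free branch: t_free (3t - t_free) / (9t), increasing in t
  tt <- seq(p0$t_free, 100, by = 0.5)
  v <- normalized_sq_confinement(tt, p0)
  expect_equal(v, p0$t_free * (3 * tt - p0$t_free) / (9 * tt))
  expect_true(all(diff(v) > 0))
  expect_error(normalized_sq_confinement(0, p0), "> 0")
})

test_that("convection speeds follow the four taxis modes", {
  p <- best_fit()
  for (md in c("none", "simple", "orthotaxis", "topotaxis", "klinotaxis"))
    expect_equal(convection_speed(md, 0, p), 0)
  expect_equal(convection_speed("orthotaxis", 1, p), 18.8 * 2 / (3 * 2.5))
  expect_equal(convection_speed("orthotaxis", 1, p), 5.013, tolerance = 1e-4)
  # topotaxis and klinotaxis give exactly the orthotaxis speed
  expect_equal(convection_speed("topotaxis", 0.6, p),
               convection_speed("orthotaxis", 0.6, p))
  expect_equal(convection_speed("klinotaxis", 0.6, p),
               convection_speed("orthotaxis", 0.6, p))
  # simple mode: drift distance per cycle over cycle time
  expect_equal(convection_speed("simple", 1, p), 18.8 * 0.5 / 2.5)
  expect_equal(convection_speed("simple", 1, p), 3.76)
  expect_error(convection_speed("chemotaxis", 1, p), "unknown")
})

test_that("Fuerth's equation has the right limits", {
  expect_equal(furth_msd(0, 94.25, 1), 0)
  expect_equal(furth_msd(10, 94.25, 0), 2 * 94.25 * 10)
  expect_equal(furth_msd(1, 94.25, 1), 2 * 94.25 * exp(-1))
  tt <- c(0.1, 1, 10, 100)
  expect_equal(furth_msd(tt, 50, 1e-9), 2 * 50 * tt, tolerance = 1e-6)
  expect_error(furth_msd(-1, 1, 1), ">= 0")
})

test_that("the Gaussian density solves the convection-diffusion equation", {
  M <- 94.25; C <- 3; t <- 10
  f <- function(x) gaussian_density(x, t, C, M)
  expect_equal(stats::integrate(f, -Inf, Inf)$value, 1, tolerance = 1e-6)
  expect_equal(stats::integrate(function(x) x * f(x), -Inf, Inf)$value,
               C * t, tolerance = 1e-6)
  expect_equal(stats::integrate(function(x) (x - C * t)^2 * f(x),
                                -Inf, Inf)$value, 2 * M * t,
               tolerance = 1e-5)
  # finite-difference residual of dphi/dt + C dphi/dx - M d2phi/dx2
  h <- 0.05; k <- 0.05
  for (x in c(-20, 0, 30, 80)) {
    dpdt <- (gaussian_density(x, t + k, C, M) -
               gaussian_density(x, t - k, C, M)) / (2 * k)
    dpdx <- (gaussian_density(x + h, t, C, M) -
               gaussian_density(x - h, t, C, M)) / (2 * h)
    d2pdx2 <- (gaussian_density(x + h, t, C, M) - 2 * f(x) +
                 gaussian_density(x - h, t, C, M)) / h^2
    # residual small relative to the ~1e-4 scale of the time derivative
    expect_lt(abs(dpdt - (-C * dpdx + M * d2pdx2)), 1e-6)
  }
  expect_error(gaussian_density(0, 0, C, M), "> 0")
})
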