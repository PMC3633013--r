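test_that("phase initialization is synchronized or uniform over the cycle", {
  p <- best_fit()
  expect_equal(init_phase(p, "synchronized")$tau0, 0)
  set.seed(11)
  tau <- replicate(2e4, init_phase(p, "stationary")$tau0)
  expect_true(all(tau >= 0 & tau < p$t_run))
  # P(initially pausing) = t_pause / t_run = 0.2
  frac <- mean(tau < p$t_pause)
  expect_lt(abs(frac - 0.2), 4 * sqrt(0.2 * 0.8 / 2e4))
  expect_gt(stats::ks.test(tau, "punif", 0, p$t_run)$p.value, 0.001)
  # no pause phase when t_pause = 0
  tau0 <- replicate(200, init_phase(model_params(0, 2, 18.8),
                                    "stationary")$tau0)
  expect_true(all(tau0 >= 0))
  expect_false(any(tau0 < 0))
})

test_that("simulate_track validates inputs and handles degenerate cases", {
  p <- best_fit()
  expect_error(simulate_track(p, duration = 0, sample_dt = 1), "duration")
  expect_error(simulate_track(p, duration = 10, sample_dt = 0), "sample_dt")
  expect_error(simulate_track(p, duration = 10, sample_dt = 20), "sample_dt")
  # synchronized cell pauses first: observing only the pause stays at origin
  set.seed(5)
  tr <- simulate_track(p, duration = p$t_pause, sample_dt = p$t_pause,
                       phase = "synchronized")
  expect_equal(as.numeric(unlist(tr[c("x", "y", "z")])), rep(0, 6))
  # zero speed (non-simple taxis) gives a constant track
  tr0 <- simulate_track(model_params(0.5, 2, 0),
                        taxis_spec("orthotaxis", 0.5), duration = 10,
                        sample_dt = 1, phase = "stationary")
  expect_true(all(tr0$x == 0 & tr0$y == 0 & tr0$z == 0))
  expect_equal(tr0$t, 0:10)
})

test_that("one synchronized cycle travels exactly the step radius", {
  p <- best_fit()
  ts <- simulate_ensemble(500, p, duration = p$t_run, sample_dt = p$t_run,
                          phase = "synchronized", seed = 8)
  m <- as.data.frame(ts)[as.data.frame(ts)$t == p$t_run, ]
  r <- sqrt(m$x^2 + m$y^2 + m$z^2)
  # a single straight run of length v_free * t_free
  expect_equal(r, rep(p$r, nrow(m)), tolerance = 1e-9)
})

test_that("ensembles are reproducible and extendable by track index", {
  p <- best_fit()
  a <- simulate_ensemble(4, p, duration = 6, sample_dt = 1, seed = 99)
  b <- simulate_ensemble(4, p, duration = 6, sample_dt = 1, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # per-track substreams: the first tracks do not depend on n
  c6 <- simulate_ensemble(6, p, duration = 6, sample_dt = 1, seed = 99)
  expect_equal(as.data.frame(c6)[c6$track_id <= 4, ], as.data.frame(a),
               ignore_attr = TRUE)
  # a different seed gives different tracks
  d <- simulate_ensemble(4, p, duration = 6, sample_dt = 1, seed = 100)
  expect_false(identical(as.data.frame(a), as.data.frame(d)))
  # the caller's RNG state is untouched
  set.seed(1); x1 <- rnorm(1)
  set.seed(1); invisible(simulate_ensemble(2, p, duration = 3,
                                           sample_dt = 1, seed = 7))
  expect_identical(rnorm(1), x1)
})

test_that("synchronized and stationary phases give the published variance shapes", {
  p <- best_fit()
  M <- motility_coefficient(p)
  # synchronized: per-dimension variance at t_run is (v t_free)^2/3 = 2M t_run
  ts <- simulate_ensemble(5000, p, duration = p$t_run, sample_dt = p$t_run,
                          phase = "synchronized", seed = 31)
  m <- as.data.frame(ts)[as.data.frame(ts)$t == p$t_run, ]
  vtheory <- (p$v_free * p$t_free)^2 / 3
  for (v in list(m$x, m$y, m$z))
    expect_lt(abs(var(v) - vtheory), 4 * vtheory * sqrt(2 / (nrow(m) - 1)))
  # stationary: ensemble MSD matches the smooth phase-averaged curve
  ts2 <- simulate_ensemble(5000, p, duration = 20, sample_dt = 1,
                           phase = "stationary", seed = 32)
  cv <- mean_square_displacement(ts2, "x")
  z <- (cv$estimate - msd_ensemble(cv$t, p)) / cv$se
  expect_true(all(abs(z[cv$t > 0]) < 4))
})

test_that("long-time displacement is Gaussian with variance from the theory", {
  p <- best_fit()
  t_end <- 100 * p$t_run
  ts <- simulate_ensemble(2000, p, duration = t_end, sample_dt = t_end,
                          phase = "stationary", seed = 41)
  m <- as.data.frame(ts)[as.data.frame(ts)$t == t_end, ]
  sd_th <- sqrt(msd_ensemble(t_end, p))
  expect_gt(stats::ks.test(m$x, "pnorm", 0, sd_th)$p.value, 0.001)
  # same histogram matches the convection-diffusion Gaussian with C = 0
  expect_gt(stats::ks.test(m$y / sd_th, "pnorm")$p.value, 0.001)
})

test_that("unbiased displacements are isotropic and uncorrelated", {
  p <- best_fit()
  ts <- simulate_ensemble(4000, p, duration = 20, sample_dt = 10,
                          phase = "stationary", seed = 55)
  dc <- displacement_covariance(ts, 20)
  vth <- msd_ensemble(20, p)
  for (k in 1:3) expect_lt(abs(dc$cov[k, k] - vth), 4 * dc$se[k, k])
  for (k in 1:2) for (l in (k + 1):3)
    expect_lt(abs(dc$cov[k, l]), 4 * dc$se[k, l])
})

test_that("each taxis mode drifts at its closed-form convection speed", {
  p <- best_fit()
  for (md in c("simple", "orthotaxis", "topotaxis", "klinotaxis")) {
    tx <- taxis_spec(md, p = 0.8, b = c(0, 0, 1))
    cs <- convection_speed(md, 0.8, p)
    ts <- simulate_ensemble(1500, p, tx, duration = 60, sample_dt = 30,
                            phase = "stationary", seed = 60)
    m <- as.data.frame(ts)[as.data.frame(ts)$t == 60, ]
    se <- sd(m$z) / sqrt(nrow(m))
    expect_lt(abs(mean(m$z) - cs * 60), 4 * se)
    # no drift perpendicular to the bias
    expect_lt(abs(mean(m$x)), 4 * sd(m$x) / sqrt(nrow(m)))
  }
})

test_that("simple-mode taxis changes the mean but not the variance", {
  p <- best_fit()
  tx <- taxis_spec("simple", p = 1, b = c(1, 0, 0))
  ts <- simulate_ensemble(4000, p, tx, duration = 20, sample_dt = 20,
                          phase = "stationary", seed = 71)
  m <- as.data.frame(ts)[as.data.frame(ts)$t == 20, ]
  vth <- msd_ensemble(20, p)
  for (v in list(m$x, m$y, m$z))
    expect_lt(abs(var(v) - vth), 4 * vth * sqrt(2 / (nrow(m) - 1)))
  expect_gt(mean(m$x), 30)  # but the mean has moved (C t = 75.2 um)
})
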