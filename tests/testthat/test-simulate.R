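test_that("discretised lognormal hits its volume-weighted mean and total exactly", {
  d <- synth_distribution(mean_radius = 2.53, gsd = 1.15, n_bins = 25,
                          total_phi = 4.0e-4)
  s <- distribution_summary(d)
  expect_equal(s$mean_radius, 2.53, tolerance = 1e-3)
  expect_equal(s$total_phi, 4.0e-4, tolerance = 1e-12)

  # gsd -> 1 collapses to a single dominant bin
  d1 <- synth_distribution(gsd = 1)
  expect_equal(nrow(d1), 1)
  expect_equal(d1$r, 2.53)
  expect_equal(nrow(synth_distribution(n_bins = 1)), 1)
})

test_that("synthetic curves are exact without noise and reproducible with it", {
  q <- default_qgrid(80)
  dist <- tiny_dist()
  th <- theta_ref()
  clean <- synth_curve(q, dist, theta = th, noise_f = 0, noise_b = 0)
  expect_equal(clean$I, model_intensity(q, dist, theta = th)$I)
  expect_false("sigma_I" %in% names(clean))

  n1 <- synth_curve(q, dist, theta = th, seed = 123)
  n2 <- synth_curve(q, dist, theta = th, seed = 123)
  expect_identical(n1$I, n2$I)
  expect_false(identical(n1$I, synth_curve(q, dist, theta = th, seed = 124)$I))
})

test_that("the noise model is self-consistent: true model has chi2_red near 1", {
  q <- default_qgrid(400)
  dist <- tiny_dist()
  th <- theta_ref()
  Im <- model_intensity(q, dist, theta = th)$I
  crv <- synth_curve(q, dist, theta = th, noise_f = 0.01, seed = 31)
  chi2 <- sum(((crv$I - Im) / crv$sigma_I)^2) / length(q)
  expect_equal(chi2, 1, tolerance = 0.2)
})

test_that("mean of noisy replicates converges to the noiseless model", {
  q <- default_qgrid(30)
  dist <- size_distribution(2.5, 4e-4)
  Im <- dilute_intensity(q, dist)$I
  reps <- withr::with_seed(77, {
    vapply(1:400, function(i) synth_curve(q, dist, noise_f = 0.02,
                                          noise_b = 1e-4)$I,
           numeric(length(q)))
  })
  se <- apply(reps, 1, stats::sd) / sqrt(ncol(reps))
  expect_true(all(abs(rowMeans(reps) - Im) < 3.5 * se))
})

test_that("trajectory preset respects the fitting bounds and the truth table", {
  t <- seq(25, 175, by = 1)
  tr <- composite_trajectory(t)
  cfg <- fit_config()
  for (p in c("nu", "aR_mean", "aR_sd", "A", "D")) {
    expect_true(all(tr[[p]] >= cfg$lower[[p]] & tr[[p]] <= cfg$upper[[p]]),
                info = p)
  }
  expect_true(all(diff(tr$nu) >= 0))
  # the aggregate amplitude rises about 4.5-fold over the first ~35 s
  expect_equal(max(tr$A[t <= 60]) / tr$A[1], 4.5, tolerance = 0.15)

  ts <- synth_timeseries(n_frames = 12, seed = 3, q = default_qgrid(60),
                         dist = tiny_dist())
  expect_equal(nrow(ts$series), 12)
  pars <- c("nu", "aR_mean", "aR_sd", "A", "D")
  expect_identical(ts$truth[pars], composite_trajectory(ts$truth$t)[pars])
  expect_identical(ts$series$t, ts$truth$t)
})
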