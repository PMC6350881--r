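test_that("noiseless round trip recovers the generating parameters", {
  q <- default_qgrid(250)
  dist <- tiny_dist()
  th <- theta_ref()
  crv <- synth_curve(q, dist, theta = th, noise_f = 0, noise_b = 0)
  fit <- fit_frame(crv, dist)   # log weighting picked automatically
  expect_true(fit$converged)
  expect_lt(max(abs(fit$theta - th) / th), 1e-3)
  expect_lt(fit$chi2_red, 1e-10)

  td <- tidy(fit)
  expect_equal(td$term, names(th))
  expect_equal(glance(fit)$nobs, 250)
})

test_that("fits are invariant under uniform intensity rescaling with a free scale", {
  q <- default_qgrid(150)
  dist <- tiny_dist()
  th <- theta_ref()
  crv <- synth_curve(q, dist, theta = th, seed = 8)
  cfg <- fit_config(free_scale = TRUE)
  fit1 <- fit_frame(crv, dist, config = cfg)
  scaled <- scattering_curve(crv$q, crv$I * 7.3, sigma_I = crv$sigma_I * 7.3)
  fit2 <- fit_frame(scaled, dist, config = cfg)
  expect_equal(fit2$theta, fit1$theta, tolerance = 1e-5)
  expect_equal(fit2$scale / fit1$scale, 7.3, tolerance = 1e-5)
  expect_equal(fit2$chi2_red, fit1$chi2_red, tolerance = 1e-6)
})

test_that("warm-started fitting of a stationary series matches per-frame fits", {
  q <- default_qgrid(120)
  dist <- tiny_dist()
  th <- theta_ref()
  curves <- lapply(1:4, function(i) {
    synth_curve(q, dist, theta = th, noise_f = 0, noise_b = 0,
                t = 0.05 * i)
  })
  series <- as_saxs_series(curves)
  fs <- fit_series(series, dist)
  expect_true(all(fs$converged))
  for (p in fit_par_names()) {
    expect_lt(max(abs(fs[[p]] - th[[p]])) / th[[p]], 1e-4)
  }
  solo <- fit_frame(curves[[3]], dist)
  expect_equal(unlist(fs[3, fit_par_names()]),
               solo$theta[fit_par_names()], tolerance = 1e-4)
})

test_that("pre-injection frames are fitted as pure form factor", {
  q <- default_qgrid(100)
  dist <- tiny_dist()
  th <- theta_ref()
  curves <- c(
    lapply(1:2, function(i) synth_curve(q, dist, theta = NULL, seed = i,
                                        t = i * 0.05)),
    lapply(3:4, function(i) synth_curve(q, dist, theta = th, seed = i,
                                        t = 20 + i * 0.05))
  )
  fs <- fit_series(as_saxs_series(curves), dist, injection_time = 10)
  expect_equal(fs$pre_injection, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(fs$nu[1:2], c(0, 0))
  expect_equal(fs$A[1:2], c(0, 0))
  expect_true(all(is.na(fs$D[1:2])))
  expect_lt(max(fs$chi2_red[1:2]), 2)       # dilute model explains period I
  expect_equal(fs$nu[3:4], rep(th[["nu"]], 2), tolerance = 0.05)
})

test_that("spacer parameters become ill-determined when packing is negligible", {
  q <- default_qgrid(150)
  dist <- tiny_dist()
  low <- c(nu = 0.015, aR_mean = 0.9, aR_sd = 0.4, A = 0.02, D = 2.0)
  high <- c(nu = 0.45, aR_mean = 0.9, aR_sd = 0.4, A = 0.02, D = 2.0)
  fit_low <- fit_frame(synth_curve(q, dist, theta = low, seed = 15), dist)
  fit_high <- fit_frame(synth_curve(q, dist, theta = high, seed = 15), dist)
  rel <- function(f, p) f$theta_sd[[p]] / f$theta[[p]]
  expect_gt(rel(fit_low, "aR_mean") / rel(fit_high, "aR_mean"), 5)
  expect_gt(rel(fit_low, "aR_sd") / rel(fit_high, "aR_sd"), 5)
})

test_that("an interaction with no physical solution anywhere fails loudly", {
  q <- default_qgrid(100)
  dist <- tiny_dist()
  crv <- synth_curve(q, dist, theta = theta_ref(), seed = 2)
  expect_error(
    fit_frame(crv, dist, interaction = shs_interaction(u_well = -15),
              config = fit_config(upper = c(nu = 0.15, aR_mean = 3,
                                            aR_sd = 1.5, A = 10, D = 3.999))),
    class = "stickysaxs_fit_failure")
})

test_that("profile intervals agree with curvature errors and widen when degenerate", {
  q <- default_qgrid(150)
  dist <- tiny_dist()
  th <- theta_ref()

  # noiseless: the interval collapses towards zero width
  clean <- synth_curve(q, dist, theta = th, noise_f = 0, noise_b = 0)
  fit0 <- fit_frame(clean, dist)
  pu0 <- profile_uncertainty(fit0, "nu", max_steps = 6)
  expect_lt(pu0$upper - pu0$lower, 1e-3)

  # well-conditioned noisy fit: profile interval brackets the curvature sd
  crv <- synth_curve(q, dist, theta = th, seed = 8)
  fit <- fit_frame(crv, dist)
  pu <- profile_uncertainty(fit, "nu")
  half <- (pu$upper - pu$lower) / 2
  expect_gt(half, 0.3 * fit$theta_sd[["nu"]])
  expect_lt(half, 3 * fit$theta_sd[["nu"]])
  expect_true(pu$lower < fit$theta[["nu"]] && fit$theta[["nu"]] < pu$upper)

  # a low-q-only window barely constrains the packing fraction (the
  # correlation peak is excluded): the interval inflates strongly
  narrow <- fit_config(q_range = c(0.04, 0.35))
  fitn <- fit_frame(crv, dist, config = narrow)
  pun <- profile_uncertainty(fitn, "nu")
  expect_gt(pun$upper - pun$lower, 10 * (pu$upper - pu$lower))
})
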