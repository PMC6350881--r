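mc_small <- function(...) {
  base <- list(n_contributions = 100, max_iterations = 20000,
               n_repetitions = 4, n_bins = 22, seed = 42)
  do.call(mc_config, utils::modifyList(base, list(...)))
}

test_that("inversion of a monodisperse curve recovers radius and volume fraction", {
  q <- default_qgrid(150)
  truth <- size_distribution(2.5, 4e-4)
  crv <- synth_curve(q, truth, noise_f = 0, noise_b = 0)
  # noiseless data: the chain needs a large proposal budget to collapse all
  # contributions onto one radius (it stops early once below target)
  fit <- mcsas_fit(crv,
                   config = mc_small(max_iterations = 1e6, n_repetitions = 3),
                   surrogate_sigma = 0.01)
  s <- distribution_summary(fit)
  expect_lt(abs(s$mean_radius / 2.5 - 1), 0.02)
  expect_lt(abs(s$total_phi / 4e-4 - 1), 0.05)
  expect_s3_class(attr(fit, "convergence"), "tbl_df")
  expect_true(all(attr(fit, "convergence")$converged))
})

test_that("histogram volume is conserved against the fitted scale", {
  q <- default_qgrid(120)
  truth <- synth_distribution(n_bins = 6)
  crv <- synth_curve(q, truth, seed = 5)
  fit <- suppressWarnings(mcsas_fit(crv, config = mc_small()))
  cfg <- attr(fit, "config")
  scales <- attr(fit, "scale")
  phi_from_scale <- mean(scales) * cfg$n_contributions /
    (1e7 * contrast_config()$drho^2)
  expect_lt(abs(sum(fit$phi) / phi_from_scale - 1), 1e-6)
})

test_that("the chain is deterministic under the master seed", {
  q <- default_qgrid(100)
  crv <- synth_curve(q, tiny_dist(), seed = 9)
  f1 <- suppressWarnings(mcsas_fit(crv, config = mc_small()))
  f2 <- suppressWarnings(mcsas_fit(crv, config = mc_small()))
  expect_identical(f1$phi, f2$phi)
  f3 <- suppressWarnings(mcsas_fit(crv, config = mc_small(seed = 43)))
  expect_false(identical(f1$phi, f3$phi))
})

test_that("a bimodal population is resolved with the right volume split", {
  q <- default_qgrid(200)
  truth <- size_distribution(c(2, 4), c(2e-4, 2e-4))
  crv <- synth_curve(q, truth, noise_f = 0.01, noise_b = 0, seed = 21)
  fit <- suppressWarnings(
    mcsas_fit(crv, config = mc_config(n_contributions = 150,
                                      max_iterations = 40000,
                                      n_repetitions = 4, n_bins = 22,
                                      seed = 7)))
  phi_small <- sum(fit$phi[fit$r < 3])
  phi_large <- sum(fit$phi[fit$r >= 3])
  split <- phi_small / (phi_small + phi_large)
  expect_equal(split, 0.5, tolerance = 0.2)

  # two distinct modes: local maxima near 2 and 4 nm
  mode_small <- fit$r[fit$r < 3][which.max(fit$phi[fit$r < 3])]
  mode_large <- fit$r[fit$r >= 3][which.max(fit$phi[fit$r >= 3])]
  expect_equal(mode_small, 2, tolerance = 0.2)
  expect_equal(mode_large, 4, tolerance = 0.2)
})

test_that("unreached chi2 target is a warning carried in metadata, not an error", {
  q <- default_qgrid(100)
  crv <- synth_curve(q, tiny_dist(), seed = 4)
  expect_warning(
    fit <- mcsas_fit(crv, config = mc_small(max_iterations = 300)),
    class = "stickysaxs_convergence_warning")
  expect_true(any(!attr(fit, "convergence")$converged))
})

test_that("curves without uncertainties need an explicit surrogate", {
  q <- default_qgrid(100)
  crv <- synth_curve(q, tiny_dist(), noise_f = 0, noise_b = 0)
  expect_error(mcsas_fit(crv, config = mc_small()),
               class = "stickysaxs_domain_error")
})
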