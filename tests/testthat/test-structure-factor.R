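test_that("well width follows the diameter rule with the H-bond floor", {
  expect_equal(well_width(2.5), 0.5)
  expect_equal(well_width(0.5), 0.15)    # floor active
  expect_equal(well_width(0.75), 0.15)   # boundary
  expect_equal(well_width(10), 2)
})

test_that("stickiness inverts the square-well depth", {
  # floor-inactive case simplifies to exp(-2.5) * 1.1 / 1.2 for any R_HS
  for (R in c(1, 2.5, 3.5)) {
    expect_equal(stickiness(R), exp(-2.5) * 1.1 / 1.2, tolerance = 1e-12)
  }
  # exact inversion: U = ln(12 delta / (2R + delta)) gives tau = 1
  # (delta chosen so this depth is attractive, i.e. negative)
  R <- 2.5
  delta <- 0.3
  inter <- shs_interaction(u_well = log(12 * delta / (2 * R + delta)))
  expect_equal(stickiness(R, delta, inter), 1, tolerance = 1e-12)
  # deeper wells are stickier, monotonically
  taus <- vapply(c(-1, -2, -3, -4),
                 function(u) stickiness(R, interaction = shs_interaction(u)),
                 numeric(1))
  expect_true(all(diff(taus) < 0))
  expect_error(stickiness(R, delta = -0.1), class = "stickysaxs_domain_error")
})

test_that("sticky structure factor reduces to Percus-Yevick when adhesion is off", {
  q <- seq(0.05, 10, length.out = 400)
  R <- 2.5
  delta <- well_width(R)
  ratio3 <- ((2 * R + delta) / (2 * R))^3
  for (eta in c(0.1, 0.3, 0.5)) {
    nu <- eta / ratio3  # so the rescaled packing equals the target eta
    S_py <- py_structure_factor(q, R, eta)
    for (tau in c(1e6, 1e8)) {
      S <- s_shs(q, R, nu, tau = tau, delta = delta)$S
      expect_lt(max(abs(S - S_py)), 1e-5)
    }
  }
})

test_that("structure factor limits: no correlations at nu = 0, unity at high q", {
  q <- seq(0.05, 5, length.out = 50)
  expect_equal(s_shs(q, 3.5, 0)$S, rep(1, 50))

  # the adhesive surface term decays like 1/(q R): the envelope of |S - 1|
  # falls monotonically and S -> 1 in the high-q limit
  R <- 3.5
  envelope <- function(nu, kappa) {
    qv <- kappa / (2 * R) + c(0, 0.01, 0.02)   # sample several phases
    max(abs(s_shs(qv, R, nu)$S - 1))
  }
  for (nu in c(0.1, 0.3, 0.45, 0.6)) {
    env <- vapply(c(5e2, 2e3, 5e3, 2e4), function(k) envelope(nu, k),
                  numeric(1))
    expect_true(all(diff(env) < 0))
    expect_lt(env[length(env)], 5e-4)
  }
})

test_that("correlation peak sits near 2 pi / (2 R_HS) and grows with packing", {
  q <- seq(0.1, 4.5, length.out = 2000)
  sf <- s_shs(q, 3.5, 0.45)
  expect_equal(peak_location(sf), 2 * pi / (2 * 3.5), tolerance = 0.25)

  # peak height monotone in nu (at fixed radius and adhesion)
  heights <- vapply(seq(0.1, 0.6, by = 0.1), function(nu) {
    sm <- smeared_s_shs(q, 2.53, 0.93, 0.2, nu)
    max(sm$S[q >= 0.3 & q <= 3])
  }, numeric(1))
  expect_true(all(diff(heights) > 0))

  # peak position moves to lower q as the spacer radius grows
  peaks <- vapply(c(0.5, 0.9, 1.3), function(aR) {
    peak_location(smeared_s_shs(q, 2.53, aR, 0.2, 0.45))
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("unphysical parameter regions are rejected, not silently evaluated", {
  q <- seq(0.1, 2, length.out = 20)
  # small tau with moderate packing puts eps^2 below gamma
  expect_error(s_shs(q, 2.5, 0.1, tau = 1e-4),
               class = "stickysaxs_unphysical_parameters")
  expect_error(s_shs(q, 2.5, 0.7), class = "stickysaxs_domain_error")
  expect_error(
    smeared_s_shs(q, 2.5, 0.9, 0.3, 0.2,
                  interaction = shs_interaction(u_well = -15)),
    class = "stickysaxs_unphysical_parameters")
})

test_that("Gaussian smearing: weights, delta limit, and peak suppression", {
  q <- seq(0.3, 3, length.out = 600)

  # quadrature of the Gaussian mass agrees with the analytic truncated mass
  for (sd in c(1e-4, 0.1, 0.533)) {
    nodes <- stickysaxs:::smear_nodes(0.93, sd, 64)
    m_true <- pnorm(0.93 + 8 * sd, 0.93, sd) -
      pnorm(max(0, 0.93 - 8 * sd), 0.93, sd)
    expect_lt(abs(nodes$mass - m_true), 1e-10)
    expect_equal(sum(nodes$weight), 1, tolerance = 1e-12)
  }

  # sigma -> 0 recovers the unsmeared factor at R_HS = r_i + aR
  sharp <- s_shs(q, 2.53 + 0.979, 0.454)$S
  smeared0 <- smeared_s_shs(q, 2.53, 0.979, 1e-4, 0.454)$S
  expect_lt(max(abs(smeared0 - sharp)), 1e-4)

  # nu = 0 smears to unity
  expect_equal(smeared_s_shs(q, 2.53, 0.9, 0.5, 0)$S, rep(1, length(q)))

  # at the composite-formation parameters the smeared peak is strictly lower
  # and broader than the unsmeared one at the same packing
  sm <- smeared_s_shs(q, 2.53, 0.93, 0.533, 0.454)$S
  expect_lt(max(sm), max(s_shs(q, 2.53 + 0.979, 0.454)$S))

  # quadrature refinement: 64 vs 128 nodes agree
  sm128 <- smeared_s_shs(q, 2.53, 0.93, 0.533, 0.454, n_nodes = 128)$S
  expect_lt(max(abs(sm - sm128)), 1e-6)
})

test_that("effective structure factor adds the aggregate power law", {
  q <- seq(0.05, 4, length.out = 300)
  base <- smeared_s_shs(q, 2.53, 0.9, 0.4, 0.4)$S
  expect_equal(s_eff(q, 2.53, 0.9, 0.4, 0.4, A = 0, D = 2.4)$S, base)

  # nu -> 0 leaves 1 + A q^-D; the power-law part has log-log slope -D
  se <- s_eff(q, 2.53, 0.9, 0.4, 0, A = 0.05, D = 2.37)$S
  expect_equal(se, 1 + 0.05 * q^(-2.37))
  slope <- diff(log(se - 1)) / diff(log(q))
  expect_equal(slope, rep(-2.37, length(q) - 1), tolerance = 1e-10)

  expect_equal(s_eff(q, 2.53, 0.9, 0.4, 0.4, A = 0.05, D = 2.37)$S,
               base + 0.05 * q^(-2.37), tolerance = 1e-12)
})

test_that("model intensity is consistent with its reductions and the LMA", {
  q <- default_qgrid(60)
  dist <- tiny_dist()
  ctr <- contrast_config()

  # nu = 0, A = 0 reduces to the dilute model
  expect_equal(model_intensity(q, dist, ctr, nu = 0, A = 0)$I,
               dilute_intensity(q, dist, ctr)$I, tolerance = 1e-12)

  # single-bin distribution gives the product form
  one <- size_distribution(2.5, 4e-4)
  th <- theta_ref()
  I1 <- model_intensity(q, one, ctr, theta = th)$I
  Seff <- s_eff(q, 2.5, th[["aR_mean"]], th[["aR_sd"]], th[["nu"]],
                th[["A"]], th[["D"]])$S
  expect_equal(I1,
               ctr$drho^2 * 1e7 * 4e-4 * sphere_volume(2.5) *
                 sphere_form_factor(q, 2.5) * Seff,
               tolerance = 1e-12)

  # LMA linearity: splitting a bin into two half-phi copies changes nothing
  split <- size_distribution(
    r = c(dist$r[1] * (1 - 1e-12), dist$r), # keep radii strictly increasing
    phi = c(dist$phi[1] / 2, dist$phi[1] / 2, dist$phi[-1]))
  expect_equal(model_intensity(q, split, ctr, theta = th)$I,
               model_intensity(q, dist, ctr, theta = th)$I,
               tolerance = 1e-9)

  # aggregate upturn: low-q intensity exceeds the dilute limit
  Ilow <- model_intensity(0.05, dist, ctr, theta = th)$I
  expect_gt(Ilow, 5 * dilute_intensity(0.05, dist, ctr)$I)
})
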