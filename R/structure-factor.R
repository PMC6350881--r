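#' Adhesive square-well interaction settings
#'
#' The nanoparticle-protein adhesion is modelled as a square well of depth
#' `u_well` (in units of kT, negative) and width `delta` tied to the
#' hard-sphere diameter: `delta = delta_fraction * 2 R_HS`, floored at
#' `delta_min` (0.15 nm, an average hydrogen-bond length).  The stickiness
#' parameter tau of the Baxter model follows from inverting the well-depth
#' relation `U/kT = ln[12 tau delta / (2 R_HS + delta)]`.  The default depth
#' of -2.5 kT is held fixed rather than fitted: within the physically
#' plausible range (not deeper than about -3 kT) its value does not move the
#' fits.
#'
#' @param u_well Well depth in kT units; must be negative.
#' @param delta_fraction Well width as a fraction of the hard-sphere
#'   diameter `2 R_HS`.
#' @param delta_min Lower floor on the well width, nm.
#' @return A list of class `shs_interaction`.
#' @export
shs_interaction <- function(u_well = -2.5, delta_fraction = 0.1,
                            delta_min = 0.15) {
  if (!(u_well < 0)) {
    abort("`u_well` must be negative (an attractive well).",
          class = "stickysaxs_domain_error")
  }
  if (!(delta_fraction > 0) || !(delta_min > 0)) {
    abort("`delta_fraction` and `delta_min` must be positive.",
          class = "stickysaxs_domain_error")
  }
  structure(list(u_well = u_well, delta_fraction = delta_fraction,
                 delta_min = delta_min),
            class = "shs_interaction")
}

#' Square-well width for a given hard-sphere radius
#'
#' `delta = max(delta_fraction * 2 R_HS, delta_min)`.
#'
#' @param R_HS Hard-sphere radius, nm (vectorised).
#' @param interaction An [shs_interaction()].
#' @return Well width delta, nm.
#' @export
#' @examples
#' well_width(2.5)   # 0.5 nm
#' well_width(0.5)   # floor: 0.15 nm
well_width <- function(R_HS, interaction = shs_interaction()) {
  pmax(interaction$delta_fraction * 2 * R_HS, interaction$delta_min)
}

#' Baxter stickiness parameter from the square-well depth
#'
#' Inverts the middle branch of the square-well potential:
#' `tau = exp(U/kT) (2 R_HS + delta) / (12 delta)`.  For the default
#' interaction (depth -2.5 kT, width 0.1 of the diameter, floor inactive)
#' tau is about 0.0752 independent of `R_HS`.
#'
#' @param R_HS Hard-sphere radius, nm (vectorised).
#' @param delta Well width, nm; defaults to [well_width()] of `R_HS`.
#' @param interaction An [shs_interaction()].
#' @return Stickiness tau (dimensionless, positive; smaller is stickier).
#' @export
stickiness <- function(R_HS, delta = well_width(R_HS, interaction),
                       interaction = shs_interaction()) {
  if (any(delta <= 0)) {
    abort("`delta` must be positive.", class = "stickysaxs_domain_error")
  }
  exp(interaction$u_well) * (2 * R_HS + delta) / (12 * delta)
}

# Screen the (R_HS, nu, tau, delta) sets for the Baxter real-root condition.
# Returns a logical vector; attributes carry eta for messages.
shs_screen <- function(R_HS, nu, tau, delta) {
  eta <- nu * ((2 * R_HS + delta) / (2 * R_HS))^3
  eps <- tau + eta / (1 - eta)
  gam <- nu * (1 + eta / 2) / (3 * (1 - eta)^2)
  ok <- eta < 1 & eps^2 >= gam
  structure(ok, eta = eta)
}

#' Sticky-hard-sphere (Baxter) structure factor
#'
#' Evaluates the adhesive hard-sphere structure factor
#' `S(q) = 1 / (1 - C(q))` from the closed-form direct correlation function
#' of the Baxter model in the Percus-Yevick approximation, with the packing
#' fraction rescaled for the finite well width,
#' `eta = nu ((2 R_HS + delta) / (2 R_HS))^3`, and the physical (minus)
#' root of the Baxter quadratic for the adhesion strength lambda.  In the
#' non-sticky limit (tau -> Inf) it reduces to the Percus-Yevick hard-sphere
#' structure factor at packing fraction eta; for nu = 0 it is identically 1.
#'
#' @param q Momentum transfer grid, nm^-1 (positive).
#' @param R_HS Hard-sphere radius, nm.
#' @param nu Local packing fraction inside the aggregate; for random packing
#'   of polydisperse spheres it does not exceed 0.65.
#' @param tau Stickiness; defaults to [stickiness()] of `R_HS` under
#'   `interaction`.
#' @param delta Well width, nm; defaults to [well_width()].
#' @param interaction An [shs_interaction()].
#' @return A tibble with columns `q` and `S`.
#' @export
#' @examples
#' s_shs(seq(0.1, 5, 0.1), R_HS = 3.5, nu = 0.45)
s_shs <- function(q, R_HS, nu, tau = NULL, delta = NULL,
                  interaction = shs_interaction()) {
  if (any(q <= 0)) {
    abort("`q` must be positive.", class = "stickysaxs_domain_error")
  }
  if (!(R_HS > 0)) {
    abort("`R_HS` must be positive.", class = "stickysaxs_domain_error")
  }
  if (nu < 0 || nu > 0.65) {
    abort("`nu` must lie in [0, 0.65].", class = "stickysaxs_domain_error")
  }
  delta <- delta %||% well_width(R_HS, interaction)
  tau <- tau %||% stickiness(R_HS, delta, interaction)
  if (nu > 0) {
    ok <- shs_screen(R_HS, nu, tau, delta)
    eta <- attr(ok, "eta")
    if (eta >= 1) {
      abort(sprintf("Rescaled packing fraction eta = %.3f >= 1.", eta),
            class = "stickysaxs_domain_error")
    }
    if (!ok) {
      abort(sprintf(paste0("No real Baxter solution at R_HS = %.4g nm, ",
                           "nu = %.4g, tau = %.4g (eps^2 < gamma)."),
                    R_HS, nu, tau),
            class = "stickysaxs_unphysical_parameters")
    }
  }
  S <- drop(.shs_matrix_cpp(as.numeric(q), R_HS, nu, tau, delta))
  tibble(q = as.numeric(q), S = S)
}

# Gauss-Legendre base nodes on [-1, 1], cached per node count.
gl_cache <- new.env(parent = emptyenv())
gl_base <- function(n) {
  key <- as.character(n)
  if (is.null(gl_cache[[key]])) {
    gl_cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  }
  gl_cache[[key]]
}

# Quadrature nodes/weights for the spacer-radius integral on
# [0, aR_mean + 8 aR_sd], with the Gaussian weight already normalised by the
# quadrature of the truncated Gaussian mass (the denominator of the smearing
# ratio).
smear_nodes <- function(aR_mean, aR_sd, n_nodes) {
  upper <- aR_mean + 8 * aR_sd
  # The integrand is zero to machine precision below mean - 8 sd, so the
  # quadrature starts there instead of 0 when possible; this resolves the
  # narrow-Gaussian (sigma -> 0) limit without changing the integral.
  lower <- max(0, aR_mean - 8 * aR_sd)
  gl <- gl_base(n_nodes)
  R <- lower + (gl$x + 1) * (upper - lower) / 2
  w <- gl$w * (upper - lower) / 2
  dg <- dnorm(R, mean = aR_mean, sd = aR_sd)
  wt <- w * dg
  list(R = R, weight = wt / sum(wt), mass = sum(wt))
}

#' Gaussian-smeared sticky-hard-sphere structure factor
#'
#' Averages [s_shs()] over a Gaussian distribution of the additional
#' effective hard-sphere ("spacer") radius: the protein molecule bridging
#' two particles contributes `R_HS = r_i + R` with
#' `R ~ N(aR_mean, aR_sd^2)`, truncated to `[0, aR_mean + 8 aR_sd]` and
#' renormalised.  The well width and the stickiness are recomputed at every
#' integration node from that node's `R_HS`, because the well-width rule is
#' tied to the hard-sphere diameter.  Smearing lowers and broadens the
#' correlation peak at constant `nu`.
#'
#' @inheritParams s_shs
#' @param r_i Primary-particle radius of the size class, nm.
#' @param aR_mean Mean additional effective hard-sphere radius, nm (>= 0).
#' @param aR_sd Standard deviation of the spacer radius, nm (> 0).
#' @param n_nodes Number of Gauss-Legendre quadrature nodes.
#' @return A tibble with columns `q` and `S`.
#' @export
smeared_s_shs <- function(q, r_i, aR_mean, aR_sd, nu,
                          interaction = shs_interaction(), n_nodes = 64) {
  if (any(q <= 0)) {
    abort("`q` must be positive.", class = "stickysaxs_domain_error")
  }
  if (!(r_i > 0) || aR_mean < 0 || !(aR_sd > 0)) {
    abort("Require r_i > 0, aR_mean >= 0 and aR_sd > 0.",
          class = "stickysaxs_domain_error")
  }
  if (nu < 0 || nu > 0.65) {
    abort("`nu` must lie in [0, 0.65].", class = "stickysaxs_domain_error")
  }
  if (nu == 0) return(tibble(q = as.numeric(q), S = rep(1, length(q))))

  nodes <- smear_nodes(aR_mean, aR_sd, n_nodes)
  R_HS <- r_i + nodes$R
  delta <- well_width(R_HS, interaction)
  tau <- stickiness(R_HS, delta, interaction)
  ok <- shs_screen(R_HS, nu, tau, delta)
  if (!all(ok)) {
    bad <- R_HS[!ok][[1]]
    abort(sprintf(paste0("No real Baxter solution at smearing node ",
                         "R_HS = %.4g nm (nu = %.4g)."), bad, nu),
          class = "stickysaxs_unphysical_parameters")
  }
  Smat <- .shs_matrix_cpp(as.numeric(q), R_HS, nu, tau, delta)
  tibble(q = as.numeric(q), S = drop(Smat %*% nodes$weight))
}

#' Effective structure factor: internal correlations plus aggregate term
#'
#' `S_eff(q, r_i) = <S_SHS>(q, r_i) + A q^-D`: the smeared sticky-hard-sphere
#' factor carries the interparticle correlation peak, while the power law
#' `A q^-D` carries the low-q upturn of the mass-fractal aggregates.  `A` is
#' a single collective amplitude proportional to the product of the
#' aggregate number density and specific surface area; its implicit units
#' absorb `q^-D` on the nm^-1 scale (values of `A` are only comparable for q
#' expressed in nm^-1).  `D` is the mass-fractal dimension, `1 <= D < 4`.
#'
#' @inheritParams smeared_s_shs
#' @param A Aggregate amplitude (>= 0), for q in nm^-1.
#' @param D Mass-fractal dimension.
#' @return A tibble with columns `q` and `S`.
#' @export
s_eff <- function(q, r_i, aR_mean, aR_sd, nu, A, D,
                  interaction = shs_interaction(), n_nodes = 64) {
  if (A < 0 || D < 1 || D >= 4) {
    abort("Require A >= 0 and 1 <= D < 4.",
          class = "stickysaxs_domain_error")
  }
  out <- smeared_s_shs(q, r_i, aR_mean, aR_sd, nu,
                       interaction = interaction, n_nodes = n_nodes)
  out$S <- out$S + A * out$q^(-D)
  out
}

#' Full model intensity: local monodisperse approximation
#'
#' Absolute scattering intensity of a polydisperse sphere population whose
#' size classes each carry their own effective structure factor (local
#' monodisperse approximation):
#' `I(q) = drho^2 sum_i phi_i V(r_i) P(q, r_i) S_eff(q, r_i)`,
#' with `R_HS,i = r_i + R` inside the spacer-smearing integral.  Reduces to
#' [dilute_intensity()] for `nu = 0, A = 0`.
#'
#' @inheritParams dilute_intensity
#' @inheritParams s_eff
#' @param theta Alternatively to the five scalars, a named vector/list with
#'   elements `nu`, `aR_mean`, `aR_sd`, `A`, `D`.
#' @return A tibble with columns `q` (nm^-1) and `I` (cm^-1).
#' @export
#' @examples
#' dist <- synth_distribution(n_bins = 10)
#' model_intensity(seq(0.05, 4.5, length.out = 30), dist,
#'                 nu = 0.45, aR_mean = 0.93, aR_sd = 0.53,
#'                 A = 0.044, D = 2.4)
model_intensity <- function(q, dist, contrast = contrast_config(),
                            nu = 0, aR_mean = 1, aR_sd = 0.4, A = 0, D = 2.4,
                            interaction = shs_interaction(), n_nodes = 64,
                            theta = NULL) {
  if (!is.null(theta)) {
    theta <- as.list(theta)
    nu <- theta$nu; aR_mean <- theta$aR_mean; aR_sd <- theta$aR_sd
    A <- theta$A; D <- theta$D
  }
  validate_distribution(dist)
  q <- as.numeric(q)
  Seff <- seff_matrix(q, dist$r, nu, aR_mean, aR_sd, A, D, interaction,
                      n_nodes, on_invalid = "error")
  I <- drop((ff_matrix(q, dist$r) * Seff) %*% dist$phi) * contrast$drho^2 * 1e7
  tibble(q = q, I = I)
}

# S_eff values as an nq x nbins matrix.  on_invalid = "error" raises the
# unphysical-parameters condition; "na" returns NULL so the fitter can
# apply a penalty instead.
seff_matrix <- function(q, r, nu, aR_mean, aR_sd, A, D, interaction, n_nodes,
                        on_invalid = c("error", "na")) {
  on_invalid <- match.arg(on_invalid)
  nbins <- length(r)
  agg <- if (A > 0) A * q^(-D) else 0
  if (nu == 0) {
    return(matrix(1 + agg, nrow = length(q), ncol = nbins))
  }
  nodes <- smear_nodes(aR_mean, aR_sd, n_nodes)
  # stack nodes of all bins into one kernel call
  R_HS <- as.vector(outer(nodes$R, r, `+`))
  delta <- well_width(R_HS, interaction)
  tau <- stickiness(R_HS, delta, interaction)
  ok <- shs_screen(R_HS, nu, tau, delta)
  if (!all(ok)) {
    if (on_invalid == "na") return(NULL)
    bad <- R_HS[!ok][[1]]
    abort(sprintf(paste0("No real Baxter solution at smearing node ",
                         "R_HS = %.4g nm (nu = %.4g)."), bad, nu),
          class = "stickysaxs_unphysical_parameters")
  }
  Smat <- .shs_matrix_cpp(q, R_HS, nu, tau, delta)
  dim(Smat) <- c(length(q), n_nodes, nbins)
  # contract over quadrature nodes per bin
  Seff <- vapply(seq_len(nbins),
                 function(j) Smat[, , j] %*% nodes$weight,
                 numeric(length(q)))
  Seff + agg
}

fit_par_names <- function() c("nu", "aR_mean", "aR_sd", "A", "D")
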