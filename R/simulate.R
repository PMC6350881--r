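#' Default logarithmic q grid
#'
#' 400 log-spaced points over the usable 0.04-4.5 nm^-1 window, wide enough
#' to exercise both the low-q aggregate upturn and the form-factor tail.
#'
#' @param n Number of points.
#' @param q_min,q_max Range, nm^-1.
#' @return Numeric vector of q values.
#' @export
default_qgrid <- function(n = 400, q_min = 0.04, q_max = 4.5) {
  exp(seq(log(q_min), log(q_max), length.out = n))
}

#' Discretised lognormal size distribution
#'
#' Builds a discrete volume-fraction histogram emulating a narrow sol of
#' few-nanometre spheres.  The lognormal is parameterised directly on the
#' volume-weighted scale, so `distribution_summary()` of the result returns
#' `mean_radius` equal to `mean_radius` exactly: bin positions are the
#' conditional means of the lognormal inside each bin, not the bin centres.
#'
#' @param mean_radius Volume-weighted mean radius, nm.  The default 2.53 nm
#'   is typical for a freshly polymerised silica sol.
#' @param gsd Geometric standard deviation (> 1 for a spread; values near
#'   1.15 give the narrow distribution of such sols).
#' @param n_bins Number of histogram bins (1 gives a delta distribution).
#' @param total_phi Total particle volume fraction (the default 4.0e-4,
#'   i.e. 0.040 %, matches a 1000 ppm silica solution).
#' @param coverage Central lognormal mass covered by the binning grid.
#' @return A [size_distribution()] tibble.
#' @export
#' @examples
#' distribution_summary(synth_distribution())  # 2.53 nm, 4e-4
synth_distribution <- function(mean_radius = 2.53, gsd = 1.15, n_bins = 25,
                               total_phi = 4.0e-4, coverage = 0.998) {
  stopifnot(mean_radius > 0, gsd >= 1, n_bins >= 1, total_phi > 0)
  if (n_bins == 1 || gsd < 1 + 1e-9) {
    return(size_distribution(mean_radius, total_phi))
  }
  sdlog <- log(gsd)
  meanlog <- log(mean_radius) - sdlog^2 / 2   # E[X] = mean_radius
  lo <- (1 - coverage) / 2
  edges <- qlnorm(seq(lo, 1 - lo, length.out = n_bins + 1),
                  meanlog = meanlog, sdlog = sdlog)
  p_edge <- plnorm(edges, meanlog, sdlog)
  mass <- diff(p_edge)
  # E[X; a < X < b] for a lognormal, giving exact conditional bin means
  m_edge <- pnorm((log(edges) - meanlog - sdlog^2) / sdlog)
  partial_mean <- exp(meanlog + sdlog^2 / 2) * diff(m_edge)
  r <- partial_mean / mass
  phi <- total_phi * mass / sum(mass)
  size_distribution(r, phi)
}

#' Simulate one noisy scattering frame at known parameters
#'
#' Evaluates the full model and applies a counting-statistics-like noise
#' model: `I_noisy = I (1 + f e1) + b e2` with independent standard-normal
#' draws, and `sigma_I = sqrt((f I)^2 + b^2)`.  With `noise_f = noise_b = 0`
#' the exact model curve is returned (without a `sigma_I` column).  Output
#' is bitwise-reproducible for a given seed.
#'
#' @param q Momentum transfer grid, nm^-1.
#' @param dist A [size_distribution()].
#' @param theta Named parameter vector/list (`nu`, `aR_mean`, `aR_sd`, `A`,
#'   `D`); `NULL` simulates the dilute (pre-aggregation) limit.
#' @param contrast A [contrast_config()].
#' @param interaction An [shs_interaction()].
#' @param noise_f Multiplicative noise fraction.
#' @param noise_b Additive noise floor, cm^-1.
#' @param seed Optional integer seed (local to this call).
#' @param t Optional timestamp, s.
#' @param n_nodes Smearing quadrature nodes.
#' @return A [scattering_curve()] tibble.
#' @export
#' @examples
#' synth_curve(default_qgrid(50), synth_distribution(n_bins = 5),
#'             theta = c(nu = 0.45, aR_mean = 0.93, aR_sd = 0.53,
#'                       A = 0.044, D = 2.37), seed = 1)
synth_curve <- function(q, dist, theta = NULL, contrast = contrast_config(),
                        interaction = shs_interaction(), noise_f = 0.01,
                        noise_b = 1e-4, seed = NULL, t = NULL, n_nodes = 64) {
  stopifnot(noise_f >= 0, noise_b >= 0)
  Im <- if (is.null(theta)) {
    dilute_intensity(q, dist, contrast)$I
  } else {
    model_intensity(q, dist, contrast, interaction = interaction,
                    n_nodes = n_nodes, theta = theta)$I
  }
  if (noise_f == 0 && noise_b == 0) {
    return(scattering_curve(q, Im, t = t))
  }
  draw <- function() {
    e1 <- rnorm(length(q))
    e2 <- rnorm(length(q))
    Im * (1 + noise_f * e1) + noise_b * e2
  }
  I_noisy <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  sigma <- sqrt((noise_f * Im)^2 + noise_b^2)
  scattering_curve(q, I_noisy, sigma_I = pmax(sigma, 1e-300), t = t)
}

#' Kinetic parameter trajectories of composite formation
#'
#' Piecewise-smooth trajectories encoding the canonical kinetics of
#' protein-bridged nanoparticle aggregation over the 25-175 s window after
#' mixing: the local packing fraction `nu` rises logistically to a plateau
#' of about 0.45; the mean spacer radius climbs from about 0.7 nm rapidly to
#' 0.9 nm and then more gradually towards 1.1 nm; its spread grows from 0.35
#' to about 0.5 nm; the aggregate amplitude `A` undergoes a bound-exponential
#' 4.5-fold rise over the first ~20 s of aggregation followed by a slow
#' linear increase; and the fractal dimension ramps from an open 1.9 towards
#' a dense 2.4.  All values respect the fitting bounds at all times.
#'
#' @param t Time after the start of the experiment, s (mixing at ~24.5 s).
#' @return A tibble with columns `t`, `nu`, `aR_mean`, `aR_sd`, `A`, `D`.
#' @export
#' @examples
#' composite_trajectory(c(30, 60, 120))
composite_trajectory <- function(t) {
  logistic <- function(t, mid, scale) 1 / (1 + exp(-(t - mid) / scale))
  tibble(
    t = t,
    nu = 0.45 * logistic(t, 40, 8),
    aR_mean = 0.7 + 0.2 * logistic(t, 40, 6) +
      0.2 * pmin(pmax(t - 50, 0), 100) / 100,
    aR_sd = 0.35 + 0.15 * logistic(t, 40, 8),
    A = 0.0097 * (4.5 - 3.5 * exp(-pmax(t - 25, 0) / 8)) +
      2e-5 * pmax(t - 50, 0),
    D = 1.9 + 0.5 * logistic(t, 40, 8)
  )
}

#' Simulate a time series of frames with known ground truth
#'
#' Generates a frame series along parameter trajectories, together with the
#' truth table used by recovery studies.  The default emulates a kinetic
#' aggregation run scaled down to 50 frames: the 25-175 s trajectory window
#' sampled every 3 s (a full-rate run at 50 ms per frame is obtained with
#' `frame_interval = 0.05` and a correspondingly larger `n_frames`).
#'
#' @param n_frames Number of frames.
#' @param t_start Time of the first frame, s.
#' @param frame_interval Frame spacing, s.
#' @param trajectory A function of `t` returning a data frame with columns
#'   `nu`, `aR_mean`, `aR_sd`, `A`, `D` (default [composite_trajectory()]).
#' @param dist,contrast,interaction,noise_f,noise_b,n_nodes As in
#'   [synth_curve()].
#' @param q Momentum transfer grid, nm^-1.
#' @param seed Integer seed controlling all noise draws.
#' @return A list with elements `series` (a `saxs_series`) and `truth` (a
#'   tibble of the trajectory evaluated at the frame timestamps).
#' @export
synth_timeseries <- function(n_frames = 50, t_start = 25, frame_interval = 3,
                             trajectory = composite_trajectory,
                             dist = synth_distribution(),
                             q = default_qgrid(),
                             contrast = contrast_config(),
                             interaction = shs_interaction(),
                             noise_f = 0.01, noise_b = 1e-4, seed = 1,
                             n_nodes = 64) {
  t <- t_start + (seq_len(n_frames) - 1) * frame_interval
  truth <- as_tibble(trajectory(t))
  stopifnot(all(fit_par_names() %in% names(truth)))
  curves <- withr::with_seed(seed, {
    purrr::map(seq_len(n_frames), function(k) {
      theta <- as.list(truth[k, fit_par_names()])
      synth_curve(q, dist, theta = theta, contrast = contrast,
                  interaction = interaction, noise_f = noise_f,
                  noise_b = noise_b, t = t[[k]], n_nodes = n_nodes)
    })
  })
  truth$t <- t
  list(series = as_saxs_series(curves, frame_interval = frame_interval),
       truth = truth)
}
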