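#' Settings for the Monte Carlo size-distribution inversion
#'
#' @param n_contributions Number of live sphere radii maintained by the
#'   accept/reject chain (>= 50).
#' @param r_min,r_max Uniform prior range for radii, nm.  The default
#'   0.5-6 nm brackets few-nanometre sol particles with margin.
#' @param max_iterations Proposal budget per repetition.
#' @param chi2_target Reduced chi-squared at which a repetition stops.
#' @param n_repetitions Independent repetitions (>= 3); the spread across
#'   repetitions yields the per-bin uncertainty.
#' @param n_bins Number of output histogram bins.
#' @param seed Master seed; repetition k uses `seed + k`.
#' @return A list of class `mc_config`.
#' @export
mc_config <- function(n_contributions = 200, r_min = 0.5, r_max = 6,
                      max_iterations = 100000, chi2_target = 1,
                      n_repetitions = 10, n_bins = 30, seed = 1) {
  if (!(r_min > 0) || !(r_max > r_min)) {
    abort("Require 0 < r_min < r_max.", class = "stickysaxs_domain_error")
  }
  if (n_contributions < 50) {
    abort("`n_contributions` must be at least 50.",
          class = "stickysaxs_domain_error")
  }
  if (n_repetitions < 3) {
    abort("`n_repetitions` must be at least 3.",
          class = "stickysaxs_domain_error")
  }
  structure(list(n_contributions = n_contributions, r_min = r_min,
                 r_max = r_max, max_iterations = max_iterations,
                 chi2_target = chi2_target, n_repetitions = n_repetitions,
                 n_bins = n_bins, seed = seed),
            class = "mc_config")
}

#' Monte Carlo inversion of a curve into a sphere-size distribution
#'
#' Form-free inversion of a measured dilute-limit curve into a discrete
#' volume-fraction histogram of sphere radii, in the style of McSAS-type
#' analyses.  The chain maintains `n_contributions` radii drawn uniformly
#' from the prior range; at every step one randomly chosen radius is
#' replaced by a fresh uniform draw, the overall scale is re-derived
#' analytically by weighted linear least squares, and the move is accepted
#' iff the reduced chi-squared decreases.  Repetitions with different
#' sub-seeds are binned into a volume-weighted histogram: `phi` is the mean
#' across repetitions and `phi_sd` the standard deviation.
#'
#' @param curve A scattering curve with `sigma_I`, or supply
#'   `surrogate_sigma`.
#' @param contrast A [contrast_config()]; converts the fitted scale into
#'   absolute volume fractions.
#' @param config An [mc_config()].
#' @param surrogate_sigma Optional noise model when the curve carries no
#'   uncertainties: a single fraction (sigma = fraction * I) or a vector of
#'   per-point sigmas.
#'
#' @return A [size_distribution()] tibble (`r`, `phi`, `phi_sd`) with a
#'   `convergence` attribute: a tibble of per-repetition reduced
#'   chi-squared, iterations and convergence flags.  Failure of any
#'   repetition to reach `chi2_target` is reported as a warning and in the
#'   attribute, not as an error.  Bin positions are the per-bin means of the
#'   accepted radii, so [distribution_summary()] of the result reproduces
#'   the chain's volume-weighted mean radius exactly.
#' @export
#' @examples
#' \donttest{
#' dist <- synth_distribution(n_bins = 5)
#' crv <- synth_curve(default_qgrid(100), dist, noise_f = 0.01, seed = 7)
#' fit <- mcsas_fit(crv, config = mc_config(n_contributions = 50,
#'                                          max_iterations = 5000,
#'                                          n_repetitions = 3))
#' distribution_summary(fit)
#' }
mcsas_fit <- function(curve, contrast = contrast_config(),
                      config = mc_config(), surrogate_sigma = NULL) {
  validate_curve(curve)
  if (has_sigma(curve)) {
    sigma <- curve$sigma_I
  } else if (!is.null(surrogate_sigma)) {
    sigma <- if (length(surrogate_sigma) == 1) {
      pmax(abs(surrogate_sigma * curve$I), 1e-12)
    } else {
      surrogate_sigma
    }
  } else {
    abort("Curve has no `sigma_I`; supply `surrogate_sigma`.",
          class = "stickysaxs_domain_error")
  }
  w <- 1 / sigma^2
  q <- curve$q
  I <- curve$I

  reps <- purrr::map(seq_len(config$n_repetitions), function(k) {
    withr::with_seed(config$seed + k, {
      r0 <- stats::runif(config$n_contributions, config$r_min, config$r_max)
      .mcsas_kernel_cpp(q, I, w, r0, config$r_min, config$r_max,
                        as.integer(config$max_iterations),
                        config$chi2_target)
    })
  })

  conv <- tibble(
    repetition = seq_along(reps),
    chi2_red = purrr::map_dbl(reps, "chi2_red"),
    iterations = purrr::map_int(reps, "iterations"),
    accepted = purrr::map_int(reps, "accepted"),
    converged = purrr::map_lgl(reps, "converged")
  )
  if (!all(conv$converged)) {
    warn(sprintf("mcsas_fit: %d of %d repetitions did not reach chi2_red <= %.3g.",
                 sum(!conv$converged), nrow(conv), config$chi2_target),
         class = "stickysaxs_convergence_warning")
  }

  # scale s = 1e7 drho^2 phi_contribution  (Eq for one equal-volume-fraction
  # contribution); histogram total volume equals n * phi_contribution.
  breaks <- seq(config$r_min, config$r_max, length.out = config$n_bins + 1)
  phi_per_rep <- vapply(reps, function(rep) {
    phi_c <- rep$scale / (1e7 * contrast$drho^2)
    counts <- tabulate(findInterval(rep$r, breaks, rightmost.closed = TRUE,
                                    all.inside = TRUE),
                       nbins = config$n_bins)
    counts * phi_c
  }, numeric(config$n_bins))

  all_r <- unlist(purrr::map(reps, "r"))
  bin_of <- findInterval(all_r, breaks, rightmost.closed = TRUE,
                         all.inside = TRUE)
  # per-bin mean radius weighted by each repetition's phi per contribution
  wts <- rep(purrr::map_dbl(reps, function(rep) {
    rep$scale / (1e7 * contrast$drho^2)
  }), each = config$n_contributions)
  r_centre <- vapply(seq_len(config$n_bins), function(b) {
    sel <- bin_of == b
    if (!any(sel)) (breaks[b] + breaks[b + 1]) / 2
    else sum(all_r[sel] * wts[sel]) / sum(wts[sel])
  }, numeric(1))

  phi <- rowMeans(phi_per_rep)
  phi_sd <- apply(phi_per_rep, 1, stats::sd)
  keep <- phi > 0
  out <- size_distribution(r_centre[keep], phi[keep], phi_sd = phi_sd[keep])
  attr(out, "convergence") <- conv
  attr(out, "scale") <- purrr::map_dbl(reps, "scale")
  attr(out, "config") <- config
  out
}
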