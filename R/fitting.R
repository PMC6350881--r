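#' Configuration for single-frame and series fitting
#'
#' Bounds, weighting and optimizer settings for fitting the five structure
#' parameters `theta = (nu, aR_mean, aR_sd, A, D)` to a measured curve with
#' the size distribution held fixed.
#'
#' @param lower,upper Named bounds for the five parameters.  Defaults:
#'   `nu` in (0, 0.65] (random packing of polydisperse spheres does not
#'   exceed 0.65), `aR_mean` in [0, 3] nm, `aR_sd` in [0.02, 1.5] nm,
#'   `A >= 0`, `D` in [1, 4).
#' @param weighting `"sigma"` uses experimental uncertainties
#'   (`(model - data) / sigma_I`); `"log"` uses log-intensity residuals,
#'   which balance the several-decade dynamic range when no uncertainties
#'   are available.  `"auto"` picks `"sigma"` when the curve has `sigma_I`.
#' @param q_range Fit range in nm^-1; the default spans the full usable
#'   0.04-4.5 nm^-1 window.
#' @param init Initial `theta` (named, all five parameters).  `NULL` uses
#'   `(0.3, 1.0, 0.4, A0, 2.4)` with `A0` estimated from the low-q excess
#'   over the dilute model.
#' @param free_scale If `TRUE`, a global intensity scale factor is freed
#'   (for data without absolute calibration); default fixed at 1.
#' @param n_nodes Gauss-Legendre nodes for the spacer smearing integral.
#' @param ftol Relative tolerance on the cost.
#' @param max_evals Maximum residual evaluations.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(lower = c(nu = 1e-3, aR_mean = 0, aR_sd = 0.02,
                                 A = 0, D = 1),
                       upper = c(nu = 0.65, aR_mean = 3, aR_sd = 1.5,
                                 A = 10, D = 3.999),
                       weighting = c("auto", "sigma", "log"),
                       q_range = c(0.04, 4.5), init = NULL,
                       free_scale = FALSE, n_nodes = 64, ftol = 1e-10,
                       max_evals = 2000) {
  weighting <- match.arg(weighting)
  pars <- fit_par_names()
  stopifnot(all(pars %in% names(lower)), all(pars %in% names(upper)))
  structure(list(lower = lower[pars], upper = upper[pars],
                 weighting = weighting, q_range = q_range, init = init,
                 free_scale = free_scale, n_nodes = n_nodes, ftol = ftol,
                 max_evals = max_evals),
            class = "fit_config")
}

# Low-q plateau estimate of the aggregate amplitude: the mean excess of the
# data over the dilute model at the five lowest q, read through A q^-2.4.
estimate_A_init <- function(curve, dist, contrast) {
  n <- min(5, nrow(curve))
  idx <- seq_len(n)
  dil <- dilute_intensity(curve$q[idx], dist, contrast)$I
  ratio <- pmax(curve$I[idx] / dil - 1, 1e-3)
  max(stats::median(ratio * curve$q[idx]^2.4), 1e-4)
}

#' Fit the structure parameters to a single frame
#'
#' Bounded weighted least squares (Levenberg-Marquardt trust region) of the
#' full model intensity over `theta = (nu, aR_mean, aR_sd, A, D)`, with the
#' size distribution fixed (taken from the pre-aggregation inversion).
#' Parameter vectors falling in the region where the Baxter solution turns
#' complex are rejected through a large residual penalty, so the optimizer
#' never sees silent NaNs.  Uncertainties come from the inverse of the
#' weighted Gauss-Newton normal matrix at the optimum, scaled by the reduced
#' chi-squared.
#'
#' @param curve A scattering curve (see [scattering_curve()]).
#' @param dist A fixed [size_distribution()].
#' @param contrast A [contrast_config()].
#' @param interaction An [shs_interaction()].
#' @param config A [fit_config()].
#' @return An object of class `shs_fit`: a list with elements `theta`,
#'   `theta_sd`, `vcov`, `chi2_red`, `converged`, `t`, `scale`, `nfev` and
#'   the inputs needed to re-evaluate the model.  Non-convergence sets the
#'   flag and returns the best parameters found.  Use [tidy()], [glance()]
#'   and [autoplot()] on the result.
#' @export
fit_frame <- function(curve, dist, contrast = contrast_config(),
                      interaction = shs_interaction(),
                      config = fit_config()) {
  validate_curve(curve)
  validate_distribution(dist)
  ctx <- fit_context(curve, dist, contrast, interaction, config)
  init <- fit_init(ctx, config)
  run_lm_fit(ctx, init, config)
}

# Precompute everything the residual function reuses.
fit_context <- function(curve, dist, contrast, interaction, config) {
  keep <- curve$q >= config$q_range[1] & curve$q <= config$q_range[2]
  crv <- curve[keep, , drop = FALSE]
  weighting <- config$weighting
  if (weighting == "auto") {
    weighting <- if (has_sigma(crv)) "sigma" else "log"
  }
  if (weighting == "sigma" && !has_sigma(crv)) {
    abort("Curve has no `sigma_I`; use log weighting.",
          class = "stickysaxs_domain_error")
  }
  if (weighting == "log") {
    pos <- crv$I > 0
    crv <- crv[pos, , drop = FALSE]
  }
  if (nrow(crv) < 10) {
    abort("Fewer than 10 usable points in the fit range.",
          class = "stickysaxs_malformed_input")
  }
  list(curve = crv, q = crv$q, I = crv$I,
       sigma = if (has_sigma(crv)) crv$sigma_I else NULL,
       weighting = weighting,
       ffm = ff_matrix(crv$q, dist$r),
       dist = dist, contrast = contrast, interaction = interaction,
       prefactor = contrast$drho^2 * 1e7,
       t = curve_time(crv))
}

fit_init <- function(ctx, config) {
  init <- config$init %||%
    c(nu = 0.3, aR_mean = 1.0, aR_sd = 0.4,
      A = estimate_A_init(ctx$curve, ctx$dist, ctx$contrast), D = 2.4)
  init <- init[fit_par_names()]
  span <- config$upper - config$lower
  pmin(pmax(init, config$lower + 1e-6 * span), config$upper - 1e-6 * span)
}

model_I_theta <- function(ctx, theta, n_nodes) {
  Seff <- seff_matrix(ctx$q, ctx$dist$r, theta[["nu"]], theta[["aR_mean"]],
                      theta[["aR_sd"]], theta[["A"]], theta[["D"]],
                      ctx$interaction, n_nodes, on_invalid = "na")
  if (is.null(Seff)) return(NULL)
  drop((ctx$ffm * Seff) %*% ctx$dist$phi) * ctx$prefactor
}

run_lm_fit <- function(ctx, init, config) {
  pars <- fit_par_names()
  lower <- config$lower
  upper <- config$upper
  if (config$free_scale) {
    init <- c(init, scale = 1)
    lower <- c(lower, scale = 1e-3)
    upper <- c(upper, scale = 1e3)
  }
  penalty <- rep(1e8, length(ctx$q))
  n_invalid <- 0L
  resid_fn <- function(p) {
    theta <- p[pars]
    Im <- model_I_theta(ctx, theta, config$n_nodes)
    if (is.null(Im)) {
      n_invalid <<- n_invalid + 1L
      return(penalty)
    }
    if (config$free_scale) Im <- Im * p[["scale"]]
    if (ctx$weighting == "sigma") {
      (Im - ctx$I) / ctx$sigma
    } else {
      log(pmax(Im, 1e-300)) - log(ctx$I)
    }
  }

  fit <- minpack.lm::nls.lm(
    par = init, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      ftol = config$ftol, ptol = 1e-10, gtol = 0,
      maxfev = config$max_evals, maxiter = 1000))

  res <- resid_fn(fit$par)
  if (all(res == penalty)) {
    abort("Fit failed: the structure factor is unphysical over the whole trial region.",
          class = "stickysaxs_fit_failure")
  }
  dof <- max(1, length(res) - length(fit$par))
  chi2_red <- sum(res^2) / dof
  vcov <- tryCatch(solve(fit$hessian) * chi2_red,
                   error = function(e) matrix(NA_real_, length(fit$par),
                                              length(fit$par)))
  dimnames(vcov) <- list(names(fit$par), names(fit$par))
  theta_sd <- sqrt(pmax(diag(vcov), 0))
  converged <- fit$info %in% 1:4 && is.finite(chi2_red)

  structure(list(
    theta = fit$par[pars], theta_sd = theta_sd[pars],
    scale = if (config$free_scale) unname(fit$par[["scale"]]) else 1,
    scale_sd = if (config$free_scale) unname(theta_sd[["scale"]]) else NA_real_,
    vcov = vcov, chi2_red = chi2_red, converged = converged,
    info = fit$info, message = fit$message, nfev = n_eval(fit),
    n_invalid = n_invalid, t = ctx$t, n_points = length(ctx$q),
    curve = ctx$curve, dist = ctx$dist, contrast = ctx$contrast,
    interaction = ctx$interaction, config = config, pre_injection = FALSE),
    class = "shs_fit")
}

n_eval <- function(fit) {
  # minpack.lm reports the deviance trace; its length tracks iterations
  length(fit$rsstrace)
}

#' @export
print.shs_fit <- function(x, ...) {
  cat("<shs_fit>\n")
  if (x$pre_injection) {
    cat(sprintf("  pre-injection frame (nu = 0, A = 0 frozen), chi2_red = %.4g\n",
                x$chi2_red))
  } else {
    est <- sprintf("%s = %.4g +/- %.3g", names(x$theta), x$theta, x$theta_sd)
    cat(" ", paste(est, collapse = ", "), "\n")
    cat(sprintf("  chi2_red = %.4g, converged = %s, n = %d\n",
                x$chi2_red, x$converged, x$n_points))
  }
  invisible(x)
}

#' Predicted model curve of a fit
#'
#' @param fit An `shs_fit` from [fit_frame()].
#' @param q Optional q grid; defaults to the fitted data's grid.
#' @return A tibble with columns `q`, `I`.
#' @export
predict_intensity <- function(fit, q = NULL) {
  q <- q %||% fit$curve$q
  if (fit$pre_injection) {
    out <- dilute_intensity(q, fit$dist, fit$contrast)
  } else {
    out <- model_intensity(q, fit$dist, fit$contrast,
                           interaction = fit$interaction,
                           n_nodes = fit$config$n_nodes, theta = fit$theta)
    out$I <- out$I * fit$scale
  }
  out
}

#' @export
tidy.shs_fit <- function(x, ...) {
  tibble(term = names(x$theta), estimate = unname(x$theta),
         std.error = unname(x$theta_sd))
}

#' @export
glance.shs_fit <- function(x, ...) {
  tibble(chi2_red = x$chi2_red, converged = x$converged, nobs = x$n_points,
         t = x$t, pre_injection = x$pre_injection)
}

fit_series_row <- function(fit, frame = 1L) {
  sd <- setNames(as.list(fit$theta_sd), paste0(fit_par_names(), "_sd"))
  dplyr::bind_cols(
    tibble(frame = frame, t = fit$t),
    as_tibble(as.list(fit$theta)), as_tibble(sd),
    tibble(chi2_red = fit$chi2_red, converged = fit$converged,
           pre_injection = fit$pre_injection)
  )
}

na_fit_row <- function(frame, t, pre_injection = FALSE) {
  vals <- setNames(as.list(rep(NA_real_, 10)),
                   c(fit_par_names(), paste0(fit_par_names(), "_sd")))
  dplyr::bind_cols(tibble(frame = frame, t = t), as_tibble(vals),
                   tibble(chi2_red = NA_real_, converged = FALSE,
                          pre_injection = pre_injection))
}

#' Fit a whole frame series with warm starts
#'
#' Fits every frame of a series; frame k > 1 is initialised at frame
#' k - 1's optimum, so that slowly varying parameter trajectories are
#' tracked without restarts.  Frames acquired before an annotated injection
#' time are treated as pure form-factor frames (`nu = 0`, `A = 0` frozen, no
#' structure parameters fitted).  Individual frame failures are flagged and
#' the series continues.
#'
#' @param series A `saxs_series` (see [as_saxs_series()] /
#'   [read_saxs_series()]).
#' @inheritParams fit_frame
#' @param injection_time Optional time (s) before which frames contain only
#'   unaggregated particles.
#' @return A tibble of class `shs_fit_series`, one row per frame: `frame`,
#'   `t`, the five parameters, their uncertainties, `chi2_red`, `converged`
#'   and `pre_injection`.  Use [tidy()], [glance()], [autoplot()] and
#'   [write_fit_table()] on it.
#' @export
fit_series <- function(series, dist, contrast = contrast_config(),
                       interaction = shs_interaction(),
                       config = fit_config(), injection_time = NULL) {
  stopifnot(inherits(series, "saxs_series"))
  validate_distribution(dist)
  warm <- NULL
  rows <- purrr::map(seq_len(nrow(series)), function(k) {
    crv <- series$data[[k]]
    t_k <- series$t[[k]]
    if (!is.null(injection_time) && t_k < injection_time) {
      return(pre_injection_row(crv, dist, contrast, config, series$frame[[k]],
                               t_k))
    }
    cfg <- config
    if (!is.null(warm)) cfg$init <- warm
    fit <- tryCatch(
      fit_frame(crv, dist, contrast, interaction, cfg),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      warn(sprintf("Frame %d (t = %.4g s) failed: %s",
                   series$frame[[k]], t_k, conditionMessage(fit)))
      return(na_fit_row(series$frame[[k]], t_k))
    }
    if (fit$converged) warm <<- fit$theta
    fit_series_row(fit, frame = series$frame[[k]])
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("shs_fit_series", class(out))
  out
}

pre_injection_row <- function(curve, dist, contrast, config, frame, t) {
  ctx <- fit_context(curve, dist, contrast, shs_interaction(), config)
  Im <- dilute_intensity(ctx$q, dist, contrast)$I
  res <- if (ctx$weighting == "sigma") {
    (Im - ctx$I) / ctx$sigma
  } else {
    log(pmax(Im, 1e-300)) - log(ctx$I)
  }
  row <- na_fit_row(frame, t, pre_injection = TRUE)
  row$nu <- 0
  row$A <- 0
  row$chi2_red <- sum(res^2) / max(1, length(res))
  row$converged <- TRUE
  row
}

#' @export
tidy.shs_fit_series <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::select(x, "frame", "t", dplyr::all_of(fit_par_names())),
    cols = dplyr::all_of(fit_par_names()),
    names_to = "term", values_to = "estimate")
}

#' @export
glance.shs_fit_series <- function(x, ...) {
  tibble(n_frames = nrow(x), n_converged = sum(x$converged),
         n_pre_injection = sum(x$pre_injection),
         median_chi2_red = stats::median(x$chi2_red, na.rm = TRUE))
}

#' Profile-likelihood 1-sigma interval for one parameter
#'
#' Robust alternative to the curvature-based uncertainties: the chosen
#' parameter is stepped away from its optimum while the remaining parameters
#' are re-optimized, and the interval is bounded where the (weighted) cost
#' rises by one estimated residual variance above its minimum
#' (delta chi-squared = 1).  Near-degenerate directions (e.g. the A-D
#' trade-off on a narrow q window) yield correspondingly wide intervals.
#'
#' @param fit An `shs_fit` from [fit_frame()].
#' @param param One of `"nu"`, `"aR_mean"`, `"aR_sd"`, `"A"`, `"D"`.
#' @param max_steps Search budget per side.
#' @return A one-row tibble with `term`, `estimate`, `lower`, `upper`.
#' @export
profile_uncertainty <- function(fit, param, max_steps = 12) {
  stopifnot(inherits(fit, "shs_fit"), param %in% fit_par_names())
  config <- fit$config
  ctx <- fit_context(fit$curve, fit$dist, fit$contrast, fit$interaction,
                     config)
  free <- setdiff(fit_par_names(), param)
  s2 <- fit$chi2_red
  cost_min <- fit$chi2_red * max(1, fit$n_points - length(fit$theta))

  cost_at <- function(value) {
    cfg <- config
    cfg$lower[param] <- value
    cfg$upper[param] <- value
    cfg$init <- fit$theta
    cfg$init[param] <- value
    sub <- run_lm_fit(ctx, fit_init(ctx, cfg), cfg)
    sub$chi2_red * max(1, sub$n_points - length(sub$theta))
  }

  bound_side <- function(direction) {
    step0 <- fit$theta_sd[[param]]
    if (!is.finite(step0) || step0 <= 0) {
      step0 <- 0.05 * (config$upper[[param]] - config$lower[[param]])
    }
    hard <- if (direction > 0) config$upper[[param]] else config$lower[[param]]
    x_prev <- fit$theta[[param]]
    c_prev <- cost_min
    step <- step0
    for (i in seq_len(max_steps)) {
      x <- x_prev + direction * step
      if ((direction > 0 && x >= hard) || (direction < 0 && x <= hard)) {
        x <- hard
      }
      cx <- cost_at(x)
      if (cx >= cost_min + s2) {
        # linear interpolation of the crossing in cost
        frac <- (cost_min + s2 - c_prev) / (cx - c_prev)
        return(x_prev + frac * (x - x_prev))
      }
      if (x == hard) return(hard)
      x_prev <- x
      c_prev <- cx
      step <- step * 2
    }
    x_prev
  }

  tibble(term = param, estimate = fit$theta[[param]],
         lower = bound_side(-1), upper = bound_side(+1))
}
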