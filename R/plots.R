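#' @export
autoplot.saxs_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$q, y = .data$I))
  if (has_sigma(object)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(.data$I - .data$sigma_I, .Machine$double.xmin),
                   ymax = .data$I + .data$sigma_I),
      alpha = 0.3)
  }
  p + ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ (nm^-1)), y = expression(I ~ (cm^-1)))
}

#' @export
autoplot.size_distribution <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$phi)) +
    ggplot2::geom_col(width = min(diff(object$r), na.rm = TRUE) * 0.9,
                      fill = "grey40")
  if ("phi_sd" %in% names(object)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$phi - .data$phi_sd, 0),
                   ymax = .data$phi + .data$phi_sd), width = 0)
  }
  p + ggplot2::labs(x = "r (nm)", y = expression(phi[i]))
}

#' @export
autoplot.shs_fit <- function(object, ...) {
  data <- object$curve
  model <- predict_intensity(object)
  model$what <- "full model"
  layers <- list(model)
  if (!object$pre_injection) {
    dil <- dilute_intensity(data$q, object$dist, object$contrast)
    dil$what <- "form factor only"
    layers <- c(layers, list(dil))
  }
  lines <- dplyr::bind_rows(layers)
  ggplot2::ggplot(data, ggplot2::aes(x = .data$q, y = .data$I)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_line(data = lines,
                       ggplot2::aes(colour = .data$what), linewidth = 0.7) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ (nm^-1)), y = expression(I ~ (cm^-1)),
                  colour = NULL)
}

#' @export
autoplot.shs_fit_series <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "t", dplyr::all_of(fit_par_names())),
    cols = -"t", names_to = "term", values_to = "estimate")
  long$term <- factor(long$term, levels = fit_par_names())
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$estimate)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "t (s)", y = NULL)
}

#' Compare smeared and unsmeared structure factors
#'
#' Convenience plot of [s_shs()] at `R_HS = r_i + aR_mean` against the
#' Gaussian-smeared [smeared_s_shs()] at the same packing fraction,
#' illustrating how spacer-radius polydispersity lowers and broadens the
#' correlation peak at constant `nu`.
#'
#' @inheritParams smeared_s_shs
#' @return A ggplot object.
#' @export
plot_smearing_effect <- function(q, r_i, aR_mean, aR_sd, nu,
                                 interaction = shs_interaction(),
                                 n_nodes = 64) {
  sharp <- s_shs(q, r_i + aR_mean, nu, interaction = interaction)
  sharp$what <- "unsmeared"
  sm <- smeared_s_shs(q, r_i, aR_mean, aR_sd, nu, interaction = interaction,
                      n_nodes = n_nodes)
  sm$what <- "smeared"
  ggplot2::ggplot(dplyr::bind_rows(sharp, sm),
                  ggplot2::aes(x = .data$q, y = .data$S,
                               colour = .data$what)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(q ~ (nm^-1)), y = "S(q)", colour = NULL)
}
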