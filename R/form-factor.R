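#' Sphere form factor
#'
#' Normalised single-particle scattering function of a homogeneous sphere,
#' `P(q, r) = [3 (sin x - x cos x) / x^3]^2` with `x = q r`.  `P(0, r) = 1`
#' and `0 <= P <= 1`; the first zero sits at `q r ~ 4.4934`.
#'
#' @param q Momentum transfer, nm^-1 (vectorised, `q >= 0`).
#' @param r Sphere radius, nm (`r > 0`).
#' @return Dimensionless form-factor values, same length as `q`.
#' @export
#' @examples
#' sphere_form_factor(0, 2.5)        # 1
#' sphere_form_factor(1, 2.5)        # ~0.249
sphere_form_factor <- function(q, r) {
  if (!is.numeric(r) || length(r) != 1 || r <= 0) {
    abort("`r` must be a single positive radius.",
          class = "stickysaxs_domain_error")
  }
  if (any(q < 0)) {
    abort("`q` must be non-negative.", class = "stickysaxs_domain_error")
  }
  x <- q * r
  out <- numeric(length(x))
  small <- x < 1e-4
  out[small] <- (1 - x[small]^2 / 10)^2
  xl <- x[!small]
  out[!small] <- (3 * (sin(xl) - xl * cos(xl)) / xl^3)^2
  out
}

#' Sphere volume
#'
#' @param r Radius, nm (vectorised).
#' @return Volume `(4/3) pi r^3`, nm^3.
#' @export
sphere_volume <- function(r) 4 / 3 * pi * r^3

#' X-ray contrast configuration
#'
#' Scattering-length densities (SLD) of particle and solvent, in nm^-2.  The
#' defaults are the Thomson-scattering SLDs of amorphous silica at a density
#' of 2.2 g/cm^3 and of water, appropriate for a 10 keV X-ray experiment and
#' overridable for other materials or densities.  Absolute volume fractions
#' derived from measured intensities inherit this choice.
#'
#' @param sld_particle Particle SLD, nm^-2.
#' @param sld_solvent Solvent SLD, nm^-2.
#' @return A list of class `contrast_config` with the SLDs and the derived
#'   contrast `drho = sld_particle - sld_solvent` (must be non-zero).
#' @export
#' @examples
#' contrast_config()$drho    # ~9.2e-4 nm^-2 for silica in water
contrast_config <- function(sld_particle = sld_silica(),
                            sld_solvent = sld_water()) {
  drho <- sld_particle - sld_solvent
  if (!is.finite(drho) || drho == 0) {
    abort("Contrast `sld_particle - sld_solvent` must be non-zero.",
          class = "stickysaxs_domain_error")
  }
  structure(list(sld_particle = sld_particle, sld_solvent = sld_solvent,
                 drho = drho),
            class = "contrast_config")
}

R_ELECTRON_NM <- 2.8179403262e-6   # classical electron radius, nm
AVOGADRO <- 6.02214076e23

#' @rdname contrast_config
#' @param density Mass density in g/cm^3.
#' @export
sld_silica <- function(density = 2.2) {
  # SiO2: 30 electrons, 60.0843 g/mol; electrons/nm^3 = rho NA Z / M / 1e21
  e_per_nm3 <- density * AVOGADRO * 30 / 60.0843 / 1e21
  e_per_nm3 * R_ELECTRON_NM
}

#' @rdname contrast_config
#' @export
sld_water <- function(density = 0.9982) {
  e_per_nm3 <- density * AVOGADRO * 10 / 18.0153 / 1e21
  e_per_nm3 * R_ELECTRON_NM
}

#' Discrete sphere-size distribution
#'
#' A histogram of sphere radii with per-bin volume fractions, the container
#' produced by [mcsas_fit()] and [synth_distribution()] and consumed by the
#' intensity models.  The sum of `phi` is the total particle volume fraction.
#'
#' @param r Bin-centre radii, nm; positive and strictly increasing.
#' @param phi Volume fraction per bin (dimensionless, `>= 0`).
#' @param phi_sd Optional per-bin uncertainty on `phi`.
#' @return A tibble of class `size_distribution` with columns `r`, `phi` and
#'   optionally `phi_sd`.
#' @export
size_distribution <- function(r, phi, phi_sd = NULL) {
  r <- as.numeric(r)
  phi <- as.numeric(phi)
  if (length(r) != length(phi) || length(r) < 1) {
    abort("`r` and `phi` must be non-empty and of equal length.")
  }
  if (any(!is.finite(r)) || any(r <= 0) || any(diff(r) <= 0)) {
    abort("`r` must be positive, finite and strictly increasing.",
          class = "stickysaxs_domain_error")
  }
  if (any(!is.finite(phi)) || any(phi < 0)) {
    abort("`phi` must be finite and non-negative.",
          class = "stickysaxs_domain_error")
  }
  out <- tibble(r = r, phi = phi)
  if (!is.null(phi_sd)) out$phi_sd <- as.numeric(phi_sd)
  class(out) <- c("size_distribution", class(out))
  out
}

validate_distribution <- function(dist) {
  if (!is.data.frame(dist) || !all(c("r", "phi") %in% names(dist))) {
    abort("`dist` must be a data frame with columns `r` and `phi`.")
  }
  invisible(dist)
}

#' Summary statistics of a size distribution
#'
#' @param dist A [size_distribution()].
#' @return A one-row tibble with the volume-weighted mean radius
#'   `mean_radius = sum(phi r) / sum(phi)` (nm) and the total volume fraction
#'   `total_phi = sum(phi)`.
#' @export
#' @examples
#' distribution_summary(size_distribution(2.5, 4e-4))
distribution_summary <- function(dist) {
  validate_distribution(dist)
  tot <- sum(dist$phi)
  tibble(mean_radius = sum(dist$phi * dist$r) / tot, total_phi = tot)
}

#' Dilute-limit (structure-factor-free) model intensity
#'
#' Absolute intensity of a non-interacting polydisperse sphere population:
#' `I(q) = drho^2 sum_i phi_i V(r_i) P(q, r_i)`, the model appropriate for a
#' well-suspended, unaggregated particle population whose curve flattens out
#' at low q.  With drho in nm^-2, V in nm^3 and the 1e7 nm/cm conversion the
#' result is in absolute units, cm^-1.
#'
#' @param q Momentum transfer grid, nm^-1.
#' @param dist A [size_distribution()].
#' @param contrast A [contrast_config()].
#' @return A tibble with columns `q` (nm^-1) and `I` (cm^-1).
#' @export
dilute_intensity <- function(q, dist, contrast = contrast_config()) {
  validate_distribution(dist)
  I <- drop(ff_matrix(q, dist$r) %*% dist$phi) * contrast$drho^2 * 1e7
  tibble(q = as.numeric(q), I = I)
}

# V(r_j) P(q_i r_j) matrix, nq x nbins
ff_matrix <- function(q, r) {
  vapply(r, function(rj) sphere_volume(rj) * sphere_form_factor(q, rj),
         numeric(length(q)))
}
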