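#' Bound-protein concentration from the composite weight fraction
#'
#' If a fraction `w_protein` of the dried, washed composite solid is
#' protein, and the co-precipitated particle mass concentration is
#' `c_silica`, the protein mass bound per litre is
#' `x = w c / (1 - w)`, i.e. the amount that makes the solid `w` protein by
#' weight.  For w = 0.327 and c = 0.8737 g/L this gives 0.4245 g/L.
#'
#' @param w_protein Protein weight fraction of the composite solid, in
#'   `[0, 1)`.
#' @param c_silica Particle (silica) mass concentration, g/L.
#' @return Bound protein concentration, g/L.
#' @export
#' @examples
#' bound_protein_concentration(0.327, 0.8737)  # 0.4245
bound_protein_concentration <- function(w_protein, c_silica) {
  if (any(w_protein < 0 | w_protein >= 1)) {
    abort("`w_protein` must lie in [0, 1).", class = "stickysaxs_domain_error")
  }
  if (any(c_silica <= 0)) {
    abort("`c_silica` must be positive.", class = "stickysaxs_domain_error")
  }
  w_protein * c_silica / (1 - w_protein)
}

#' Inverse of [bound_protein_concentration()]
#'
#' @param x Bound protein concentration, g/L.
#' @param c_silica Particle mass concentration, g/L.
#' @return The protein weight fraction of the composite solid,
#'   `x / (x + c_silica)`.
#' @export
protein_weight_fraction <- function(x, c_silica) x / (x + c_silica)

#' Molecular number density from a mass concentration
#'
#' @param c Mass concentration, g/L.
#' @param mw Molecular weight, g/mol (14313 g/mol for hen egg-white
#'   lysozyme).
#' @return Number density, molecules per litre (`c / mw * N_A`).
#' @export
#' @examples
#' number_density(0.4245, 14313)  # ~1.79e19 per litre
number_density <- function(c, mw) {
  if (any(mw <= 0)) {
    abort("`mw` must be positive.", class = "stickysaxs_domain_error")
  }
  c / mw * AVOGADRO
}

#' Particle number density from a volume distribution
#'
#' Converts a volume-fraction size distribution into a number density given
#' the particle material density and the particle mass concentration: bin i
#' holds mass `c phi_i / sum(phi)` per litre, divided by the single-particle
#' mass `rho V(r_i)`.
#'
#' @param dist A [size_distribution()].
#' @param rho Particle material density, g/cm^3 (default 2.2 for amorphous
#'   silica).
#' @param c Particle mass concentration, g/L.
#' @return Number density, particles per litre.
#' @export
particle_number_density <- function(dist, rho = 2.2, c) {
  validate_distribution(dist)
  if (rho <= 0 || any(c <= 0)) {
    abort("`rho` and `c` must be positive.", class = "stickysaxs_domain_error")
  }
  # V in nm^3 -> particle mass rho * V * 1e-21 g
  frac <- dist$phi / sum(dist$phi)
  sum(c * frac / (rho * sphere_volume(dist$r) * 1e-21))
}

#' Hard-sphere radius estimate from the correlation-peak position
#'
#' The approximate relation `2 R_HS ~ 2 pi / q_max` for (sticky) hard-sphere
#' correlations, i.e. `R_HS = pi / q_max`.  For polydisperse, strongly
#' adhesive systems this heuristic is only accurate to roughly 15 %; the full
#' structure-factor fit should be preferred.
#'
#' @param q_max Position of the correlation peak, nm^-1.
#' @return Estimated hard-sphere radius, nm.
#' @export
#' @examples
#' peak_radius_estimate(0.9)  # ~3.49 nm
peak_radius_estimate <- function(q_max) {
  if (any(q_max <= 0)) {
    abort("`q_max` must be positive.", class = "stickysaxs_domain_error")
  }
  pi / q_max
}
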