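# Independent oracles and small fixtures shared across test files.

# Percus-Yevick hard-sphere structure factor, Ashcroft-Lekner closed form.
# Coded independently of the package's sticky-hard-sphere kernel.
py_structure_factor <- function(q, R, eta) {
  k <- 2 * q * R
  a <- (1 + 2 * eta)^2 / (1 - eta)^4
  b <- -6 * eta * (1 + eta / 2)^2 / (1 - eta)^4
  c <- eta * a / 2
  G <- a * (sin(k) - k * cos(k)) / k^2 +
    b * (2 * k * sin(k) + (2 - k^2) * cos(k) - 2) / k^3 +
    c * (-k^4 * cos(k) +
           4 * ((3 * k^2 - 6) * cos(k) + (k^3 - 6 * k) * sin(k) + 6)) / k^5
  1 / (1 + 24 * eta * G / k)
}

# Sphere form factor through the spherical Bessel function j1 expressed via
# besselJ (order 3/2), an implementation path independent of the package's
# sin/cos closed form.
bessel_sphere_ff <- function(q, r) {
  x <- q * r
  j1 <- sqrt(pi / (2 * x)) * besselJ(x, 3 / 2)
  (3 * j1 / x)^2
}

# Location of the correlation-peak maximum of a (q, S) tibble, restricted to
# a window so the low-q adhesive rise is not mistaken for the peak.
peak_location <- function(sf, window = c(0.3, 3)) {
  sel <- sf$q >= window[1] & sf$q <= window[2]
  sf$q[sel][which.max(sf$S[sel])]
}

tiny_dist <- function() synth_distribution(n_bins = 8)

theta_ref <- function() {
  c(nu = 0.454, aR_mean = 0.93, aR_sd = 0.533, A = 0.0437, D = 2.37)
}
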