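#' Construct a reduced 1D SAXS curve
#'
#' A scattering curve is a tibble with columns `q` (momentum transfer,
#' nm^-1), `I` (absolute intensity, cm^-1) and optionally `sigma_I` (1-sigma
#' intensity uncertainty, cm^-1), carrying an optional acquisition timestamp
#' `t` (seconds) as an attribute.  All model and fitting functions in the
#' package accept such a tibble (or any data frame with these columns).
#'
#' @param q Numeric vector of momentum transfer values, nm^-1.  Must be
#'   strictly increasing and positive, with at least 10 points.
#' @param I Numeric vector of absolute intensities, cm^-1.
#' @param sigma_I Optional numeric vector of 1-sigma uncertainties, cm^-1
#'   (all positive).
#' @param t Optional acquisition timestamp in seconds.
#'
#' @return A tibble of class `saxs_curve` with columns `q`, `I` and, when
#'   supplied, `sigma_I`.
#' @export
#' @examples
#' q <- seq(0.05, 4.5, length.out = 50)
#' scattering_curve(q, exp(-q^2))
scattering_curve <- function(q, I, sigma_I = NULL, t = NULL) {
  out <- tibble(q = as.numeric(q), I = as.numeric(I))
  if (!is.null(sigma_I) && !all(is.na(sigma_I))) {
    out$sigma_I <- as.numeric(sigma_I)
  }
  out <- new_saxs_curve(out, t = t)
  validate_curve(out)
  out
}

new_saxs_curve <- function(x, t = NULL) {
  x <- as_tibble(x)
  class(x) <- c("saxs_curve", class(x))
  attr(x, "t") <- if (is.null(t)) NA_real_ else as.numeric(t)
  x
}

#' Timestamp of a scattering curve
#'
#' @param curve A curve as returned by [scattering_curve()] or
#'   [read_saxs_curve()].
#' @return The acquisition time in seconds, or `NA` if unknown.
#' @export
curve_time <- function(curve) {
  t <- attr(curve, "t", exact = TRUE)
  if (is.null(t)) NA_real_ else t
}

validate_curve <- function(curve, arg = "curve") {
  if (!is.data.frame(curve) || !all(c("q", "I") %in% names(curve))) {
    abort(sprintf("`%s` must be a data frame with columns `q` and `I`.", arg))
  }
  q <- curve$q
  if (length(q) < 10) {
    abort(sprintf("`%s` must have at least 10 points, got %d.", arg, length(q)),
          class = "stickysaxs_malformed_input")
  }
  if (anyNA(q) || any(!is.finite(q)) || any(q <= 0)) {
    abort(sprintf("`%s$q` must be finite and positive.", arg))
  }
  if (any(diff(q) <= 0)) {
    abort(sprintf("`%s$q` must be strictly increasing.", arg))
  }
  if (any(!is.finite(curve$I))) {
    abort(sprintf("`%s$I` must be finite.", arg))
  }
  if ("sigma_I" %in% names(curve)) {
    s <- curve$sigma_I
    if (length(s) != length(q) || any(!is.finite(s)) || any(s <= 0)) {
      abort(sprintf("`%s$sigma_I` must be finite, positive and match `q`.", arg))
    }
  }
  invisible(curve)
}

has_sigma <- function(curve) "sigma_I" %in% names(curve)

#' Convert momentum transfer between nm^-1 and Angstrom^-1
#'
#' The package-internal unit is nm^-1 throughout.  Conversion is involutive:
#' `convert_q(convert_q(q, "nm^-1", "A^-1"), "A^-1", "nm^-1")` is the
#' identity.
#'
#' @param q Numeric vector of momentum transfer values.
#' @param from,to Units, one of `"nm^-1"` or `"A^-1"`.
#' @return Numeric vector in the target unit.
#' @export
#' @examples
#' convert_q(1, "A^-1", "nm^-1")  # 10 nm^-1
convert_q <- function(q, from = c("nm^-1", "A^-1"), to = c("nm^-1", "A^-1")) {
  from <- match.arg(from)
  to <- match.arg(to)
  factor <- c("nm^-1" = 1, "A^-1" = 10)
  q * factor[[from]] / factor[[to]]
}

#' Bundle scattering curves into a time-ordered frame series
#'
#' A frame series is a nested tibble with one row per frame: an integer
#' `frame` index, a timestamp `t` (seconds) and a `data` list-column holding
#' the individual curves.  All frames must share one q grid (relative
#' tolerance 1e-9).  Curves without timestamps are assigned
#' `frame index * frame_interval`.
#'
#' @param curves A list of curves (see [scattering_curve()]).
#' @param frame_interval Spacing in seconds used when timestamps are absent.
#'   The default 0.05 s matches a 20 frames-per-second acquisition.
#' @param labels Optional character labels (e.g. file names) used in error
#'   messages and for ordering when timestamps are absent.
#'
#' @return A tibble of class `saxs_series` with columns `frame`, `t`, `data`.
#' @export
as_saxs_series <- function(curves, frame_interval = 0.05, labels = NULL) {
  stopifnot(is.list(curves), length(curves) >= 1)
  labels <- labels %||% sprintf("curve %d", seq_along(curves))
  purrr::walk2(curves, labels, function(cv, lb) validate_curve(cv, arg = lb))

  q_ref <- curves[[1]]$q
  purrr::walk2(curves, labels, function(cv, lb) {
    if (length(cv$q) != length(q_ref) ||
        any(abs(cv$q - q_ref) > 1e-9 * pmax(abs(q_ref), 1e-300))) {
      abort(sprintf("q grid of '%s' does not match the first frame.", lb),
            class = "stickysaxs_grid_mismatch")
    }
  })

  t <- purrr::map_dbl(curves, curve_time)
  if (anyNA(t)) {
    t <- (seq_along(curves) - 1) * frame_interval
  } else {
    ord <- order(t)
    curves <- curves[ord]
    t <- t[ord]
    if (any(diff(t) <= 0)) {
      abort("Frame timestamps must be strictly increasing.")
    }
  }

  out <- tibble(
    frame = seq_along(curves),
    t = t,
    data = purrr::map2(curves, t, function(cv, ti) {
      attr(cv, "t") <- ti
      cv
    })
  )
  class(out) <- c("saxs_series", class(out))
  attr(out, "frame_interval") <- frame_interval
  out
}

series_qgrid <- function(series) series$data[[1]]$q

#' @export
print.saxs_curve <- function(x, ...) {
  t <- curve_time(x)
  cat(sprintf("<saxs_curve: %d points, q %.4g-%.4g nm^-1%s%s>\n",
              nrow(x), min(x$q), max(x$q),
              if (has_sigma(x)) ", with sigma_I" else "",
              if (is.na(t)) "" else sprintf(", t = %.4g s", t)))
  NextMethod()
}

#' @export
print.saxs_series <- function(x, ...) {
  cat(sprintf("<saxs_series: %d frames, t %.4g-%.4g s, %d q points>\n",
              nrow(x), min(x$t), max(x$t), length(series_qgrid(x))))
  NextMethod()
}
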