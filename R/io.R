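#' Read a reduced 1D SAXS curve from an ASCII file
#'
#' Reads plain-text reduced curves as produced by beamline pipelines: two or
#' three numeric columns (q, I and optionally sigma_I), comment lines
#' starting with `#` or `;`, whitespace- or comma-delimited.  Rows containing
#' non-finite values are dropped with a message.
#'
#' @param path Path to the file.
#' @param q_unit Unit of the q column in the file; values in Angstrom^-1 are
#'   converted to the canonical nm^-1 on input.
#' @param columns Column order in the file; a permutation of
#'   `c("q", "I", "sigma_I")` (the third entry is optional).
#' @param comment Characters that introduce comment lines.
#' @param t Optional acquisition timestamp (seconds); when `NULL`, a
#'   `# t[s] <value>` comment line (as written by [write_saxs_curve()]) is
#'   honoured.
#'
#' @return A [scattering_curve()] tibble with q in nm^-1.
#' @export
read_saxs_curve <- function(path, q_unit = c("nm^-1", "A^-1"),
                            columns = c("q", "I", "sigma_I"),
                            comment = c("#", ";"), t = NULL) {
  q_unit <- match.arg(q_unit)
  if (!file.exists(path)) {
    abort(sprintf("Cannot read '%s': no such file.", path),
          class = "stickysaxs_io_error")
  }
  t <- t %||% read_t_header(path)
  lines <- readLines(path, warn = FALSE)
  comment_re <- sprintf("^\\s*[%s]", paste(comment, collapse = ""))
  lines <- lines[!grepl(comment_re, lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort(sprintf("'%s' contains no data rows.", path),
          class = "stickysaxs_malformed_input")
  }
  delim_comma <- grepl(",", lines[[1]], fixed = TRUE)
  fields <- strsplit(trimws(lines), if (delim_comma) "\\s*,\\s*" else "\\s+")
  ncol <- min(lengths(fields))
  if (ncol < 2) {
    abort(sprintf("'%s' must have at least 2 numeric columns.", path),
          class = "stickysaxs_malformed_input")
  }
  ncol <- min(ncol, length(columns))
  mat <- suppressWarnings(
    vapply(seq_len(ncol), function(j) {
      as.numeric(vapply(fields, `[[`, character(1), j))
    }, numeric(length(fields)))
  )
  colnames(mat) <- columns[seq_len(ncol)]

  keep <- rowSums(!is.finite(mat)) == 0
  if (any(!keep)) {
    message(sprintf("read_saxs_curve: dropped %d row(s) with non-finite values from '%s'.",
                    sum(!keep), basename(path)))
    mat <- mat[keep, , drop = FALSE]
  }
  if (nrow(mat) < 10) {
    abort(sprintf("'%s' has fewer than 10 valid data rows.", path),
          class = "stickysaxs_malformed_input")
  }
  df <- as_tibble(as.data.frame(mat))
  df <- df[order(df$q), , drop = FALSE]
  q <- convert_q(df$q, from = q_unit, to = "nm^-1")
  scattering_curve(q, df$I, sigma_I = df[["sigma_I"]], t = t)
}

#' Write a scattering curve to an ASCII file
#'
#' Writes a whitespace-delimited file with a `#` header naming the units
#' (q in nm^-1, I in cm^-1).  The round trip through [read_saxs_curve()]
#' preserves values to better than 12 significant digits.
#'
#' @param curve A curve (see [scattering_curve()]); `I` must be finite.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_saxs_curve <- function(curve, path) {
  validate_curve(curve)
  with_sigma <- has_sigma(curve)
  header <- if (with_sigma) {
    "# q[nm^-1] I[cm^-1] sigma_I[cm^-1]"
  } else {
    "# q[nm^-1] I[cm^-1]"
  }
  t <- curve_time(curve)
  lines <- c(
    if (!is.na(t)) sprintf("# t[s] %.15g", t),
    header,
    if (with_sigma) {
      sprintf("%.15g %.15g %.15g", curve$q, curve$I, curve$sigma_I)
    } else {
      sprintf("%.15g %.15g", curve$q, curve$I)
    }
  )
  tryCatch(writeLines(lines, path),
           error = function(e) abort(sprintf("Cannot write '%s': %s", path,
                                             conditionMessage(e)),
                                     class = "stickysaxs_io_error"))
  invisible(path)
}

#' Read a frame series from files or a directory
#'
#' All files must share one q grid (relative tolerance 1e-9); a mismatch is
#' reported with the offending file name.  Frames are ordered by the `t`
#' timestamps parsed from a `# t[s]` header line when present, otherwise by
#' file order with timestamps `index * frame_interval`.
#'
#' @param paths Character vector of file paths, or a single directory whose
#'   files are read in lexicographic order.
#' @param pattern Optional regular expression selecting files when `paths`
#'   is a directory.
#' @inheritParams read_saxs_curve
#' @inheritParams as_saxs_series
#' @return A `saxs_series` tibble (see [as_saxs_series()]).
#' @export
read_saxs_series <- function(paths, q_unit = c("nm^-1", "A^-1"),
                             columns = c("q", "I", "sigma_I"),
                             comment = c("#", ";"), frame_interval = 0.05,
                             pattern = NULL) {
  q_unit <- match.arg(q_unit)
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- sort(list.files(paths, full.names = TRUE, pattern = pattern))
  }
  if (length(paths) == 0) {
    abort("No input files.", class = "stickysaxs_io_error")
  }
  curves <- purrr::map(paths, function(p) {
    read_saxs_curve(p, q_unit = q_unit, columns = columns, comment = comment)
  })
  as_saxs_series(curves, frame_interval = frame_interval,
                 labels = basename(paths))
}

read_t_header <- function(path) {
  lines <- readLines(path, n = 5, warn = FALSE)
  hit <- grep("^\\s*[#;]\\s*t\\[s\\]", lines, value = TRUE)
  if (length(hit) == 0) return(NULL)
  as.numeric(sub("^\\s*[#;]\\s*t\\[s\\]\\s*", "", hit[[1]]))
}

#' Write a fit-result table
#'
#' Serialises per-frame fit results (see [fit_series()]) as CSV with a fixed
#' header: timestamp, the five model parameters, their 1-sigma uncertainties,
#' the reduced chi-squared and the convergence flag.
#'
#' @param results A `shs_fit_series` tibble from [fit_series()], or a single
#'   fit from [fit_frame()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fit_table <- function(results, path) {
  if (inherits(results, "shs_fit")) results <- fit_series_row(results)
  cols <- c("frame", "t", fit_par_names(), paste0(fit_par_names(), "_sd"),
            "chi2_red", "converged")
  missing <- setdiff(cols, names(results))
  if (length(missing) > 0) {
    abort(sprintf("Fit table is missing columns: %s.",
                  paste(missing, collapse = ", ")))
  }
  readr::write_csv(results[cols], path)
  invisible(path)
}

#' Read back a fit-result table written by [write_fit_table()]
#'
#' @param path Path to the CSV file.
#' @return A tibble with one row per frame.
#' @export
read_fit_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  class(out) <- c("shs_fit_series", class(out))
  out
}
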