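#' Construct a 1D scattering curve
#'
#' A `saxs_curve` holds a measured or simulated small-angle scattering
#' profile: momentum transfer `q` (1/Angstrom, strictly increasing and
#' positive), intensity `I(q)` in arbitrary units and, optionally, a
#' 1-sigma error per point.  When errors are absent, downstream fits fall
#' back to unit weights.
#'
#' @param q numeric vector of momentum transfer values, 1/Angstrom,
#'   strictly increasing, all positive.
#' @param intensity numeric vector of intensities, same length as `q`.
#' @param sigma optional numeric vector of 1-sigma errors, same length as
#'   `q`, all positive.  `NULL` means no error model.
#' @param label free-text label carried through reports.
#' @return An object of class `saxs_curve`: a list with elements `q`,
#'   `intensity`, `sigma` (possibly `NULL`) and `label`.
#' @examples
#' sc <- scatter_curve(q = c(0.01, 0.02, 0.03), intensity = c(100, 99, 97))
#' sc
#' @export
scatter_curve <- function(q, intensity, sigma = NULL, label = "") {
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  if (length(q) == 0) stop("empty curve: need at least 1 point")
  if (length(q) != length(intensity))
    stop("q and intensity must have equal length")
  if (any(!is.finite(q)) || any(!is.finite(intensity)))
    stop("q and intensity must be finite")
  if (any(q <= 0))
    stop("all q must be positive (trim the zero-angle region on read)")
  if (is.unsorted(q, strictly = TRUE))
    stop("non-monotonic q: q must be strictly increasing")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q))
      stop("sigma must match q in length")
    if (any(!is.finite(sigma)) || any(sigma <= 0))
      stop("sigma must be finite and positive")
  }
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 label = as.character(label)[1]),
            class = "saxs_curve")
}

#' @export
print.saxs_curve <- function(x, ...) {
  cat(sprintf("saxs_curve%s: %d points, q in [%.4g, %.4g] 1/A, %s\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) "no errors" else "with errors"))
  invisible(x)
}

#' @export
length.saxs_curve <- function(x) length(x$q)

#' @export
as.data.frame.saxs_curve <- function(x, ...) {
  d <- data.frame(q = x$q, intensity = x$intensity)
  if (!is.null(x$sigma)) d$sigma <- x$sigma
  d
}

## Effective weights for error-weighted fits: 1/sigma^2, or unit weights
## when the curve carries no error model.
curve_weights <- function(curve) {
  if (is.null(curve$sigma)) rep(1, length(curve$q)) else 1 / curve$sigma^2
}

curve_sigma_or_unit <- function(curve) {
  if (is.null(curve$sigma)) rep(1, length(curve$q)) else curve$sigma
}

#' Read a 3-column scattering data file
#'
#' Reads the de facto SAXS exchange format: whitespace-separated columns
#' `q I [sigma]`, with `#`-prefixed comment lines.  Rows with non-finite
#' or non-numeric values are dropped with a message; points at q <= 0
#' (zero-angle region, beamstop artefacts) are trimmed.
#'
#' @param path path to the file.
#' @param q_unit `"A"` (default) if q is in 1/Angstrom, `"nm"` if in
#'   1/nm (converted to 1/Angstrom on read by dividing by 10).
#' @return A [scatter_curve()] with `sigma = NULL` when the file has only
#'   two usable columns.
#' @export
read_dat <- function(path, q_unit = c("A", "nm")) {
  q_unit <- match.arg(q_unit)
  if (!file.exists(path)) stop("unreadable file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "[ \t,]+")
  ncol_row <- vapply(fields, length, integer(1))
  has_sigma <- all(ncol_row >= 3) && length(ncol_row) > 0
  parse_row <- function(f) {
    v <- suppressWarnings(as.numeric(f[seq_len(min(3, length(f)))]))
    c(v, rep(NA_real_, 3 - length(v)))
  }
  m <- do.call(rbind, lapply(fields, parse_row))
  if (is.null(m)) stop("no data rows in ", path)
  keep <- is.finite(m[, 1]) & is.finite(m[, 2]) & m[, 1] > 0
  if (has_sigma) keep <- keep & is.finite(m[, 3]) & m[, 3] > 0
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message("read_dat: dropped ", n_drop, " unusable row(s) from ", path)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 5) stop("fewer than 5 usable rows in ", path)
  q <- m[, 1]
  if (q_unit == "nm") q <- q / 10
  if (is.unsorted(q, strictly = TRUE))
    stop("non-monotonic q in ", path)
  scatter_curve(q, m[, 2], sigma = if (has_sigma) m[, 3] else NULL,
                label = basename(path))
}

#' Write a scattering curve to a 3-column data file
#'
#' Writes `q I sigma` (or `q I` when the curve has no errors) with 6+
#' significant digits so that [read_dat()] round-trips the curve.
#'
#' @param curve a [scatter_curve()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_dat <- function(curve, path) {
  stopifnot(inherits(curve, "saxs_curve"))
  if (length(curve$q) == 0) stop("empty curve")
  hdr <- sprintf("# saxcraft scattering curve%s",
                 if (nzchar(curve$label)) paste0(": ", curve$label) else "")
  fmt <- function(v) formatC(v, digits = 8, format = "g")
  if (is.null(curve$sigma)) {
    body <- paste(fmt(curve$q), fmt(curve$intensity))
  } else {
    body <- paste(fmt(curve$q), fmt(curve$intensity), fmt(curve$sigma))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

## Linear interpolation of a curve's intensity onto a new q grid.
## Points outside the source range yield NA (callers drop them with a log).
interp_intensity <- function(curve, q_new) {
  stats::approx(curve$q, curve$intensity, xout = q_new, rule = 1)$y
}
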