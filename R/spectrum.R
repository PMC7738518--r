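#' Construct a spectrum
#'
#' A spectrum is the common currency of all optical operations in this
#' package: a strictly increasing wavelength grid (nm) paired with
#' non-negative intensities (absorbance or fluorescence, arbitrary units).
#'
#' @param wavelength_nm Numeric vector of wavelengths in nm, strictly
#'   increasing.
#' @param value Numeric vector of intensities, same length, finite and
#'   non-negative.
#' @param label Free-text label carried along for provenance.
#' @return An object of class `"spectrum"`: a list with elements
#'   `wavelength_nm`, `value` and `label`.
#' @examples
#' s <- spectrum(400:500, exp(-((400:500) - 445)^2 / 200))
#' redmost_peak(s)
#' @export
spectrum <- function(wavelength_nm, value, label = "") {
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  if (length(wavelength_nm) != length(value)) {
    stop("wavelength_nm and value must have the same length")
  }
  if (length(wavelength_nm) == 0L) stop("empty spectrum")
  if (!all(is.finite(wavelength_nm)) || !all(is.finite(value))) {
    stop("wavelengths and values must all be finite")
  }
  if (any(diff(wavelength_nm) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (any(value < 0)) stop("intensities must be non-negative")
  structure(
    list(wavelength_nm = wavelength_nm, value = value, label = as.character(label)[1L]),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf(
    "<spectrum%s: %d points, %.1f-%.1f nm, max %.4g>\n",
    if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
    length(x$wavelength_nm), min(x$wavelength_nm), max(x$wavelength_nm),
    max(x$value)
  ))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength_nm, value = x$value)
}

is_spectrum <- function(x) inherits(x, "spectrum")

#' Wavelength of the red-most local maximum
#'
#' Finds the largest-wavelength interior local maximum of a spectrum and
#' refines its position by fitting a parabola through the three samples
#' around the discrete maximum.  This is the quantity the Soret-region
#' deconvolution reports for each spectral form: the lowest-energy
#' absorption peak.
#'
#' @param x A [spectrum()].
#' @return The refined peak wavelength in nm, or `NA_real_` (with attribute
#'   `no_peak = TRUE`) when the spectrum is monotone and has no interior
#'   maximum.
#' @export
redmost_peak <- function(x) {
  stopifnot(is_spectrum(x))
  w <- x$wavelength_nm
  v <- x$value
  n <- length(v)
  if (n < 3L) stop("need at least 3 points to locate a peak")
  i <- 2:(n - 1L)
  is_max <- v[i] >= v[i - 1L] & v[i] >= v[i + 1L] &
    (v[i] > v[i - 1L] | v[i] > v[i + 1L])
  if (!any(is_max)) {
    return(structure(NA_real_, no_peak = TRUE))
  }
  k <- max(i[is_max])
  # parabola through the 3 surrounding samples (grid may be non-uniform)
  ws <- w[(k - 1L):(k + 1L)]
  vs <- v[(k - 1L):(k + 1L)]
  d <- ws - ws[2L]
  fit <- stats::lm.fit(cbind(1, d, d^2), vs)
  b <- fit$coefficients
  if (!is.finite(b[3L]) || b[3L] >= 0) return(w[k])
  vertex <- ws[2L] - b[2L] / (2 * b[3L])
  # keep the refinement inside the bracketing interval
  max(min(vertex, ws[3L]), ws[1L])
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; values are clipped at zero.  Extrapolation outside
#' the source range is refused.
#'
#' @param x A [spectrum()].
#' @param grid Target wavelengths (nm), strictly increasing, inside the
#'   range of `x`.
#' @return A [spectrum()] on `grid`.
#' @export
resample <- function(x, grid) {
  stopifnot(is_spectrum(x))
  grid <- as.numeric(grid)
  if (length(grid) == 0L) stop("empty target grid")
  if (min(grid) < min(x$wavelength_nm) || max(grid) > max(x$wavelength_nm)) {
    stop("target grid extends outside the source range (extrapolation refused)")
  }
  v <- stats::approx(x$wavelength_nm, x$value, xout = grid, method = "linear")$y
  spectrum(grid, pmax(v, 0), label = x$label)
}

#' Restrict a spectrum to a wavelength window
#'
#' @param x A [spectrum()].
#' @param window Length-2 numeric `(lo, hi)` in nm.
#' @return A [spectrum()] containing the samples with `lo <= w <= hi`.
#' @export
crop_spectrum <- function(x, window) {
  stopifnot(is_spectrum(x), length(window) == 2L, window[1L] < window[2L])
  keep <- x$wavelength_nm >= window[1L] & x$wavelength_nm <= window[2L]
  if (sum(keep) < 3L) stop("window not covered by the spectrum")
  spectrum(x$wavelength_nm[keep], x$value[keep], label = x$label)
}

#' Read a two-column spectrum file
#'
#' Accepts CSV, TSV or whitespace-separated text with columns
#' (wavelength_nm, value); `#`-prefixed comment lines and an optional header
#' row are allowed.
#'
#' @param path File path.
#' @param label Label for the returned spectrum; defaults to the file name.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no data in ", path)
  sep <- if (grepl(",", lines[1L])) "," else if (grepl("\t", lines[1L])) "\t" else ""
  split1 <- strsplit(trimws(lines[1L]), if (sep == "") "\\s+" else sep)[[1L]]
  header <- any(is.na(suppressWarnings(as.numeric(split1))))
  df <- utils::read.table(
    text = lines, sep = sep, header = header,
    comment.char = "#", strip.white = TRUE
  )
  if (ncol(df) < 2L) stop("expected two columns (wavelength_nm, value) in ", path)
  spectrum(df[[1L]], df[[2L]], label = label)
}

#' Write a spectrum to a two-column CSV file
#'
#' @param x A [spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path) {
  stopifnot(is_spectrum(x))
  con <- file(path, "w")
  on.exit(close(con))
  if (nzchar(x$label)) writeLines(paste0("# ", x$label), con)
  writeLines("wavelength_nm,value", con)
  writeLines(paste(format(x$wavelength_nm, trim = TRUE, digits = 15),
                   format(x$value, trim = TRUE, digits = 15), sep = ","), con)
  invisible(path)
}
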