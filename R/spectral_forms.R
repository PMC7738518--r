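#' @name pigments
#' @title Pigment vocabulary
#' @description The pigment species handled by the deconvolution:
#' chlorophylls a and b and the three xanthophylls (lutein, violaxanthin,
#' neoxanthin) bound by LHC-family complexes.  Loroxanthin is deliberately
#' absent: LHCSR subunits do not bind it even when it is present in the
#' refolding pigment mix.
NULL

PIGMENTS <- c("chl_a", "chl_b", "lutein", "violaxanthin", "neoxanthin")
CAROTENOIDS <- c("lutein", "violaxanthin", "neoxanthin")

#' Carotenoid pigment names
#' @return Character vector of the xanthophyll pigment identifiers.
#' @export
carotenoid_pigments <- function() CAROTENOIDS

# sum-of-Gaussians band evaluation; fwhm parameterisation
gauss_bands <- function(grid, bands, shift = 0) {
  v <- numeric(length(grid))
  for (i in seq_len(nrow(bands))) {
    c0 <- bands$center_nm[i] + shift
    w <- bands$fwhm_nm[i]
    v <- v + bands$height[i] * exp(-4 * log(2) * (grid - c0)^2 / w^2)
  }
  v
}

# analytic integral of the band sum over the whole line
bands_area <- function(bands) {
  sum(bands$height * bands$fwhm_nm) * sqrt(pi / (4 * log(2)))
}

#' Construct a pigment spectral form
#'
#' A spectral form is the parametric absorption shape of one pigment
#' population, modelled as a sum of Gaussian bands and shiftable rigidly
#' along the wavelength axis.  The red-most Soret maximum of the zero-shift
#' form (`reference_peak_nm`) is computed at construction from a dense
#' evaluation, so it is self-consistent with [evaluate_form()] by
#' definition.
#'
#' @param pigment One of `"chl_a"`, `"chl_b"`, `"lutein"`,
#'   `"violaxanthin"`, `"neoxanthin"`.
#' @param bands Data frame with columns `center_nm` (380-560 nm),
#'   `fwhm_nm` (> 0) and `height` (> 0); one row per Gaussian band.
#' @return An object of class `"spectral_form"` with fields `pigment`,
#'   `bands`, `reference_peak_nm` and `reference_peak_value` (height of the
#'   red-most peak of the area-normalised zero-shift form).
#' @export
spectral_form <- function(pigment, bands) {
  pigment <- match.arg(pigment, PIGMENTS)
  bands <- as.data.frame(bands)
  req <- c("center_nm", "fwhm_nm", "height")
  if (!all(req %in% names(bands))) {
    stop("bands needs columns center_nm, fwhm_nm, height")
  }
  if (nrow(bands) < 1L) stop("at least one band is required")
  if (any(bands$center_nm < 380 | bands$center_nm > 560)) {
    stop("band centers must lie within 380-560 nm")
  }
  if (any(bands$fwhm_nm <= 0) || any(bands$height <= 0)) {
    stop("band fwhm and height must be positive")
  }
  pad <- 2 * max(bands$fwhm_nm)
  dense <- seq(min(bands$center_nm) - pad, max(bands$center_nm) + pad, by = 0.01)
  v <- gauss_bands(dense, bands, 0)
  pk <- redmost_peak(spectrum(dense, v))
  if (is.na(pk)) stop("band set has no interior red-most maximum")
  area <- bands_area(bands)
  peak_value <- gauss_bands(pk, bands, 0) / area
  structure(
    list(
      pigment = pigment, bands = bands,
      reference_peak_nm = as.numeric(pk),
      reference_peak_value = as.numeric(peak_value)
    ),
    class = "spectral_form"
  )
}

#' @export
print.spectral_form <- function(x, ...) {
  cat(sprintf(
    "<spectral_form %s: %d band(s), red-most peak %.2f nm>\n",
    x$pigment, nrow(x$bands), x$reference_peak_nm
  ))
  invisible(x)
}

#' Evaluate a spectral form on a wavelength grid
#'
#' Evaluates the sum of Gaussian bands with every band centre translated by
#' `+shift` nm (red shift positive).  With `normalize = "area"` (the
#' default) the form integrates to 1 over its bands, so one amplitude unit
#' corresponds to one pigment molecule under the equal-oscillator-strength
#' convention used by the stoichiometry-constrained fit; `"peak"`
#' normalises the red-most peak to unit height; `"none"` returns the raw
#' band sum.
#'
#' @param form A [spectral_form()].
#' @param grid Wavelengths (nm).
#' @param shift Red shift in nm, inside `shift_bounds`.
#' @param normalize `"area"`, `"peak"` or `"none"`.
#' @param shift_bounds Allowed shift range, default `c(0, 25)` nm.
#' @return A [spectrum()] labelled with the pigment name.
#' @export
evaluate_form <- function(form, grid, shift = 0,
                          normalize = c("area", "peak", "none"),
                          shift_bounds = c(0, 25)) {
  stopifnot(inherits(form, "spectral_form"))
  normalize <- match.arg(normalize)
  grid <- as.numeric(grid)
  if (length(grid) == 0L) stop("empty wavelength grid")
  if (!is.finite(shift) || shift < shift_bounds[1L] || shift > shift_bounds[2L]) {
    stop(sprintf("shift %.3f nm outside bounds [%g, %g]", shift,
                 shift_bounds[1L], shift_bounds[2L]))
  }
  v <- gauss_bands(grid, form$bands, shift)
  v <- switch(normalize,
    area = v / bands_area(form$bands),
    peak = v / (form$reference_peak_value * bands_area(form$bands)),
    none = v
  )
  spectrum(grid, v, label = form$pigment)
}

#' Default pigment spectral-form basis
#'
#' A documented default band table for the five pigments: two vibronic
#' Gaussians per carotenoid and a Soret Gaussian plus a blue shoulder per
#' chlorophyll, with zero-shift red-most peaks near the solvent absorption
#' maxima (Chl a ~430 nm, Chl b ~458 nm, neoxanthin ~467 nm, violaxanthin
#' ~472 nm, lutein ~474 nm).  This table is configuration, not literature
#' ground truth: deconvolution correctness is established by
#' generate-and-refit tests that use the same basis on both sides, and the
#' basis is fully replaceable via [spectral_form()] or a pipeline config.
#'
#' @return Named list of [spectral_form()] objects keyed by pigment.
#' @export
default_basis <- function() {
  list(
    chl_a = spectral_form("chl_a", data.frame(
      center_nm = c(410, 430), fwhm_nm = c(34, 24), height = c(0.45, 1.00)
    )),
    chl_b = spectral_form("chl_b", data.frame(
      center_nm = c(432, 458), fwhm_nm = c(30, 24), height = c(0.40, 1.00)
    )),
    lutein = spectral_form("lutein", data.frame(
      center_nm = c(446, 476), fwhm_nm = c(30, 29), height = c(1.00, 0.95)
    )),
    violaxanthin = spectral_form("violaxanthin", data.frame(
      center_nm = c(441, 470), fwhm_nm = c(21, 19), height = c(1.00, 0.95)
    )),
    neoxanthin = spectral_form("neoxanthin", data.frame(
      center_nm = c(435, 464), fwhm_nm = c(23, 21), height = c(1.00, 0.80)
    ))
  )
}

#' Read a spectral-form basis from a config list
#'
#' Converts the `basis` section of a pipeline config (a named list:
#' pigment -> list of band lists with `center_nm`, `fwhm_nm`, `height`)
#' into [spectral_form()] objects.  Pigments absent from the config fall
#' back to [default_basis()].
#'
#' @param config_basis Named list as found in a parsed JSON/YAML config, or
#'   `NULL` for the default basis.
#' @return Named list of [spectral_form()] objects.
#' @export
basis_from_config <- function(config_basis = NULL) {
  basis <- default_basis()
  if (is.null(config_basis)) return(basis)
  for (p in names(config_basis)) {
    bands <- do.call(rbind, lapply(config_basis[[p]], as.data.frame))
    basis[[p]] <- spectral_form(p, bands)
  }
  basis
}
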