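#' Shift thresholds separating the carotenoid binding-site classes
#'
#' Xanthophylls buried in the inner L1 and L2 sites experience stronger
#' red shifts of their Soret absorption than those in the solvent-exposed
#' peripheral N1/V1-like site.  The defaults (10 and 15 nm) separate the
#' shift groups observed for LHCSR-type complexes — roughly 7.5-8.1 nm
#' (peripheral), 11-13.4 nm (L1) and 16-18.4 nm (L2) — with margin on each
#' side.
#'
#' @param n1v1_max_nm Upper shift bound (inclusive) for the peripheral
#'   N1/V1-like class.
#' @param l1_max_nm Upper shift bound (inclusive) for the L1 class; larger
#'   shifts are L2.
#' @return An object of class `"site_thresholds"`.
#' @export
site_thresholds <- function(n1v1_max_nm = 10, l1_max_nm = 15) {
  if (!(n1v1_max_nm > 0 && n1v1_max_nm < l1_max_nm)) {
    stop("require 0 < n1v1_max_nm < l1_max_nm")
  }
  structure(list(n1v1_max_nm = n1v1_max_nm, l1_max_nm = l1_max_nm),
            class = "site_thresholds")
}

#' Classify a spectral shift into a carotenoid binding-site class
#'
#' Boundary values are assigned to the lower-shift class.
#'
#' @param delta_nm Non-negative shift(s) in nm.
#' @param thresholds A [site_thresholds()].
#' @return Character vector with values `"N1V1"`, `"L1"` or `"L2"`.
#' @examples
#' classify_shift(c(8.1, 13, 17.8))
#' @export
classify_shift <- function(delta_nm, thresholds = site_thresholds()) {
  stopifnot(inherits(thresholds, "site_thresholds"))
  delta_nm <- as.numeric(delta_nm)
  if (any(!is.finite(delta_nm)) || any(delta_nm < 0)) {
    stop("shifts must be finite and >= 0")
  }
  ifelse(delta_nm <= thresholds$n1v1_max_nm, "N1V1",
         ifelse(delta_nm <= thresholds$l1_max_nm, "L1", "L2"))
}

#' Fractional carotenoid occupancy per binding site
#'
#' Groups the carotenoid components of a Soret deconvolution by
#' [classify_shift()] and reports, per site, the fraction of the site's
#' total amplitude contributed by each xanthophyll.  Chlorophyll components
#' are excluded: only carotenoids occupy the L1/L2/N1-V1 pockets.
#'
#' @param components A `"soret_fit"` object or its `components` data frame
#'   (columns pigment, shift_nm, amplitude).
#' @param thresholds A [site_thresholds()].
#' @return Named list (by site, in order N1V1, L1, L2 as present) of
#'   occupancy records: `site`, `total_amplitude` (molecule-equivalents)
#'   and `composition` (named fractions summing to 1; empty when the site
#'   total is zero).
#' @export
site_composition <- function(components, thresholds = site_thresholds()) {
  if (inherits(components, "soret_fit")) components <- components$components
  components <- as.data.frame(components)
  stopifnot(all(c("pigment", "shift_nm", "amplitude") %in% names(components)))
  cars <- components[components$pigment %in% CAROTENOIDS, , drop = FALSE]
  if (nrow(cars) == 0L) stop("no carotenoid components to assign")
  cars$site <- classify_shift(cars$shift_nm, thresholds)
  out <- list()
  for (s in intersect(c("N1V1", "L1", "L2"), unique(cars$site))) {
    sub <- cars[cars$site == s, , drop = FALSE]
    tot <- sum(sub$amplitude)
    comp <- if (tot > 0) {
      fr <- tapply(sub$amplitude, sub$pigment, sum) / tot
      fr <- fr[fr > 0]
      stats::setNames(as.numeric(fr), names(fr))
    } else {
      stats::setNames(numeric(0), character(0))
    }
    out[[s]] <- list(site = s, total_amplitude = tot, composition = comp)
  }
  structure(out, class = "site_occupancy_list")
}

#' @export
print.site_occupancy_list <- function(x, ...) {
  for (occ in x) {
    comp <- if (length(occ$composition)) {
      paste(sprintf("%s %.0f%%", names(occ$composition),
                    100 * occ$composition), collapse = ", ")
    } else "empty"
    cat(sprintf("%-5s total %.3f  (%s)\n", occ$site, occ$total_amplitude, comp))
  }
  invisible(x)
}

#' Flatten site occupancies to a data frame
#'
#' @param occupancies A [site_composition()] result.
#' @return Data frame with columns site, pigment, fraction,
#'   total_amplitude.
#' @export
occupancy_table <- function(occupancies) {
  rows <- lapply(occupancies, function(occ) {
    if (length(occ$composition) == 0L) {
      return(data.frame(site = occ$site, pigment = NA_character_,
                        fraction = NA_real_, total_amplitude = occ$total_amplitude,
                        stringsAsFactors = FALSE))
    }
    data.frame(site = occ$site, pigment = names(occ$composition),
               fraction = as.numeric(occ$composition),
               total_amplitude = occ$total_amplitude, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
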