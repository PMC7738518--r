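#' Raw pigment quantities from HPLC
#'
#' Quantities are in any consistent unit (mol, pmol, peak area calibrated
#' to mol): only ratios matter downstream.
#'
#' @param chl_a,chl_b,neo,vio,lut Non-negative quantities of chlorophyll a,
#'   chlorophyll b, neoxanthin, violaxanthin and lutein.
#' @return An object of class `"pigment_table"`.
#' @export
pigment_table <- function(chl_a, chl_b, neo = 0, vio = 0, lut = 0) {
  q <- c(chl_a = chl_a, chl_b = chl_b, neo = neo, vio = vio, lut = lut)
  if (any(!is.finite(q)) || any(q < 0)) stop("quantities must be finite and >= 0")
  if (chl_a + chl_b <= 0) stop("total chlorophyll must be positive")
  structure(as.list(q), class = "pigment_table")
}

#' @export
print.pigment_table <- function(x, ...) {
  cat("<pigment_table>\n")
  print(round(unlist(x), 3))
  invisible(x)
}

#' Read a pigment table from CSV
#'
#' Accepts either the long form with header `pigment,quantity` (pigment
#' names chl_a, chl_b, neo, vio, lut) or a wide one-row form whose header
#' names the pigments.
#'
#' @param path File path.
#' @return A [pigment_table()].
#' @export
read_pigment_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  names(df) <- tolower(names(df))
  if (all(c("pigment", "quantity") %in% names(df))) {
    q <- stats::setNames(df$quantity, tolower(df$pigment))
  } else {
    q <- stats::setNames(as.numeric(df[1L, ]), names(df))
  }
  get0q <- function(nm) if (nm %in% names(q)) as.numeric(q[[nm]]) else 0
  pigment_table(
    chl_a = get0q("chl_a"), chl_b = get0q("chl_b"),
    neo = get0q("neo"), vio = get0q("vio"), lut = get0q("lut")
  )
}

#' Normalize pigment quantities to a fixed chlorophyll total
#'
#' Rescales a raw pigment table so that Chl a + Chl b equals `chl_tot`
#' (default 8, the putative number of chlorophylls bound per LHCSR
#' apoprotein) and derives the standard stoichiometry ratios: Chl a/b,
#' Chl/Car, total carotenoids and lutein/violaxanthin.
#'
#' @param raw A [pigment_table()].
#' @param chl_tot Normalisation constant (chlorophylls per apoprotein).
#' @return An object of class `"stoich_summary"` with fields
#'   `chl_ab_ratio`, `chl_car_ratio`, `chl_tot`, `chl_a_n`, `chl_b_n`,
#'   `neo_n`, `vio_n`, `lut_n`, `cars_n`, `lut_vio_ratio` (`NA` with
#'   `lut_vio_defined = FALSE` when violaxanthin is absent).  All values
#'   are kept at full precision; the print method rounds to 2 decimals.
#' @examples
#' normalize_to_chl(pigment_table(6.431, 1.569, neo = 0.11, vio = 0.49, lut = 1.75))
#' @export
normalize_to_chl <- function(raw, chl_tot = 8) {
  stopifnot(inherits(raw, "pigment_table"), chl_tot > 0)
  s <- chl_tot / (raw$chl_a + raw$chl_b)
  chl_a_n <- raw$chl_a * s
  chl_b_n <- raw$chl_b * s
  neo_n <- raw$neo * s
  vio_n <- raw$vio * s
  lut_n <- raw$lut * s
  cars_n <- neo_n + vio_n + lut_n
  structure(
    list(
      chl_ab_ratio = if (chl_b_n > 0) chl_a_n / chl_b_n else Inf,
      chl_car_ratio = if (cars_n > 0) chl_tot / cars_n else Inf,
      chl_tot = chl_tot,
      chl_a_n = chl_a_n, chl_b_n = chl_b_n,
      neo_n = neo_n, vio_n = vio_n, lut_n = lut_n,
      cars_n = cars_n,
      lut_vio_ratio = if (vio_n > 0) lut_n / vio_n else NA_real_,
      lut_vio_defined = vio_n > 0
    ),
    class = "stoich_summary"
  )
}

#' @export
print.stoich_summary <- function(x, ...) {
  cat(sprintf("<stoich_summary: %g Chl per apoprotein>\n", x$chl_tot))
  vals <- c(
    "Chl a/b" = x$chl_ab_ratio, "Chl/Car" = x$chl_car_ratio,
    Neo = x$neo_n, Vio = x$vio_n, Lut = x$lut_n, Cars = x$cars_n,
    "Lut/Vio" = x$lut_vio_ratio
  )
  print(round(vals, 2))
  if (!x$lut_vio_defined) cat("Lut/Vio undefined (no violaxanthin)\n")
  invisible(x)
}

stoich_fields <- c("chl_ab_ratio", "chl_car_ratio", "chl_a_n", "chl_b_n",
                   "neo_n", "vio_n", "lut_n", "cars_n", "lut_vio_ratio")

#' Summarize replicate pigment tables
#'
#' Normalises each replicate with [normalize_to_chl()], then reports the
#' per-field mean together with a spread estimate: the half-range for two
#' replicates, the standard deviation for more.  Fields whose relative
#' spread exceeds `flag_threshold` (default the 15% error bound quoted for
#' duplicate HPLC quantifications) are flagged.
#'
#' @param tables List of [pigment_table()] objects (>= 1).
#' @param chl_tot Normalisation constant.
#' @param flag_threshold Relative-spread QC threshold.
#' @return List with `mean` (a `"stoich_summary"`), `spread` and
#'   `relative_spread` (named numeric), `flagged` (character vector of
#'   offending fields) and `n`.
#' @export
summarize_replicates <- function(tables, chl_tot = 8, flag_threshold = 0.15) {
  if (length(tables) < 1L) stop("need at least one pigment table")
  sums <- lapply(tables, normalize_to_chl, chl_tot = chl_tot)
  mat <- vapply(sums, function(s) unlist(s[stoich_fields]), numeric(length(stoich_fields)))
  mat <- matrix(mat, nrow = length(stoich_fields),
                dimnames = list(stoich_fields, NULL))
  mu <- rowMeans(mat)
  spread <- if (ncol(mat) == 1L) {
    stats::setNames(rep(0, nrow(mat)), rownames(mat))
  } else if (ncol(mat) == 2L) {
    (apply(mat, 1L, max) - apply(mat, 1L, min)) / 2
  } else {
    apply(mat, 1L, stats::sd)
  }
  rel <- ifelse(mu > 0, spread / mu, 0)
  mean_summary <- normalize_to_chl(
    pigment_table(
      chl_a = mu[["chl_a_n"]], chl_b = mu[["chl_b_n"]],
      neo = mu[["neo_n"]], vio = mu[["vio_n"]], lut = mu[["lut_n"]]
    ),
    chl_tot = chl_tot
  )
  list(
    mean = mean_summary,
    spread = spread,
    relative_spread = rel,
    flagged = names(rel)[is.finite(rel) & rel > flag_threshold],
    n = length(tables)
  )
}
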