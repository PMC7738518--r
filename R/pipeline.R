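#' Read a pipeline configuration file
#'
#' JSON (`.json`) or YAML (`.yml`/`.yaml`) key-value configuration.  See
#' [run_pipeline()] for the recognised sections.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    stop("config must be .json, .yml or .yaml")
  }
}

resolve_spectrum <- function(x) if (is.character(x)) read_spectrum(x) else x
resolve_pigments <- function(x) if (is.character(x)) read_pigment_table(x) else x
resolve_decay <- function(x, condition = list()) {
  if (is.character(x)) read_decay(x, condition = condition) else x
}

#' Run the full characterisation pipeline
#'
#' Orchestrates the stages end to end: pigment stoichiometry ->
#' stoichiometry-constrained Soret deconvolution -> carotenoid site
#' assignment -> per-condition decay fits -> quenching comparisons ->
#' emission connectivity QC.  Stages whose inputs are absent from the
#' config are skipped; every stage consumes only the outputs of earlier
#' stages, so each can be re-run standalone.  All randomness is governed
#' by `config$seed` (default 0), which is recorded in the report.
#'
#' @param config Named list (or path to a JSON/YAML file, see
#'   [read_config()]) with optional sections:
#'   \describe{
#'     \item{pigment_tables}{list of [pigment_table()] objects or CSV
#'       paths (replicates).}
#'     \item{chl_tot}{chlorophyll normalisation constant, default 8.}
#'     \item{spectrum}{a [spectrum()] or CSV path (Soret region).}
#'     \item{basis}{basis definition list for [basis_from_config()].}
#'     \item{soret}{options: `window`, `restarts`, `penalty_weight`,
#'       `chl_bounds`, `site_shifts`, `half_width` (the carotenoid
#'       instances use site-windowed shift bounds, see
#'       [site_window_specs()]; `half_width = 0` gives the fixed-shift
#'       protocol recommended for noisy data).}
#'     \item{site_thresholds}{list with `n1v1_max_nm`, `l1_max_nm`.}
#'     \item{decays}{named list (by condition) of [decay_histogram()]
#'       objects or CSV paths.}
#'     \item{decay_conditions}{named list (by condition) of metadata
#'       lists (`ph`, `detergent_pct`) for path inputs.}
#'     \item{reference_condition}{condition name used as the quenching
#'       reference; default the condition with the longest fitted
#'       average lifetime.}
#'     \item{emission}{an [emission_set()], or a list with `spectra`
#'       (named paths) and `reference_excitation`.}
#'     \item{seed}{integer seed, default 0.}
#'   }
#' @return An object of class `"lhc_report"`: list with any of
#'   `stoichiometry`, `soret`, `sites`, `decays` (data frame of fitted
#'   parameters per condition), `quenching`, `qc`, plus `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)
  report <- list()

  # --- stoichiometry ---------------------------------------------------
  stoich <- NULL
  if (!is.null(config$pigment_tables)) {
    chl_tot <- if (is.null(config$chl_tot)) 8 else config$chl_tot
    tables <- lapply(config$pigment_tables, resolve_pigments)
    reps <- tryCatch(
      summarize_replicates(tables, chl_tot = chl_tot),
      error = function(e) stop("stage stoichiometry: ", conditionMessage(e))
    )
    stoich <- reps$mean
    report$stoichiometry <- list(
      summary = unclass(stoich),
      spread = as.list(reps$spread),
      flagged = reps$flagged,
      n_replicates = reps$n
    )
  }

  # --- Soret deconvolution --------------------------------------------
  soret_fit_obj <- NULL
  if (!is.null(config$spectrum)) {
    basis <- basis_from_config(config$basis)
    so <- config$soret
    opts <- soret_options(
      window = if (is.null(so$window)) c(400, 520) else as.numeric(so$window),
      restarts = if (is.null(so$restarts)) 32L else so$restarts,
      seed = seed,
      penalty_weight = if (is.null(so$penalty_weight)) 1 else so$penalty_weight
    )
    specs <- site_window_specs(
      basis,
      site_shifts = if (is.null(so$site_shifts)) c(N1V1 = 8, L1 = 13, L2 = 17.5)
                    else unlist(so$site_shifts),
      half_width = if (is.null(so$half_width)) 2.5 else so$half_width,
      chl_bounds = if (is.null(so$chl_bounds)) c(0, 12) else as.numeric(so$chl_bounds)
    )
    targets <- NULL
    if (!is.null(stoich)) {
      targets <- c(
        chl_a = stoich$chl_a_n, chl_b = stoich$chl_b_n,
        lutein = stoich$lut_n, violaxanthin = stoich$vio_n,
        neoxanthin = stoich$neo_n
      )
    }
    soret_fit_obj <- tryCatch(
      fit_soret(resolve_spectrum(config$spectrum), specs,
                stoich_targets = targets, options = opts),
      error = function(e) stop("stage soret_fit: ", conditionMessage(e))
    )
    report$soret <- list(
      components = soret_fit_obj$components,
      residual_rms = soret_fit_obj$residual_rms,
      converged = soret_fit_obj$converged,
      pigment_totals = as.list(soret_fit_obj$pigment_totals)
    )
  }

  # --- site assignment -------------------------------------------------
  if (!is.null(soret_fit_obj)) {
    th <- if (is.null(config$site_thresholds)) site_thresholds() else {
      site_thresholds(config$site_thresholds$n1v1_max_nm,
                      config$site_thresholds$l1_max_nm)
    }
    occ <- tryCatch(
      site_composition(soret_fit_obj, thresholds = th),
      error = function(e) stop("stage site_assignment: ", conditionMessage(e))
    )
    report$sites <- occupancy_table(occ)
  }

  # --- decay fits ------------------------------------------------------
  fits <- NULL
  if (!is.null(config$decays)) {
    fits <- list()
    rows <- list()
    for (nm in names(config$decays)) {
      cond <- config$decay_conditions[[nm]]
      if (is.null(cond)) cond <- list()
      cond$condition <- nm
      h <- resolve_decay(config$decays[[nm]], condition = cond)
      fit <- tryCatch(
        fit_biexponential(h, seed = seed),
        error = function(e) stop("stage decay_fit [", nm, "]: ",
                                 conditionMessage(e))
      )
      fits[[nm]] <- fit
      rows[[nm]] <- data.frame(
        condition = nm,
        ph = if (is.null(cond$ph)) NA_real_ else cond$ph,
        detergent_pct = if (is.null(cond$detergent_pct)) NA_real_ else cond$detergent_pct,
        tau1_ns = fit$tau1_ns, a1 = fit$a1,
        tau2_ns = fit$tau2_ns, a2 = fit$a2,
        tau_avg_ns = fit$tau_avg_ns,
        chi2_reduced = fit$chi2_reduced,
        converged = fit$converged,
        stringsAsFactors = FALSE
      )
    }
    decays_df <- do.call(rbind, rows)
    rownames(decays_df) <- NULL
    report$decays <- decays_df

    # --- quenching comparisons ----------------------------------------
    ref_name <- config$reference_condition
    if (is.null(ref_name)) {
      ref_name <- decays_df$condition[which.max(decays_df$tau_avg_ns)]
    }
    comps <- lapply(setdiff(names(fits), ref_name), function(nm) {
      qc <- lifetime_reduction(fits[[ref_name]], fits[[nm]])
      data.frame(
        reference = ref_name, quenched = nm,
        tau_avg_reference_ns = average_lifetime(qc$reference),
        tau_avg_quenched_ns = average_lifetime(qc$quenched),
        fractional_reduction = qc$fractional_reduction,
        stringsAsFactors = FALSE
      )
    })
    if (length(comps)) {
      q <- do.call(rbind, comps)
      rownames(q) <- NULL
      report$quenching <- q
    }
  }

  # --- emission QC -----------------------------------------------------
  if (!is.null(config$emission)) {
    em <- config$emission
    if (!inherits(em, "emission_set")) {
      spectra <- lapply(em$spectra, resolve_spectrum)
      em <- emission_set(spectra,
                         reference_excitation = if (is.null(em$reference_excitation)) 440
                                                else em$reference_excitation)
    }
    report$qc <- tryCatch(
      connectivity_report(em),
      error = function(e) stop("stage qc_emission: ", conditionMessage(e))
    )
  }

  if (length(report) == 0L) stop("config provides no inputs for any stage")
  report$provenance <- list(
    package = "lhcquench",
    version = as.character(utils::packageVersion("lhcquench")),
    seed = seed
  )
  structure(report, class = "lhc_report")
}

#' @export
print.lhc_report <- function(x, ...) {
  cat("<lhc_report> stages:",
      paste(setdiff(names(x), "provenance"), collapse = ", "), "\n")
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` (full precision) plus flat TSV sidecars for the
#' tabular sections (`decays.tsv`, `components.tsv`, `sites.tsv`,
#' `quenching.tsv`, `qc.tsv`) for spreadsheet use.
#'
#' @param report An `"lhc_report"`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the path of `report.json`.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "lhc_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  main <- file.path(outdir, "report.json")
  jsonlite::write_json(unclass(report), main, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  tsv <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(report$decays)) tsv(report$decays, "decays.tsv")
  if (!is.null(report$soret)) tsv(report$soret$components, "components.tsv")
  if (!is.null(report$sites)) tsv(report$sites, "sites.tsv")
  if (!is.null(report$quenching)) tsv(report$quenching, "quenching.tsv")
  if (!is.null(report$qc)) tsv(report$qc, "qc.tsv")
  invisible(main)
}
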