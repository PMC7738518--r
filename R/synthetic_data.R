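#' Define a synthetic measurement scenario
#'
#' A scenario is the generative twin of a full in vitro characterisation:
#' a carotenoid site plan (molecule counts per binding site), a chlorophyll
#' plan (counts split over spectral instances with their shifts), the
#' site-to-shift mapping, a decay plan (bi-exponential parameters per
#' pH/detergent condition) and noise settings.  All generators consume a
#' scenario plus a seed, so a scenario fixes the study conditions once.
#'
#' @param name Scenario label.
#' @param site_plan Named list (sites `"N1V1"`, `"L1"`, `"L2"`) of named
#'   numeric vectors: carotenoid -> molecule count.  `NULL` when no
#'   spectral part is needed.
#' @param chl_plan Named list (`chl_a`, `chl_b`) of lists with `n`
#'   (molecule count) and `shifts` (nm, one per spectral instance; the
#'   count is split equally over instances).
#' @param shift_plan Named numeric: site -> red shift (nm) applied to every
#'   carotenoid form in that site.
#' @param decay_plan Data frame with columns `condition`, `ph`,
#'   `detergent_pct`, `tau1`, `a1`, `tau2`, `a2`.
#' @param noise List: `spectrum_sigma` (additive Gaussian SD relative to
#'   the spectrum maximum), `hplc_cv` (multiplicative lognormal CV per
#'   pigment), `decay_total_counts` (Poisson total per histogram).
#' @return An object of class `"scenario"`.
#' @export
scenario <- function(name, site_plan = NULL, chl_plan = NULL,
                     shift_plan = c(N1V1 = 8, L1 = 13, L2 = 17.5),
                     decay_plan = NULL,
                     noise = list(spectrum_sigma = 0, hplc_cv = 0,
                                  decay_total_counts = 2e6)) {
  if (!is.null(site_plan)) {
    for (s in names(site_plan)) {
      amt <- site_plan[[s]]
      if (any(amt < 0)) stop("site amounts must be >= 0")
      if (!all(names(amt) %in% CAROTENOIDS)) {
        stop("site plans may only contain carotenoids")
      }
      if (!s %in% names(shift_plan)) stop("no shift planned for site ", s)
    }
  }
  if (!is.null(decay_plan)) {
    stopifnot(all(c("condition", "tau1", "a1", "tau2", "a2") %in% names(decay_plan)),
              all(decay_plan$tau1 > 0), all(decay_plan$tau2 > 0),
              all(decay_plan$a1 >= 0), all(decay_plan$a2 >= 0))
  }
  structure(
    list(name = name, site_plan = site_plan, chl_plan = chl_plan,
         shift_plan = shift_plan, decay_plan = decay_plan, noise = noise),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario '%s': %d site(s), %d decay condition(s)>\n",
              x$name, length(x$site_plan),
              if (is.null(x$decay_plan)) 0L else nrow(x$decay_plan)))
  invisible(x)
}

# true per-pigment molecule counts implied by the plans
scenario_true_counts <- function(s) {
  counts <- stats::setNames(numeric(length(PIGMENTS)), PIGMENTS)
  for (p in names(s$chl_plan)) counts[p] <- counts[p] + s$chl_plan[[p]]$n
  for (site in names(s$site_plan)) {
    amt <- s$site_plan[[site]]
    counts[names(amt)] <- counts[names(amt)] + amt
  }
  counts
}

#' True pigment table of a scenario (no noise)
#'
#' @param s A [scenario()].
#' @return A [pigment_table()] with the exact planned molecule counts.
#' @export
scenario_true_pigment_table <- function(s) {
  counts <- scenario_true_counts(s)
  pigment_table(chl_a = counts[["chl_a"]], chl_b = counts[["chl_b"]],
                neo = counts[["neoxanthin"]], vio = counts[["violaxanthin"]],
                lut = counts[["lutein"]])
}

with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate an HPLC pigment quantification
#'
#' Applies per-pigment multiplicative lognormal noise with the scenario's
#' `hplc_cv` to the true molecule counts.  The lognormal is
#' mean-corrected, so the expectation equals the true count.
#'
#' @param s A [scenario()].
#' @param seed Integer seed.
#' @return A [pigment_table()].
#' @export
scenario_to_pigment_table <- function(s, seed = 1L) {
  stopifnot(inherits(s, "scenario"))
  counts <- scenario_true_counts(s)
  cv <- s$noise$hplc_cv
  if (is.null(cv) || cv <= 0) {
    noisy <- counts
  } else {
    sdlog <- sqrt(log(1 + cv^2))
    noisy <- with_seed(seed, {
      counts * stats::rlnorm(length(counts), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    })
  }
  pigment_table(chl_a = noisy[["chl_a"]], chl_b = noisy[["chl_b"]],
                neo = noisy[["neoxanthin"]], vio = noisy[["violaxanthin"]],
                lut = noisy[["lutein"]])
}

#' Simulate a Soret-region absorption spectrum
#'
#' Sums `count x unit-area shifted form` over the chlorophyll instances and
#' every carotenoid in every site, then adds Gaussian noise with SD
#' `spectrum_sigma x max(spectrum)` and clips at zero.
#'
#' @param s A [scenario()] with spectral plans.
#' @param basis Named list of [spectral_form()], default [default_basis()].
#' @param grid Wavelength grid in nm.
#' @param seed Integer seed.
#' @return A [spectrum()] labelled with the scenario name.
#' @export
scenario_to_spectrum <- function(s, basis = default_basis(),
                                 grid = seq(400, 520, by = 0.5), seed = 1L) {
  stopifnot(inherits(s, "scenario"))
  if (is.null(s$site_plan) && is.null(s$chl_plan)) {
    stop("scenario has no spectral plan")
  }
  v <- numeric(length(grid))
  for (p in names(s$chl_plan)) {
    if (is.null(basis[[p]])) stop("pigment ", p, " absent from basis")
    plan <- s$chl_plan[[p]]
    per <- plan$n / length(plan$shifts)
    for (sh in plan$shifts) {
      v <- v + per * evaluate_form(basis[[p]], grid, sh)$value
    }
  }
  for (site in names(s$site_plan)) {
    sh <- s$shift_plan[[site]]
    amt <- s$site_plan[[site]]
    for (p in names(amt)) {
      if (amt[[p]] <= 0) next
      if (is.null(basis[[p]])) stop("pigment ", p, " absent from basis")
      v <- v + amt[[p]] * evaluate_form(basis[[p]], grid, sh)$value
    }
  }
  sigma <- s$noise$spectrum_sigma
  if (!is.null(sigma) && sigma > 0) {
    v <- with_seed(seed, v + stats::rnorm(length(v), sd = sigma * max(v)))
    v <- pmax(v, 0)
  }
  spectrum(grid, v, label = s$name)
}

#' Simulate TCSPC decay histograms for every planned condition
#'
#' Evaluates the bi-exponential model of each decay-plan row on the time
#' grid, scales it to `decay_total_counts` and draws Poisson counts.  With
#' `poisson = FALSE` the exact (non-integer) scaled model is returned —
#' the infinite-counts limit.
#'
#' @param s A [scenario()] with a decay plan.
#' @param seed Integer seed.
#' @param time_ns Time grid, default [default_time_grid()].
#' @param irf Optional Gaussian IRF list applied to the model and recorded
#'   in the histograms.
#' @param poisson Draw Poisson counting noise (default `TRUE`).
#' @return Named list of [decay_histogram()] keyed by condition.
#' @export
scenario_to_decays <- function(s, seed = 1L, time_ns = default_time_grid(),
                               irf = NULL, poisson = TRUE) {
  stopifnot(inherits(s, "scenario"))
  if (is.null(s$decay_plan) || nrow(s$decay_plan) == 0L) {
    stop("scenario has no decay plan")
  }
  total <- s$noise$decay_total_counts
  out <- list()
  for (i in seq_len(nrow(s$decay_plan))) {
    row <- s$decay_plan[i, ]
    shape <- biexp_model(time_ns, c(row$tau1, row$tau2), c(row$a1, row$a2),
                         irf = irf)
    scaled <- if (is.finite(total)) shape * total / sum(shape) else shape
    counts <- if (poisson && is.finite(total)) {
      with_seed(seed + i, stats::rpois(length(scaled), scaled))
    } else {
      scaled
    }
    cond <- list(protein = s$name, condition = row$condition)
    if ("ph" %in% names(row)) cond$ph <- row$ph
    if ("detergent_pct" %in% names(row)) cond$detergent_pct <- row$detergent_pct
    out[[row$condition]] <- decay_histogram(time_ns, counts, irf = irf,
                                            condition = cond)
  }
  out
}

# Solve inner-site totals so that the site compositions reproduce given
# total lutein/violaxanthin/neoxanthin quantities exactly.  L1 and L2 get
# equal totals; neoxanthin and the leftover violaxanthin sit in the
# peripheral N1/V1-like site.
allocate_sites <- function(lut, vio, neo, l1_lut_frac, l2_lut_frac) {
  t12 <- lut / (l1_lut_frac + l2_lut_frac)
  vio_inner <- (2 - l1_lut_frac - l2_lut_frac) * t12
  vio_n1v1 <- vio - vio_inner
  if (vio_n1v1 < 0) stop("site fractions inconsistent with pigment totals")
  list(
    L1 = c(lutein = l1_lut_frac * t12, violaxanthin = (1 - l1_lut_frac) * t12),
    L2 = c(lutein = l2_lut_frac * t12, violaxanthin = (1 - l2_lut_frac) * t12),
    N1V1 = c(violaxanthin = vio_n1v1, neoxanthin = neo)
  )
}

chl_split <- function(chl_ab_ratio, chl_tot = 8,
                      chl_a_shifts = c(2, 5, 9), chl_b_shifts = c(3, 7)) {
  chl_a <- chl_tot * chl_ab_ratio / (1 + chl_ab_ratio)
  list(
    chl_a = list(n = chl_a, shifts = chl_a_shifts),
    chl_b = list(n = chl_tot - chl_a, shifts = chl_b_shifts)
  )
}

decay_plan_df <- function(rows) {
  do.call(rbind, lapply(rows, function(r) {
    data.frame(condition = r[[1L]], ph = r[[2L]], detergent_pct = r[[3L]],
               tau1 = r[[4L]], a1 = r[[5L]], tau2 = r[[6L]], a2 = r[[7L]],
               stringsAsFactors = FALSE)
  }))
}

#' Published exponential-fit parameters for the LHCSR decay conditions
#'
#' The bi-exponential decay constants and fractional amplitudes reported
#' for refolded LHCSR1 and LHCSR3 across the pH (7.5, 5) by detergent
#' (0.03%, 0.007% beta-DM) condition matrix, together with the printed
#' amplitude-weighted average lifetimes.  These are inputs for fixtures
#' and round-trip validation.
#'
#' @return Data frame with columns `protein`, `ph`, `detergent_pct`,
#'   `tau1`, `a1`, `tau2`, `a2`, `tau_avg_printed`.
#' @export
lhcsr_decay_parameters <- function() {
  data.frame(
    protein = rep(c("LHCSR1", "LHCSR3"), each = 4L),
    ph = rep(c(7.5, 7.5, 5, 5), 2L),
    detergent_pct = rep(c(0.03, 0.007, 0.03, 0.007), 2L),
    tau1 = c(4.540, 3.800, 3.940, 3.760, 4.050, 3.200, 2.930, 2.870),
    a1 = c(0.509, 0.357, 0.331, 0.225, 0.474, 0.520, 0.372, 0.161),
    tau2 = c(1.490, 1.190, 1.000, 0.802, 1.530, 1.250, 0.900, 0.583),
    a2 = c(0.491, 0.643, 0.669, 0.775, 0.526, 0.480, 0.628, 0.839),
    tau_avg_printed = c(3.043, 2.121, 1.974, 1.467, 2.725, 2.265, 1.655, 0.950),
    stringsAsFactors = FALSE
  )
}

#' Published pigment stoichiometries of refolded LHCSR complexes
#'
#' Per-pigment quantities normalised to 8 chlorophylls per apoprotein and
#' the derived ratios, as reported for refolded LHCSR1 and LHCSR3.
#'
#' @return Data frame with columns `protein`, `chl_ab`, `chl_car`,
#'   `chl_tot`, `neo`, `vio`, `lut`, `cars`, `lut_vio`.
#' @export
lhcsr_pigment_stoichiometry <- function() {
  data.frame(
    protein = c("LHCSR1", "LHCSR3"),
    chl_ab = c(4.10, 6.31), chl_car = c(3.40, 3.01), chl_tot = c(8, 8),
    neo = c(0.11, 0.03), vio = c(0.49, 1.20), lut = c(1.75, 1.43),
    cars = c(2.35, 2.66), lut_vio = c(3.57, 1.19),
    stringsAsFactors = FALSE
  )
}

protein_decay_plan <- function(protein) {
  tab <- lhcsr_decay_parameters()
  tab <- tab[tab$protein == protein, , drop = FALSE]
  decay_plan_df(lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    list(sprintf("pH %g %g%% b-DM", r$ph, r$detergent_pct),
         r$ph, r$detergent_pct, r$tau1, r$a1, r$tau2, r$a2)
  }))
}

#' LHCSR1-like synthetic scenario
#'
#' Encodes the published LHCSR1 characterisation: pigment totals
#' (neo 0.11, vio 0.49, lut 1.75 per 8 Chl at Chl a/b 4.10), L1 site
#' 94% lutein / 6% violaxanthin, L2 site 70% lutein / 30% violaxanthin,
#' remaining violaxanthin plus all neoxanthin in the peripheral site, and
#' the four measured decay conditions.  Inner-site totals (~1.07
#' carotenoids each) are solved so the site compositions and pigment
#' totals are exactly consistent — the published data do not state the
#' per-site totals.  Site shifts use the midpoints of the observed groups
#' (8 / 13 / 17.5 nm).
#'
#' @param noise Noise settings, see [scenario()].
#' @return A [scenario()].
#' @export
lhcsr1_scenario <- function(noise = list(spectrum_sigma = 0, hplc_cv = 0,
                                         decay_total_counts = 2e6)) {
  scenario(
    name = "LHCSR1-like",
    site_plan = allocate_sites(lut = 1.75, vio = 0.49, neo = 0.11,
                               l1_lut_frac = 0.94, l2_lut_frac = 0.70),
    chl_plan = chl_split(4.10),
    decay_plan = protein_decay_plan("LHCSR1"),
    noise = noise
  )
}

#' LHCSR3-like synthetic scenario
#'
#' As [lhcsr1_scenario()] but with the LHCSR3 characterisation: pigment
#' totals neo 0.03, vio 1.20, lut 1.43 per 8 Chl at Chl a/b 6.31, L1 site
#' 96% lutein / 4% violaxanthin, L2 site 17% lutein / 83% violaxanthin.
#'
#' @param noise Noise settings, see [scenario()].
#' @return A [scenario()].
#' @export
lhcsr3_scenario <- function(noise = list(spectrum_sigma = 0, hplc_cv = 0,
                                         decay_total_counts = 2e6)) {
  scenario(
    name = "LHCSR3-like",
    site_plan = allocate_sites(lut = 1.43, vio = 1.20, neo = 0.03,
                               l1_lut_frac = 0.96, l2_lut_frac = 0.17),
    chl_plan = chl_split(6.31),
    decay_plan = protein_decay_plan("LHCSR3"),
    noise = noise
  )
}

#' LHCII-like synthetic scenario (approximate)
#'
#' A trimeric-LHCII-like control for the quenching comparison.  The decay
#' parameters are synthetic — no main-text values exist for this control —
#' and are chosen so that the extreme-condition comparison (pH 5 / 0.007%
#' vs pH 7.5 / 0.03% beta-DM) gives exactly a 10% reduction of the
#' amplitude-weighted lifetime, mirroring the reported ~10% for LHCII.
#'
#' @param noise Noise settings, see [scenario()].
#' @return A [scenario()] with a decay plan only.
#' @export
lhcii_scenario <- function(noise = list(spectrum_sigma = 0, hplc_cv = 0,
                                        decay_total_counts = 2e6)) {
  scenario(
    name = "LHCII-like",
    decay_plan = decay_plan_df(list(
      list("pH 7.5 0.03% b-DM", 7.5, 0.03, 4.0, 0.80, 1.5, 0.20),
      list("pH 5 0.007% b-DM", 5, 0.007, 4.0, 0.66, 1.5, 0.34)
    )),
    noise = noise
  )
}

#' Write a scenario's synthetic data set to disk
#'
#' Writes the pigment table, the Soret spectrum and one decay CSV per
#' condition, plus `truth.json` recording the generating plans, into
#' `outdir`.  Identical seeds yield byte-identical files.
#'
#' @param s A [scenario()].
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed.
#' @param basis,grid Passed to [scenario_to_spectrum()].
#' @return Invisibly, the vector of written paths.
#' @export
write_scenario <- function(s, outdir, seed = 1L, basis = default_basis(),
                           grid = seq(400, 520, by = 0.5)) {
  stopifnot(inherits(s, "scenario"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if (!is.null(s$site_plan) || !is.null(s$chl_plan)) {
    tab <- scenario_to_pigment_table(s, seed = seed)
    p <- file.path(outdir, "pigments.csv")
    utils::write.csv(
      data.frame(pigment = names(unlist(tab)), quantity = as.numeric(unlist(tab))),
      p, row.names = FALSE, quote = FALSE
    )
    paths <- c(paths, p)
    sp <- scenario_to_spectrum(s, basis = basis, grid = grid, seed = seed)
    p <- file.path(outdir, "soret.csv")
    write_spectrum(sp, p)
    paths <- c(paths, p)
  }
  if (!is.null(s$decay_plan)) {
    decays <- scenario_to_decays(s, seed = seed)
    for (nm in names(decays)) {
      p <- file.path(outdir, paste0("decay_", gsub("[^A-Za-z0-9.]+", "_", nm), ".csv"))
      write_decay(decays[[nm]], p)
      paths <- c(paths, p)
    }
  }
  truth <- list(
    name = s$name,
    site_plan = lapply(s$site_plan, as.list),
    shift_plan = as.list(s$shift_plan),
    chl_plan = s$chl_plan,
    decay_plan = s$decay_plan,
    noise = s$noise,
    seed = seed
  )
  p <- file.path(outdir, "truth.json")
  jsonlite::write_json(truth, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, p))
}
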