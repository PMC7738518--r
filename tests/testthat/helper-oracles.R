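# shared helpers: analytic curves, brute-force oracles, error summaries

gauss_curve <- function(grid, center, fwhm, height = 1) {
  height * exp(-4 * log(2) * (grid - center)^2 / fwhm^2)
}

# maximum absolute error between recovered and planned site fractions
occupancy_errors <- function(occ, site_plan) {
  errs <- c()
  for (s in names(site_plan)) {
    plan <- site_plan[[s]]
    plan <- plan[plan > 0] / sum(plan[plan > 0])
    got <- if (s %in% names(occ)) occ[[s]]$composition else numeric(0)
    for (p in names(plan)) {
      got_p <- if (p %in% names(got)) got[[p]] else 0
      errs[paste(s, p)] <- abs(got_p - plan[[p]])
    }
  }
  errs
}

# stoichiometry targets implied by a scenario's true pigment table
scenario_targets <- function(sc, chl_tot = 8) {
  st <- normalize_to_chl(scenario_true_pigment_table(sc), chl_tot = chl_tot)
  c(chl_a = st$chl_a_n, chl_b = st$chl_b_n, lutein = st$lut_n,
    violaxanthin = st$vio_n, neoxanthin = st$neo_n)
}

# exhaustive search over a shift grid with NNLS amplitudes: the
# independent oracle for the outer shift optimisation
grid_search_soret <- function(data, specs, step = 0.5, stoich_targets = NULL,
                              penalty_weight = 1) {
  inst <- do.call(rbind, lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    data.frame(spec = i, lo = sp$shift_bounds[1], hi = sp$shift_bounds[2])
  }))
  axes <- lapply(seq_len(nrow(inst)), function(j) seq(inst$lo[j], inst$hi[j], by = step))
  grids <- do.call(expand.grid, axes)
  best <- list(obj = Inf)
  pigments <- vapply(specs, function(sp) sp$form$pigment, character(1))
  for (r in seq_len(nrow(grids))) {
    shifts <- as.numeric(grids[r, ])
    forms <- lapply(seq_along(specs), function(i) {
      evaluate_form(specs[[i]]$form, data$wavelength_nm, shifts[i])
    })
    amps <- amplitudes_given_shifts(data, forms, stoich_targets, penalty_weight)
    n_pen <- length(stoich_targets)
    fitv <- Reduce(`+`, Map(function(f, a) a * f$value, forms, as.numeric(amps)))
    pen <- 0
    if (n_pen > 0) {
      sums <- vapply(names(stoich_targets),
                     function(p) sum(as.numeric(amps)[pigments == p]), numeric(1))
      pen <- sum((penalty_weight * (sums - unlist(stoich_targets)))^2)
    }
    obj <- sqrt((sum((data$value - fitv)^2) + pen) /
                  (length(data$value) + n_pen))
    if (obj < best$obj) best <- list(obj = obj, shifts = shifts, amps = as.numeric(amps))
  }
  best
}

# brute-force single-exponential oracle: tau grid + non-negative amplitude
grid_search_single_exp <- function(hist, taus = seq(0.2, 10, by = 0.002)) {
  t <- hist$time_ns
  y <- hist$counts
  w <- 1 / pmax(y, 1)
  best <- list(sse = Inf)
  for (tau in taus) {
    b <- exp(-t / tau)
    a <- max(sum(w * b * y) / sum(w * b^2), 0)
    sse <- sum(w * (y - a * b)^2)
    if (sse < best$sse) best <- list(sse = sse, tau = tau, a = a)
  }
  best
}
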