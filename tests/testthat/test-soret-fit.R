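basis <- default_basis()
soret_grid <- seq(400, 520, by = 0.5)

test_that("a single-component spectrum is recovered exactly", {
  f <- evaluate_form(basis$chl_a, soret_grid, 3)
  data <- spectrum(soret_grid, 2 * f$value)
  amps <- amplitudes_given_shifts(data, list(f))
  expect_equal(as.numeric(amps), 2, tolerance = 1e-10)
  expect_lt(attr(amps, "residual_rms"), 1e-12)
})

test_that("well-separated two-component amplitudes match the linear oracle", {
  f1 <- evaluate_form(basis$chl_a, soret_grid, 0)
  f2 <- evaluate_form(basis$lutein, soret_grid, 17)
  data <- spectrum(soret_grid, 1.5 * f1$value + 0.5 * f2$value)
  amps <- amplitudes_given_shifts(data, list(f1, f2))
  expect_equal(as.numeric(amps), c(1.5, 0.5), tolerance = 1e-6)
  # already-satisfied stoichiometry constraint must not move the solution
  amps2 <- amplitudes_given_shifts(
    data, list(f1, f2),
    stoich_targets = c(chl_a = 1.5, lutein = 0.5), penalty_weight = 1e3
  )
  expect_equal(as.numeric(amps2), c(1.5, 0.5), tolerance = 1e-6)
})

test_that("duplicated identical forms are pooled with a degeneracy flag", {
  f <- evaluate_form(basis$chl_b, soret_grid, 5)
  data <- spectrum(soret_grid, 2 * f$value)
  amps <- amplitudes_given_shifts(data, list(f, f))
  expect_true(attr(amps, "degenerate"))
  expect_equal(as.numeric(amps)[1], as.numeric(amps)[2])
  expect_equal(2 * sum(as.numeric(amps)[1]), 2, tolerance = 1e-8)
})

test_that("stoichiometry penalty rows drive pigment sums toward targets", {
  f1 <- evaluate_form(basis$lutein, soret_grid, 13)
  f2 <- evaluate_form(basis$violaxanthin, soret_grid, 13)
  # data slightly inconsistent with the target (HPLC error emulation)
  data <- spectrum(soret_grid, 1.0 * f1$value + 1.0 * f2$value)
  targets <- c(lutein = 1.2, violaxanthin = 0.8)
  dev <- sapply(c(2, 50), function(w) {
    a <- as.numeric(amplitudes_given_shifts(data, list(f1, f2),
                                            stoich_targets = targets,
                                            penalty_weight = w))
    abs(c(a[1] - 1.2, a[2] - 0.8))
  })
  # stronger penalty pulls the sums closer to the targets
  expect_true(all(dev[, 2] <= dev[, 1] + 1e-9))
})

test_that("fit_soret recovers a noiseless three-component mixture", {
  true_shifts <- c(3, 13, 8)
  true_amps <- c(2, 1.2, 0.4)
  forms <- list(basis$chl_a, basis$lutein, basis$neoxanthin)
  v <- Reduce(`+`, Map(function(f, sh, a) a * evaluate_form(f, soret_grid, sh)$value,
                       forms, true_shifts, true_amps))
  data <- spectrum(soret_grid, v)
  specs <- lapply(forms, form_spec)
  fit <- fit_soret(data, specs, options = soret_options(restarts = 4, seed = 1))
  expect_true(fit$converged)
  comp <- fit$components[match(c("chl_a", "lutein", "neoxanthin"),
                               fit$components$pigment), ]
  expect_lt(max(abs(comp$shift_nm - true_shifts)), 0.5)
  expect_lt(max(abs(comp$amplitude - true_amps) / true_amps), 0.02)
})

test_that("fit_soret matches the exhaustive grid-search oracle", {
  specs <- list(
    form_spec(basis$chl_a, 1L, c(2, 6)),
    form_spec(basis$lutein, 1L, c(11, 15)),
    form_spec(basis$violaxanthin, 1L, c(6, 10))
  )
  v <- 1.5 * evaluate_form(basis$chl_a, soret_grid, 3.7)$value +
    0.9 * evaluate_form(basis$lutein, soret_grid, 13.2)$value +
    0.5 * evaluate_form(basis$violaxanthin, soret_grid, 8.4)$value
  data <- spectrum(soret_grid, v)
  oracle <- grid_search_soret(data, specs, step = 0.5)
  fit <- fit_soret(data, specs, options = soret_options(restarts = 2, seed = 1))
  # optimizer must do at least as well as the coarse exhaustive search
  expect_lte(fit$objective, oracle$obj * 1.01)
})

test_that("adding an allowed instance never worsens the noiseless residual", {
  v <- 2 * evaluate_form(basis$chl_a, soret_grid, 4)$value +
    0.8 * evaluate_form(basis$lutein, soret_grid, 13)$value
  data <- spectrum(soret_grid, v)
  specs1 <- list(form_spec(basis$chl_a, 1L, c(0, 12)))
  specs2 <- c(specs1, list(form_spec(basis$lutein, 1L, c(10, 16))))
  f1 <- fit_soret(data, specs1, options = soret_options(restarts = 2, seed = 1))
  f2 <- fit_soret(data, specs2, options = soret_options(restarts = 2, seed = 1))
  expect_lte(f2$residual_rms, f1$residual_rms + 1e-12)
})

test_that("parameter recovery is near-exact over random separated scenarios", {
  set.seed(42)
  sh_errs <- c()
  amp_errs <- c()
  for (i in 1:10) {
    pigs <- sample(names(basis), sample(2:3, 1))
    repeat {
      shifts <- sort(runif(length(pigs), 1, 20))
      if (length(shifts) < 2 || min(diff(shifts)) > 4) break
    }
    amps <- runif(length(pigs), 0.5, 3)
    v <- Reduce(`+`, Map(function(p, sh, a) {
      a * evaluate_form(basis[[p]], soret_grid, sh)$value
    }, pigs, shifts, amps))
    fit <- fit_soret(spectrum(soret_grid, v),
                     lapply(pigs, function(p) form_spec(basis[[p]])),
                     options = soret_options(restarts = 4, seed = i))
    comp <- fit$components[match(pigs, fit$components$pigment), ]
    sh_errs <- c(sh_errs, abs(comp$shift_nm - shifts))
    amp_errs <- c(amp_errs, abs(comp$amplitude - amps) / amps)
  }
  expect_lt(median(sh_errs), 0.5)
  expect_lt(median(amp_errs), 0.02)
})

test_that("reconstruction round-trips an exact fit and its residual", {
  v <- 1.2 * evaluate_form(basis$chl_b, soret_grid, 6)$value +
    0.7 * evaluate_form(basis$violaxanthin, soret_grid, 17)$value
  data <- spectrum(soret_grid, v)
  specs <- list(form_spec(basis$chl_b, 1L, c(0, 12)),
                form_spec(basis$violaxanthin, 1L, c(14, 20)))
  fit <- fit_soret(data, specs, options = soret_options(restarts = 2, seed = 1))
  rec <- reconstruct(fit)
  expect_lt(max(abs(rec$value - v)) / max(v), 1e-5)
  rms <- sqrt(mean((data$value - rec$value)^2))
  expect_equal(rms, fit$residual_rms, tolerance = 1e-6)
})

test_that("zero-amplitude components reconstruct to the zero spectrum", {
  specs <- list(form_spec(basis$chl_a, 1L))
  fit <- structure(list(
    components = data.frame(pigment = "chl_a", instance = 1L,
                            shift_nm = 0, amplitude = 0),
    specs = specs,
    data = spectrum(soret_grid, rep(1, length(soret_grid)))
  ), class = "soret_fit")
  expect_equal(max(reconstruct(fit)$value), 0)
})

test_that("fit window must be covered by the data", {
  short <- spectrum(seq(430, 520, 0.5), rep(1, 181))
  expect_error(fit_soret(short, list(form_spec(basis$chl_a))), "window")
})
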