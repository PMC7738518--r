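test_that("fixture scenarios normalize to the published pigment rows", {
  ref <- lhcsr_pigment_stoichiometry()
  for (i in 1:2) {
    sc <- list(lhcsr1_scenario, lhcsr3_scenario)[[i]]()
    s <- normalize_to_chl(scenario_true_pigment_table(sc))
    expect_equal(s$neo_n, ref$neo[i], tolerance = 1e-9)
    expect_equal(s$vio_n, ref$vio[i], tolerance = 1e-9)
    expect_equal(s$lut_n, ref$lut[i], tolerance = 1e-9)
    expect_lt(abs(s$cars_n - ref$cars[i]), 0.005)
    expect_lt(abs(s$chl_ab_ratio - ref$chl_ab[i]), 0.005)
  }
})

test_that("noiseless generation is deterministic across seeds", {
  sc <- lhcsr1_scenario()
  t1 <- scenario_to_pigment_table(sc, seed = 1)
  t2 <- scenario_to_pigment_table(sc, seed = 99)
  expect_equal(unlist(t1), unlist(t2))
  s1 <- scenario_to_spectrum(sc, seed = 1)
  s2 <- scenario_to_spectrum(sc, seed = 99)
  expect_equal(s1$value, s2$value)
})

test_that("identical seeds give identical noisy output", {
  sc <- lhcsr1_scenario(noise = list(spectrum_sigma = 0.01, hplc_cv = 0.15,
                                     decay_total_counts = 1e5))
  expect_equal(unlist(scenario_to_pigment_table(sc, seed = 7)),
               unlist(scenario_to_pigment_table(sc, seed = 7)))
  expect_equal(scenario_to_spectrum(sc, seed = 7)$value,
               scenario_to_spectrum(sc, seed = 7)$value)
  d1 <- scenario_to_decays(sc, seed = 7)
  d2 <- scenario_to_decays(sc, seed = 7)
  expect_equal(d1[[1]]$counts, d2[[1]]$counts)
})

test_that("HPLC noise reproduces the configured coefficient of variation", {
  sc <- lhcsr1_scenario(noise = list(spectrum_sigma = 0, hplc_cv = 0.15,
                                     decay_total_counts = 1e6))
  luts <- sapply(1:200, function(seed) scenario_to_pigment_table(sc, seed)$lut)
  cv <- sd(luts) / mean(luts)
  expect_lt(abs(cv - 0.15) / 0.15, 0.20)
  # mean-corrected: expectation matches the true count
  expect_lt(abs(mean(luts) - 1.75) / 1.75, 0.05)
})

test_that("spectrum generation is linear in the molecule counts", {
  sc <- lhcsr3_scenario()
  doubled <- sc
  doubled$site_plan <- lapply(sc$site_plan, function(x) 2 * x)
  doubled$chl_plan <- lapply(sc$chl_plan, function(p) {
    p$n <- 2 * p$n
    p
  })
  s1 <- scenario_to_spectrum(sc)
  s2 <- scenario_to_spectrum(doubled)
  expect_equal(s2$value, 2 * s1$value, tolerance = 1e-12)
})

test_that("a pure single-pigment scenario equals the shifted form", {
  sc <- scenario("one", chl_plan = list(chl_a = list(n = 1, shifts = 4)))
  g <- seq(400, 520, by = 0.5)
  s <- scenario_to_spectrum(sc, grid = g)
  expect_equal(s$value, evaluate_form(default_basis()$chl_a, g, 4)$value,
               tolerance = 1e-12)
})

test_that("per-pigment spectral amplitudes equal the pigment table counts", {
  sc <- lhcsr1_scenario()
  counts <- unlist(scenario_true_pigment_table(sc))
  site_sums <- c(lut = 0, vio = 0, neo = 0)
  for (site in names(sc$site_plan)) {
    amt <- sc$site_plan[[site]]
    site_sums["lut"] <- site_sums["lut"] + sum(amt[names(amt) == "lutein"])
    site_sums["vio"] <- site_sums["vio"] + sum(amt[names(amt) == "violaxanthin"])
    site_sums["neo"] <- site_sums["neo"] + sum(amt[names(amt) == "neoxanthin"])
  }
  expect_equal(site_sums[["lut"]], counts[["lut"]], tolerance = 1e-12)
  expect_equal(site_sums[["vio"]], counts[["vio"]], tolerance = 1e-12)
  expect_equal(site_sums[["neo"]], counts[["neo"]], tolerance = 1e-12)
})

test_that("noise-free decays are proportional to the analytic model", {
  sc <- lhcii_scenario()
  d <- scenario_to_decays(sc, poisson = FALSE)
  t <- d[[1]]$time_ns
  model <- biexp_model(t, c(4.0, 1.5), c(0.80, 0.20))
  ratio <- d[[1]]$counts / model
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-12)
})

test_that("halving total counts halves the Poisson expectation", {
  mk <- function(total) lhcii_scenario(noise = list(
    spectrum_sigma = 0, hplc_cv = 0, decay_total_counts = total
  ))
  sums_hi <- sapply(1:30, function(s) sum(scenario_to_decays(mk(2e5), seed = s)[[1]]$counts))
  sums_lo <- sapply(1:30, function(s) sum(scenario_to_decays(mk(1e5), seed = s)[[1]]$counts))
  expect_lt(abs(mean(sums_hi) / mean(sums_lo) - 2), 0.02)
})

test_that("written scenario files are byte-identical for equal seeds", {
  sc <- lhcsr1_scenario(noise = list(spectrum_sigma = 0.01, hplc_cv = 0.15,
                                     decay_total_counts = 1e4))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_scenario(sc, d1, seed = 3)
  write_scenario(sc, d2, seed = 3)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # and the written inputs re-read cleanly
  expect_s3_class(read_spectrum(file.path(d1, "soret.csv")), "spectrum")
  expect_s3_class(read_pigment_table(file.path(d1, "pigments.csv")),
                  "pigment_table")
})
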