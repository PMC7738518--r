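test_that("single-exponential limits of the decay model are exact", {
  t <- default_time_grid(20, 512)
  m <- biexp_model(t, c(4, 1), c(1, 0))
  # log-linear with slope -1/tau when the second amplitude vanishes
  slope <- coef(lm(log(m) ~ t))[[2]]
  expect_equal(slope, -1 / 4, tolerance = 1e-9)
  # equal decay constants collapse to a single exponential for any split
  m2 <- biexp_model(t, c(2, 2), c(0.3, 0.7))
  expect_equal(m2, exp(-t / 2), tolerance = 1e-12)
  expect_error(biexp_model(t, c(-1, 2), c(0.5, 0.5)), "positive")
})

test_that("analytic IRF convolution matches a numerical quadrature oracle", {
  tau <- 2.3
  irf <- list(center_ns = 2, fwhm_ns = 0.35)
  sigma <- irf$fwhm_ns / (2 * sqrt(2 * log(2)))
  grid <- c(0.5, 1, 1.8, 2, 2.3, 3, 5, 9, 14, 18)
  num <- vapply(grid, function(tt) {
    # integrand support: the decay runs for s <= t, the kernel lives
    # within a few sigma of the IRF centre
    stats::integrate(function(s) dnorm(s, irf$center_ns, sigma) *
                       exp(-(tt - s) / tau),
                     lower = irf$center_ns - 12 * sigma,
                     upper = min(tt, irf$center_ns + 12 * sigma),
                     rel.tol = 1e-10)$value
  }, numeric(1))
  ana <- biexp_model(grid, tau, 1, irf = irf)
  expect_lt(max(abs(ana - num)) / max(num), 1e-4)
})

test_that("average_lifetime reproduces every published fit row", {
  tab <- lhcsr_decay_parameters()
  for (i in seq_len(nrow(tab))) {
    tavg <- average_lifetime(c(tab$tau1[i], tab$tau2[i]),
                             c(tab$a1[i], tab$a2[i]))
    expect_lt(abs(tavg - tab$tau_avg_printed[i]), 0.005)
  }
  # degenerate case: equal decay constants return that constant
  expect_equal(average_lifetime(c(2, 2), c(0.4, 0.6)), 2)
})

test_that("average_lifetime is invariant to joint amplitude rescaling", {
  expect_equal(average_lifetime(c(4.5, 1.5), c(0.5, 0.5)),
               average_lifetime(c(4.5, 1.5), c(5, 5)))
})

test_that("a noiseless bi-exponential decay is recovered within 0.5%", {
  t <- default_time_grid()
  true_tau <- c(4.540, 1.490)
  true_a <- c(0.509, 0.491)
  shape <- biexp_model(t, true_tau, true_a)
  h <- decay_histogram(t, shape * 1e6 / sum(shape))
  fit <- fit_biexponential(h)
  expect_lt(abs(fit$tau1_ns - true_tau[1]) / true_tau[1], 0.005)
  expect_lt(abs(fit$tau2_ns - true_tau[2]) / true_tau[2], 0.005)
  expect_lt(abs(fit$a1 - true_a[1]), 0.005)
  expect_equal(fit$a1 + fit$a2, 1, tolerance = 1e-9)
  expect_true(fit$tau1_ns >= fit$tau2_ns)
  expect_true(fit$tau_avg_ns >= fit$tau2_ns && fit$tau_avg_ns <= fit$tau1_ns)
})

test_that("Poisson-noise lifetime estimates are accurate at 1e6 counts", {
  sc <- scenario("sim", decay_plan = data.frame(
    condition = "c", ph = 7.5, detergent_pct = 0.03,
    tau1 = 3.2, a1 = 0.52, tau2 = 1.25, a2 = 0.48
  ), noise = list(spectrum_sigma = 0, hplc_cv = 0, decay_total_counts = 1e6))
  true_tavg <- average_lifetime(c(3.2, 1.25), c(0.52, 0.48))
  errs <- sapply(1:25, function(seed) {
    h <- scenario_to_decays(sc, seed = seed)[[1]]
    fit <- fit_biexponential(h, n_starts = 1)
    abs(fit$tau_avg_ns - true_tavg) / true_tavg
  })
  expect_lt(median(errs), 0.02)
  expect_lt(abs(mean(errs)), 0.02)  # near-unbiased tau_avg at high counts
})

test_that("single-exponential data fit with two components keeps tau_avg", {
  t <- default_time_grid()
  shape <- exp(-t / 2.5)
  h <- decay_histogram(t, shape * 1e6 / sum(shape))
  fit <- fit_biexponential(h)
  expect_lt(abs(fit$tau_avg_ns - 2.5) / 2.5, 0.01)
})

test_that("fit_biexponential matches the brute-force single-exp oracle", {
  t <- default_time_grid(20, 1024)
  shape <- exp(-t / 3.1)
  h <- decay_histogram(t, shape * 5e5 / sum(shape))
  oracle <- grid_search_single_exp(h)
  fit <- fit_biexponential(h, n_components = 1L)
  expect_lt(abs(fit$tau_ns[1] - oracle$tau) / oracle$tau, 0.005)
})

test_that("quenching comparisons quantify the lifetime reduction", {
  ref <- biexp_parameters(c(4.05, 1.53), c(0.474, 0.526))
  q <- biexp_parameters(c(2.87, 0.583), c(0.161, 0.839))
  cmp <- lifetime_reduction(ref, q)
  # oracle by direct arithmetic on the two average lifetimes
  expect_equal(cmp$fractional_reduction,
               1 - average_lifetime(q) / average_lifetime(ref),
               tolerance = 1e-12)
  expect_equal(lifetime_reduction(ref, ref)$fractional_reduction, 0)
  # LHCII-like mild quenching pair: ~10% reduction
  lhcii <- lhcii_scenario()$decay_plan
  r <- biexp_parameters(c(lhcii$tau1[1], lhcii$tau2[1]),
                        c(lhcii$a1[1], lhcii$a2[1]))
  qq <- biexp_parameters(c(lhcii$tau1[2], lhcii$tau2[2]),
                         c(lhcii$a1[2], lhcii$a2[2]))
  expect_equal(lifetime_reduction(r, qq)$fractional_reduction, 0.10,
               tolerance = 1e-9)
})

test_that("published-fixture lifetimes order by pH and detergent", {
  tab <- lhcsr_decay_parameters()
  for (prot in unique(tab$protein)) {
    sub <- tab[tab$protein == prot, ]
    tavg <- with(sub, mapply(function(t1, a1, t2, a2) {
      average_lifetime(c(t1, t2), c(a1, a2))
    }, tau1, a1, tau2, a2))
    names(tavg) <- paste(sub$ph, sub$detergent_pct)
    expect_lt(tavg[["5 0.03"]], tavg[["7.5 0.03"]])
    expect_lt(tavg[["5 0.007"]], tavg[["7.5 0.007"]])
    expect_lt(tavg[["7.5 0.007"]], tavg[["7.5 0.03"]])
    expect_lt(tavg[["5 0.007"]], tavg[["5 0.03"]])
  }
})

test_that("decay histogram validation and IO round trip", {
  expect_error(decay_histogram(c(1, 1, 2), c(0, 1, 2)), "increasing")
  expect_error(decay_histogram(1:3, c(1, -1, 2)), ">= 0")
  t <- default_time_grid(20, 64)
  h <- decay_histogram(t, round(1000 * exp(-t / 2)),
                       condition = list(ph = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_decay(h, path)
  h2 <- read_decay(path, condition = list(ph = 5))
  expect_equal(h2$time_ns, h$time_ns)
  expect_equal(h2$counts, h$counts)
})
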