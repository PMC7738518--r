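test_that("spectral_form validates band tables and is self-consistent", {
  expect_error(spectral_form("chl_a", data.frame(center_nm = 300, fwhm_nm = 20, height = 1)),
               "380-560")
  expect_error(spectral_form("chl_a", data.frame(center_nm = 430, fwhm_nm = -1, height = 1)),
               "positive")
  expect_error(spectral_form("loroxanthin",
                             data.frame(center_nm = 440, fwhm_nm = 20, height = 1)))
  # reference peak equals the red-most maximum of the evaluated zero-shift form
  for (f in default_basis()) {
    g <- seq(380, 560, by = 0.05)
    pk <- redmost_peak(evaluate_form(f, g, 0))
    expect_lt(abs(pk - f$reference_peak_nm), 0.1)
  }
})

test_that("zero shift leaves the red-most maximum at the reference peak", {
  b <- default_basis()
  g <- seq(400, 520, by = 0.5)
  s <- evaluate_form(b$lutein, g, 0)
  expect_lt(abs(redmost_peak(s) - b$lutein$reference_peak_nm), 0.05)
})

test_that("a 13 nm red shift moves the lutein peak by 13 nm (L1-like tuning)", {
  b <- default_basis()
  g <- seq(400, 520, by = 0.5)
  s <- evaluate_form(b$lutein, g, 13)
  expect_lt(abs(redmost_peak(s) - (b$lutein$reference_peak_nm + 13)), 0.05)
})

test_that("shifted peak position matches a dense-grid argmax oracle", {
  b <- default_basis()
  f <- b$violaxanthin
  dense <- seq(380, 560, by = 0.01)
  v <- numeric(length(dense))
  for (i in seq_len(nrow(f$bands))) {
    v <- v + gauss_curve(dense, f$bands$center_nm[i] + 5.3, f$bands$fwhm_nm[i],
                         f$bands$height[i])
  }
  # oracle: red-most local max of the dense band sum
  loc <- which(diff(sign(diff(v))) == -2) + 1
  oracle_peak <- dense[max(loc)]
  s <- evaluate_form(f, seq(400, 520, by = 0.5), 5.3)
  expect_lt(abs(redmost_peak(s) - oracle_peak), 0.5)
})

test_that("shift covariance holds for every pigment across the shift range", {
  b <- default_basis()
  g <- seq(395, 540, by = 0.25)
  for (f in b) {
    base <- redmost_peak(evaluate_form(f, g, 0))
    for (delta in c(2, 8.1, 13, 17.8)) {
      pk <- redmost_peak(evaluate_form(f, g, delta))
      expect_lt(abs((pk - base) - delta), 0.25)
    }
  }
})

test_that("unit-area normalization integrates to 1 independent of shift", {
  b <- default_basis()
  g <- seq(350, 600, by = 0.25)
  for (f in b) {
    for (delta in c(0, 10, 20)) {
      s <- evaluate_form(f, g, delta, shift_bounds = c(0, 25))
      area <- sum(s$value) * 0.25
      expect_lt(abs(area - 1), 1e-3)
    }
  }
})

test_that("evaluation is linear in the band heights", {
  bands <- data.frame(center_nm = c(440, 470), fwhm_nm = c(22, 20),
                      height = c(1, 0.8))
  f1 <- spectral_form("lutein", bands)
  bands2 <- transform(bands, height = 3 * height)
  f2 <- spectral_form("lutein", bands2)
  g <- seq(400, 520, by = 0.5)
  v1 <- evaluate_form(f1, g, 4, normalize = "none")$value
  v2 <- evaluate_form(f2, g, 4, normalize = "none")$value
  expect_equal(v2, 3 * v1, tolerance = 1e-12)
})

test_that("shift bounds and empty grids are rejected", {
  b <- default_basis()
  expect_error(evaluate_form(b$chl_a, seq(400, 520, 1), 26), "bounds")
  expect_error(evaluate_form(b$chl_a, seq(400, 520, 1), -1), "bounds")
  expect_error(evaluate_form(b$chl_a, numeric(0), 0), "empty")
})

test_that("basis_from_config overrides named pigments only", {
  cfg <- list(lutein = list(list(center_nm = 450, fwhm_nm = 24, height = 1)))
  b <- basis_from_config(cfg)
  expect_equal(nrow(b$lutein$bands), 1L)
  expect_equal(b$chl_a$bands, default_basis()$chl_a$bands)
})
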