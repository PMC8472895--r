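test_that("dose curves interpolate the reference knots exactly", {
  knots <- uhmwpeTable1("P-0")
  cur <- defaultDoseCurves("P-0", knots$wavelength_nm)
  expect_equal(cur$mu_a, knots$mu_a)
  expect_equal(cur$mu_s, knots$mu_s)
  at630 <- defaultDoseCurves("P-0", 630)
  expect_equal(at630$mu_a, 5.34)
  expect_equal(at630$mu_s, 120.06)
  at700 <- defaultDoseCurves("P-30", 700)
  expect_equal(at700$mu_a, 5.80)
  expect_equal(at700$mu_s, 94.93)
  expect_error(defaultDoseCurves("P-7"), "arg")
  expect_error(defaultDoseCurves("P-0", 500), "range")
})

test_that("interpolated curves stay monotone in the steep region", {
  # monotone piecewise-cubic interpolation must not overshoot between the
  # 630 and 700 nm knots of the irradiated doses
  wl <- seq(630, 700, by = 0.5)
  for (dose in c("P-30", "P-100")) {
    cur <- defaultDoseCurves(dose, wl)
    expect_true(all(diff(cur$mu_a) >= 0))
    expect_true(all(diff(cur$mu_s) >= 0))
  }
})

test_that("noiseless generation round-trips through the inversion", {
  wl <- seq(630, 800, by = 5)
  sp <- generateSpectrum("P-100", wl, noiseRelSd = 0, seed = 1)
  truth <- defaultDoseCurves("P-100", wl)
  inv <- as.data.frame(kmInvert(sp, g = 0.9))
  expect_equal(inv$mu_a, truth$mu_a, tolerance = 1e-6)
  expect_equal(inv$mu_s, truth$mu_s, tolerance = 1e-6)
})

test_that("generation is deterministic given a seed and records truth", {
  wl <- seq(630, 800, by = 10)
  a <- generateSpectrum("P-30", wl, noiseRelSd = 0.03, seed = 77)
  b <- generateSpectrum("P-30", wl, noiseRelSd = 0.03, seed = 77)
  expect_identical(reflectance(a), reflectance(b))
  expect_identical(transmittance(a), transmittance(b))
  c <- generateSpectrum("P-30", wl, noiseRelSd = 0.03, seed = 78)
  expect_false(identical(reflectance(a), reflectance(c)))

  md <- spectrumMetadata(a)
  expect_equal(md$noiseRelSd, 0.03)
  expect_equal(md$seed, 77)
  expect_equal(md$truth$mu_a, defaultDoseCurves("P-30", wl)$mu_a)
  expect_s4_class(a, "MeasuredSpectrum")  # invariants held despite noise
})

test_that("mean recovered absorption at 800 nm is unbiased at 3% noise", {
  recovered <- vapply(1:100, function(r) {
    sp <- generateSpectrum("P-0", c(790, 800), noiseRelSd = 0.03,
                           seed = 2000 + r)
    as.data.frame(kmInvert(sp))$mu_a[2]
  }, numeric(1))
  se <- stats::sd(recovered) / sqrt(length(recovered))
  expect_lt(abs(mean(recovered) - 6.09), 2 * se)
})

test_that("median recovery error stays below 5% across doses", {
  wl <- seq(630, 800, by = 10)
  for (dose in c("P-0", "P-30", "P-100")) {
    truth <- defaultDoseCurves(dose, wl)
    rel_a <- rel_s <- NULL
    for (r in 1:100) {
      sp <- generateSpectrum(dose, wl, noiseRelSd = 0.03, seed = 5000 + r)
      inv <- as.data.frame(kmInvert(sp))
      rel_a <- c(rel_a, abs(inv$mu_a - truth$mu_a) / truth$mu_a)
      rel_s <- c(rel_s, abs(inv$mu_s - truth$mu_s) / truth$mu_s)
    }
    expect_lt(stats::median(rel_a), 0.05)
    expect_lt(stats::median(rel_s), 0.05)
  }
})
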