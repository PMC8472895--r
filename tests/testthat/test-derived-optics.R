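test_that("scalar derived quantities match hand-computed values", {
  expect_equal(totalAttenuation(5.34, 120.06), 125.40)
  expect_equal(totalAttenuation(6.65, 102.78), 109.43)
  expect_equal(totalAttenuation(0, 0), 0)
  expect_equal(effectiveAttenuation(1.67, 29.72, g = 0.9), 4.642)
  expect_equal(effectiveAttenuation(5, 0, g = 0.9), 5)    # mu_s = 0
  expect_equal(effectiveAttenuation(5, 100, g = 1), 5)    # fully forward
  expect_equal(penetrationDepth(10), 0.1)
  expect_equal(penetrationDepth(4.642), 0.2154, tolerance = 1e-3)   # 2.15 mm
  expect_equal(penetrationDepth(10.325), 0.0969, tolerance = 1e-3)  # 0.97 mm
  expect_error(penetrationDepth(0), "positive")
  expect_equal(transportAlbedo(5, 0), 0)
  expect_error(transportAlbedo(0, 0), "positive")
})

test_that("derived quantities accept OpticalProperties objects", {
  op <- OpticalProperties(muA = 6.09, muS = 128.02, g = 0.9)
  expect_equal(totalAttenuation(op), 134.11)
  expect_equal(effectiveAttenuation(op), 6.09 + 12.802)
  expect_equal(transportAlbedo(op), 128.02 / 134.11)
  expect_equal(diffusionEffectiveAttenuation(op),
               sqrt(3 * 6.09 * (6.09 + 128.02 * 0.1)))
})

test_that("albedo is scale invariant and delta decreases with attenuation", {
  set.seed(3)
  mu_a <- runif(10, 0.5, 10); mu_s <- runif(10, 20, 130)
  for (c_scale in c(0.1, 3, 42))
    expect_equal(transportAlbedo(c_scale * mu_a, c_scale * mu_s),
                 transportAlbedo(mu_a, mu_s))
  d0 <- penetrationDepth(effectiveAttenuation(mu_a, mu_s))
  expect_true(all(penetrationDepth(effectiveAttenuation(mu_a + 1, mu_s)) < d0))
  expect_true(all(penetrationDepth(effectiveAttenuation(mu_a, mu_s + 1)) < d0))
})

test_that("pristine-sample penetration depth is flat across the band", {
  # flatness measured as the coefficient of variation of delta over
  # 630-800 nm for the unirradiated sample
  tab <- buildSpectralTable(stats::setNames(
    uhmwpeTable1("P-0")[c("wavelength_nm", "dose", "mu_a", "mu_s")],
    c("wavelength", "dose", "mu_a", "mu_s")))
  cv <- stats::sd(tab$delta_cm) / mean(tab$delta_cm)
  expect_lt(cv, 0.07)
})

test_that("spectral table assembly populates, orders and validates", {
  one <- buildSpectralTable(data.frame(wavelength = 800, dose = "P-0",
                                       mu_a = 6.09, mu_s = 128.02))
  expect_equal(nrow(one), 1L)
  expect_equal(one$mu_t, 134.11)
  expect_equal(one$delta_cm, 1 / one$mu_eff)
  expect_equal(one$delta_mm, 10 * one$delta_cm)

  empty <- buildSpectralTable(data.frame(wavelength = numeric(),
                                         dose = character(),
                                         mu_a = numeric(), mu_s = numeric()))
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("mu_t", "mu_eff", "delta_mm", "albedo") %in%
                  names(empty)))

  dup <- data.frame(wavelength = c(800, 800), dose = "P-0",
                    mu_a = c(6, 6), mu_s = c(120, 121))
  expect_error(buildSpectralTable(dup), "duplicate")
})

test_that("spectral table from the full reference fixture has 54 rows", {
  tab <- uhmwpeTable1()
  st <- buildSpectralTable(data.frame(wavelength = tab$wavelength_nm,
                                      dose = tab$dose, mu_a = tab$mu_a,
                                      mu_s = tab$mu_s))
  expect_equal(nrow(st), 54L)
  expect_equal(length(unique(st$wavelength)), 18L)
  expect_true(all(st$albedo > 0 & st$albedo < 1))
  # printed attenuation column agrees with mu_a + mu_s within print rounding
  m <- merge(st, tab, by.x = c("wavelength", "dose"),
             by.y = c("wavelength_nm", "dose"))
  expect_true(all(abs(m$mu_t - m$mu_t_printed) <= 0.02))
})
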