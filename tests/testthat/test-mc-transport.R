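test_that("free-path sampling follows the exponential law", {
  expect_equal(sampleStep(1, 134.11), 0)
  expect_equal(sampleStep(exp(-1), 134.11), 1 / 134.11)
  expect_error(sampleStep(0, 134.11), "resample")
  set.seed(5)
  n <- 2e5
  s <- sampleStep(1 - runif(n), muT = 20)
  # exponential mean 1/mu_t, sd 1/mu_t
  expect_lt(abs(mean(s) - 1 / 20), 3 * (1 / 20) / sqrt(n))
})

test_that("Henyey-Greenstein sampling has the right moments and limits", {
  expect_equal(sampleHG(0.75, g = 0), 0.5)
  set.seed(6)
  xi <- runif(1e6)
  ct <- sampleHG(xi, g = 0.9)
  expect_true(all(ct >= -1 & ct <= 1))
  expect_lt(abs(mean(ct) - 0.9), 3 * stats::sd(ct) / sqrt(length(ct)))
  # isotropic limit: cos(theta) uniform on [-1, 1]
  ct0 <- sampleHG(runif(2e4), g = 0)
  ks <- suppressWarnings(stats::ks.test(ct0, "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("Fresnel reflectance covers matched, normal and critical regimes", {
  expect_equal(fresnelReflectance(1.54, 1.54, 0.7), 0)
  expect_equal(fresnelReflectance(1, 1.54, 1), ((1 - 1.54) / (1 + 1.54))^2,
               tolerance = 1e-12)
  # total internal reflection beyond the critical angle (sin_c = 1/1.54)
  cos_crit <- sqrt(1 - (1 / 1.54)^2)
  expect_equal(fresnelReflectance(1.54, 1, 0.5 * cos_crit), 1)
  expect_lt(fresnelReflectance(1.54, 1, 1), 1)
})

test_that("weight bookkeeping closes exactly and runs are reproducible", {
  cfg <- MCConfig(nPhotons = 2e4, seed = 31)
  for (geo in list(SlabGeometry(matched = TRUE), SlabGeometry())) {
    r <- mcRun(OpticalProperties(muA = 6.09, muS = 128.02), geo, cfg)
    expect_lt(abs(r@rSpecular + r@rDiffuse + r@tDiffuse + r@aTotal - 1),
              1e-9)
    expect_equal(sum(r@aRZ), r@aTotal, tolerance = 1e-12)
  }
  r1 <- mcRun(OpticalProperties(muA = 2, muS = 50), config = cfg)
  r2 <- mcRun(OpticalProperties(muA = 2, muS = 50), config = cfg)
  expect_identical(r1@aRZ, r2@aRZ)
  expect_identical(r1@rDiffuse, r2@rDiffuse)
  r3 <- mcRun(OpticalProperties(muA = 2, muS = 50),
              config = MCConfig(nPhotons = 2e4, seed = 32))
  expect_false(identical(r1@rDiffuse, r3@rDiffuse))
})

test_that("pure absorber reproduces Beer-Lambert transmission", {
  mu_a <- 25; t <- 0.05
  r <- mcRun(OpticalProperties(muA = mu_a, muS = 0),
             SlabGeometry(thickness = t, matched = TRUE),
             MCConfig(nPhotons = 1e5, seed = 8))
  t_ref <- exp(-mu_a * t)
  expect_lt(abs(r@tDiffuse - t_ref), 3 * se_frac(t_ref, 1e5))
  expect_equal(r@rDiffuse, 0)  # nothing scatters back
})

test_that("non-absorbing slab splits all weight between R and T", {
  r <- mcRun(OpticalProperties(muA = 0, muS = 80),
             SlabGeometry(matched = TRUE),
             MCConfig(nPhotons = 2e4, seed = 9))
  expect_identical(r@aTotal, 0)
  expect_equal(r@rDiffuse + r@tDiffuse, 1, tolerance = 1e-12)
  expect_true(all(r@aRZ == 0))
})

test_that("engine reproduces the van de Hulst reference slab", {
  n <- 4e5
  r <- mcRun(OpticalProperties(muA = vdh_slab$mu_a, muS = vdh_slab$mu_s,
                               g = vdh_slab$g),
             SlabGeometry(thickness = vdh_slab$d, matched = TRUE),
             MCConfig(nPhotons = n, seed = 12))
  expect_lt(abs(r@rDiffuse - vdh_slab$rd), 4 * se_frac(vdh_slab$rd, n))
  expect_lt(abs(r@tDiffuse - vdh_slab$td), 4 * se_frac(vdh_slab$td, n))
})

test_that("Monte Carlo error shrinks as one over root n", {
  reps <- function(n, seeds) vapply(seeds, function(s)
    mcRun(OpticalProperties(muA = 10, muS = 90, g = 0.75),
          SlabGeometry(thickness = 0.02, matched = TRUE),
          MCConfig(nPhotons = n, seed = s))@rDiffuse, numeric(1))
  sd4 <- stats::sd(reps(1e4, 101:112))
  sd5 <- stats::sd(reps(1e5, 201:212))
  sd6 <- stats::sd(reps(1e6, 301:312))
  # expected ratios sqrt(10) and 10; wide bands absorb the sd-of-sd noise
  expect_gt(sd4 / sd5, sqrt(10) / 2.5); expect_lt(sd4 / sd5, sqrt(10) * 2.5)
  expect_gt(sd4 / sd6, 10 / 2.5);       expect_lt(sd4 / sd6, 10 * 2.5)
})

test_that("isotropic scattering gives an azimuthally uniform exit", {
  # mu_a = 0 so every escaping packet carries unit weight: the phi-binned
  # reflectance is a true count vector suitable for a chi-square test
  n <- 5e4
  r <- mcRun(OpticalProperties(muA = 0, muS = 60, g = 0),
             SlabGeometry(matched = TRUE),
             MCConfig(nPhotons = n, seed = 13))
  counts <- round(colSums(r@rAngular) * n)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("absorption map normalizations are consistent", {
  r <- mcRun(OpticalProperties(muA = 6.09, muS = 128.02),
             SlabGeometry(matched = TRUE), MCConfig(nPhotons = 2e4, seed = 14))
  frac <- absorptionMap(r, "fraction")
  expect_equal(sum(frac$grid$value), r@aTotal, tolerance = 1e-12)
  pa <- absorptionMap(r, "per_area")
  pv <- absorptionMap(r, "per_volume")
  expect_equal(pv$grid$value, pa$grid$value / r@config@dz)
  expect_error(absorptionMap(r, "per_parsec"))

  # a non-interacting run yields an all-zero map
  r0 <- mcRun(OpticalProperties(muA = 0, muS = 60),
              SlabGeometry(matched = TRUE), MCConfig(nPhotons = 100, seed = 1))
  m0 <- absorptionMap(r0, "fraction")
  expect_true(all(m0$grid$value == 0))
  expect_true(is.na(m0$isoDepthCm))
})

test_that("irradiated sample absorbs deeper than pristine at 800 nm", {
  cfg <- MCConfig(nPhotons = 2e5, seed = 15)
  geo <- SlabGeometry(matched = TRUE)
  d_p0 <- absorptionMap(mcRun(table1Properties("P-0", 800), geo, cfg),
                        "per_area", isoLevel = 0.5)$isoDepthCm
  d_p30 <- absorptionMap(mcRun(table1Properties("P-30", 800), geo, cfg),
                         "per_area", isoLevel = 0.5)$isoDepthCm
  expect_gte(d_p30, d_p0)
})

test_that("simulator guards its domain", {
  expect_error(mcRun(OpticalProperties(muA = 0, muS = 0)), "positive")
  expect_error(mcRun(OpticalProperties(muA = c(1, 2), muS = c(3, 4))),
               "length 1")
  expect_error(mcRun(OpticalProperties(muA = 1, muS = 10),
                     SlabGeometry(thickness = 0.2),
                     MCConfig(dz = 1e-3, nz = 10)),
               "cover")
})
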