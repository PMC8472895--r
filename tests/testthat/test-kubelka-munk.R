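test_that("auxiliaries hit the non-absorbing limit and reject unphysical pairs", {
  # rd + td = 1 forces x = (1 - td^2 + rd^2)/(2 rd) = 1, y = 0
  aux <- kmAuxiliaries(0.3, 0.7)
  expect_equal(aux$x, 1)
  expect_equal(aux$y, 0)
  expect_error(kmAuxiliaries(0.5, 0.6), "invalid measurement")
  expect_error(kmAuxiliaries(1.2, 0.1), "rd")
})

test_that("auxiliaries match direct evaluation at a forward-model point", {
  # R_d/T_d produced by the forward model at mu_a = 6.09, mu_s = 128.02,
  # g = 0.9, t = 0.05 (frozen from the closed form); x, y by direct algebra
  fw <- kmForward(6.09, 0.05, muS = 128.02, g = 0.9)
  aux <- kmAuxiliaries(fw$rd, fw$td)
  x_direct <- (1 - fw$td^2 + fw$rd^2) / (2 * fw$rd)
  expect_equal(aux$x, x_direct, tolerance = 1e-12)
  expect_equal(aux$x, 2.5076123, tolerance = 1e-7)
  expect_equal(aux$y, 2.2995912, tolerance = 1e-7)
})

test_that("forward closed form agrees with the two-flux ODE oracle", {
  set.seed(42)
  for (i in 1:20) {
    mu_s <- runif(1, 25, 135)
    mu_a <- runif(1, 0.5, 0.25 * mu_s)  # keep inside the model's domain
    t <- runif(1, 0.02, 0.1)
    fw <- kmForward(mu_a, t, muS = mu_s, g = 0.9)
    ode <- twoflux_ode_oracle(mu_a, mu_s, 0.9, t)
    expect_equal(fw$rd, ode$rd, tolerance = 1e-8)
    expect_equal(fw$td, ode$td, tolerance = 1e-8)
  }
})

test_that("forward model limits: no absorption and vanishing slab", {
  fw0 <- kmForward(0, 0.05, muS = 100, g = 0.9)
  expect_equal(fw0$rd + fw0$td, 1)
  fwt <- kmForward(5, 1e-12, muS = 100, g = 0.9)
  expect_equal(fwt$rd, 0, tolerance = 1e-9)
  expect_equal(fwt$td, 1, tolerance = 1e-9)
  expect_error(kmForward(50, 0.05, muS = 10, g = 0.9), "conversion-domain")
})

test_that("forward model conserves energy and is monotone in absorption", {
  set.seed(7)
  for (i in 1:20) {
    mu_s <- runif(1, 25, 135)
    mu_a <- sort(runif(3, 0.5, 0.25 * mu_s))
    fw <- kmForward(mu_a, 0.05, muS = rep(mu_s, 3), g = 0.9)
    expect_true(all(fw$rd + fw$td < 1))
    expect_true(all(diff(fw$rd) < 0))   # more absorption, less reflectance
    expect_true(all(diff(fw$td) < 0))
  }
})

test_that("inversion of forward-model output recovers reference coefficients", {
  # mu_a = 6.09, mu_s = 128.02 (pristine sample at 800 nm)
  fw <- kmForward(6.09, 0.05, muS = 128.02, g = 0.9)
  sp <- MeasuredSpectrum(800, fw$rd, fw$td, thickness = 0.05, label = "P-0")
  inv <- as.data.frame(kmInvert(sp, g = 0.9))
  expect_equal(inv$mu_a, 6.09, tolerance = 1e-6)
  expect_equal(inv$mu_s, 128.02, tolerance = 1e-6)
  expect_equal(inv$s, 8.079, tolerance = 1e-4)   # S = (3(1-g)mu_s - mu_a)/4
  expect_equal(inv$k, 12.18, tolerance = 1e-4)   # K = 2 mu_a
})

test_that("round trip is exact to 1e-6 across the coefficient range", {
  grid <- expand.grid(mu_a = seq(1, 10, length.out = 5),
                      mu_s = seq(25, 135, length.out = 5))
  # the two-flux model is only defined where 3(1-g) mu_s > mu_a
  grid <- grid[3 * 0.1 * grid$mu_s > grid$mu_a, ]
  fw <- kmForward(grid$mu_a, 0.05, muS = grid$mu_s, g = 0.9)
  sp <- MeasuredSpectrum(seq_len(nrow(grid)) + 600, fw$rd, fw$td,
                         thickness = 0.05)
  inv <- as.data.frame(kmInvert(sp, g = 0.9))
  expect_equal(inv$mu_a, grid$mu_a, tolerance = 1e-6)
  expect_equal(inv$mu_s, grid$mu_s, tolerance = 1e-6)
})

test_that("degenerate and invalid measurements raise informative errors", {
  sp <- MeasuredSpectrum(700, 0.3, 0.7, thickness = 0.05)  # rd + td = 1
  expect_error(kmInvert(sp), "degenerate")
  expect_error(MeasuredSpectrum(700, 0.5, 0.6, thickness = 0.05),
               "exceed")
  expect_error(MeasuredSpectrum(c(700, 650), c(0.2, 0.2), c(0.3, 0.3)),
               "increasing")
})
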