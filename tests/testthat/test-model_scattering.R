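test_that("Debye closed forms: single scatterer and two-site dumbbell", {
  q <- seq(0, 0.5, length.out = 60)
  one <- debye_curve(coordinate_model(rbind(c(1, 1, 1)), weights = 2), q)
  expect_true(all(one$I == 4))
  two <- debye_curve(coordinate_model(rbind(c(0, 0, 0), c(0, 0, 10))), q)
  x <- 10 * q
  expected <- 2 * (1 + ifelse(x == 0, 1, sin(x) / x))
  expect_equal(two$I, expected, tolerance = 1e-12)
  expect_equal(two$I[1L], 4)       # I(0) = (sum w)^2
})

test_that("Debye output is invariant under rigid motion and I(0) exact", {
  set.seed(11)
  q <- seq(0.005, 0.4, length.out = 50)
  m <- ball_model(120, 18, seed = 3)
  m$weights <- runif(120, 0.5, 2)
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  m2 <- coordinate_model(m$positions %*% t(R) +
                           matrix(c(7, -4, 11), 120, 3, byrow = TRUE),
                         weights = m$weights)
  I1 <- debye_curve(m, q)$I
  I2 <- debye_curve(m2, q)$I
  expect_lt(max(abs(I1 / I2 - 1)), 1e-10)
  q0 <- debye_curve(m, c(0, 0.01, 0.02, 0.03, 0.04))$I[1L]
  expect_equal(q0, sum(m$weights)^2, tolerance = 1e-12)
})

test_that("ball sample reproduces the analytic sphere form factor", {
  n <- 2000
  qg <- seq(0.001, 6 / 30, length.out = 80)
  bm <- ball_model(n, 30, seed = 2)
  I <- debye_curve(bm, qg)$I
  Ihat <- (I - n) / (n * (n - 1))       # distinct-pair normalized
  F2 <- sphere_curve(30, 1, qg)$I
  # deviation on unit-normalized curves (relative to forward scattering)
  expect_lt(max(abs(Ihat - F2)), 0.03)
})

test_that("histogram and exact Debye paths agree within chi 0.05", {
  q <- seq(0.005, 0.35, length.out = 80)
  m <- ball_model(600, 20, seed = 8)
  binned <- debye_curve(m, q, bin_width = 0.5)   # N > 500: histogram
  d <- as.numeric(dist(m$positions))             # brute-force pair sum
  exact <- vapply(q, function(qq)
    600 + 2 * sum(sin(qq * d) / (qq * d)), numeric(1L))
  datp <- scattering_profile(q, exact, sigma = 0.01 * exact)
  f <- fit_to_profile(binned, datp)
  expect_lte(f$chi, 0.05)
})

test_that("low-q expansion: Guinier Rg of the Debye curve matches the model", {
  m <- ball_model(500, 25, seed = 4)
  rg_m <- rg_from_model(m)
  q <- seq(0.002, 1.4 / rg_m, length.out = 120)
  g <- guinier_fit(debye_curve(m, q))
  expect_lt(abs(g$Rg / rg_m - 1), 0.01)
})

test_that("model radius of gyration closed forms", {
  expect_equal(rg_from_model(coordinate_model(rbind(c(3, 2, 1)))), 0)
  two <- coordinate_model(rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(rg_from_model(two), 5)
  expect_lt(abs(rg_from_model(ball_model(20000, 30, seed = 1)) /
                  (sqrt(3 / 5) * 30) - 1), 0.01)
})

test_that("profile fitting recovers affine parameters and ranks nested fits", {
  q <- seq(0.005, 0.3, length.out = 100)
  model <- sphere_curve(28, 1, q)
  data0 <- scattering_profile(q, model$I, sigma = rep(0.01, 100))
  f0 <- fit_to_profile(model, data0)
  expect_equal(f0$scale_c, 1, tolerance = 1e-12)
  expect_equal(f0$chi, 0, tolerance = 1e-9)
  data1 <- scattering_profile(q, 5 * model$I + 0.1,
                              sigma = rep(0.01, 100))
  f1 <- fit_to_profile(model, data1, subtract_constant = TRUE)
  expect_equal(f1$scale_c, 5, tolerance = 1e-9)
  expect_equal(f1$constant_b, 0.1, tolerance = 1e-9)
  expect_equal(f1$chi, 0, tolerance = 1e-6)
  f2 <- fit_to_profile(model, data1, subtract_constant = FALSE)
  expect_equal(f2$constant_b, 0)
  expect_gt(f2$chi, f1$chi)
  expect_error(
    fit_to_profile(scattering_profile(q + 10, model$I), data1), "grid")
})

test_that("model ranking orders by chi with stable ties", {
  q <- seq(0.005, 0.3, length.out = 80)
  compact <- ball_model(200, 20, seed = 1)
  elong <- coordinate_model(sweep(compact$positions, 2L, c(1, 1, 3), "*"))
  truth <- debye_curve(compact, q)
  data <- scattering_profile(q, truth$I, sigma = 0.01 * truth$I)
  tab <- rank_models(list(elongated = elong, compact = compact), data)
  expect_equal(tab$model[1L], "compact")
  # rigid translation gives an exact chi tie, broken by input order
  shifted <- coordinate_model(compact$positions +
                                matrix(c(5, 5, 5), 200, 3, byrow = TRUE))
  tab2 <- rank_models(list(a = compact, b = shifted), data)
  expect_equal(tab2$chi[1L], tab2$chi[2L], tolerance = 1e-9)
  expect_equal(tab2$model, c("a", "b"))
  expect_error(rank_models(list(), data), "empty")
})

test_that("solvent-contrast weighting reduces effective weights", {
  m <- coordinate_model(rbind(c(0, 0, 0), c(0, 0, 8)),
                        weights = c(2, 2), volumes = c(10, 10))
  q <- seq(0, 0.3, length.out = 20)
  full <- debye_curve(m, q)$I[1L]
  half <- debye_curve(m, q, solvent_contrast = 0.5)$I[1L]
  expect_equal(full, 16)
  expect_equal(half, 4)   # weights halved -> I(0) quartered
})
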