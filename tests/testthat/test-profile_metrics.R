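test_that("Guinier fit recovers exact exponentials to 1e-6 relative", {
  q <- seq(0.002, 0.2, length.out = 100)
  set.seed(7)
  for (rep in 1:20) {
    a <- exp(runif(1, -2, 3))
    Rg <- runif(1, 10, 45)
    p <- scattering_profile(q, a * exp(-q^2 * Rg^2 / 3))
    g <- guinier_fit(p)
    expect_lt(abs(g$Rg / Rg - 1), 1e-6)
    expect_lt(abs(g$I0 / a - 1), 1e-6)
  }
})

test_that("Guinier fit on the sphere curve matches sqrt(3/5)*R", {
  q <- seq(0.004, 0.35, length.out = 200)
  g <- guinier_fit(sphere_curve(30, 5, q))
  expect_lt(abs(g$Rg / (sqrt(3 / 5) * 30) - 1), 0.005)
  expect_lte(g$q_window[2L] * g$Rg, 1.3 + 1e-9)
  expect_gte(g$n_points, 5L)
})

test_that("flat and degenerate profiles yield no Guinier region", {
  q <- seq(0.01, 0.2, length.out = 50)
  expect_error(guinier_fit(scattering_profile(q, rep(1, 50))),
               "no-Guinier-region")
  # rising intensity: positive slope everywhere
  expect_error(guinier_fit(scattering_profile(q, exp(q^2 * 100))),
               "no-Guinier-region")
})

test_that("skip_low_q excludes contaminated low-q points", {
  q <- seq(0.003, 0.15, length.out = 80)
  I <- 5 * exp(-q^2 * 25^2 / 3)
  I[1:4] <- I[1:4] * 1.5           # aggregation-like upturn
  g <- guinier_fit(scattering_profile(q, I), skip_low_q = 4L)
  expect_lt(abs(g$Rg - 25), 0.01)
})

test_that("Kratky transform is pointwise I*q^2 with zero at q = 0", {
  q <- c(0, seq(0.01, 0.2, length.out = 30))
  k <- kratky_transform(scattering_profile(q, rep(1, length(q))))
  expect_equal(k$Iq2, q^2)
  expect_equal(k$Iq2[1L], 0)
})

test_that("globular curves peak in Kratky; Gaussian chains plateau", {
  q <- seq(0.001, 0.6, length.out = 300)
  ks <- kratky_transform(sphere_curve(30, 1, q))
  peak <- which.max(ks$Iq2)
  expect_gt(peak, 5L)
  expect_lt(peak, length(q) - 5L)      # interior maximum
  kc <- kratky_transform(gaussian_chain_curve(30, 1, q))
  # high-q values approach the 2*I0/Rg^2 plateau from below
  plateau <- 2 * 1 / 30^2
  tail_vals <- kc$Iq2[q > 0.3]
  expect_true(all(diff(tail_vals) > -1e-12))
  expect_lt(abs(tail_vals[length(tail_vals)] / plateau - 1), 0.05)
})

test_that("Porod volume of a sphere is recovered within 10%", {
  q <- seq(0.002, 25 / 30, length.out = 2000)
  po <- porod_volume(sphere_curve(30, 1, q), I0 = 1)
  expect_lt(abs(po$Vp / (4 / 3 * pi * 30^3) - 1), 0.10)
})

test_that("Porod tail extension equals the analytic q^-4 integral", {
  # for I = q^-4 the remaining invariant integral past qmax is
  # qmax^4 * I(qmax) * qmax^-1 = I(qmax) * qmax^3
  q <- seq(0.05, 0.4, length.out = 500)
  p <- scattering_profile(q, q^-4)
  Q_with <- porod_volume(p, I0 = 1, tail_power_law = TRUE)$Q_invariant
  Q_wo <- suppressWarnings(
    porod_volume(p, I0 = 1, tail_power_law = FALSE)$Q_invariant)
  expect_equal(Q_with - Q_wo, max(q)^3 * max(q)^-4, tolerance = 1e-12)
})

test_that("Porod volume is invariant under uniform intensity scaling", {
  q <- seq(0.002, 0.6, length.out = 600)
  s <- sphere_curve(25, 1, q)
  v1 <- porod_volume(s, I0 = 1)$Vp
  v2 <- porod_volume(scattering_profile(q, 2 * s$I), I0 = 2)$Vp
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("mass and dimer-fraction arithmetic behaves at the endpoints", {
  expect_equal(mass_from_porod(0), 0)
  expect_error(mass_from_porod(-1), "domain")
  expect_equal(oligomer_fraction(38014, 38014)$dimer_fraction, 0)
  expect_equal(oligomer_fraction(2 * 38014, 38014)$dimer_fraction, 1)
  expect_error(oligomer_fraction(1, 0), "domain")
  # monotone non-decreasing in apparent mass, bounded in [0, 1]
  ws <- vapply(seq(20000, 100000, length.out = 40), function(m)
    oligomer_fraction(m, 38014)$dimer_fraction, numeric(1L))
  expect_true(!is.unsorted(ws))
  expect_true(all(ws >= 0 & ws <= 1))
})

test_that("concentration scaling and infinite-dilution extrapolation", {
  q <- seq(0.005, 0.25, length.out = 80)
  base <- sphere_curve(25, 4, q)
  one <- base; one$concentration <- 2
  s1 <- scale_and_extrapolate(list(one))
  expect_equal(s1$I, base$I / 2)
  # structure-factor-like phantom: I(q, c) = I0(q) (1 - k c)
  k <- 0.04
  series <- lapply(c(1, 2, 5), function(cc) {
    p <- scattering_profile(q, cc * base$I * (1 - k * cc))
    p$concentration <- cc
    p
  })
  ext <- scale_and_extrapolate(series)
  expect_lt(max(abs(ext$I / base$I - 1)), 1e-6)
  expect_error(scale_and_extrapolate(list(base)), "concentration")
})

test_that("range merging rescales and splices correctly", {
  q <- seq(0.005, 0.3, length.out = 150)
  truth <- sphere_curve(28, 3, q)
  lo <- scattering_profile(q[q <= 0.16], truth$I[q <= 0.16])
  hi <- scattering_profile(q[q >= 0.07], 3 * truth$I[q >= 0.07])
  mg <- merge_ranges(lo, hi, c(0.08, 0.15))
  expect_equal(attr(mg, "scale_factor"), 1 / 3, tolerance = 1e-9)
  common <- q[q > 0.01 & q < 0.29]
  expect_lt(max(abs(approx(mg$q, mg$I, common)$y /
                    approx(q, truth$I, common)$y - 1)), 1e-9)
  expect_true(all(diff(mg$q) > 0))
  expect_error(merge_ranges(lo, hi, c(0.4, 0.5)), "merge error")
})
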