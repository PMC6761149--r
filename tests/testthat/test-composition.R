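test_that("noiseless mixtures decompose exactly for any simplex point", {
  pair <- phantom_pair()
  data <- scattering_profile(q_default,
                             0.6 * pair$I_mono$I + 0.4 * pair$I_dimer$I)
  mx <- fit_mixture(data, list(pair$I_mono, pair$I_dimer))
  expect_equal(mx$fractions, c(0.6, 0.4), tolerance = 1e-9)
  expect_equal(sum(mx$fractions), 1, tolerance = 1e-9)
  expect_lt(mx$chi, 1e-9)
  set.seed(21)
  comps <- list(pair$I_mono, pair$I_dimer,
                sphere_curve(12, 1, q_default))
  for (rep in 1:10) {
    f <- as.numeric(rmultinom(1, 1000, c(1, 1, 1))) / 1000
    data <- scattering_profile(q_default,
                               f[1] * comps[[1]]$I + f[2] * comps[[2]]$I +
                                 f[3] * comps[[3]]$I)
    mx <- fit_mixture(data, comps)
    expect_equal(mx$fractions, f, tolerance = 1e-6)
    expect_lt(mx$chi, 1e-6)
  }
})

test_that("single-component mixtures reduce to fit_to_profile", {
  pair <- phantom_pair()
  data <- scattering_profile(q_default, 3 * pair$I_mono$I,
                             sigma = 0.01 * pair$I_mono$I)
  mx <- fit_mixture(data, list(pair$I_mono))
  ft <- fit_to_profile(pair$I_mono, data)
  expect_equal(mx$fractions, 1)
  expect_equal(mx$chi, ft$chi, tolerance = 1e-9)
  expect_equal(mx$scale_c, ft$scale_c, tolerance = 1e-9)
})

test_that("mixture solver agrees with an independent NNLS on clean designs", {
  pair <- phantom_pair()
  w <- 0.35
  data <- mix_curve(pair, w)
  C <- cbind(pair$I_mono$I, pair$I_dimer$I)
  ref <- pracma::lsqnonneg(C, data$I)$x
  mx <- fit_mixture(data, list(pair$I_mono, pair$I_dimer))
  expect_equal(mx$fractions, ref / sum(ref), tolerance = 1e-8)
})

test_that("noisy monomer/dimer fractions are recovered without bias", {
  pair <- phantom_pair()
  errs <- numeric(0)
  for (w in c(0.1, 0.42)) {
    for (s in 1:15) {
      noisy <- add_noise(mix_curve(pair, w), 0.01, seed = 100 * w + s)
      mx <- fit_mixture(noisy, list(pair$I_mono, pair$I_dimer))
      errs <- c(errs, weight_fraction(mx) - w)
    }
  }
  expect_lt(mean(abs(errs)), 0.02)
})

test_that("all-zero components are rejected", {
  q <- seq(0.01, 0.2, length.out = 50)
  data <- sphere_curve(20, 1, q)
  expect_error(fit_mixture(data,
                           list(scattering_profile(q, rep(0, 50)))),
               "degenerate-design")
})

test_that("conformer pools honor walk geometry and determinism", {
  core <- ball_model(60, 12, seed = 2)
  segs <- list(list(attach = which.max(core$positions[, 3L]), n = 31))
  pool <- generate_pool(core, segs, n_conformers = 5, seed = 9)
  expect_length(pool, 5L)
  for (cf in pool) {
    expect_equal(nrow(cf$positions), 91L)
    tail_pos <- cf$positions[61:91, ]
    attach <- core$positions[segs[[1L]]$attach, ]
    steps <- sqrt(rowSums(diff(rbind(attach, tail_pos))^2))
    expect_true(all(abs(steps - 3.8) < 1e-9))
    # no clash: every tail site >= 3.0 A from every other site
    d <- as.matrix(dist(cf$positions))
    diag(d) <- Inf
    expect_gte(min(d[61:91, ]), 3.0)
  }
  pool2 <- generate_pool(core, segs, n_conformers = 5, seed = 9)
  expect_identical(pool, pool2)
  # rigid limit: no segments -> exact copies of the core
  rigid <- generate_pool(core, list(), n_conformers = 3, seed = 1)
  expect_identical(rigid[[1L]]$positions, core$positions)
  expect_error(generate_pool(core, list(list(attach = 999, n = 5)), 2),
               "existing core site")
})

test_that("genetic algorithm finds the generating members of the pool", {
  q <- q_default
  pool <- lapply(1:20, function(k) sphere_curve(14 + k, 1, q))
  needle <- select_ensemble(pool, pool[[7L]], ensemble_size = 1,
                            n_generations = 30, n_rounds = 2, seed = 4)
  expect_equal(needle$member_ids, 7L)
  expect_lt(needle$chi, 1e-8)
  mixdat <- scattering_profile(q, 0.5 * pool[[3L]]$I + 0.5 * pool[[15L]]$I)
  pairsel <- select_ensemble(pool, mixdat, ensemble_size = 2,
                             n_generations = 60, n_rounds = 3, seed = 4)
  expect_setequal(pairsel$member_ids, c(3L, 15L))
  expect_true(all(abs(pairsel$weights - 0.5) <= 0.05))
  # nesting: ensemble never beats itself by dropping to one member
  singles <- vapply(pool, function(p)
    fit_mixture(mixdat, list(p))$chi, numeric(1L))
  expect_lte(pairsel$chi, min(singles))
  # elitism: best chi non-increasing across generations
  expect_true(all(diff(pairsel$chi_trace) <= 1e-12))
  expect_error(select_ensemble(pool, mixdat, ensemble_size = 30),
               "domain")
})

test_that("ensemble selection is seed-deterministic", {
  q <- q_default
  pool <- lapply(1:12, function(k) sphere_curve(10 + 2 * k, 1, q))
  dat <- scattering_profile(q, 0.7 * pool[[2L]]$I + 0.3 * pool[[9L]]$I)
  a <- select_ensemble(pool, dat, 2, n_generations = 20, n_rounds = 2,
                       seed = 5)
  b <- select_ensemble(pool, dat, 2, n_generations = 20, n_rounds = 2,
                       seed = 5)
  expect_identical(a$member_ids, b$member_ids)
  expect_identical(a$chi, b$chi)
})
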