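# small, fast annealing setups; the full-size round-trip lives in the
# acceptance suite
fast_schedule <- list(n_per_T = 400L, max_T_steps = 60L, patience = 25L)

small_target <- function(seed = 1) {
  lat <- oligosaxs:::bead_lattice(28, 4)
  occ <- which((lat$pos[, 1L] / 20)^2 + (lat$pos[, 2L] / 15)^2 +
                 (lat$pos[, 3L] / 12)^2 <= 1)
  phant <- coordinate_model(lat$pos[occ, , drop = FALSE])
  q <- seq(0.01, 0.30, length.out = 50)
  cur <- debye_curve(phant, q)
  list(lat = lat, phantom = phant,
       data = scattering_profile(q, cur$I, sigma = 0.02 * cur$I))
}

test_that("annealing improves on the initial configuration, reproducibly", {
  tg <- small_target()
  bm <- reconstruct(tg$data, 4, 28, seed = 3, schedule = fast_schedule)
  expect_lte(bm$chi, bm$chi_initial)
  expect_true(all(diff(bm$energy_trace) <= 1e-12))   # elitist best energy
  bm2 <- reconstruct(tg$data, 4, 28, seed = 3, schedule = fast_schedule)
  expect_identical(bm$occupied, bm2$occupied)
  expect_identical(bm$chi, bm2$chi)
  # occupied set is one 26-connected component
  lat <- oligosaxs:::bead_lattice(28, 4)
  keys <- paste(lat$ijk[, 1L], lat$ijk[, 2L], lat$ijk[, 3L])
  occ <- keys %in% paste(bm$occupied[, 1L], bm$occupied[, 2L],
                         bm$occupied[, 3L])
  expect_true(oligosaxs:::occ_connected(occ, lat$nbr))
})

test_that("P2 reconstructions are exactly two-fold symmetric", {
  q <- seq(0.01, 0.28, length.out = 45)
  mono <- ball_model(120, 13, seed = 3)
  dc <- dimer_curve(mono, 30, q_grid = q)
  dat <- scattering_profile(q, dc$curve$I, sigma = 0.02 * dc$curve$I)
  bp <- reconstruct(dat, 4, 34, symmetry = "P2", seed = 5,
                    schedule = fast_schedule)
  key <- paste(bp$occupied[, 1L], bp$occupied[, 2L], bp$occupied[, 3L])
  sym <- paste(-bp$occupied[, 1L], -bp$occupied[, 2L], bp$occupied[, 3L])
  expect_true(all(sym %in% key))
})

test_that("polydisperse fitting mixes a fixed monomer fraction", {
  q <- seq(0.01, 0.28, length.out = 45)
  mono <- ball_model(120, 13, seed = 3)
  dc <- dimer_curve(mono, 30, q_grid = q)
  Imono <- debye_curve(mono, q)
  mixI <- 0.58 * Imono$I / pracma::trapz(q, Imono$I) +
    0.42 * dc$curve$I / pracma::trapz(q, dc$curve$I)
  dat <- scattering_profile(q, mixI, sigma = 0.02 * mixI)
  bm <- reconstruct(dat, 4, 34, monomer_fraction = 0.58,
                    monomer_curve = Imono, seed = 2,
                    schedule = fast_schedule)
  expect_lte(bm$chi, bm$chi_initial)
  expect_equal(bm$monomer_fraction, 0.58)
  expect_error(reconstruct(dat, 4, 34, monomer_fraction = 0.58),
               "monomer_curve")
})

test_that("NSD: identity, symmetry, and alignment recover rigid motions", {
  lat <- oligosaxs:::bead_lattice(30, 5)
  occ <- (lat$pos[, 1L] / 24)^2 + (lat$pos[, 2L] / 16)^2 +
    (lat$pos[, 3L] / 10)^2 <= 1
  A <- lat$pos[occ, , drop = FALSE]
  expect_lt(nsd(A, A)$nsd, 1e-6)
  th <- 0.7
  R1 <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  th2 <- 0.4
  R2 <- rbind(c(1, 0, 0), c(0, cos(th2), -sin(th2)),
              c(0, sin(th2), cos(th2)))
  B <- A %*% t(R1 %*% R2) + matrix(c(5, -3, 8), nrow(A), 3, byrow = TRUE)
  expect_lte(nsd(A, B)$nsd, 0.05)
  expect_equal(nsd(A, B)$nsd, nsd(B, A)$nsd, tolerance = 1e-9)
  expect_error(nsd(rbind(c(0, 0, 0)), A), "degenerate-model")
})

test_that("NSD of offset unit chains equals the closed form", {
  # two parallel chains of spacing 1, offset laterally by 1:
  # d_A = d_B = 1 and every nearest-neighbor distance is 1 -> NSD = 1
  A <- cbind(1:10, 0, 0)
  B <- cbind(1:10, 1, 0)
  expect_equal(nsd(A, B, alignment = "none")$nsd, 1, tolerance = 1e-12)
})

test_that("averaging keeps consensus beads and filters outliers", {
  lat <- oligosaxs:::bead_lattice(30, 5)
  occ <- which((lat$pos[, 1L] / 22)^2 + (lat$pos[, 2L] / 15)^2 +
                 (lat$pos[, 3L] / 11)^2 <= 1)
  m <- make_bead_model(lat, occ)
  av <- average_filter(list(m, m, m))
  expect_setequal(paste(av$occupied[, 1L], av$occupied[, 2L],
                        av$occupied[, 3L]),
                  paste(m$occupied[, 1L], m$occupied[, 2L],
                        m$occupied[, 3L]))
  # threshold semantics on single-bead models at adjacent sites
  i0 <- which(lat$ijk[, 1L] == 0 & lat$ijk[, 2L] == 0 & lat$ijk[, 3L] == 0)
  i1 <- which(lat$ijk[, 1L] == 1 & lat$ijk[, 2L] == 0 & lat$ijk[, 3L] == 0)
  both <- average_filter(list(make_bead_model(lat, i0),
                              make_bead_model(lat, i1)), 0.5)
  expect_equal(both$n_beads, 2L)
  inter <- average_filter(list(make_bead_model(lat, c(i0, i1)),
                               make_bead_model(lat, i0)), 0.6)
  expect_equal(inter$n_beads, 1L)
  expect_error(average_filter(list(m)), "length")
  other <- make_bead_model(oligosaxs:::bead_lattice(30, 4), i0)
  expect_error(average_filter(list(m, other)), "spacing")
})

test_that("averaging noisy reconstructions does not degrade the consensus", {
  tg <- small_target()
  runs <- lapply(1:3, function(s)
    reconstruct(tg$data, 4, 28, seed = s, schedule = fast_schedule))
  nsds <- vapply(runs, function(r)
    nsd(r, tg$phantom)$nsd, numeric(1L))
  av <- average_filter(runs)
  expect_lte(nsd(av, tg$phantom)$nsd, min(nsds) + 0.1)
  # independent seeds stay within the same shape family
  pairwise <- c(nsd(runs[[1]], runs[[2]])$nsd,
                nsd(runs[[1]], runs[[3]])$nsd,
                nsd(runs[[2]], runs[[3]])$nsd)
  expect_true(all(pairwise <= 1.0))
})
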