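#' Analytic scattering curve of a homogeneous sphere
#'
#' `I(q) = I0 * [3 (sin x - x cos x) / x^3]^2` with `x = qR`; the classic
#' hard-sphere form factor used here as a globular phantom with known
#' ground truth (`Rg = sqrt(3/5) R`, `Dmax = 2R`, volume `4/3 pi R^3`).
#'
#' @param R sphere radius, Angstrom.
#' @param I0 forward scattering (value at q = 0).
#' @param q_grid momentum transfer grid, 1/Angstrom.
#' @return A `saxs_profile`.
#' @export
sphere_curve <- function(R, I0 = 1, q_grid) {
  stopifnot(R > 0)
  x <- q_grid * R
  f <- ifelse(x < 1e-4, 1 - x^2 / 10,           # series limit at x -> 0
              3 * (sin(x) - x * cos(x)) / x^3)
  scattering_profile(q_grid, I0 * f^2,
                     label = sprintf("sphere R=%g", R))
}

#' Debye scattering curve of an ideal Gaussian chain
#'
#' `I(q) = I0 * 2 (exp(-x) - 1 + x) / x^2` with `x = (q Rg)^2`; the
#' flexible-polymer phantom. Its Kratky transform plateaus at high q,
#' the signature used to diagnose disordered tails.
#'
#' @param Rg radius of gyration, Angstrom.
#' @param I0 forward scattering.
#' @param q_grid momentum transfer grid, 1/Angstrom.
#' @return A `saxs_profile`.
#' @export
gaussian_chain_curve <- function(Rg, I0 = 1, q_grid) {
  stopifnot(Rg > 0)
  x <- (q_grid * Rg)^2
  f <- ifelse(x < 1e-6, 1 - x / 3, 2 * (exp(-x) - 1 + x) / x^2)
  scattering_profile(q_grid, I0 * f,
                     label = sprintf("gaussian chain Rg=%g", Rg))
}

#' Sample a uniform ball of point scatterers
#'
#' Draws `n` points uniformly inside a ball of radius `R`; a sampled
#' realization of the sphere phantom for Debye-formula cross-checks.
#'
#' @param n number of sites.
#' @param R ball radius, Angstrom.
#' @param seed RNG seed.
#' @param weight per-site weight.
#' @return A `coord_model`.
#' @export
ball_model <- function(n, R, seed = 1, weight = 1) {
  set.seed(seed)
  # radius via inverse CDF, direction via normalized Gaussians
  r <- R * runif(n)^(1 / 3)
  d <- matrix(rnorm(3 * n), ncol = 3)
  d <- d / sqrt(rowSums(d^2))
  coordinate_model(d * r, weights = rep(weight, n))
}

#' Compact-core-plus-flexible-tail phantom
#'
#' Builds a residue-level monomer stand-in: a globular core of `n_core`
#' sites sampled uniformly in a ball, plus an `n_tail`-residue
#' self-avoiding random-coil tail attached at the core surface (3.8 A
#' virtual Ca-Ca steps). Defaults emulate a ~38 kDa photoenzyme with a
#' disordered C-terminal extension: 285-residue core, 31-residue tail.
#'
#' @param n_core core residue count.
#' @param n_tail tail residue count (0 for a rigid globule).
#' @param R_core core radius, Angstrom.
#' @param seed RNG seed.
#' @return A `coord_model` with attribute `core_size`.
#' @export
core_plus_tail_model <- function(n_core = 285, n_tail = 31, R_core = 24,
                                 seed = 1) {
  core <- ball_model(n_core, R_core, seed = seed)
  if (n_tail == 0L) return(core)
  # attach at the outermost core site, then delegate to the pool walker
  attach_site <- which.max(rowSums(core$positions^2))
  pool <- generate_pool(core,
                        flexible_segments = list(list(attach = attach_site,
                                                      n = n_tail)),
                        n_conformers = 1L, seed = seed + 1L)
  m <- pool[[1L]]
  attr(m, "core_size") <- n_core
  m
}

#' Build a two-fold-symmetric dimer from a monomer model
#'
#' The second protomer is the monomer rotated 180 degrees about `axis`
#' and translated by `separation` along it, giving an exact P2 particle.
#' Forward scattering of the dimer is 4x that of the monomer (weights
#' add coherently at q = 0).
#'
#' @param monomer a `coord_model`.
#' @param separation center-to-center distance, Angstrom.
#' @param axis unit 3-vector (rotation and translation axis).
#' @param q_grid optional q grid; when given, the dimer Debye curve is
#'   also returned.
#' @return A list with elements `model` (`coord_model`) and, when
#'   `q_grid` is supplied, `curve` (`saxs_profile`).
#' @export
dimer_curve <- function(monomer, separation, axis = c(0, 0, 1),
                        q_grid = NULL) {
  stopifnot(separation > 0)
  axis <- axis / sqrt(sum(axis^2))
  # Rodrigues rotation by pi about `axis`: R = 2 a a^T - I
  Rm <- 2 * tcrossprod(axis) - diag(3)
  ctr <- colMeans(monomer$positions)
  p1 <- sweep(monomer$positions, 2L, ctr)
  p2 <- p1 %*% t(Rm)
  shift <- separation / 2
  p1 <- sweep(p1, 2L, shift * axis, "-")
  p2 <- sweep(p2, 2L, shift * axis, "+")
  mind <- min(pair_min_distance(p1, p2))
  if (mind < 1)
    warning(sprintf("clash warning: protomer copies approach to %.2f A",
                    mind))
  dimer <- coordinate_model(rbind(p1, p2),
                            weights = rep(monomer$weights, 2L),
                            volumes = if (is.null(monomer$volumes)) NULL
                                      else rep(monomer$volumes, 2L))
  out <- list(model = dimer)
  if (!is.null(q_grid)) out$curve <- debye_curve(dimer, q_grid)
  out
}

# minimum cross-set distances, one per row of a
pair_min_distance <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(apply(d2, 1L, min), 0))
}

#' Phantom specification for a monomer-dimer concentration series
#'
#' Collects the ground-truth parameters of a simulated dilution series:
#' particle geometry, dimerization constant, concentrations and noise.
#' The dimer weight fraction follows the binding isotherm
#' `w(c) = c / (c + K)`, a deliberately simple stand-in for a low-uM
#' self-association equilibrium.
#'
#' @param kind phantom kind.
#' @param R_monomer monomer-equivalent sphere radius, Angstrom.
#' @param separation dimer center-to-center separation, Angstrom.
#' @param K isotherm constant, mg/ml (`w = 0.5` at `c = K`; `Inf` for a
#'   pure-monomer series).
#' @param concentrations mg/ml values of the series.
#' @param noise_level fractional counting-noise scale at I(0).
#' @param n_sites sites per monomer realization.
#' @param seed RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = "monomer_dimer_series", R_monomer = 22,
                         separation = 46, K = 2,
                         concentrations = c(0.5, 1, 2, 5),
                         noise_level = 0.01, n_sites = 800, seed = 1) {
  stopifnot(R_monomer > 0, separation > 0, K > 0,
            all(concentrations > 0), noise_level >= 0, n_sites >= 1)
  structure(list(kind = kind, R_monomer = R_monomer,
                 separation = separation, K = K,
                 concentrations = concentrations,
                 noise_level = noise_level, n_sites = n_sites,
                 seed = seed),
            class = "phantom_spec")
}

#' Simulate a monomer-dimer concentration series
#'
#' For each concentration `c` the dimer weight fraction is
#' `w(c) = c / (c + K)` and the per-unit-mass intensity is
#' `(1 - w) I_mono + (w / 2) I_dimer`, so the apparent mass from I(0)
#' interpolates between the monomer mass (w = 0) and twice it (w = 1).
#' The recorded intensity is that curve multiplied by `c` (counting
#' statistics scale with sample mass), with noise from [add_noise()].
#' The default q grid stops at 0.30 1/A: point-scatterer models develop
#' an incoherent floor (I -> N) at higher q that continuum particles do
#' not have, which would distort Porod-invariant analysis.
#'
#' @param spec a [phantom_spec()].
#' @param q_grid momentum transfer grid, 1/Angstrom.
#' @return List of `saxs_profile`s, one per concentration, each carrying
#'   attributes `true_dimer_fraction`, `spec` and `seed`; the list carries
#'   attributes `monomer_curve` and `dimer_curve` (noiseless, per
#'   particle).
#' @export
mixture_series <- function(spec, q_grid = seq(1e-3, 0.30, length.out = 181)) {
  stopifnot(inherits(spec, "phantom_spec"))
  mono <- ball_model(spec$n_sites, spec$R_monomer, seed = spec$seed)
  I_mono <- debye_curve(mono, q_grid)
  dim_out <- dimer_curve(mono, spec$separation, q_grid = q_grid)
  I_dim <- dim_out$curve
  out <- vector("list", length(spec$concentrations))
  for (i in seq_along(spec$concentrations)) {
    cc <- spec$concentrations[i]
    w <- if (is.finite(spec$K)) cc / (cc + spec$K) else 0
    I_mass <- (1 - w) * I_mono$I + (w / 2) * I_dim$I
    prof <- scattering_profile(q_grid, cc * I_mass,
                               concentration = cc,
                               label = sprintf("phantom c=%g", cc))
    prof <- add_noise(prof, spec$noise_level, seed = spec$seed + i)
    attr(prof, "true_dimer_fraction") <- w
    attr(prof, "spec") <- spec
    attr(prof, "seed") <- spec$seed + i
    out[[i]] <- prof
  }
  attr(out, "monomer_curve") <- I_mono
  attr(out, "dimer_curve") <- I_dim
  attr(out, "spec") <- spec
  out
}

#' Add counting-like noise to a scattering curve
#'
#' The error model is `sigma(q) = s * I(0) * sqrt(I(q)/I(0) + 0.01)` with
#' `s = noise_level`: Poisson-like scaling with intensity plus a floor at
#' 1% of the forward-scattering scale (detector/buffer-subtraction
#' background). Intensities are perturbed by centered Gaussians of that
#' width; the sigma column is populated. With `noise_level = 0` the
#' intensities are untouched and the sigma column holds the floor shape
#' at a nominal 1% scale (so weighted fits remain defined).
#'
#' @param curve a `saxs_profile`.
#' @param noise_level fractional sigma at I(0); >= 0.
#' @param seed RNG seed (deterministic output for a fixed seed).
#' @return A `saxs_profile` with sigma set, attributes `noise_level` and
#'   `seed` recorded.
#' @export
add_noise <- function(curve, noise_level, seed = 1) {
  stopifnot(noise_level >= 0)
  I0 <- max(curve$I[1L], max(abs(curve$I)) * 1e-6)
  shape <- sqrt(pmax(curve$I, 0) / I0 + 0.01)
  s <- if (noise_level > 0) noise_level else 0.01
  sigma <- s * I0 * shape
  I <- curve$I
  if (noise_level > 0) {
    set.seed(seed)
    I <- I + rnorm(length(I), sd = sigma)
  }
  out <- scattering_profile(curve$q, I, sigma = sigma,
                            concentration = curve$concentration,
                            label = curve$label)
  attr(out, "noise_level") <- noise_level
  attr(out, "seed") <- seed
  out
}
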