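# shared fixtures, all generated in code

q_default <- seq(0.004, 0.30, length.out = 120)

# bead model wrapper around an explicit occupied index set of a lattice
make_bead_model <- function(lat, idx) {
  structure(list(lattice_origin = c(0, 0, 0),
                 bead_radius = lat$bead_radius, spacing = lat$spacing,
                 occupied = lat$ijk[idx, , drop = FALSE],
                 positions = lat$pos[idx, , drop = FALSE],
                 symmetry = "P1", search_radius = lat$search_radius,
                 n_beads = length(idx), chi = NA_real_,
                 energy_trace = numeric(0), seed = 1L),
            class = "bead_model")
}

# monomer/dimer phantom pair used across mixture tests
phantom_pair <- function(q = q_default, n_sites = 300, R = 22,
                         separation = 46, seed = 1) {
  mono <- ball_model(n_sites, R, seed = seed)
  list(mono = mono,
       I_mono = debye_curve(mono, q),
       I_dimer = dimer_curve(mono, separation, q_grid = q)$curve)
}

# weight-fraction mixture curve on the per-unit-mass scale
mix_curve <- function(pair, w) {
  scattering_profile(pair$I_mono$q,
                     (1 - w) * pair$I_mono$I + (w / 2) * pair$I_dimer$I)
}

# recover the dimer weight fraction from intensity-amplitude fractions
weight_fraction <- function(mx) {
  2 * mx$fractions[2L] / (mx$fractions[1L] + 2 * mx$fractions[2L])
}

# minimal PDB writer for structure-reading tests
write_mini_pdb <- function(path, atoms) {
  # atoms: data.frame with resno, resid, name, elem, x, y, z
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, a$name, a$resid, a$resno, a$x, a$y, a$z, a$elem)
  }, character(1L))
  writeLines(c(lines, "END"), path)
}
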