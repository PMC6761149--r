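# Simple-cubic search lattice. Bead radius = 0.62 * spacing gives
# overlapping spheres, adequate at SAXS resolution and with trivial
# 26-neighborhood logic. Sites are all lattice nodes within
# `search_radius` of the origin; `nbr` is a 0-padded M x 26 neighbor
# index matrix and `sym` maps each site to its image under a 180-degree
# rotation about z ((i,j,k) -> (-i,-j,k), exact on this lattice).
bead_lattice <- function(search_radius, bead_radius) {
  spacing <- bead_radius / 0.62
  L <- floor(search_radius / spacing)
  g <- seq(-L, L)
  ijk <- as.matrix(expand.grid(i = g, j = g, k = g))
  pos <- ijk * spacing
  keep <- rowSums(pos^2) <= search_radius^2
  ijk <- ijk[keep, , drop = FALSE]
  pos <- pos[keep, , drop = FALSE]
  M <- nrow(ijk)
  side <- 2L * L + 3L
  key <- function(m) (m[, 1L] + L + 1L) + (m[, 2L] + L + 1L) * side +
    (m[, 3L] + L + 1L) * side * side
  lookup <- integer(side^3)
  lookup[key(ijk)] <- seq_len(M)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  nbr <- matrix(0L, M, 26L)
  for (o in seq_len(26L)) {
    nij <- sweep(ijk, 2L, offs[o, ], "+")
    inside <- abs(nij[, 1L]) <= L & abs(nij[, 2L]) <= L & abs(nij[, 3L]) <= L
    idx <- integer(M)
    idx[inside] <- lookup[key(nij[inside, , drop = FALSE])]
    nbr[, o] <- idx
  }
  symij <- cbind(-ijk[, 1L], -ijk[, 2L], ijk[, 3L])
  sym <- lookup[key(symij)]
  list(ijk = ijk, pos = pos, nbr = nbr, sym = sym, spacing = spacing,
       bead_radius = bead_radius, search_radius = search_radius, M = M)
}

# connectivity of the occupied set (26-connected), frontier BFS
occ_connected <- function(occ, nbr, start = which(occ)[1L]) {
  n_occ <- sum(occ)
  if (n_occ <= 1L) return(TRUE)
  visited <- logical(length(occ))
  visited[start] <- TRUE
  frontier <- start
  count <- 1L
  while (length(frontier) > 0L) {
    nxt <- as.vector(nbr[frontier, , drop = FALSE])
    nxt <- nxt[nxt > 0L]
    nxt <- unique(nxt[occ[nxt] & !visited[nxt]])
    visited[nxt] <- TRUE
    count <- count + length(nxt)
    frontier <- nxt
  }
  count == n_occ
}

# weighted scale-only fit of a model intensity vector; returns chi^2
chi2_scale <- function(Iexp, Imod, invs2) {
  cc <- sum(invs2 * Iexp * Imod) / sum(invs2 * Imod^2)
  sum(invs2 * (Iexp - cc * Imod)^2) / max(length(Iexp) - 1L, 1L)
}

#' Ab initio bead-shape reconstruction by simulated annealing
#'
#' Reconstructs a low-resolution molecular envelope from a scattering
#' curve: dummy beads on a simple-cubic lattice are switched on and off
#' by Metropolis annealing, minimizing
#' `E = chi^2 + alpha_compact * looseness`, where chi^2 is the reduced
#' fit of the bead-model Debye curve (scale fitted) and looseness is the
#' fraction of occupied beads with fewer than 6 occupied neighbors (of
#' 26). Moves that disconnect the occupied set, and removals below 2
#' beads, are rejected, so the model is always a single 26-connected
#' component. Under P2 symmetry every flip is applied jointly to a site
#' and its 180-degree image about the z axis, so the constraint holds
#' exactly at every accepted step. For polydisperse monomer/dimer
#' samples a fixed `monomer_fraction` mixes an area-normalized monomer
#' form factor into the fitted curve, so the beads only account for the
#' dimer component.
#'
#' The starting temperature is calibrated so roughly half of the uphill
#' trial moves would initially be accepted; cooling is geometric
#' (x0.93 per `n_per_T` attempted flips) and the search stops after
#' `patience` temperature steps without improvement of the best energy
#' (elitist: the best-so-far configuration is returned). Deterministic
#' for a fixed seed.
#'
#' @param data `saxs_profile` to reconstruct from.
#' @param bead_radius dummy-bead radius, Angstrom.
#' @param search_radius radius of the spherical search volume, Angstrom
#'   (must exceed 4x the bead radius).
#' @param symmetry `"P1"` (none) or `"P2"` (two-fold about z).
#' @param monomer_fraction fixed monomer intensity fraction in \[0, 1);
#'   0 for a monodisperse sample.
#' @param monomer_curve `saxs_profile` of the monomer form factor;
#'   required when `monomer_fraction > 0`.
#' @param seed RNG seed.
#' @param schedule named list overriding annealing defaults:
#'   `n_per_T` (1000), `cool` (0.93), `patience` (60),
#'   `max_T_steps` (250), `t0_accept` (0.5), `bin_width` (1.0),
#'   `start_radius` (NULL: from a Guinier estimate).
#' @return A `bead_model` with the occupied lattice, positions, final
#'   `chi`, `energy_trace`, and run metadata.
#' @export
reconstruct <- function(data, bead_radius, search_radius,
                        symmetry = c("P1", "P2"), monomer_fraction = 0,
                        monomer_curve = NULL, seed = 1,
                        schedule = list()) {
  symmetry <- match.arg(symmetry)
  validate_profile(data)
  if (bead_radius >= search_radius / 4)
    stop("bead_radius must be smaller than search_radius / 4",
         call. = FALSE)
  if (monomer_fraction < 0 || monomer_fraction >= 1)
    stop("monomer_fraction must be in [0, 1)", call. = FALSE)
  if (monomer_fraction > 0 && is.null(monomer_curve))
    stop("monomer_curve required when monomer_fraction > 0", call. = FALSE)
  sc <- utils::modifyList(
    list(n_per_T = 1000L, cool = 0.93, patience = 60L, max_T_steps = 250L,
         t0_accept = 0.5, bin_width = 1.0, start_radius = NULL),
    schedule)
  set.seed(seed)
  lat <- bead_lattice(search_radius, bead_radius)
  q <- data$q
  Iexp <- data$I
  invs2 <- if (is.null(data$sigma)) rep(1, length(q)) else 1 / data$sigma^2
  nbins <- ceiling(2 * search_radius / sc$bin_width) + 1L
  centers <- (seq_len(nbins) - 0.5) * sc$bin_width
  S <- outer(centers, q, function(r, qq) sinc(qq * r))   # nbins x nq
  mono_n <- NULL
  if (monomer_fraction > 0) {
    Im <- approx(monomer_curve$q, monomer_curve$I, q, rule = 2L)$y
    mono_n <- Im / pracma::trapz(q, Im)
  }
  model_I <- function(N, H) {
    Ib <- N + as.numeric(crossprod(H, S))
    if (is.null(mono_n)) return(Ib)
    Ibn <- Ib / pracma::trapz(q, Ib)
    monomer_fraction * mono_n + (1 - monomer_fraction) * Ibn
  }

  # initial configuration: a connected lattice ball sized from a Guinier
  # estimate of the data (fallback: a third of the search volume)
  r0 <- sc$start_radius
  if (is.null(r0)) {
    rg <- tryCatch(guinier_fit(data)$Rg, error = function(e) NA_real_)
    r0 <- if (is.finite(rg)) sqrt(5 / 3) * rg else search_radius / 3
    r0 <- min(max(r0, 2.5 * lat$spacing), 0.9 * search_radius)
  }
  occ <- rowSums(lat$pos^2) <= r0^2
  if (symmetry == "P2") occ <- occ | occ[lat$sym]    # ball is symmetric
  if (sum(occ) < 2L)
    stop("initialization error: no connected seed shape fits the lattice",
         call. = FALSE)
  N <- sum(occ)
  occidx <- which(occ)
  d0 <- as.numeric(stats::dist(lat$pos[occidx, , drop = FALSE]))
  H <- numeric(nbins)
  tab <- tabulate(pmax(1L, ceiling(d0 / sc$bin_width)), nbins)
  H <- H + 2 * tab
  ncnt <- integer(lat$M)
  for (o in seq_len(26L)) {
    nb <- lat$nbr[occidx, o]
    nb <- nb[nb > 0L]
    ncnt[nb] <- ncnt[nb] + 1L
  }
  loose <- function() sum(ncnt[occidx] < 6L) / length(occidx)
  chi2_now <- chi2_scale(Iexp, model_I(N, H), invs2)
  chi2_init <- chi2_now
  alpha <- 10 * chi2_now
  E <- chi2_now + alpha * loose()

  # histogram delta for adding/removing the site set `bs` (1 or 2 sites)
  delta_H <- function(bs, others_idx) {
    dH <- numeric(nbins)
    for (b in bs) {
      if (length(others_idx) > 0L) {
        dd <- sqrt(rowSums(sweep(lat$pos[others_idx, , drop = FALSE],
                                 2L, lat$pos[b, ])^2))
        dH <- dH + 2 * tabulate(pmax(1L, ceiling(dd / sc$bin_width)), nbins)
      }
    }
    if (length(bs) == 2L) {
      dd <- sqrt(sum((lat$pos[bs[1L], ] - lat$pos[bs[2L], ])^2))
      dH <- dH + 2 * tabulate(pmax(1L, ceiling(dd / sc$bin_width)), nbins)
    }
    dH
  }

  propose <- function() {
    # additions target empty neighbors of occupied beads; removals any
    # occupied bead; under P2 the symmetric mate is flipped jointly
    if (runif(1) < 0.5) {
      anchor <- occidx[sample.int(length(occidx), 1L)]
      cand <- lat$nbr[anchor, ]
      cand <- cand[cand > 0L]
      cand <- cand[!occ[cand]]
      if (length(cand) == 0L) return(NULL)
      s <- if (length(cand) == 1L) cand else sample(cand, 1L)
      list(add = TRUE, s = s)
    } else {
      list(add = FALSE, s = occidx[sample.int(length(occidx), 1L)])
    }
  }

  # temperature calibration from the uphill tail of trial moves
  trial_dE <- numeric(0L)
  ntrial <- 0L
  while (length(trial_dE) < 30L && ntrial < 400L) {
    ntrial <- ntrial + 1L
    pr <- propose()
    if (is.null(pr)) next
    bs <- pr$s
    if (symmetry == "P2" && lat$sym[pr$s] != pr$s) bs <- c(pr$s, lat$sym[pr$s])
    if (pr$add && any(occ[bs])) next
    if (!pr$add && length(occidx) - length(bs) < 2L) next
    others <- if (pr$add) occidx else setdiff(occidx, bs)
    dH <- delta_H(bs, others)
    sgn <- if (pr$add) 1 else -1
    c2 <- chi2_scale(Iexp, model_I(N + sgn * length(bs), H + sgn * dH),
                     invs2)
    dE <- (c2 - chi2_now)
    if (dE > 0) trial_dE <- c(trial_dE, dE)
  }
  Temp <- if (length(trial_dE) > 0L)
    mean(trial_dE) / log(1 / sc$t0_accept) else 1
  best <- list(E = E, occ = occ, chi2 = chi2_now)
  trace <- numeric(0L)
  stale <- 0L
  for (step_T in seq_len(sc$max_T_steps)) {
    improved <- FALSE
    for (it in seq_len(sc$n_per_T)) {
      pr <- propose()
      if (is.null(pr)) next
      bs <- pr$s
      if (symmetry == "P2" && lat$sym[pr$s] != pr$s)
        bs <- c(pr$s, lat$sym[pr$s])
      if (pr$add) {
        if (any(occ[bs])) next
      } else {
        if (length(occidx) - length(bs) < 2L) next
      }
      others <- if (pr$add) occidx else setdiff(occidx, bs)
      if (!pr$add) {
        # connectivity: remaining set must stay 26-connected
        occ[bs] <- FALSE
        still <- occ_connected(occ, lat$nbr, start = others[1L])
        occ[bs] <- TRUE
        if (!still) next
      }
      dH <- delta_H(bs, others)
      sgn <- if (pr$add) 1 else -1
      N_new <- N + sgn * length(bs)
      H_new <- H + sgn * dH
      c2_new <- chi2_scale(Iexp, model_I(N_new, H_new), invs2)
      # neighbor-count bookkeeping for the looseness term
      ncnt_new <- ncnt
      for (b in bs) {
        nb <- lat$nbr[b, ]
        nb <- nb[nb > 0L]
        ncnt_new[nb] <- ncnt_new[nb] + sgn
      }
      occidx_new <- if (pr$add) c(occidx, bs) else others
      loose_new <- sum(ncnt_new[occidx_new] < 6L) / length(occidx_new)
      E_new <- c2_new + alpha * loose_new
      if (E_new <= E || runif(1) < exp(-(E_new - E) / Temp)) {
        occ[bs] <- pr$add
        occidx <- occidx_new
        H <- H_new
        N <- N_new
        ncnt <- ncnt_new
        chi2_now <- c2_new
        E <- E_new
        if (E < best$E) {
          best <- list(E = E, occ = occ, chi2 = chi2_now)
          improved <- TRUE
        }
      }
    }
    trace <- c(trace, best$E)
    stale <- if (improved) 0L else stale + 1L
    if (stale >= sc$patience) break
    Temp <- Temp * sc$cool
  }
  occb <- best$occ
  idx <- which(occb)
  structure(list(lattice_origin = c(0, 0, 0), bead_radius = bead_radius,
                 spacing = lat$spacing, occupied = lat$ijk[idx, , drop = FALSE],
                 positions = lat$pos[idx, , drop = FALSE],
                 symmetry = symmetry, search_radius = search_radius,
                 n_beads = length(idx), chi = sqrt(best$chi2),
                 chi_initial = sqrt(chi2_init),
                 monomer_fraction = monomer_fraction,
                 energy_trace = trace, seed = seed),
            class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf(
    "bead_model: %d beads (r = %.2f A, spacing %.2f A, %s), chi = %.3f\n",
    x$n_beads, x$bead_radius, x$spacing, x$symmetry, x$chi))
  invisible(x)
}

#' Convert a bead model to a coordinate model
#'
#' @param model a `bead_model`.
#' @return A `coord_model` with unit weights.
#' @export
as_coord_model <- function(model) {
  stopifnot(inherits(model, "bead_model"))
  coordinate_model(model$positions,
                   weights = rep(1, nrow(model$positions)))
}

#' Excluded volume of a bead model
#'
#' One lattice cell per occupied bead; for an averaged-and-filtered
#' dimer envelope, halving the derived mass gives a per-protomer
#' estimate.
#'
#' @param model a `bead_model`.
#' @return Volume in A^3.
#' @export
bead_model_volume <- function(model) model$n_beads * model$spacing^3

point_matrix <- function(m) {
  if (inherits(m, "bead_model")) m$positions
  else if (inherits(m, "coord_model")) m$positions
  else as.matrix(m)
}

# mean nearest-neighbor distance within a point set
mean_nn <- function(p) {
  if (nrow(p) < 2L)
    stop("degenerate-model error: nearest-neighbor distance undefined for a single point",
         call. = FALSE)
  d <- as.matrix(stats::dist(p))
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}

nsd_raw <- function(a, b) {
  da <- mean_nn(a)
  db <- mean_nn(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2 <- pmax(d2, 0)
  termA <- sum(apply(d2, 1L, min)) / (nrow(a) * db^2)
  termB <- sum(apply(d2, 2L, min)) / (nrow(b) * da^2)
  sqrt((termA + termB) / 2)
}

# principal axes of a point set: centered coordinates rotated into the
# eigenframe of the covariance (descending), right-handed
principal_frame <- function(p) {
  ctr <- colMeans(p)
  pc <- sweep(p, 2L, ctr)
  V <- eigen(crossprod(pc) / nrow(pc), symmetric = TRUE)$vectors
  if (det(V) < 0) V[, 3L] <- -V[, 3L]
  list(ctr = ctr, V = V, aligned = pc %*% V)
}

#' Normalized spatial discrepancy between two models
#'
#' `NSD(A,B) = sqrt( (1/2) [ (1/(N_A d_B^2)) sum_i min_j |a_i - b_j|^2
#' + (1/(N_B d_A^2)) sum_j min_i |b_j - a_i|^2 ] )` where `d` is the
#' average nearest-neighbor distance within each set: 0 for identical
#' sets, around 1 when the models are systematically different. With
#' `alignment = "principal_axes"` both sets are superposed on their
#' inertial frames and all four proper axis-sign combinations are
#' tried, returning the minimum and the applied transform.
#'
#' @param a,b `bead_model`s, `coord_model`s, or N x 3 matrices.
#' @param alignment `"principal_axes"` (default) or `"none"`.
#' @return An `nsd_report` with `nsd` and `transform` (rotation applied
#'   to `b` and the two centroids), or an identity transform for
#'   `"none"`.
#' @export
nsd <- function(a, b, alignment = c("principal_axes", "none")) {
  alignment <- match.arg(alignment)
  pa <- point_matrix(a)
  pb <- point_matrix(b)
  if (alignment == "none") {
    val <- nsd_raw(pa, pb)
    return(structure(list(nsd = val,
                          transform = list(R = diag(3),
                                           centroid_a = c(0, 0, 0),
                                           centroid_b = c(0, 0, 0))),
                     class = "nsd_report"))
  }
  fa <- principal_frame(pa)
  fb <- principal_frame(pb)
  signs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  bestv <- Inf
  bestS <- signs[1L, ]
  for (s in seq_len(4L)) {
    bs <- sweep(fb$aligned, 2L, signs[s, ], "*")
    v <- nsd_raw(fa$aligned, bs)
    if (v < bestv) { bestv <- v; bestS <- signs[s, ] }
  }
  # rotation taking centered b into the centered-a frame
  R <- fb$V %*% diag(bestS) %*% t(fa$V)
  structure(list(nsd = bestv,
                 transform = list(R = R, centroid_a = fa$ctr,
                                  centroid_b = fb$ctr)),
            class = "nsd_report")
}

#' @export
print.nsd_report <- function(x, ...) {
  cat(sprintf("NSD = %.4f\n", x$nsd))
  invisible(x)
}

#' Average and filter a set of bead models
#'
#' Aligns all models to the reference with the lowest mean pairwise NSD
#' (principal-axes superposition), accumulates a per-lattice-node
#' occupancy map, keeps nodes occupied in at least `occupancy_cutoff` of
#' the models, and returns the largest 26-connected component — the
#' standard consensus-envelope construction from repeated stochastic
#' reconstructions. Models with fewer than 4 beads are merged with
#' identity alignment (their inertial frame is degenerate).
#'
#' @param models list of >= 2 `bead_model`s on a common lattice spacing.
#' @param occupancy_cutoff retention threshold in (0, 1\].
#' @return A filtered consensus `bead_model` (symmetry `"P1"`).
#' @export
average_filter <- function(models, occupancy_cutoff = 0.5) {
  stopifnot(length(models) >= 2L)
  sp <- vapply(models, function(m) m$spacing, numeric(1L))
  if (max(sp) - min(sp) > 1e-9)
    stop("domain error: models must share one lattice spacing",
         call. = FALSE)
  spacing <- sp[1L]
  nm <- length(models)
  degenerate <- any(vapply(models, function(m) m$n_beads < 4L, logical(1L)))
  if (!degenerate) {
    nsd_mat <- matrix(0, nm, nm)
    for (i in seq_len(nm - 1L)) for (j in (i + 1L):nm) {
      v <- nsd(models[[i]], models[[j]])$nsd
      nsd_mat[i, j] <- nsd_mat[j, i] <- v
    }
    ref <- which.min(rowSums(nsd_mat) / (nm - 1L))
  } else ref <- 1L
  counts <- new.env(hash = TRUE, parent = emptyenv())
  bump <- function(ijk) {
    keys <- apply(ijk, 1L, paste, collapse = ",")
    for (k in keys)
      assign(k, (if (exists(k, envir = counts)) get(k, envir = counts)
                 else 0L) + 1L, envir = counts)
  }
  for (i in seq_len(nm)) {
    if (degenerate || i == ref) {
      pos <- models[[i]]$positions
    } else {
      tr <- nsd(models[[ref]], models[[i]])$transform
      pos <- sweep(models[[i]]$positions, 2L, tr$centroid_b) %*% tr$R
      pos <- sweep(pos, 2L, tr$centroid_a, "+")
    }
    bump(unique(round(pos / spacing)))
  }
  keys <- ls(envir = counts)
  occ <- vapply(keys, function(k) get(k, envir = counts), integer(1L))
  keep <- keys[occ / nm >= occupancy_cutoff]
  if (length(keep) == 0L)
    stop("no lattice node reaches the occupancy cutoff", call. = FALSE)
  ijk <- do.call(rbind, lapply(strsplit(keep, ","), as.numeric))
  # largest 26-connected component
  comp <- rep(0L, nrow(ijk))
  cid <- 0L
  keyset <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(nrow(ijk)))
    assign(paste(ijk[r, ], collapse = ","), r, envir = keyset)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  for (r in seq_len(nrow(ijk))) {
    if (comp[r] > 0L) next
    cid <- cid + 1L
    frontier <- r
    comp[r] <- cid
    while (length(frontier) > 0L) {
      nxt <- integer(0L)
      for (f in frontier) {
        cand <- sweep(offs, 2L, ijk[f, ], "+")
        ck <- apply(cand, 1L, paste, collapse = ",")
        for (k in ck) {
          if (exists(k, envir = keyset)) {
            rr <- get(k, envir = keyset)
            if (comp[rr] == 0L) { comp[rr] <- cid; nxt <- c(nxt, rr) }
          }
        }
      }
      frontier <- nxt
    }
  }
  big <- which.max(tabulate(comp))
  ijk <- ijk[comp == big, , drop = FALSE]
  pos <- ijk * spacing
  structure(list(lattice_origin = c(0, 0, 0),
                 bead_radius = models[[1L]]$bead_radius, spacing = spacing,
                 occupied = ijk, positions = pos, symmetry = "P1",
                 search_radius = max(vapply(models, function(m)
                   m$search_radius, numeric(1L))),
                 n_beads = nrow(ijk), chi = NA_real_,
                 energy_trace = numeric(0L), seed = NA_integer_),
            class = "bead_model")
}
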