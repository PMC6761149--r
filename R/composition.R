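#' Decompose a measured curve into component volume fractions
#'
#' Sigma-weighted non-negative least squares for the amplitudes of a set
#' of component form-factor curves (optionally plus a free additive
#' constant, which may take either sign). Amplitudes are renormalized to
#' fractions summing to 1 with the overall scale factored out; the
#' goodness of fit `chi` is the square-root reduced chi-square as in
#' [fit_to_profile()]. With a single component this reduces exactly to
#' [fit_to_profile()].
#'
#' @param data `saxs_profile` of the measurement.
#' @param components list of `saxs_profile`s (form factors), interpolated
#'   onto the data grid.
#' @param subtract_constant fit an additive background.
#' @return A `mixture_result` with `fractions`, `scale_c`, `constant_b`,
#'   `chi`, `n_points`.
#' @export
fit_mixture <- function(data, components, subtract_constant = FALSE) {
  stopifnot(length(components) >= 1L)
  qlo <- max(vapply(components, function(p) min(p$q), numeric(1L)),
             min(data$q))
  qhi <- min(vapply(components, function(p) max(p$q), numeric(1L)),
             max(data$q))
  if (qlo >= qhi)
    stop("grid error: component and data q ranges do not overlap",
         call. = FALSE)
  keep <- data$q >= qlo & data$q <= qhi
  q <- data$q[keep]
  Iexp <- data$I[keep]
  s <- if (is.null(data$sigma)) rep(1, length(q)) else data$sigma[keep]
  C <- vapply(components, function(p) approx(p$q, p$I, q)$y,
              numeric(length(q)))
  C <- matrix(C, nrow = length(q))
  if (all(abs(C) < 1e-300))
    stop("degenerate-design error: all components are zero", call. = FALSE)
  k <- ncol(C)
  Xw <- C / s
  yw <- Iexp / s
  if (subtract_constant) {
    # free-sign constant inside NNLS via +/- column pair
    Xw <- cbind(Xw, 1 / s, -1 / s)
  }
  sol <- nnls_lh(Xw, yw)
  a <- sol$x[seq_len(k)]
  b <- if (subtract_constant) sol$x[k + 1L] - sol$x[k + 2L] else 0
  total <- sum(a)
  if (total <= 0)
    stop("degenerate-design error: all component amplitudes zero",
         call. = FALSE)
  fr <- a / total
  p <- k + as.integer(subtract_constant)
  res <- (Iexp - C %*% a - b) / s
  chi2 <- sum(res^2) / max(length(q) - p, 1L)
  structure(list(fractions = fr, scale_c = total, constant_b = b,
                 chi = sqrt(chi2), n_points = length(q)),
            class = "mixture_result")
}

#' @export
print.mixture_result <- function(x, ...) {
  cat(sprintf("mixture: fractions = (%s), chi = %.4f, c = %.4g, b = %.4g\n",
              paste(sprintf("%.3f", x$fractions), collapse = ", "),
              x$chi, x$scale_c, x$constant_b))
  invisible(x)
}

# one self-avoiding random-walk segment of n steps from `start`,
# 3.8 A virtual Ca-Ca steps, hard-sphere 3.0 A clash distance to all
# sites in `context` and to earlier segment sites
walk_segment <- function(start, n, context, step = 3.8, clash = 3.0,
                         max_step_retries = 100L, max_restarts = 50L) {
  for (restart in seq_len(max_restarts)) {
    seg <- matrix(NA_real_, n, 3L)
    cur <- start
    ok <- TRUE
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(max_step_retries)) {
        d <- rnorm(3L)
        cand <- cur + step * d / sqrt(sum(d^2))
        others <- rbind(context, seg[seq_len(i - 1L), , drop = FALSE])
        d2 <- rowSums(sweep(others, 2L, cand)^2)
        if (min(d2) >= clash^2) {
          seg[i, ] <- cand
          cur <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(seg)
  }
  NULL
}

#' Generate a pool of conformers with flexible segments
#'
#' Each conformer is the rigid core plus, per flexible segment, a
#' self-avoiding random walk of virtual residues attached at a stated
#' core site: fixed 3.8 Angstrom steps (the Ca-Ca virtual bond) and a
#' 3.0 Angstrom hard-sphere clash distance to all previously placed
#' sites. This is the standard random-coil pool construction feeding
#' ensemble selection for proteins with disordered termini or loops.
#' Deterministic for a fixed seed.
#'
#' @param core a `coord_model` (rigid part).
#' @param flexible_segments list of `list(attach = site index,
#'   n = residue count)` entries; empty list for a rigid pool.
#' @param n_conformers number of conformers (>= 1).
#' @param seed RNG seed.
#' @return List of `coord_model`s of length `n_conformers`.
#' @export
generate_pool <- function(core, flexible_segments = list(),
                          n_conformers, seed = 1) {
  stopifnot(inherits(core, "coord_model"), n_conformers >= 1L)
  for (seg in flexible_segments) {
    if (is.null(seg$attach) || is.null(seg$n) ||
        seg$attach < 1L || seg$attach > nrow(core$positions))
      stop("flexible segment must attach to an existing core site",
           call. = FALSE)
  }
  set.seed(seed)
  out <- vector("list", n_conformers)
  for (cf in seq_len(n_conformers)) {
    pos <- core$positions
    w <- core$weights
    for (seg in flexible_segments) {
      start <- core$positions[seg$attach, ]
      new <- walk_segment(start, seg$n, context = pos)
      if (is.null(new))
        stop(sprintf(
          "conformer-generation error: segment at site %d (%d residues) failed to close",
          seg$attach, seg$n), call. = FALSE)
      pos <- rbind(pos, new)
      w <- c(w, rep(1, seg$n))
    }
    out[[cf]] <- coordinate_model(pos, weights = w)
  }
  out
}

#' Select a conformer sub-ensemble by genetic algorithm
#'
#' Minimizes the mixture-fit chi of a fixed-size subset of pool curves
#' against the data over `n_rounds` independent genetic-algorithm runs
#' (tournament selection, single-point crossover on the sorted member
#' lists, per-gene member-swap mutation, elitism), returning the best
#' subset across rounds. Member weights come from the non-negative
#' mixture fit of the winning subset. Deterministic for a fixed seed.
#'
#' @param pool_curves list of `saxs_profile`s (one per pool conformer).
#' @param data `saxs_profile` to fit.
#' @param ensemble_size subset size (<= pool size).
#' @param n_generations generations per round (default 200).
#' @param n_rounds independent rounds (default 3).
#' @param seed RNG seed.
#' @param population GA population size (default 50).
#' @param mutation_rate per-gene swap probability (default 0.1).
#' @return An `ensemble_result` with `member_ids`, `weights`, `chi`,
#'   `rg_distribution` (Guinier Rg of each selected member curve, NA
#'   where the fit fails), `seed`, and `chi_trace` (best chi per
#'   generation of the winning round).
#' @export
select_ensemble <- function(pool_curves, data, ensemble_size,
                            n_generations = 200L, n_rounds = 3L, seed = 1,
                            population = 50L, mutation_rate = 0.1) {
  np <- length(pool_curves)
  if (ensemble_size > np)
    stop("domain error: ensemble_size exceeds pool size", call. = FALSE)
  stopifnot(ensemble_size >= 1L, n_generations >= 1L, n_rounds >= 1L)
  fitness <- function(idx)
    fit_mixture(data, pool_curves[idx], subtract_constant = FALSE)$chi
  best <- NULL
  for (round in seq_len(n_rounds)) {
    set.seed(seed + 7919L * (round - 1L))
    popn <- replicate(population,
                      sort(sample.int(np, ensemble_size)),
                      simplify = FALSE)
    fit <- vapply(popn, fitness, numeric(1L))
    trace <- numeric(n_generations)
    for (g in seq_len(n_generations)) {
      ord <- order(fit)
      elite <- popn[[ord[1L]]]
      newpop <- vector("list", population)
      newpop[[1L]] <- elite
      for (i in 2L:population) {
        # tournament selection of two parents
        pick <- function() {
          cand <- sample.int(population, 2L)
          popn[[cand[which.min(fit[cand])]]]
        }
        p1 <- pick(); p2 <- pick()
        if (ensemble_size > 1L) {
          cut <- sample.int(ensemble_size - 1L, 1L)
          child <- c(p1[seq_len(cut)], p2[(cut + 1L):ensemble_size])
        } else child <- p1
        # repair duplicates, then mutate by member swap
        child <- unique(child)
        while (length(child) < ensemble_size)
          child <- unique(c(child, sample.int(np, 1L)))
        mut <- runif(ensemble_size) < mutation_rate
        if (any(mut)) {
          avail <- setdiff(seq_len(np), child)
          for (k in which(mut)) {
            if (length(avail) == 0L) break
            pickidx <- if (length(avail) == 1L) avail
                       else sample(avail, 1L)
            avail <- c(setdiff(avail, pickidx), child[k])
            child[k] <- pickidx
          }
        }
        newpop[[i]] <- sort(child)
      }
      popn <- newpop
      fit <- vapply(popn, fitness, numeric(1L))
      # elitism guarantees the best individual never regresses
      trace[g] <- min(fit)
    }
    kb <- which.min(fit)
    if (is.null(best) || fit[kb] < best$chi)
      best <- list(ids = popn[[kb]], chi = fit[kb], trace = cummin(trace),
                   round = round)
  }
  mix <- fit_mixture(data, pool_curves[best$ids],
                     subtract_constant = FALSE)
  rgs <- vapply(pool_curves[best$ids], function(p)
    tryCatch(guinier_fit(p)$Rg, error = function(e) NA_real_),
    numeric(1L))
  structure(list(member_ids = best$ids, weights = mix$fractions,
                 chi = mix$chi, rg_distribution = rgs, seed = seed,
                 chi_trace = best$trace),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf(
    "ensemble: %d members (%s), chi = %.4f, weights = (%s)\n",
    length(x$member_ids), paste(x$member_ids, collapse = ","), x$chi,
    paste(sprintf("%.3f", x$weights), collapse = ", ")))
  invisible(x)
}
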