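#' Concentration scaling and extrapolation to infinite dilution
#'
#' Divides each intensity by its sample concentration and, when two or
#' more concentrations are available, extrapolates to c = 0 by a per-q
#' linear regression of I/c against c (removing the linear
#' interparticle-interference term). Profiles on different grids are
#' interpolated onto the common overlapping part of the first profile's
#' grid. Uncertainties are propagated (single profile: sigma/c; series:
#' standard error of the regression intercept).
#'
#' @param profiles list of `saxs_profile`s, each with a positive
#'   `concentration`.
#' @return A `saxs_profile` at infinite dilution (units I per mg/ml).
#' @export
scale_and_extrapolate <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  cs <- vapply(profiles, function(p) {
    if (is.null(p$concentration) || p$concentration <= 0)
      stop("every profile needs a positive concentration", call. = FALSE)
    p$concentration
  }, numeric(1L))
  lo <- max(vapply(profiles, function(p) min(p$q), numeric(1L)))
  hi <- min(vapply(profiles, function(p) max(p$q), numeric(1L)))
  if (lo >= hi)
    stop("grid error: profiles have no overlapping q range", call. = FALSE)
  q <- profiles[[1L]]$q
  q <- q[q >= lo & q <= hi]
  if (length(q) < 5L)
    stop("grid error: common q range too short", call. = FALSE)
  Imat <- vapply(profiles, function(p) approx(p$q, p$I, q)$y,
                 numeric(length(q)))
  Imat <- matrix(Imat, nrow = length(q))
  if (length(profiles) == 1L) {
    p <- profiles[[1L]]
    s <- if (is.null(p$sigma)) NULL else approx(p$q, p$sigma, q)$y / cs
    return(scattering_profile(q, Imat[, 1L] / cs, sigma = s,
                              label = "infinite dilution"))
  }
  Ic <- sweep(Imat, 2L, cs, "/")
  # per-q regression of I/c on c; intercept is the c -> 0 limit
  X <- cbind(1, cs)
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, t(Ic))          # 2 x nq coefficients
  I0q <- B[1L, ]
  if (length(profiles) > 2L) {
    res <- t(Ic) - X %*% B
    s2 <- colSums(res^2) / (length(cs) - 2L)
    se <- sqrt(pmax(s2 * XtXi[1L, 1L], 1e-300))
  } else {
    # two points determine the line exactly; carry measurement sigma
    sig <- vapply(seq_along(profiles), function(i) {
      p <- profiles[[i]]
      if (is.null(p$sigma)) rep(NA_real_, length(q))
      else approx(p$q, p$sigma, q)$y / cs[i]
    }, numeric(length(q)))
    se <- if (anyNA(sig)) NULL else sqrt(rowSums(matrix(sig, nrow = length(q))^2))
  }
  scattering_profile(q, I0q, sigma = se, label = "infinite dilution")
}

#' Merge low-q and high-q measurement ranges
#'
#' Scales the high-q profile onto the low-q one by the least-squares
#' factor over the stated overlap interval, then splices: low-q points
#' below the overlap midpoint, scaled high-q points above it.
#'
#' @param low_q,high_q `saxs_profile`s covering the lower and upper q
#'   ranges.
#' @param overlap length-2 numeric, q interval common to both.
#' @return A merged `saxs_profile`; attribute `scale_factor` records the
#'   factor applied to `high_q`.
#' @export
merge_ranges <- function(low_q, high_q, overlap) {
  stopifnot(length(overlap) == 2L, overlap[1L] < overlap[2L])
  inlo <- low_q$q >= overlap[1L] & low_q$q <= overlap[2L]
  inhi <- high_q$q >= overlap[1L] & high_q$q <= overlap[2L]
  if (!any(inlo) || !any(inhi))
    stop("merge error: empty overlap interval", call. = FALSE)
  qo <- low_q$q[inlo]
  Ih <- approx(high_q$q, high_q$I, qo, rule = 2L)$y
  f <- sum(low_q$I[inlo] * Ih) / sum(Ih^2)
  mid <- mean(overlap)
  keep_lo <- low_q$q <= mid
  keep_hi <- high_q$q > mid
  q <- c(low_q$q[keep_lo], high_q$q[keep_hi])
  I <- c(low_q$I[keep_lo], f * high_q$I[keep_hi])
  s <- if (!is.null(low_q$sigma) && !is.null(high_q$sigma))
    c(low_q$sigma[keep_lo], f * high_q$sigma[keep_hi]) else NULL
  out <- scattering_profile(q, I, sigma = s,
                            label = paste0(low_q$label, "+", high_q$label))
  attr(out, "scale_factor") <- f
  out
}

#' Guinier analysis with automatic range selection
#'
#' Fits `ln I = ln I0 - q^2 Rg^2 / 3` by weighted linear regression over
#' an automatically chosen low-q window. Candidate windows are contiguous
#' runs of at least 5 points starting after `skip_low_q`; a window is
#' admissible when the self-consistency conditions `qmax * Rg <= qRg_limit`
#' and `qmin * Rg <= 0.65` hold for its own fit. The longest admissible
#' window is selected, ties broken by the highest r-squared — the common
#' automated-Guinier heuristic.
#'
#' @param profile a `saxs_profile` with positive intensities over the
#'   candidate window.
#' @param qRg_limit upper validity bound on `qmax * Rg` (default 1.3, the
#'   standard globular-particle limit).
#' @param skip_low_q number of lowest-q points to exclude (beamstop or
#'   trace-aggregation region).
#' @return A `guinier_result` with fields `Rg`, `I0`, `q_window`,
#'   `n_points`, `fit_r2`, `Rg_err`, `I0_err`.
#' @export
guinier_fit <- function(profile, qRg_limit = 1.3, skip_low_q = 0L) {
  validate_profile(profile)
  q <- profile$q; I <- profile$I
  n <- length(q)
  first <- skip_low_q + 1L
  # candidate region: positive intensities from `first` up to the first
  # non-positive point
  pos <- I > 0
  last_ok <- if (all(pos[first:n])) n else first + which(!pos[first:n])[1L] - 2L
  if (is.na(last_ok) || last_ok - first + 1L < 5L)
    stop("no-Guinier-region error: too few positive low-q points",
         call. = FALSE)
  lnI <- log(I[first:last_ok])
  q2 <- q[first:last_ok]^2
  wts <- if (!is.null(profile$sigma))
    (I[first:last_ok] / profile$sigma[first:last_ok])^2 else
      rep(1, length(lnI))
  m <- length(lnI)
  best <- NULL
  for (s in seq_len(m - 4L)) {
    if (!is.null(best)) break          # earliest admissible start wins
    for (e in seq(s + 4L, m)) {
      fit <- stats::lm.wfit(cbind(1, q2[s:e]), lnI[s:e], wts[s:e])
      slope <- fit$coefficients[2L]
      if (!is.finite(slope) || slope >= 0) next
      Rg <- sqrt(-3 * slope)
      if (sqrt(q2[e]) * Rg > qRg_limit) break   # longer windows only worse
      if (sqrt(q2[s]) * Rg > 0.65) next
      ss_res <- sum(wts[s:e] * fit$residuals^2)
      ybar <- sum(wts[s:e] * lnI[s:e]) / sum(wts[s:e])
      ss_tot <- sum(wts[s:e] * (lnI[s:e] - ybar)^2)
      r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
      len <- e - s + 1L
      # the Guinier region is the lowest-q admissible window: prefer the
      # earliest start, then the best r2, then the longest window.
      # A purely length-based rule locks onto spuriously self-consistent
      # flat stretches at high q; r2 preference shrinks the window when
      # curvature (Guinier-approximation breakdown) dominates and grows
      # it when noise dominates.
      if (is.null(best) || s < best$s ||
          (s == best$s && (r2 > best$r2 + 1e-12 ||
                           (abs(r2 - best$r2) <= 1e-12 &&
                            len > best$len)))) {
        # standard errors from the weighted normal equations
        X <- cbind(1, q2[s:e])
        XtWXi <- tryCatch(solve(crossprod(X * sqrt(wts[s:e]))),
                          error = function(e) NULL)
        s2 <- ss_res / max(len - 2L, 1L)
        ses <- if (is.null(XtWXi)) c(NA, NA) else sqrt(diag(XtWXi) * s2)
        best <- list(s = s, e = e, len = len, r2 = r2, Rg = Rg,
                     I0 = exp(fit$coefficients[1L]),
                     I0_err = exp(fit$coefficients[1L]) * ses[1L],
                     Rg_err = if (is.na(ses[2L])) NA_real_
                              else 3 * ses[2L] / (2 * Rg))
      }
    }
  }
  if (is.null(best))
    stop("no-Guinier-region error: no admissible window with qmax*Rg <= ",
         qRg_limit, call. = FALSE)
  structure(list(Rg = unname(best$Rg), I0 = unname(best$I0),
                 q_window = c(sqrt(q2[best$s]), sqrt(q2[best$e])),
                 n_points = best$len, fit_r2 = best$r2,
                 Rg_err = unname(best$Rg_err), I0_err = unname(best$I0_err)),
            class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf(
    "Guinier fit: Rg = %.3f A, I0 = %.5g (%d pts, q in [%.4f, %.4f], qmaxRg = %.2f, r2 = %.4f)\n",
    x$Rg, x$I0, x$n_points, x$q_window[1L], x$q_window[2L],
    x$q_window[2L] * x$Rg, x$fit_r2))
  invisible(x)
}

#' Kratky transform
#'
#' Returns the dimensionless-shape diagnostic `I(q) * q^2` on the input
#' grid: bell-shaped with an interior maximum for globular particles,
#' plateauing at high q for disordered chains.
#'
#' @param profile a `saxs_profile`.
#' @return A data frame with columns `q` and `Iq2`.
#' @export
kratky_transform <- function(profile) {
  validate_profile(profile)
  data.frame(q = profile$q, Iq2 = profile$I * profile$q^2)
}

#' Porod invariant and Porod volume
#'
#' Computes the invariant `Q = integral of q^2 I(q) dq` by trapezoidal
#' quadrature on the measured grid (with the exact `q^2 I -> 0` limit at
#' q = 0 prepended) and the Porod volume `Vp = 2 pi^2 I0 / Q`. With
#' `tail_power_law = TRUE` (default) the integral is extended beyond the
#' last measured point assuming Porod's law `I ~ q^-4`, whose tail
#' contributes exactly `I(qmax) * qmax^3`; truncated ranges otherwise
#' bias Vp upward.
#'
#' @param profile a `saxs_profile`.
#' @param I0 forward scattering, same units as `I` (from a Guinier or
#'   P(r) analysis).
#' @param tail_power_law extend the integrand analytically beyond qmax.
#' @return A `porod_result` with `Q_invariant`, `Vp`, `q_range_used`,
#'   `tail_extrapolated`.
#' @export
porod_volume <- function(profile, I0, tail_power_law = TRUE) {
  validate_profile(profile)
  stopifnot(I0 > 0)
  q <- profile$q; I <- profile$I
  integrand <- q^2 * I
  if (q[1L] > 0) {
    q <- c(0, q); integrand <- c(0, integrand)
  }
  Q <- pracma::trapz(q, integrand)
  qmax <- max(q)
  n <- length(profile$q)
  # Porod-regime sanity: q^4 I should be roughly flat near qmax
  p4 <- profile$q^4 * profile$I
  tailpts <- p4[max(1L, n - 9L):n]
  if (mean(tailpts) > 0 &&
      stats::sd(tailpts) / mean(tailpts) > 0.5)
    warning("q^4*I not approximately constant near qmax; Porod regime may not be reached")
  if (tail_power_law) Q <- Q + profile$I[n] * qmax^3
  if (Q <= 0)
    stop("integration error: non-positive Porod invariant", call. = FALSE)
  structure(list(Q_invariant = Q, Vp = 2 * pi^2 * I0 / Q,
                 q_range_used = range(profile$q),
                 tail_extrapolated = tail_power_law),
            class = "porod_result")
}

#' @export
print.porod_result <- function(x, ...) {
  cat(sprintf("Porod: Q = %.5g, Vp = %.0f A^3 (q <= %.3f%s)\n",
              x$Q_invariant, x$Vp, x$q_range_used[2L],
              if (x$tail_extrapolated) ", q^-4 tail extended" else ""))
  invisible(x)
}

#' Molecular mass from the Porod volume
#'
#' `M = density_factor * Vp`, with the empirical protein conversion
#' factor 0.588 Da per cubic Angstrom (equivalently a protein density of
#' 0.588 g/ml on the Porod-volume scale). Reported to the nearest Dalton.
#'
#' @param Vp Porod volume, A^3.
#' @param density_factor Da per A^3; default 0.588.
#' @return Mass in Da, rounded to the nearest integer.
#' @export
mass_from_porod <- function(Vp, density_factor = 0.588) {
  if (Vp < 0) stop("domain error: negative Porod volume", call. = FALSE)
  round(Vp * density_factor)
}

#' Dimer weight fraction from an apparent mass
#'
#' Under the assumption that only monomers and dimers contribute to the
#' scattering, the apparent (mass-weighted) molecular mass is
#' `M = (1 + w) M_monomer`, so the dimer weight fraction is
#' `w = M_apparent / M_monomer - 1`, clipped to the physical interval
#' [0, 1].
#'
#' @param M_apparent apparent molecular mass, Da (from I(0) or Vp).
#' @param M_monomer theoretical monomer mass, Da (from chemical
#'   composition).
#' @param source which route produced `M_apparent`:
#'   `"porod_volume"` or `"forward_scattering"`.
#' @return A `mass_estimate` with `M`, `M_monomer_ref`, `dimer_fraction`,
#'   `source`.
#' @export
oligomer_fraction <- function(M_apparent, M_monomer,
                              source = c("porod_volume",
                                         "forward_scattering")) {
  source <- match.arg(source)
  if (M_monomer <= 0)
    stop("domain error: monomer mass must be positive", call. = FALSE)
  if (M_apparent < 0)
    stop("domain error: negative apparent mass", call. = FALSE)
  w <- min(max(M_apparent / M_monomer - 1, 0), 1)
  structure(list(M = M_apparent, M_monomer_ref = M_monomer,
                 dimer_fraction = w, source = source),
            class = "mass_estimate")
}

#' @export
print.mass_estimate <- function(x, ...) {
  cat(sprintf("M = %.0f Da (monomer %.0f Da, %s): dimer content %.1f%%\n",
              x$M, x$M_monomer_ref, x$source, 100 * x$dimer_fraction))
  invisible(x)
}

#' Apparent mass from forward scattering
#'
#' On an absolutely calibrated scale, `M = k_cal * I(0) / c` with an
#' instrument calibration constant `k_cal` (Da per (1/cm) per (mg/ml)).
#' The constant is instrument- and contrast-specific and must be supplied
#' by the user; all downstream dimer-content numerics work on mass
#' ratios and are calibration-free.
#'
#' @param I0 forward scattering, 1/cm.
#' @param concentration protein concentration, mg/ml.
#' @param k_cal calibration constant, Da cm mg^-1 ml.
#' @return Apparent mass, Da.
#' @export
mass_from_forward_scattering <- function(I0, concentration, k_cal) {
  stopifnot(I0 >= 0, concentration > 0, k_cal > 0)
  round(k_cal * I0 / concentration)
}
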