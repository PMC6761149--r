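#' Construct a scattering profile
#'
#' A `saxs_profile` holds an orientationally averaged scattering intensity
#' `I(q)` on a momentum-transfer grid `q` (in inverse Angstrom), with an
#' optional per-point standard error `sigma` and an optional sample
#' concentration in mg/ml.
#'
#' @param q numeric vector of momentum transfer values, 1/Angstrom; must be
#'   strictly increasing and non-negative.
#' @param I numeric vector of intensities, same length as `q`; arbitrary
#'   units (relative) or 1/cm (absolute).
#' @param sigma optional numeric vector of standard errors, strictly
#'   positive, same length as `q`.
#' @param concentration optional scalar protein concentration, mg/ml.
#' @param label free-text sample label.
#' @return An object of class `saxs_profile`.
#' @export
scattering_profile <- function(q, I, sigma = NULL, concentration = NULL,
                               label = "") {
  p <- structure(
    list(q = as.numeric(q), I = as.numeric(I),
         sigma = if (is.null(sigma)) NULL else as.numeric(sigma),
         concentration = concentration, label = label),
    class = "saxs_profile")
  validate_profile(p)
  p
}

#' Validate a scattering profile's invariants
#'
#' Checks the container invariants: at least 5 points, strictly increasing
#' non-negative `q`, finite `I`, and (when present) strictly positive
#' `sigma` of matching length.
#'
#' @param p a `saxs_profile`.
#' @return `p`, invisibly; errors if any invariant is violated.
#' @export
validate_profile <- function(p) {
  stopifnot(inherits(p, "saxs_profile"))
  if (length(p$q) < 5L)
    stop("malformed profile: fewer than 5 points", call. = FALSE)
  if (length(p$I) != length(p$q))
    stop("malformed profile: q and I lengths differ", call. = FALSE)
  if (any(!is.finite(p$q)) || any(p$q < 0))
    stop("malformed profile: q must be finite and >= 0", call. = FALSE)
  if (any(diff(p$q) <= 0))
    stop("profile ordering error: q must be strictly increasing",
         call. = FALSE)
  if (any(!is.finite(p$I)))
    stop("malformed profile: non-finite intensities", call. = FALSE)
  if (!is.null(p$sigma)) {
    if (length(p$sigma) != length(p$q))
      stop("malformed profile: sigma length differs from q", call. = FALSE)
    if (any(!is.finite(p$sigma)) || any(p$sigma <= 0))
      stop("malformed profile: sigma must be finite and > 0", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("saxs_profile '%s': %d points, q = [%.4g, %.4g] 1/A%s%s\n",
              x$label, length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) ", no sigma" else "",
              if (is.null(x$concentration)) ""
              else sprintf(", c = %g mg/ml", x$concentration)))
  invisible(x)
}

#' Read a scattering profile from an ASCII .dat file
#'
#' Parses the common 2/3-column ASCII dialect (`q I [sigma]`). Any line
#' whose first whitespace token does not parse as a number is treated as a
#' header or comment and skipped. `q` is stored internally in 1/Angstrom;
#' inputs tabulated in 1/nm are converted (divided by 10) at this boundary.
#'
#' @param path path to the file.
#' @param q_unit unit of the q column in the file: `"inverse_angstrom"`
#'   (default) or `"inverse_nanometer"`.
#' @param label optional sample label; defaults to the file name.
#' @param concentration optional concentration, mg/ml.
#' @return A `saxs_profile`.
#' @export
read_profile <- function(path,
                         q_unit = c("inverse_angstrom", "inverse_nanometer"),
                         label = basename(path), concentration = NULL) {
  q_unit <- match.arg(q_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  ncol_seen <- NULL
  for (ln in lines) {
    toks <- strsplit(trimws(ln), "[[:space:],]+")[[1]]
    if (length(toks) < 2L) next
    vals <- suppressWarnings(as.numeric(toks))
    if (is.na(vals[1L])) next          # header/comment line
    vals <- vals[!is.na(vals)]
    if (length(vals) < 2L) next
    rows[[length(rows) + 1L]] <- vals[seq_len(min(3L, length(vals)))]
  }
  if (length(rows) < 5L)
    stop("malformed profile: fewer than 5 valid data rows in ", path,
         call. = FALSE)
  nc <- min(vapply(rows, length, integer(1L)))
  m <- do.call(rbind, lapply(rows, function(r) r[seq_len(nc)]))
  q <- m[, 1L]
  if (q_unit == "inverse_nanometer") q <- q / 10
  scattering_profile(q, m[, 2L],
                     sigma = if (nc >= 3L) m[, 3L] else NULL,
                     concentration = concentration, label = label)
}

#' Write a scattering profile to an ASCII .dat file
#'
#' Writes 3 columns (`q I sigma`) or 2 when no sigma is stored, preceded by
#' a one-line comment header. Round-trips through [read_profile()] to the
#' formatting precision (9 significant digits).
#'
#' @param profile a valid `saxs_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  validate_profile(profile)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# oligosaxs profile: %s (q in 1/A)", profile$label),
             con)
  if (is.null(profile$sigma)) {
    writeLines(sprintf("%.9g %.9g", profile$q, profile$I), con)
  } else {
    writeLines(sprintf("%.9g %.9g %.9g", profile$q, profile$I,
                       profile$sigma), con)
  }
  invisible(path)
}

# effective X-ray scattering weight per element: electron count
.element_weights <- c(H = 1, C = 6, N = 7, O = 8, S = 16, P = 15,
                      SE = 34, FE = 26, ZN = 30, MG = 12, CA = 20,
                      MN = 25, CL = 17, `NA` = 11, K = 19, CU = 29, I = 53)

# displaced solvent volume per element, A^3 (single-atom van der Waals
# spheres; coarse, used only for the optional contrast correction)
.element_volumes <- c(H = 5.15, C = 16.44, N = 2.49, O = 9.13, S = 19.86,
                      P = 5.73, SE = 28.7, FE = 7.99, ZN = 9.85, MG = 17.2,
                      CA = 31.9, MN = 9.2, CL = 22.4, `NA` = 4.4, K = 11.0,
                      CU = 8.78, I = 32.2)

#' Construct a coordinate model
#'
#' A `coord_model` is a set of point scatterers (atoms or residue
#' centroids): positions in Angstrom, per-site effective scattering
#' weights, and optional per-site displaced-solvent volumes.
#'
#' @param positions numeric matrix, N x 3, Angstrom.
#' @param weights numeric vector of positive scattering weights, length N.
#' @param volumes optional numeric vector of positive volumes, A^3.
#' @param site_labels optional character vector of site identifiers.
#' @return An object of class `coord_model`.
#' @export
coordinate_model <- function(positions, weights = rep(1, nrow(positions)),
                             volumes = NULL, site_labels = NULL) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 1L)
    stop("empty-structure error: model needs at least 1 site", call. = FALSE)
  if (ncol(positions) != 3L) stop("positions must be N x 3", call. = FALSE)
  if (any(!is.finite(positions)))
    stop("non-finite coordinates", call. = FALSE)
  weights <- as.numeric(weights)
  if (length(weights) != nrow(positions) || any(weights <= 0) ||
      any(!is.finite(weights)))
    stop("weights must be positive, one per site", call. = FALSE)
  if (!is.null(volumes)) {
    volumes <- as.numeric(volumes)
    if (length(volumes) != nrow(positions) || any(volumes <= 0))
      stop("volumes must be positive, one per site", call. = FALSE)
  }
  structure(list(positions = positions, weights = weights,
                 volumes = volumes, site_labels = site_labels),
            class = "coord_model")
}

#' @export
print.coord_model <- function(x, ...) {
  cat(sprintf("coord_model: %d sites, total weight %.4g%s\n",
              nrow(x$positions), sum(x$weights),
              if (is.null(x$volumes)) "" else
                sprintf(", total volume %.4g A^3", sum(x$volumes))))
  invisible(x)
}

#' Read a coordinate model from a PDB file
#'
#' Reads ATOM/HETATM records with bio3d and converts them into a
#' `coord_model`. In `atomic` mode each non-hydrogen atom becomes a site
#' with an element-dependent weight (electron count); in
#' `residue_centroid` mode each residue becomes a single site at the mean
#' heavy-atom position with uniform weight 1 (uniform-contrast coarse
#' grain). Only altloc blank-or-'A' records are kept.
#'
#' @param path path to a PDB file.
#' @param mode `"atomic"` or `"residue_centroid"`.
#' @param chain optional chain identifier(s) to keep; default all.
#' @return A `coord_model`.
#' @export
read_structure <- function(path, mode = c("atomic", "residue_centroid"),
                           chain = NULL) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop("empty-structure error: no parseable ATOM records in ",
                         path, call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("empty-structure error: no ATOM records in ", path, call. = FALSE)
  keep <- at$alt %in% c("", "A") | is.na(at$alt)
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L)
    stop("empty-structure error: no atoms after filtering", call. = FALSE)
  elem <- toupper(trimws(at$elesy))
  bad <- is.na(elem) | elem == ""
  # fall back to the first letter of the atom name when the element
  # column is absent (minimal PDB dialects)
  elem[bad] <- substr(gsub("[^A-Za-z].*$", "",
                           toupper(trimws(at$elety[bad]))), 1L, 1L)
  if (mode == "atomic") {
    nh <- elem != "H" & elem != "D"
    at <- at[nh, , drop = FALSE]
    elem <- elem[nh]
    if (nrow(at) == 0L)
      stop("empty-structure error: no heavy atoms", call. = FALSE)
    w <- unname(.element_weights[elem])
    if (any(is.na(w))) {
      warning("unknown element(s) ",
              paste(unique(elem[is.na(w)]), collapse = ", "),
              "; using default weight 6")
      w[is.na(w)] <- 6
    }
    v <- unname(.element_volumes[elem])
    v[is.na(v)] <- 16.44
    coordinate_model(cbind(at$x, at$y, at$z), weights = w, volumes = v,
                     site_labels = paste0(at$resid, at$resno, ":",
                                          trimws(at$elety)))
  } else {
    nh <- elem != "H" & elem != "D"
    at <- at[nh, , drop = FALSE]
    key <- paste(at$chain, at$resno, at$insert, sep = "|")
    idx <- split(seq_len(nrow(at)), factor(key, levels = unique(key)))
    pos <- t(vapply(idx, function(i)
      c(mean(at$x[i]), mean(at$y[i]), mean(at$z[i])), numeric(3L)))
    labs <- vapply(idx, function(i) paste0(at$resid[i[1L]], at$resno[i[1L]]),
                   character(1L))
    coordinate_model(pos, weights = rep(1, nrow(pos)), site_labels = labs)
  }
}

#' Write a coordinate or bead model as a PDB file
#'
#' Each site is written as one HETATM record (residue DUM), suitable for
#' superposition and rendering in standard structure viewers.
#'
#' @param model a `coord_model` or `bead_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  pos <- if (inherits(model, "bead_model")) model$positions
         else model$positions
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(pos)
  for (i in seq_len(n)) {
    writeLines(sprintf(
      "HETATM%5d  CA  DUM A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      i %% 100000L, i %% 10000L, pos[i, 1L], pos[i, 2L], pos[i, 3L]), con)
  }
  writeLines("END", con)
  invisible(path)
}
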