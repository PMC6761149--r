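#' Assemble a pipeline configuration
#'
#' Collects every knob of the oligomer-analysis workflow into one
#' explicit record so a run is fully reproducible from its persisted
#' configuration (all seeds and tolerances are part of the report).
#'
#' @param profiles list of `saxs_profile`s, or character paths to .dat
#'   files.
#' @param monomer_mass theoretical monomer mass from chemical
#'   composition, Da.
#' @param q_unit unit of q columns when `profiles` are paths.
#' @param qRg_limit Guinier validity bound (default 1.3).
#' @param skip_low_q low-q points excluded from the Guinier scan.
#' @param dmax fixed Dmax in Angstrom, or `NULL` to scan.
#' @param dmax_scan length-2 scan range (used when `dmax` is `NULL`).
#' @param n_dmax_scan scan points.
#' @param alpha P(r) regularization weight (`NULL` = L-curve).
#' @param mixture_components optional list of component `saxs_profile`s
#'   (or paths) for a mixture decomposition of each sample.
#' @param subtract_constant fit additive backgrounds in model fits.
#' @param k_cal optional absolute calibration constant for
#'   [mass_from_forward_scattering()]; `NULL` disables the I(0) mass
#'   route (the Vp route is calibration-free).
#' @param seed master seed recorded in the report.
#' @param out_dir optional output directory for JSON/TSV reports.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(profiles, monomer_mass,
                            q_unit = "inverse_angstrom",
                            qRg_limit = 1.3, skip_low_q = 0L,
                            dmax = NULL, dmax_scan = c(40, 160),
                            n_dmax_scan = 25L, alpha = NULL,
                            mixture_components = NULL,
                            subtract_constant = FALSE, k_cal = NULL,
                            seed = 1L, out_dir = NULL) {
  stopifnot(monomer_mass > 0)
  structure(list(profiles = profiles, monomer_mass = monomer_mass,
                 q_unit = q_unit, qRg_limit = qRg_limit,
                 skip_low_q = skip_low_q, dmax = dmax,
                 dmax_scan = dmax_scan, n_dmax_scan = n_dmax_scan,
                 alpha = alpha, mixture_components = mixture_components,
                 subtract_constant = subtract_constant, k_cal = k_cal,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

resolve_profiles <- function(x, q_unit) {
  if (is.character(x)) x <- as.list(x)
  lapply(x, function(p) {
    if (is.character(p)) read_profile(p, q_unit = q_unit) else p
  })
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  stripped <- config[setdiff(names(config), c("profiles",
                                              "mixture_components"))]
  jsonlite::write_json(stripped, tf, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tf))
}

#' Run the full oligomer analysis on a set of scattering profiles
#'
#' For each input profile: Guinier fit (Rg, I(0)), P(r) inversion (Dmax
#' either fixed or scanned; real-space Rg and I(0)), Porod invariant and
#' volume, mass from Vp, and the dimer weight fraction from the
#' Vp-route mass (and from the I(0) route when a calibration constant
#' is supplied). When component form factors are given, each sample is
#' also decomposed into non-negative component fractions. One row per
#' profile, schema-stable; a stage that fails for one sample is
#' recorded as NA with the error message captured, and the remaining
#' stages still run.
#'
#' @param config a [pipeline_config()].
#' @return An `oligomer_report`: list with `table` (data frame),
#'   `mixtures` (list of `mixture_result` or NULL), `errors`,
#'   `config_hash`, `package_version`, `seed`. When `config$out_dir` is
#'   set, `report.json` and `report.tsv` are written there.
#' @export
run_oligomer_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  profs <- resolve_profiles(config$profiles, config$q_unit)
  comps <- if (is.null(config$mixture_components)) NULL
           else resolve_profiles(config$mixture_components, config$q_unit)
  n <- length(profs)
  rows <- vector("list", n)
  mixtures <- vector("list", n)
  errors <- list()
  note_err <- function(stage, i, e) {
    errors[[length(errors) + 1L]] <<- list(stage = stage, profile = i,
                                           message = conditionMessage(e))
    NULL
  }
  for (i in seq_len(n)) {
    p <- profs[[i]]
    gu <- tryCatch(guinier_fit(p, qRg_limit = config$qRg_limit,
                               skip_low_q = config$skip_low_q),
                   error = function(e) note_err("guinier", i, e))
    dmax_i <- config$dmax
    if (is.null(dmax_i))
      dmax_i <- tryCatch({
        args <- list(p, config$dmax_scan, n_scan = config$n_dmax_scan)
        if (!is.null(config$alpha)) args$alpha <- config$alpha
        as.numeric(do.call(estimate_dmax, args))
      }, error = function(e) note_err("dmax_scan", i, e))
    pr <- if (is.null(dmax_i)) NULL else
      tryCatch(fit_pr(p, Dmax = dmax_i, alpha = config$alpha),
               error = function(e) note_err("pr", i, e))
    I0 <- if (!is.null(gu)) gu$I0 else if (!is.null(pr)) pr$I0_real else NA
    po <- if (is.na(I0)) NULL else
      tryCatch(porod_volume(p, I0 = I0),
               error = function(e) note_err("porod", i, e))
    M_vp <- if (is.null(po)) NA_real_ else mass_from_porod(po$Vp)
    w_vp <- if (is.na(M_vp)) NA_real_ else
      oligomer_fraction(M_vp, config$monomer_mass,
                        source = "porod_volume")$dimer_fraction
    M_i0 <- w_i0 <- NA_real_
    if (!is.null(config$k_cal) && !is.na(I0) &&
        !is.null(p$concentration)) {
      M_i0 <- mass_from_forward_scattering(I0, p$concentration,
                                           config$k_cal)
      w_i0 <- oligomer_fraction(M_i0, config$monomer_mass,
                                source = "forward_scattering")$dimer_fraction
    }
    if (!is.null(comps))
      mixtures[[i]] <- tryCatch(
        fit_mixture(p, comps,
                    subtract_constant = config$subtract_constant),
        error = function(e) note_err("mixture", i, e))
    rows[[i]] <- data.frame(
      label = p$label,
      concentration = if (is.null(p$concentration)) NA_real_
                      else p$concentration,
      I0 = I0,
      Rg_guinier = if (is.null(gu)) NA_real_ else gu$Rg,
      Rg_real = if (is.null(pr)) NA_real_ else pr$Rg_real,
      Dmax = if (is.null(pr)) NA_real_ else pr$Dmax,
      Vp = if (is.null(po)) NA_real_ else po$Vp,
      M_from_Vp = M_vp,
      dimer_pct_Vp = round(100 * w_vp, 1),
      M_from_I0 = M_i0,
      dimer_pct_I0 = round(100 * w_i0, 1),
      mixture_chi = if (is.null(mixtures[[i]])) NA_real_
                    else mixtures[[i]]$chi,
      stringsAsFactors = FALSE)
  }
  report <- structure(
    list(table = do.call(rbind, rows), mixtures = mixtures,
         errors = errors, config_hash = config_hash(config),
         package_version =
           as.character(utils::packageVersion("oligosaxs")),
         seed = config$seed),
    class = "oligomer_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(report$table,
                       file.path(config$out_dir, "report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(table = report$table, config_hash = report$config_hash,
           package_version = report$package_version,
           seed = report$seed),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  report
}

#' @export
print.oligomer_report <- function(x, ...) {
  cat(sprintf("oligomer analysis (%s, oligosaxs %s):\n", x$config_hash,
              x$package_version))
  print(x$table, row.names = FALSE)
  if (length(x$errors) > 0L)
    cat(sprintf("  %d stage error(s); see $errors\n", length(x$errors)))
  invisible(x)
}
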