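# End-to-end reproducible runs: a configuration record, the NOE ->
# restraints -> conformer -> classification chain, the isotherm workup
# chain, and JSON reports that fully reconstruct a run.

#' Pipeline run configuration
#'
#' Bundles every tunable threshold and seed of the analysis chain so that
#' a report can state exactly how its numbers were produced.
#'
#' @param noe A [noe_config()].
#' @param folded_window,d_u Conformation taxonomy parameters
#'   (see [classify_conformation()]).
#' @param tau_small,tau_large,tau_zero Localization thresholds in ppm
#'   (see [localize()]).
#' @param grid_step,sg_window,min_curvature Isotherm workup parameters
#'   (see [collapse_pressure()]).
#' @param seed Integer seed used by every stochastic stage.
#' @param n_starts Multi-start count for [fit_conformer()].
#' @return List of class `run_config`.
#' @export
run_config <- function(noe = noe_config(), folded_window = c(60, 120),
                       d_u = 6.0, tau_small = 0.03, tau_large = 0.05,
                       tau_zero = 0.005, grid_step = 0.25, sg_window = 11,
                       min_curvature = 1.0, seed = 1, n_starts = 24) {
  stopifnot(inherits(noe, "noe_config"),
            folded_window[1L] < folded_window[2L], d_u > 0,
            tau_zero < tau_small, tau_large > 0)
  structure(list(noe = noe, folded_window = folded_window, d_u = d_u,
                 tau_small = tau_small, tau_large = tau_large,
                 tau_zero = tau_zero, grid_step = grid_step,
                 sg_window = sg_window, min_curvature = min_curvature,
                 seed = seed, n_starts = n_starts),
            class = "run_config")
}

#' Run the NOE conformation pipeline
#'
#' Normalizes a cross-peak table, derives distance restraints, fits a
#' conformer of the given topology and classifies its conformation.
#'
#' @param peaks Peak data frame (or path to a peak CSV).
#' @param topology An [`lq_topology`][build_topology()] (default UQ-2).
#' @param reference_pair Reference group pair (default `c("H_W","H_MN")`).
#' @param config A [run_config()].
#' @param expected_pairs Optional monitored pairs for absence restraints
#'   (see [restraints_from_table()]).
#' @return List of class `noe_run`: `normalized`, `restraints`, `fit`,
#'   `classification`, `config`, `warnings`.
#' @export
run_noe_pipeline <- function(peaks, topology = NULL,
                             reference_pair = c("H_W", "H_MN"),
                             config = run_config(),
                             expected_pairs = NULL) {
  if (is.character(peaks)) peaks <- read_peak_csv(peaks)
  if (is.null(topology)) topology <- build_topology("UQ", 2)
  warns <- character(0)
  wh <- function(w) { warns <<- c(warns, conditionMessage(w))
                      invokeRestart("muffleWarning") }
  norm <- withCallingHandlers(
    normalize_volumes(peaks, reference_pair, config$noe), warning = wh)
  restr <- withCallingHandlers(
    restraints_from_table(norm, config$noe, expected_pairs), warning = wh)
  fit <- fit_conformer(topology, restr, seed = config$seed,
                       n_starts = config$n_starts)
  cls <- classify_conformation(fit$conformer, config$folded_window,
                               config$d_u)
  structure(list(normalized = norm, restraints = restr, fit = fit,
                 classification = cls, config = config, warnings = warns),
            class = "noe_run")
}

#' @export
print.noe_run <- function(x, ...) {
  cat(sprintf(
    "NOE pipeline run: %d peak(s) -> %d restraint(s) -> %s (phi %.1f deg, penalty %.3g)\n",
    nrow(x$normalized), nrow(x$restraints$restraints),
    x$classification$label, x$classification$phi, x$fit$penalty))
  if (length(x$warnings)) cat("warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Run the isotherm workup pipeline
#'
#' Averages replicates, detects the collapse pressure, computes the
#' compression modulus and, when a pure-film control is supplied, the
#' physiological-window expansion and band-overlap verdict.
#'
#' @param curves List of [isotherm_curve()] replicates (or isotherm CSV
#'   path).
#' @param control Optional control replicates (pure-phospholipid film).
#' @param config A [run_config()].
#' @param window Pressure window (mN/m) for expansion/overlap (default
#'   `c(30, 35)`).
#' @return List of class `isotherm_run`: `mean`, `collapse`, `modulus`,
#'   optionally `expansion_percent` and `overlap`, plus `config`.
#' @export
run_isotherm_pipeline <- function(curves, control = NULL,
                                  config = run_config(),
                                  window = c(30, 35)) {
  if (is.character(curves)) curves <- read_isotherm_csv(curves)
  m <- average_replicates(curves, grid_step = config$grid_step)
  col <- collapse_pressure(m, grid_step = config$grid_step,
                           sg_window = config$sg_window,
                           min_curvature = config$min_curvature)
  mod <- compression_modulus(m, grid_step = config$grid_step,
                             sg_window = config$sg_window)
  out <- list(mean = m, collapse = col, modulus = mod, config = config)
  if (!is.null(control)) {
    if (is.character(control)) control <- read_isotherm_csv(control)
    mc <- average_replicates(control, grid_step = config$grid_step)
    out$control_mean <- mc
    out$expansion_percent <- area_expansion(m, mc, window = window)
    out$overlap <- tryCatch(overlap_flag(m, mc, window = window),
                            error = function(e) NA_character_)
  }
  structure(out, class = "isotherm_run")
}

#' @export
print.isotherm_run <- function(x, ...) {
  print(x$collapse)
  cat(sprintf("max compression modulus: %.1f mN/m\n",
              max(x$modulus$modulus, na.rm = TRUE)))
  if (!is.null(x$expansion_percent))
    cat(sprintf("area expansion over window: %.1f%% (%s)\n",
                x$expansion_percent,
                if (is.na(x$overlap)) "overlap n/a" else x$overlap))
  invisible(x)
}

#' Write a run report as JSON
#'
#' Serializes the configuration echo and per-stage outputs of a
#' [run_noe_pipeline()] or [run_isotherm_pipeline()] result; together
#' with the input files this reconstructs the run.
#'
#' @param run A `noe_run` or `isotherm_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(run, path) {
  cfg <- run$config
  cfg_rec <- list(seed = cfg$seed, n_starts = cfg$n_starts,
                  folded_window = cfg$folded_window, d_u = cfg$d_u,
                  tau_small = cfg$tau_small, tau_large = cfg$tau_large,
                  tau_zero = cfg$tau_zero, grid_step = cfg$grid_step,
                  sg_window = cfg$sg_window,
                  min_curvature = cfg$min_curvature,
                  noe = unclass(cfg$noe))
  rec <- if (inherits(run, "noe_run")) {
    list(kind = "noe_run", config = cfg_rec,
         restraints = run$restraints$restraints,
         excluded = nrow(run$restraints$excluded),
         penalty = run$fit$penalty,
         phi = run$classification$phi,
         conformation = run$classification$label,
         torsions = as.list(run$fit$conformer$torsions),
         warnings = run$warnings)
  } else if (inherits(run, "isotherm_run")) {
    list(kind = "isotherm_run", config = cfg_rec,
         collapse_pressure = run$collapse$collapse_pressure,
         collapse_detected = run$collapse$detected,
         max_modulus = max(run$modulus$modulus, na.rm = TRUE),
         expansion_percent = run$expansion_percent,
         overlap = if (!is.null(run$overlap)) as.character(run$overlap))
  } else stop("unsupported run object")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}
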