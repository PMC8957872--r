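# Seeded synthetic-data generators: NOE peak tables from a known conformer,
# piecewise-phase Langmuir isotherms with a known collapse pressure, and
# chemical-shift tables with a known probe location.  All generators are
# pure functions of (parameters, seed).

#' Simulate a NOE cross-peak table from a known conformer
#'
#' Computes the effective inter-group distance for every monitored proton
#' group pair of the conformer (arithmetic-mean convention by default, to
#' match the calibration against the known ~3.5 A mean H_W-H_MN
#' distance), converts it to a volume with the r^-6 law scaled so the
#' reference pair has volume exactly 1 before noise, drops pairs beyond
#' the NOE detection limit, and applies mean-one multiplicative lognormal
#' noise with coefficient of variation `cv`.
#'
#' For a conformer ensemble (list), volumes are proportional to the
#' ensemble mean of d^-6, i.e. effective distances pool as
#' `(mean d^-6)^(-1/6)`.
#'
#' @param conformer An `lq_conformer` or a list of them (ensemble).
#' @param reference_pair Character length-2 group labels (default
#'   `c("H_W", "H_MN")`).
#' @param cv Multiplicative noise coefficient of variation (>= 0).
#' @param seed Integer seed (required when `cv > 0`).
#' @param detection_limit NOE detection range in Angstrom (default 5).
#' @param pairs Optional 2-column matrix/data frame of group pairs to
#'   monitor; default all unordered proton-group pairs of the topology.
#' @param mode Distance convention passed to [group_distance()].
#' @param spectrum,environment Metadata columns for the emitted table.
#' @return Data frame with columns `group_a`, `group_b`, `volume`,
#'   `spectrum`, `environment`, `overlap_flag`, plus attributes `truth`
#'   (per-pair true effective distance and noiseless volume, including
#'   suppressed pairs and a `detected` flag) and `reference_distance`.
#' @export
simulate_peak_table <- function(conformer, reference_pair = c("H_W", "H_MN"),
                                cv = 0, seed = NULL, detection_limit = 5.0,
                                pairs = NULL, mode = c("mean", "r6"),
                                spectrum = "NOESY",
                                environment = "synthetic") {
  mode <- match.arg(mode)
  ens <- if (inherits(conformer, "lq_conformer")) list(conformer) else
    conformer
  stopifnot(length(ens) >= 1L,
            all(vapply(ens, inherits, TRUE, "lq_conformer")))
  top <- ens[[1L]]$topology
  if (is.null(pairs)) {
    gn <- names(top$proton_groups)
    pairs <- t(utils::combn(gn, 2L))
  } else {
    pairs <- as.matrix(as.data.frame(pairs, stringsAsFactors = FALSE))
  }
  stopifnot(ncol(pairs) == 2L)
  if (cv < 0) stop("cv must be >= 0")
  if (cv > 0 && is.null(seed)) stop("a seed is required when cv > 0")

  eff <- vapply(seq_len(nrow(pairs)), function(k) {
    d <- vapply(ens, group_distance, 0, pairs[k, 1L], pairs[k, 2L],
                mode = mode)
    (mean(d^-6))^(-1 / 6)
  }, 0)
  key <- canonical_pair(pairs[, 1L], pairs[, 2L])
  refkey <- canonical_pair(reference_pair[1L], reference_pair[2L])
  iref <- match(refkey, key)
  if (is.na(iref)) {
    # reference pair is always monitored
    d <- vapply(ens, group_distance, 0, reference_pair[1L],
                reference_pair[2L], mode = mode)
    dref <- (mean(d^-6))^(-1 / 6)
  } else dref <- eff[iref]
  if (dref > detection_limit)
    stop("reference pair lies beyond the detection limit (",
         round(dref, 2), " A)")
  v0 <- (dref / eff)^6
  detected <- eff <= detection_limit
  truth <- data.frame(group_a = pairs[, 1L], group_b = pairs[, 2L],
                      distance = eff, volume = v0, detected = detected,
                      stringsAsFactors = FALSE)
  out <- truth[detected, c("group_a", "group_b", "volume")]
  if (cv > 0) {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    sdlog <- sqrt(log(1 + cv^2))
    out$volume <- out$volume *
      stats::rlnorm(nrow(out), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  out$spectrum <- spectrum
  out$environment <- environment
  out$overlap_flag <- FALSE
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  attr(out, "reference_distance") <- dref
  attr(out, "detection_limit") <- detection_limit
  out
}

#' Piecewise-phase Langmuir isotherm model
#'
#' Ground-truth generator model: an isotherm given by linear interpolation
#' between (area, pressure) knots ordered by decreasing area, with
#' pressure non-decreasing as area decreases and a terminal plateau at the
#' collapse pressure.
#'
#' @param area,pressure Numeric knot vectors (area in Angstrom^2 per
#'   molecule, strictly decreasing; pressure in mN/m, non-decreasing along
#'   compression).
#' @param collapse_pressure Ground-truth collapse pressure in mN/m (`NA`
#'   for models without a collapse plateau).
#' @param scatter_sd Replicate area scatter s.d. in Angstrom^2.
#' @return Object of class `isotherm_phase_model`.
#' @export
isotherm_phase_model <- function(area, pressure, collapse_pressure = NA,
                                 scatter_sd = 0) {
  stopifnot(length(area) == length(pressure), length(area) >= 2L,
            scatter_sd >= 0)
  if (any(diff(area) >= 0))
    stop("knot areas must be strictly decreasing (compression order)")
  if (any(diff(pressure) < 0))
    stop("knot pressures must be non-decreasing along compression")
  if (!is.na(collapse_pressure) &&
      abs(max(pressure) - collapse_pressure) > 1e-9)
    stop("collapse_pressure must equal the plateau (maximum) knot pressure")
  structure(list(area = area, pressure = pressure,
                 collapse_pressure = collapse_pressure,
                 scatter_sd = scatter_sd),
            class = "isotherm_phase_model")
}

#' Built-in phase models
#'
#' `uq2_phase_model()`: a UQ-2-like film with a low collapse plateau at
#' 21 mN/m.  `dppc_phase_model()`: a DPPC-like film with a gas/liquid
#' lift-off, a liquid-expanded/condensed transition and a high collapse at
#' 70 mN/m.
#'
#' @param scatter_sd Replicate area scatter s.d. in Angstrom^2.
#' @return An [isotherm_phase_model()].
#' @export
uq2_phase_model <- function(scatter_sd = 0) {
  isotherm_phase_model(area = c(130, 100, 70, 52, 28),
                       pressure = c(0, 2, 10, 21, 21),
                       collapse_pressure = 21, scatter_sd = scatter_sd)
}

#' @rdname uq2_phase_model
#' @export
dppc_phase_model <- function(scatter_sd = 0) {
  isotherm_phase_model(area = c(110, 95, 88, 75, 60, 48, 42, 40, 30),
                       pressure = c(0, 2, 5, 7, 12, 30, 55, 70, 70),
                       collapse_pressure = 70, scatter_sd = scatter_sd)
}

#' Simulate replicate compression isotherms
#'
#' Samples a phase model on a uniform decreasing area grid and adds
#' independent Gaussian scatter to the measured areas of each replicate.
#'
#' @param model An [isotherm_phase_model()].
#' @param n_replicates Number of replicate curves.
#' @param seed Integer seed.
#' @param n_points Grid points per curve (default 200).
#' @param gamma0,x,lipid,additive Metadata for the emitted curves.
#' @return List of [isotherm_curve()] objects with attribute `model`.
#' @export
simulate_isotherm <- function(model, n_replicates = 3, seed = 1,
                              n_points = 200, gamma0 = 72.8, x = 1,
                              lipid = "synthetic", additive = "none") {
  stopifnot(inherits(model, "isotherm_phase_model"), n_replicates >= 1L)
  agrid <- seq(max(model$area), min(model$area), length.out = n_points)
  p <- stats::approx(rev(model$area), rev(model$pressure), xout = agrid,
                     rule = 2)$y
  set.seed(as.integer(seed) %% .Machine$integer.max)
  out <- lapply(seq_len(n_replicates), function(r) {
    a <- agrid + stats::rnorm(n_points, 0, model$scatter_sd)
    isotherm_curve(area = a, pressure = p, gamma0 = gamma0, x = x,
                   lipid = lipid, additive = additive,
                   replicate = r)
  })
  attr(out, "model") <- model
  out
}

#' Simulate a reverse-micelle chemical-shift table with known location
#'
#' Generates per-proton chemical shifts in the organic endpoint, the
#' aqueous endpoint and a series of reverse-micelle environments, for a
#' probe residing in the organic bulk, at the interface or in the water
#' pool.  Interface probes show a small systematic offset from the organic
#' endpoint (as the printed UQ-2 vinyl-proton shifts do); organic-bulk
#' probes show pure jitter about the organic endpoint; aqueous probes sit
#' at the aqueous endpoint.
#'
#' @param location `"organic"`, `"interface"` or `"aqueous"` (truth).
#' @param base Data frame with columns `proton`, `organic`, `aqueous`
#'   (endpoint shifts in ppm); default the UQ-2 vinyl proton endpoints.
#' @param seed Integer seed.
#' @param jitter_sd Random per-entry jitter s.d. in ppm (default 0.003).
#' @param interface_offset Systematic interface offset magnitude in ppm
#'   (default 0.015), applied away from the aqueous endpoint.
#' @param rm_envs Reverse-micelle environment labels.
#' @return A [shift_table()] with attribute `true_location`.
#' @export
simulate_shift_table <- function(location = c("interface", "organic",
                                              "aqueous"),
                                 base = NULL, seed = 1, jitter_sd = 0.003,
                                 interface_offset = 0.015,
                                 rm_envs = paste0("w0-", c(4, 8, 12, 16, 20))) {
  location <- match.arg(location)
  if (is.null(base))
    base <- data.frame(proton = c("H_A", "H_B"),
                       organic = c(5.02, 4.93),
                       aqueous = c(4.93, 4.86))
  stopifnot(all(c("proton", "organic", "aqueous") %in% names(base)))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  rows <- list()
  for (i in seq_len(nrow(base))) {
    p <- base$proton[i]
    org <- base$organic[i]; aq <- base$aqueous[i]
    rows[[length(rows) + 1L]] <- data.frame(
      proton = p, environment = c("organic", "aqueous"),
      delta_ppm = c(org, aq), stringsAsFactors = FALSE)
    centre <- switch(location,
      organic = org,
      aqueous = aq,
      interface = org + interface_offset * sign(org - aq))
    rows[[length(rows) + 1L]] <- data.frame(
      proton = p, environment = rm_envs,
      delta_ppm = centre + stats::rnorm(length(rm_envs), 0, jitter_sd),
      stringsAsFactors = FALSE)
  }
  tab <- shift_table(do.call(rbind, rows))
  attr(tab, "true_location") <- location
  tab
}
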