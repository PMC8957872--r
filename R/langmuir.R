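# Langmuir compression isotherm workup: surface pressure, replicate
# averaging with SD checkpoints every 5 mN/m, per-phospholipid area
# normalization, compression modulus, second-derivative collapse detection
# and the physiological-window area-expansion metric.

#' Compression isotherm curve
#'
#' A single compression isotherm: area per molecule (Angstrom^2) versus
#' surface pressure (mN/m), with film metadata.  Either `pressure` or the
#' raw surface tension series `gamma` must be supplied; tension is
#' converted with [surface_pressure()].
#'
#' @param area Numeric, area per molecule in Angstrom^2.
#' @param pressure Numeric, surface pressure in mN/m.
#' @param gamma Optional raw surface tension series (mN/m).
#' @param gamma0 Subphase surface tension in mN/m (default 72.8, aqueous
#'   buffer).
#' @param x Phospholipid mole fraction of the film, in (0, 1].
#' @param lipid,additive Film composition labels.
#' @param replicate Replicate identifier.
#' @return Object of class `isotherm_curve`.
#' @export
isotherm_curve <- function(area, pressure = NULL, gamma = NULL,
                           gamma0 = 72.8, x = 1, lipid = "",
                           additive = "", replicate = 1L) {
  if (is.null(pressure)) {
    if (is.null(gamma)) stop("supply pressure or gamma")
    pressure <- surface_pressure(gamma0, gamma)
  }
  stopifnot(length(area) == length(pressure))
  if (!(x > 0 && x <= 1)) stop("mole fraction x must be in (0, 1]")
  structure(list(area = as.numeric(area), pressure = as.numeric(pressure),
                 gamma0 = gamma0, x = x, lipid = lipid,
                 additive = additive, replicate = replicate),
            class = "isotherm_curve")
}

#' @export
print.isotherm_curve <- function(x, ...) {
  cat(sprintf(
    "isotherm: %d points, pi %.1f-%.1f mN/m, A %.1f-%.1f A^2/molecule",
    length(x$area), min(x$pressure), max(x$pressure), min(x$area),
    max(x$area)))
  if (nzchar(x$lipid)) cat(sprintf(" [%s", x$lipid))
  if (nzchar(x$additive) && x$additive != "none")
    cat(sprintf(" + %s, x = %g", x$additive, x$x))
  if (nzchar(x$lipid)) cat("]")
  cat("\n")
  invisible(x)
}

#' Surface pressure from surface tension
#'
#' pi = gamma0 - gamma.  Negative pressures are physically suspicious
#' (tension above the clean subphase) and raise a warning but are
#' returned.
#'
#' @param gamma0 Clean subphase surface tension (mN/m; 72.8 for the
#'   aqueous buffer used here).
#' @param gamma Surface tension after film deposition (mN/m), vectorized.
#' @return Surface pressure in mN/m.
#' @export
surface_pressure <- function(gamma0, gamma) {
  stopifnot(is.finite(gamma0), all(is.finite(gamma)))
  p <- gamma0 - gamma
  if (any(p < 0))
    warning("negative surface pressure (gamma > gamma0) in ",
            sum(p < 0), " point(s)", call. = FALSE)
  p
}

#' Normalize area per molecule to the phospholipid content
#'
#' A_N = A / x: the mixed-film area expressed per phospholipid molecule,
#' so that a mixed isotherm can be compared with the pure-lipid control.
#'
#' @param area Area per molecule (Angstrom^2), vectorized.
#' @param x Phospholipid mole fraction in (0, 1].
#' @return Normalized area per phospholipid (Angstrom^2).
#' @export
normalize_area <- function(area, x) {
  if (!(length(x) == 1L && is.finite(x) && x > 0 && x <= 1))
    stop("mole fraction x must be a single value in (0, 1]")
  area / x
}

# compression branch as a function of pressure: sort by increasing
# pressure, keep the last-visited (smallest) area at duplicated pressures
compression_branch <- function(curve) {
  o <- order(curve$pressure, -seq_along(curve$pressure))
  p <- curve$pressure[o]; a <- curve$area[o]
  keep <- !duplicated(p)   # within ties the last-visited point comes first
  list(pressure = p[keep], area = a[keep])
}

#' Average replicate isotherms with SD checkpoints every 5 mN/m
#'
#' Interpolates the area of each replicate onto a common pressure grid,
#' averages, and reports the sample standard deviation of the area at the
#' 0, 5, 10, ... mN/m checkpoints (the convention for reporting isotherm
#' error bars).  With a single replicate the SDs are `NA`.
#'
#' @param curves List of [isotherm_curve()] replicates.
#' @param grid_step Pressure grid step in mN/m (default 0.25).
#' @param sd_every Checkpoint spacing in mN/m (default 5).
#' @return Object of class `isotherm_mean`: an averaged `isotherm_curve`
#'   in `curve`, plus `sd_checkpoints` (data frame `pressure`, `mean_area`,
#'   `sd_area`, `n`) and `n_replicates`.
#' @export
average_replicates <- function(curves, grid_step = 0.25, sd_every = 5) {
  if (inherits(curves, "isotherm_curve")) curves <- list(curves)
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, TRUE, "isotherm_curve")))
  br <- lapply(curves, compression_branch)
  lo <- max(vapply(br, function(b) min(b$pressure), 0))
  hi <- min(vapply(br, function(b) max(b$pressure), 0))
  if (lo >= hi) stop("replicates have disjoint pressure ranges")
  grid <- seq(ceiling(lo / grid_step) * grid_step, hi, by = grid_step)
  A <- vapply(br, function(b)
    stats::approx(b$pressure, b$area, xout = grid)$y, numeric(length(grid)))
  A <- matrix(A, nrow = length(grid))
  mean_a <- rowMeans(A)
  cps <- seq(0, ceiling(hi / sd_every) * sd_every, by = sd_every)
  cps <- cps[cps >= lo & cps <= hi]
  cp_a <- vapply(br, function(b)
    stats::approx(b$pressure, b$area, xout = cps)$y, numeric(length(cps)))
  cp_a <- matrix(cp_a, nrow = length(cps))
  sds <- if (length(curves) > 1L) apply(cp_a, 1L, stats::sd) else
    rep(NA_real_, length(cps))
  proto <- curves[[1L]]
  structure(list(
    curve = isotherm_curve(area = mean_a, pressure = grid,
                           gamma0 = proto$gamma0, x = proto$x,
                           lipid = proto$lipid, additive = proto$additive,
                           replicate = "mean"),
    sd_checkpoints = data.frame(pressure = cps,
                                mean_area = rowMeans(cp_a),
                                sd_area = sds, n = length(curves)),
    n_replicates = length(curves)),
    class = "isotherm_mean")
}

#' @export
print.isotherm_mean <- function(x, ...) {
  cat(sprintf("mean of %d replicate isotherm(s); SD checkpoints:\n",
              x$n_replicates))
  print(x$sd_checkpoints, ...)
  invisible(x)
}

# Savitzky-Golay smoothed derivative of y on a uniform grid
sg_deriv <- function(y, order, window, step, deriv) {
  if (length(y) < window)
    stop("curve too short for the smoothing window (need >= ", window,
         " grid points)")
  signal::sgolayfilt(y, p = order, n = window, m = deriv, ts = step)
}

#' Compression modulus Cs^-1 = -A (dpi/dA)
#'
#' Differentiates the smoothed compression branch on a uniform pressure
#' grid.  High values indicate a condensed, stiff film; mixing in a soft
#' component lowers the maximum modulus ("more elastic").
#'
#' @param curve An [isotherm_curve()] (or `isotherm_mean`).
#' @param grid_step Pressure grid step in mN/m (default 0.25).
#' @param sg_window Odd Savitzky-Golay window length in grid points
#'   (default 11); polynomial order 2.
#' @return Object of class `modulus_curve`: data frame `pressure`,
#'   `modulus` (mN/m) over the interior grid.
#' @export
compression_modulus <- function(curve, grid_step = 0.25, sg_window = 11) {
  if (inherits(curve, "isotherm_mean")) curve <- curve$curve
  b <- compression_branch(curve)
  if (length(b$pressure) < 3L) stop("need at least 3 points")
  grid <- seq(min(b$pressure), max(b$pressure), by = grid_step)
  a <- stats::approx(b$pressure, b$area, xout = grid)$y
  dAdp <- sg_deriv(a, 2, min(sg_window, odd_below(length(a))), grid_step, 1)
  asm <- sg_deriv(a, 2, min(sg_window, odd_below(length(a))), grid_step, 0)
  # Cs^-1 = -A dpi/dA = -A / (dA/dpi)
  mod <- -asm / dAdp
  structure(data.frame(pressure = grid, modulus = mod),
            class = c("modulus_curve", "data.frame"))
}

odd_below <- function(n) if (n %% 2L == 0L) n - 1L else n

#' Collapse pressure by the second-derivative criterion
#'
#' Resamples the compression branch A(pi) on a uniform pressure grid,
#' smooths with a local polynomial (Savitzky-Golay, order 2) and locates
#' the minimum of d^2 A / d pi^2: the sharp downward bend where the film
#' buckles or ejects material.  The minimum must be an interior grid point
#' and exceed `min_curvature` in magnitude, otherwise no collapse is
#' reported (e.g. for a featureless straight line).
#'
#' @param curve An [isotherm_curve()] or `isotherm_mean`.
#' @param grid_step Pressure grid step in mN/m (default 0.25).
#' @param sg_window Odd smoothing window in grid points (default 11).
#' @param min_curvature Detection threshold on |d^2A/dpi^2|
#'   (Angstrom^2 (mN/m)^-2, default 1).
#' @return Object of class `collapse_result`: `collapse_pressure` (mN/m,
#'   `NA` when none detected), `curvature` (value at the minimum),
#'   `detected`, and the diagnostics `grid_step`, `sg_window`,
#'   `min_curvature`.
#' @export
collapse_pressure <- function(curve, grid_step = 0.25, sg_window = 11,
                              min_curvature = 1.0) {
  if (inherits(curve, "isotherm_mean")) curve <- curve$curve
  b <- compression_branch(curve)
  grid <- seq(min(b$pressure), max(b$pressure), by = grid_step)
  a <- stats::approx(b$pressure, b$area, xout = grid)$y
  win <- min(sg_window, odd_below(length(a)))
  d2 <- sg_deriv(a, 2, win, grid_step, 2)
  # exclude the low-pressure edge (lift-off artifacts); the high-pressure
  # edge stays eligible because a collapse plateau caps the pressure range
  interior <- seq_along(grid) > win %/% 2L
  d2i <- ifelse(interior, d2, Inf)
  imin <- which.min(d2i)
  detected <- is.finite(d2i[imin]) && d2i[imin] < -min_curvature
  structure(list(
    collapse_pressure = if (detected) grid[imin] else NA_real_,
    curvature = d2[imin], detected = detected,
    grid_step = grid_step, sg_window = win,
    min_curvature = min_curvature),
    class = "collapse_result")
}

#' @export
print.collapse_result <- function(x, ...) {
  if (x$detected)
    cat(sprintf(
      "collapse pressure: %.2f mN/m (d2A/dpi2 = %.2f, grid %.2g mN/m)\n",
      x$collapse_pressure, x$curvature, x$grid_step))
  else cat("no collapse detected\n")
  invisible(x)
}

#' Area expansion of a mixed film over a pressure window
#'
#' Percent increase of the phospholipid-normalized mixed-film area over
#' the pure-film area, averaged over a surface-pressure window (default
#' the physiological 30-35 mN/m).  A positive expansion with
#' non-overlapping error bands indicates the additive resides in the
#' interface and spreads the phospholipids apart.
#'
#' @param mixed,pure [isotherm_curve()] or `isotherm_mean` objects for the
#'   mixed film and the pure-phospholipid control.
#' @param x Phospholipid mole fraction of the mixed film; default taken
#'   from the mixed curve.
#' @param window Pressure window in mN/m (default `c(30, 35)`).
#' @param grid_step Evaluation grid step (default 0.25 mN/m).
#' @return Percent area expansion (single number).
#' @export
area_expansion <- function(mixed, pure, x = NULL, window = c(30, 35),
                           grid_step = 0.25) {
  if (inherits(mixed, "isotherm_mean")) mixed <- mixed$curve
  if (inherits(pure, "isotherm_mean")) pure <- pure$curve
  if (is.null(x)) x <- mixed$x
  bm <- compression_branch(mixed)
  bp <- compression_branch(pure)
  if (window[1L] < max(min(bm$pressure), min(bp$pressure)) ||
      window[2L] > min(max(bm$pressure), max(bp$pressure)))
    stop("pressure window outside the data range of the curves")
  grid <- seq(window[1L], window[2L], by = grid_step)
  am <- normalize_area(stats::approx(bm$pressure, bm$area, xout = grid)$y, x)
  ap <- stats::approx(bp$pressure, bp$area, xout = grid)$y
  100 * (mean(am) - mean(ap)) / mean(ap)
}

#' Band-overlap decision between a mixed film and its control
#'
#' Declares the normalized mixed curve *separated* from the pure control
#' when the mean +/- 1 SD area bands are disjoint at every 5 mN/m SD
#' checkpoint inside the window; *overlapping* otherwise.  This formalizes
#' the visual error-bar comparison used for deciding whether an additive
#' is compressed out of the film.
#'
#' @param mixed,pure `isotherm_mean` objects (with SD checkpoints).
#' @param x Phospholipid mole fraction of the mixed film (default from
#'   the curve metadata).
#' @param window Pressure window in mN/m (default `c(30, 35)`).
#' @return `"separated"` or `"overlapping"` with attribute `checkpoints`.
#' @export
overlap_flag <- function(mixed, pure, x = NULL, window = c(30, 35)) {
  stopifnot(inherits(mixed, "isotherm_mean"), inherits(pure, "isotherm_mean"))
  if (is.null(x)) x <- mixed$curve$x
  cm <- mixed$sd_checkpoints
  cp <- pure$sd_checkpoints
  cps <- intersect(cm$pressure, cp$pressure)
  cps <- cps[cps >= window[1L] & cps <= window[2L]]
  if (!length(cps)) {
    # no 5 mN/m checkpoint falls inside the window: use its endpoints
    cps <- intersect(cm$pressure, cp$pressure)
    cps <- cps[cps >= window[1L] - 2.5 & cps <= window[2L] + 2.5]
    if (!length(cps)) stop("no SD checkpoints near the window")
  }
  im <- match(cps, cm$pressure); ip <- match(cps, cp$pressure)
  if (anyNA(cm$sd_area[im]) || anyNA(cp$sd_area[ip]))
    stop("SD bands unavailable (single replicate?)")
  lo_m <- (cm$mean_area[im] - cm$sd_area[im]) / x
  hi_m <- (cm$mean_area[im] + cm$sd_area[im]) / x
  lo_p <- cp$mean_area[ip] - cp$sd_area[ip]
  hi_p <- cp$mean_area[ip] + cp$sd_area[ip]
  disjoint <- hi_m < lo_p | hi_p < lo_m
  out <- if (all(disjoint)) "separated" else "overlapping"
  attr(out, "checkpoints") <- data.frame(pressure = cps,
                                         disjoint = disjoint)
  out
}
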