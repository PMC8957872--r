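# Preparative arithmetic: molar mass from a formula, molarity, dilution,
# the reverse-micelle water/surfactant ratio w0, pD correction, reaction
# yield and micelle occupancy.

# IUPAC 2021 standard atomic weights (abridged), D = 2H
.ATOMIC_MASS <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, P = 30.974, S = 32.06, Cl = 35.45, K = 39.098,
  Ca = 40.078, Fe = 55.845, Br = 79.904, I = 126.904, B = 10.81,
  Si = 28.085, Ti = 47.867)

#' Molar mass from a molecular formula
#'
#' Parses element-count formulas such as `"C19H26O4"` or `"D2O"`
#' (deuterium recognized as `D`) and sums standard atomic weights.
#'
#' @param formula Formula string (no parentheses or charges).
#' @return Molar mass in g/mol.
#' @examples
#' molar_mass("C19H26O4")  # UQ-2, 318.41
#' molar_mass("D2O")       # 20.03
#' @export
molar_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1L]]
  toks <- regmatches(formula, list(m))[[1L]]
  if (!length(toks) || sum(nchar(toks)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  total <- 0
  for (t in toks) {
    el <- sub("[0-9]*$", "", t)
    k <- sub("^[A-Za-z]+", "", t)
    k <- if (nzchar(k)) as.integer(k) else 1L
    if (!el %in% names(.ATOMIC_MASS))
      stop("unknown element symbol: ", el)
    total <- total + .ATOMIC_MASS[[el]] * k
  }
  total
}

#' Molar concentration of a dissolved mass
#'
#' @param mass_mg Solute mass in mg.
#' @param mw Molar mass in g/mol (or a formula string).
#' @param volume_ml Solution volume in ml.
#' @return Concentration in mM.
#' @examples
#' molarity(45.4, "C19H26O4", 10.0)  # 14.3 mM UQ-2 stock
#' @export
molarity <- function(mass_mg, mw, volume_ml) {
  if (is.character(mw)) mw <- molar_mass(mw)
  stopifnot(mass_mg >= 0, mw > 0)
  if (!(volume_ml > 0)) stop("volume must be positive")
  (mass_mg / mw) / (volume_ml / 1000)
}

#' Concentration after dilution
#'
#' @param conc Stock concentration (any unit; returned in the same unit).
#' @param v Stock volume taken (same unit as `v_total`).
#' @param v_total Final total volume.
#' @return Diluted concentration.
#' @examples
#' dilute(112, 893, 1000)  # ~100 mM UQ-2 in the w0 = 12 RM sample
#' @export
dilute <- function(conc, v, v_total) {
  if (!(v_total > 0)) stop("total volume must be positive")
  if (v > v_total) stop("aliquot volume exceeds total volume")
  if (v < 0) stop("negative volume")
  conc * v / v_total
}

#' Reverse-micelle water-to-surfactant molar ratio w0
#'
#' w0 = [water] / [surfactant] computed from the pipetted water volume and
#' the surfactant solution.
#'
#' @param water_ul Water volume in microliters.
#' @param density Water density in g/ml (1.107 for D2O at room
#'   temperature).
#' @param water_mw Water molar mass in g/mol (or formula; 20.03 for D2O).
#' @param surf_conc_M Surfactant concentration in mol/l.
#' @param surf_volume_ml Surfactant solution volume in ml.
#' @return Dimensionless w0.
#' @examples
#' w0_ratio(107, 1.107, "D2O", 0.50, 0.893)  # ~13.2 (nominal label: 12)
#' @export
w0_ratio <- function(water_ul, density, water_mw, surf_conc_M,
                     surf_volume_ml) {
  if (is.character(water_mw)) water_mw <- molar_mass(water_mw)
  stopifnot(water_ul >= 0, density > 0, water_mw > 0)
  if (!(surf_conc_M > 0 && surf_volume_ml > 0))
    stop("surfactant amount must be positive")
  mmol_water <- water_ul * density / 1000 / water_mw * 1000
  mmol_surf <- surf_conc_M * surf_volume_ml
  mmol_water / mmol_surf
}

#' pD from a pH-meter reading in D2O
#'
#' pD = meter pH + 0.4 (the standard glass-electrode correction in
#' deuterium oxide).
#'
#' @param meter_ph Meter reading.
#' @return pD.
#' @export
pD_correction <- function(meter_ph) {
  stopifnot(is.finite(meter_ph))
  meter_ph + 0.4
}

#' Percent reaction yield
#'
#' @param product_mmol Product amount (mmol).
#' @param limiting_mmol Limiting reagent amount (mmol).
#' @return Percent yield (full precision; round at the reporting layer).
#' @examples
#' percent_yield(54.2, 54.7)  # 99.1
#' @export
percent_yield <- function(product_mmol, limiting_mmol) {
  if (!(limiting_mmol > 0)) stop("limiting amount must be positive")
  if (product_mmol < 0) stop("negative product amount")
  100 * product_mmol / limiting_mmol
}

#' Average number of solute molecules per reverse micelle
#'
#' solute / (surfactant / N_agg): the mean occupancy given the surfactant
#' aggregation number N_agg (not fixed here; it depends on w0 and must be
#' supplied).
#'
#' @param solute_mM Solute concentration (mM).
#' @param surfactant_mM Surfactant concentration (mM).
#' @param n_agg Aggregation number (surfactant molecules per micelle).
#' @return Mean molecules per micelle.
#' @export
molecules_per_micelle <- function(solute_mM, surfactant_mM, n_agg) {
  if (!(surfactant_mM > 0)) stop("surfactant concentration must be positive")
  stopifnot(solute_mM >= 0, n_agg > 0)
  solute_mM / (surfactant_mM / n_agg)
}
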