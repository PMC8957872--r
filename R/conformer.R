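# Conformer construction and measurement: internal-coordinate embedding,
# torsion/dihedral readout, proton-group distances and the conformation
# taxonomy (flat-extended / folded-extended / U-shaped).

#' Embed a topology into Cartesian coordinates
#'
#' Converts the ideal internal coordinates of a topology into 3D Cartesian
#' coordinates, realizing a requested set of named torsion values exactly
#' while keeping all bond lengths and angles at their ideal values.
#'
#' @param topology An [`lq_topology`][build_topology()].
#' @param torsions Named numeric vector or list of torsion values in degrees
#'   (see `topology$torsions` for names and defaults).  Unnamed torsions
#'   keep their defaults.
#' @return An object of class `lq_conformer`: list with `topology`, `coords`
#'   (n x 3 matrix, rownames = atom labels) and the full `torsions` vector.
#' @export
embed_conformer <- function(topology, torsions = NULL) {
  stopifnot(inherits(topology, "lq_topology"))
  tv <- topology$torsions
  if (!is.null(torsions)) {
    torsions <- unlist(torsions)
    bad <- setdiff(names(torsions), names(tv))
    if (length(bad))
      stop("unknown torsion(s): ", paste(bad, collapse = ", "))
    if (is.null(names(torsions)) || any(names(torsions) == ""))
      stop("torsions must be a fully named vector")
    tv[names(torsions)] <- torsions
  }
  z <- topology$zmat
  phi <- z$phi0
  has_t <- !is.na(z$torsion)
  phi[has_t] <- phi[has_t] + tv[z$torsion[has_t]]
  X <- nerf_embed_cpp(z$ref1, z$ref2, z$ref3, z$r, z$theta, phi)
  rownames(X) <- z$label
  structure(list(topology = topology, coords = X, torsions = tv),
            class = "lq_conformer")
}

#' @export
print.lq_conformer <- function(x, ...) {
  cat(sprintf("%s-%d conformer: %d atoms", x$topology$headgroup,
              x$topology$n_units, nrow(x$coords)))
  if (!is.null(x$topology$phi_atoms))
    cat(sprintf(", phi = %.1f deg", measure_phi(x)))
  cat("\n")
  invisible(x)
}

#' Measure a named torsion of a conformer
#'
#' @param conformer An `lq_conformer`.
#' @param name Torsion name (see `topology$torsions`).
#' @return Signed dihedral in degrees in (-180, 180].
#' @export
measure_torsion <- function(conformer, name) {
  top <- conformer$topology
  q <- top$torsion_atoms[[name]]
  if (is.null(q)) stop("unknown torsion: ", name)
  X <- conformer$coords
  dihedral_angle(X[q[1L], ], X[q[2L], ], X[q[3L], ], X[q[4L], ])
}

#' Measure the headgroup-chain dihedral phi
#'
#' The dihedral about the C2-C3-Cbeta-Cgamma bond: ring methyl carbon (C2),
#' ring carbon bearing the side chain (C3), first chain carbon (Cbeta) and
#' second chain carbon (Cgamma).  A value near +/-90 degrees defines a
#' folded conformer.
#'
#' @param conformer An `lq_conformer` with at least one isoprene unit.
#' @return Dihedral in degrees in (-180, 180].
#' @export
measure_phi <- function(conformer) {
  pa <- conformer$topology$phi_atoms
  if (is.null(pa)) stop("phi is undefined for a side-chain-free topology")
  X <- conformer$coords
  dihedral_angle(X[pa[1L], ], X[pa[2L], ], X[pa[3L], ], X[pa[4L], ])
}

group_indices <- function(top, group) {
  mem <- top$proton_groups[[group]]
  if (is.null(mem)) {
    # allow a raw atom label as a singleton group
    if (group %in% top$atoms$label) mem <- group
    else stop("unknown proton group: ", group)
  }
  unname(top$lab2id[mem])
}

#' Inter-group proton distance
#'
#' Distance between two proton groups, either the arithmetic mean over all
#' member proton pairs (`mode = "mean"`) or the NOE-effective r^-6 average
#' `<r^-6>^(-1/6)` (`mode = "r6"`).  By the power-mean inequality the r6
#' value never exceeds the mean value.
#'
#' @param conformer An `lq_conformer`.
#' @param group_a,group_b Proton-group names (or single atom labels); the
#'   groups must be disjoint.
#' @param mode `"mean"` or `"r6"`.
#' @return Distance in Angstrom.
#' @export
group_distance <- function(conformer, group_a, group_b,
                           mode = c("mean", "r6")) {
  mode <- match.arg(mode)
  top <- conformer$topology
  ia <- group_indices(top, group_a)
  ib <- group_indices(top, group_b)
  if (length(intersect(ia, ib)))
    stop("proton groups overlap: ", group_a, ", ", group_b)
  X <- conformer$coords
  if (mode == "r6") return(group_r6_cpp(X, ia, ib))
  d <- outer(ia, ib, function(i, j)
    sqrt((X[i, 1] - X[j, 1])^2 + (X[i, 2] - X[j, 2])^2 +
           (X[i, 3] - X[j, 3])^2))
  mean(d)
}

#' Rotor-ensemble averaged group distance
#'
#' Averages a group distance over a uniform grid of one or more named
#' torsions (typically methyl rotors and/or the phi torsion), holding all
#' other torsions fixed.  Used for ensemble-average reference distances
#' such as the H_W to H_MN calibration distance.
#'
#' @param topology An `lq_topology`.
#' @param group_a,group_b Proton-group names.
#' @param vary Character vector of torsion names to scan.
#' @param torsions Base torsion values (as in [embed_conformer()]).
#' @param grid_step Grid step in degrees (default 30).
#' @param mode `"mean"` or `"r6"` (see [group_distance()]); the grid average
#'   is the arithmetic mean of per-state values for `"mean"` and the r^-6
#'   pooled average for `"r6"`.
#' @return Ensemble-average distance in Angstrom.
#' @export
ensemble_group_distance <- function(topology, group_a, group_b, vary,
                                    torsions = NULL, grid_step = 30,
                                    mode = c("mean", "r6")) {
  mode <- match.arg(mode)
  stopifnot(length(vary) >= 1L, all(vary %in% names(topology$torsions)))
  angles <- seq(0, 360 - grid_step, by = grid_step)
  grids <- rev(expand.grid(rep(list(angles), length(vary))))
  names(grids) <- vary
  vals <- vapply(seq_len(nrow(grids)), function(k) {
    tv <- as.list(torsions)
    tv[vary] <- as.list(grids[k, , drop = FALSE])
    conf <- embed_conformer(topology, unlist(tv))
    group_distance(conf, group_a, group_b, mode = mode)
  }, 0)
  if (mode == "r6") (mean(vals^-6))^(-1 / 6) else mean(vals)
}

#' Classify a conformer as flat-extended, folded-extended or U-shaped
#'
#' A conformer is *folded* when the absolute headgroup-chain dihedral
#' |phi| lies in a window about 90 degrees (default 90 +/- 30).  Among
#' folded conformers it is *U-shaped* when at least one terminal methyl
#' group (H_Y or H_Z) sits within `d_u` of the ring methyl H_W (mean
#' inter-proton distance, i.e. the terminal methyls are back over the
#' headgroup), and *folded-extended* otherwise.  Everything non-folded is
#' *flat-extended*.
#'
#' @param conformer An `lq_conformer`.
#' @param folded_window Numeric length-2, inclusive |phi| window in degrees
#'   for "folded" (default `c(60, 120)`).
#' @param d_u U-shape cutoff in Angstrom on the smaller of the mean
#'   H_W-H_Y / H_W-H_Z distances (default 6).
#' @return Object of class `lq_conformation`: list with `label` (one of
#'   `"flat-extended"`, `"folded-extended"`, `"U-shaped"`), `phi` and
#'   `terminal_distances`.
#' @export
classify_conformation <- function(conformer, folded_window = c(60, 120),
                                  d_u = 6.0) {
  phi <- measure_phi(conformer)
  top <- conformer$topology
  term <- intersect(c("H_Y", "H_Z"), names(top$proton_groups))
  dists <- vapply(term, function(gr)
    group_distance(conformer, "H_W", gr, mode = "mean"), 0)
  folded <- abs(phi) >= folded_window[1L] & abs(phi) <= folded_window[2L]
  label <- if (!folded) {
    "flat-extended"
  } else if (length(dists) && min(dists) <= d_u) {
    "U-shaped"
  } else {
    "folded-extended"
  }
  structure(list(label = label, phi = phi, terminal_distances = dists,
                 folded_window = folded_window, d_u = d_u),
            class = "lq_conformation")
}

#' @export
print.lq_conformation <- function(x, ...) {
  cat(sprintf("conformation: %s (phi = %.1f deg", x$label, x$phi))
  if (length(x$terminal_distances))
    cat(sprintf(", min terminal methyl-H_W distance %.2f A",
                min(x$terminal_distances)))
  cat(")\n")
  invisible(x)
}

#' Reference conformers for the three conformation families
#'
#' Returns a canonical conformer for each family of the taxonomy, defined
#' by fixed torsion assignments of the UQ-2 (default) topology:
#' `"flat-extended"` (phi = 180, side chain all-anti), `"folded-extended"`
#' (phi = 90, chain extended away from the ring so that the terminal
#' methyls sit beside, not over, the headgroup at a mean H_W-H_Y distance
#' of about 5.1 A) and `"U-shaped"` (phi = 90 with the chain curled back
#' so the terminal methyls lie over the quinone ring).
#'
#' @param label One of `"flat-extended"`, `"folded-extended"`, `"U-shaped"`.
#' @param topology Optional topology (default `build_topology("UQ", 2)`).
#' @return An `lq_conformer`.
#' @export
reference_conformer <- function(label = c("U-shaped", "folded-extended",
                                          "flat-extended"),
                                topology = NULL) {
  label <- match.arg(label)
  if (is.null(topology)) topology <- build_topology("UQ", 2)
  tors <- reference_torsions(label, topology$n_units)
  embed_conformer(topology, tors)
}

reference_torsions <- function(label, n_units = 2) {
  if (n_units != 2)
    stop("reference torsion sets are defined for 2 isoprene units")
  switch(label,
    "flat-extended" = c(phi = 180, chi_1 = 180, tauA_1 = 180, tauB_1 = 180,
                        chi_2 = 180),
    "folded-extended" = c(phi = 90, chi_1 = 90, tauA_1 = 90, tauB_1 = -30,
                          chi_2 = 150),
    "U-shaped" = c(phi = 90, chi_1 = -90, tauA_1 = -150, tauB_1 = -60,
                   chi_2 = 120),
    stop("unknown reference label"))
}
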