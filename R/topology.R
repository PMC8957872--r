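# Idealized molecular topologies for truncated lipoquinones (UQ-n, MK-n).
#
# Geometry is deliberately idealized: fixed standard bond lengths and angles
# (quinonoid/aromatic rings regular, sp3 109.5 deg, sp2 120 deg), E-configured
# chain double bonds, and all conformational freedom expressed through named
# rotatable torsions.  Sub-0.1 A bond-length fidelity is immaterial for NOE
# distance bins that are 1 A wide.

# standard ideal internal coordinates (Angstrom, degrees)
.LQ_GEOM <- list(
  ring    = 1.40,  # aromatic / quinonoid C-C
  c_o_dbl = 1.22,  # C=O
  car_c   = 1.50,  # ring C - sp3 C
  car_o   = 1.36,  # ring C - O (ether)
  o_ch3   = 1.43,  # O - CH3
  c_c     = 1.53,  # sp3 C - sp3 C
  c_csp2  = 1.51,  # sp3 C - sp2 C
  c_c_dbl = 1.34,  # C=C
  c_h     = 1.09,  # C-H
  tet     = 109.47122,
  tri     = 120,
  come    = 117    # C-O-CH3
)

#' Build an idealized lipoquinone topology
#'
#' Constructs the atom list, bond graph, internal-coordinate table, named
#' rotatable torsions and proton-group map for a truncated lipoquinone with
#' a ubiquinone (`"UQ"`, 2,3-dimethoxy-5-methyl-1,4-benzoquinone head) or
#' menaquinone (`"MK"`, 2-methyl-1,4-naphthoquinone head) headgroup and
#' `n_units` isoprene repeats.
#'
#' Proton groups follow the lipoquinone labelling convention: `H_W` is the
#' quinone ring methyl, `H_J`/`H_K` the two methoxys (UQ only), `H_MN` the
#' benzylic/allylic methylene on the first chain carbon (C-beta), `H_B` and
#' `H_A` the first and last vinyl protons, `H_X` the first-unit vinyl
#' methyl, `H_QR` the internal CH2-CH2 protons, and `H_Y`/`H_Z` the two
#' terminal methyls (`H_Y` = chain-terminus methyl, `H_Z` = the gem methyl
#' on the last double-bond carbon).  Equivalent protons are treated as
#' single composite groups throughout the package.
#'
#' The dihedral phi about the C2-C3-Cbeta-Cgamma bond (ring methyl carbon,
#' ring chain carbon, first and second chain carbons) is the named torsion
#' `"phi"`.
#'
#' @param headgroup `"UQ"` or `"MK"`.
#' @param n_units Number of isoprene units (non-negative integer).
#' @return An object of class `lq_topology`.
#' @examples
#' top <- build_topology("UQ", 2)
#' molecular_formula(top)   # "C19H26O4"
#' @export
build_topology <- function(headgroup = c("UQ", "MK"), n_units = 2) {
  headgroup <- match.arg(headgroup)
  if (!is.numeric(n_units) || length(n_units) != 1L || n_units < 0 ||
      n_units != round(n_units))
    stop("n_units must be a non-negative integer")
  n_units <- as.integer(n_units)
  g <- .LQ_GEOM

  rows <- list()
  torsions <- numeric(0)
  extra_bonds <- list()
  add <- function(label, element, ref1 = NA, ref2 = NA, ref3 = NA,
                  r = NA, theta = NA, phi0 = 0, torsion = NA_character_) {
    rows[[length(rows) + 1L]] <<- list(
      label = label, element = element,
      ref1 = ref1, ref2 = ref2, ref3 = ref3,
      r = r, theta = theta, phi0 = phi0, torsion = torsion)
  }
  add_torsion <- function(name, default) torsions[name] <<- default
  add_methyl <- function(hprefix, parent, ref2, ref3, tname, default = 60) {
    if (!tname %in% names(torsions)) add_torsion(tname, default)
    for (k in 1:3)
      add(paste0(hprefix, k), "H", parent, ref2, ref3,
          g$c_h, g$tet, (k - 1) * 120, tname)
  }

  groups <- list()

  if (headgroup == "UQ") {
    add("C1", "C")
    add("C2", "C", "C1", r = g$ring)
    add("C3", "C", "C2", "C1", r = g$ring, theta = g$tri)
    add("C4", "C", "C3", "C2", "C1", g$ring, g$tri, 0)
    add("C5", "C", "C4", "C3", "C2", g$ring, g$tri, 0)
    add("C6", "C", "C5", "C4", "C3", g$ring, g$tri, 0)
    extra_bonds[[1L]] <- c("C6", "C1")
    add("O1", "O", "C1", "C2", "C3", g$c_o_dbl, g$tri, 180)
    add("O4", "O", "C4", "C3", "C2", g$c_o_dbl, g$tri, 180)
    add("CW", "C", "C2", "C1", "C6", g$car_c, g$tri, 180)
    add("O5", "O", "C5", "C4", "C3", g$car_o, g$tri, 180)
    add("O6", "O", "C6", "C5", "C4", g$car_o, g$tri, 180)
    add_torsion("ome_K", 75)
    add("CK", "C", "O5", "C5", "C4", g$o_ch3, g$come, 0, "ome_K")
    add_torsion("ome_J", -75)
    add("CJ", "C", "O6", "C6", "C5", g$o_ch3, g$come, 0, "ome_J")
    add_methyl("HW", "CW", "C2", "C1", "me_W")
    add_methyl("HK", "CK", "O5", "C5", "me_K")
    add_methyl("HJ", "CJ", "O6", "C6", "me_J")
    groups$H_W <- paste0("HW", 1:3)
    groups$H_K <- paste0("HK", 1:3)
    groups$H_J <- paste0("HJ", 1:3)
  } else {
    add("C1", "C")
    add("C2", "C", "C1", r = g$ring)
    add("C3", "C", "C2", "C1", r = g$ring, theta = g$tri)
    add("C4", "C", "C3", "C2", "C1", g$ring, g$tri, 0)
    add("C4a", "C", "C4", "C3", "C2", g$ring, g$tri, 0)
    add("C8a", "C", "C4a", "C4", "C3", g$ring, g$tri, 0)
    extra_bonds[[1L]] <- c("C8a", "C1")
    add("C5", "C", "C4a", "C4", "C3", g$ring, g$tri, 180)
    add("C6", "C", "C5", "C4a", "C8a", g$ring, g$tri, 0)
    add("C7", "C", "C6", "C5", "C4a", g$ring, g$tri, 0)
    add("C8", "C", "C7", "C6", "C5", g$ring, g$tri, 0)
    extra_bonds[[2L]] <- c("C8", "C8a")
    add("O1", "O", "C1", "C2", "C3", g$c_o_dbl, g$tri, 180)
    add("O4", "O", "C4", "C3", "C2", g$c_o_dbl, g$tri, 180)
    add("CW", "C", "C2", "C1", "C8a", g$car_c, g$tri, 180)
    add("H5", "H", "C5", "C4a", "C8a", g$c_h, g$tri, 180)
    add("H6", "H", "C6", "C5", "C4a", g$c_h, g$tri, 180)
    add("H7", "H", "C7", "C6", "C5", g$c_h, g$tri, 180)
    add("H8", "H", "C8", "C7", "C6", g$c_h, g$tri, 180)
    add_methyl("HW", "CW", "C2", "C1", "me_W")
    groups$H_W <- paste0("HW", 1:3)
    groups$H_aro <- c("H5", "H6", "H7", "H8")
  }

  if (n_units == 0L) {
    add("H3", "H", "C3", "C2", "C1", g$c_h, g$tri, 180)
  } else {
    qr_members <- character(0)
    for (i in seq_len(n_units)) {
      lab <- function(part) sprintf("S%d_%s", i, part)
      last <- i == n_units
      if (i == 1L) {
        c1 <- "CB"
        add(c1, "C", "C3", "C2", "C1", g$car_c, g$tri, 180)
        prev <- "C3"; prev2 <- "C2"
        add_torsion("phi", 90)
        tor_b <- "phi"
        add("HM", "H", c1, prev, prev2, g$c_h, g$tet, 120, tor_b)
        add("HN", "H", c1, prev, prev2, g$c_h, g$tet, -120, tor_b)
        groups$H_MN <- c("HM", "HN")
      } else {
        c1 <- lab("1")
        prev <- sprintf("S%d_4", i - 1L); prev2 <- sprintf("S%d_3", i - 1L)
        tor_b <- sprintf("tauB_%d", i - 1L)
        add_torsion(tor_b, 180)
        add(c1, "C", prev, prev2, sprintf("S%d_2", i - 1L),
            g$c_c, g$tet, 0, sprintf("tauA_%d", i - 1L))
        ha <- sprintf("HR%da", i - 1L); hb <- sprintf("HR%db", i - 1L)
        add(ha, "H", c1, prev, prev2, g$c_h, g$tet, 120, tor_b)
        add(hb, "H", c1, prev, prev2, g$c_h, g$tet, -120, tor_b)
        qr_members <- c(qr_members, ha, hb)
      }
      c2 <- lab("2"); c3 <- lab("3"); c3m <- lab("3M")
      add(c2, "C", c1, prev, prev2, g$c_csp2, g$tet, 0, tor_b)
      chi <- sprintf("chi_%d", i)
      add_torsion(chi, 180)
      hv <- if (last) "HA" else if (i == 1L) "HB" else sprintf("HV%d", i)
      add(c3, "C", c2, c1, prev, g$c_c_dbl, g$tri, 0, chi)
      add(hv, "H", c2, c1, prev, g$c_h, g$tri, 180, chi)
      groups[[if (last) "H_A" else if (i == 1L) "H_B" else
              sprintf("H_V%d", i)]] <- hv
      add(c3m, "C", c3, c2, c1, g$car_c, g$tri, 0)
      mg <- if (last) "Z" else if (i == 1L) "X" else sprintf("X%d", i)
      add_methyl(sprintf("H%s", mg), c3m, c3, c2, paste0("me_", mg))
      groups[[paste0("H_", mg)]] <- paste0("H", mg, 1:3)
      c4 <- lab("4")
      add(c4, "C", c3, c2, c1, g$c_csp2, g$tri, 180)
      if (last) {
        add_methyl("HY", c4, c3, c2, "me_Y")
        groups$H_Y <- paste0("HY", 1:3)
      } else {
        ta <- sprintf("tauA_%d", i)
        add_torsion(ta, 180)
        ha <- sprintf("HQ%da", i); hb <- sprintf("HQ%db", i)
        add(ha, "H", c4, c3, c2, g$c_h, g$tet, 120, ta)
        add(hb, "H", c4, c3, c2, g$c_h, g$tet, -120, ta)
        qr_members <- c(qr_members, ha, hb)
      }
    }
    if (length(qr_members)) groups$H_QR <- qr_members
  }

  df <- do.call(rbind, lapply(rows, function(x)
    data.frame(x, stringsAsFactors = FALSE)))
  lab2id <- seq_len(nrow(df)); names(lab2id) <- df$label
  if (anyDuplicated(df$label)) stop("internal error: duplicate atom labels")
  toid <- function(x) ifelse(is.na(x), 0L, unname(lab2id[x]))
  zmat <- data.frame(
    label = df$label, element = df$element,
    ref1 = toid(df$ref1), ref2 = toid(df$ref2), ref3 = toid(df$ref3),
    r = df$r, theta = df$theta, phi0 = df$phi0, torsion = df$torsion,
    stringsAsFactors = FALSE)
  zmat$r[zmat$ref1 == 0L] <- 0
  zmat$theta[is.na(zmat$theta)] <- 0

  bonds <- cbind(zmat$ref1[zmat$ref1 > 0L], which(zmat$ref1 > 0L))
  for (b in extra_bonds) bonds <- rbind(bonds, unname(lab2id[b]))

  # primary defining quadruple for each named torsion: the first atom whose
  # zmat dihedral is that torsion with zero offset
  torsion_atoms <- lapply(names(torsions), function(nm) {
    i <- which(!is.na(zmat$torsion) & zmat$torsion == nm & zmat$phi0 == 0)[1L]
    c(i, zmat$ref1[i], zmat$ref2[i], zmat$ref3[i])
  })
  names(torsion_atoms) <- names(torsions)

  phi_atoms <- if (n_units >= 1L) c("C2", "C3", "CB", "S1_2") else NULL

  top <- structure(list(
    headgroup = headgroup, n_units = n_units,
    atoms = data.frame(label = zmat$label, element = zmat$element,
                       stringsAsFactors = FALSE),
    zmat = zmat, bonds = bonds,
    torsions = torsions, torsion_atoms = torsion_atoms,
    proton_groups = groups, phi_atoms = phi_atoms,
    lab2id = lab2id), class = "lq_topology")
  top$steric_pairs <- nonbonded_heavy_pairs(top)
  validate_topology(top)
  top
}

# heavy-atom pairs separated by >= 3 bonds (soft-sphere steric term)
nonbonded_heavy_pairs <- function(top) {
  n <- nrow(top$atoms)
  adj <- matrix(FALSE, n, n)
  adj[top$bonds] <- TRUE
  adj <- adj | t(adj)
  close <- adj | ((adj %*% adj) > 0) | diag(n) > 0  # self, 1-2 and 1-3
  heavy <- which(top$atoms$element != "H")
  pr <- t(utils::combn(heavy, 2L))
  pr[!close[pr], , drop = FALSE]
}

validate_topology <- function(top) {
  n <- nrow(top$atoms)
  # connectivity of the bond graph
  adj <- matrix(FALSE, n, n)
  adj[top$bonds] <- TRUE
  adj <- adj | t(adj)
  seen <- rep(FALSE, n)
  queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    nb <- which(adj[i, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  if (!all(seen)) stop("internal error: bond graph not connected")
  if (any(vapply(top$proton_groups, length, 1L) == 0L))
    stop("internal error: empty proton group")
  expected <- lq_formula_counts(top$headgroup, top$n_units)
  got <- table(factor(top$atoms$element, levels = names(expected)))
  if (!all(got == expected))
    stop("internal error: composition mismatch for ", top$headgroup, "-",
         top$n_units)
  invisible(top)
}

# element counts from composition arithmetic: head + n isoprene (C5H8) units
lq_formula_counts <- function(headgroup, n_units) {
  if (headgroup == "UQ") {
    base <- c(C = 9L, H = 10L, O = 4L)
  } else {
    base <- c(C = 11L, H = 8L, O = 2L)
  }
  base + c(C = 5L, H = 8L, O = 0L) * n_units
}

#' Molecular formula of a topology
#'
#' @param top An `lq_topology`.
#' @return Hill-order formula string, e.g. `"C19H26O4"` for UQ-2.
#' @export
molecular_formula <- function(top) {
  stopifnot(inherits(top, "lq_topology"))
  cnt <- table(top$atoms$element)
  ord <- c("C", "H", setdiff(sort(names(cnt)), c("C", "H")))
  paste0(vapply(ord, function(e) {
    k <- if (e %in% names(cnt)) cnt[[e]] else 0L
    if (k == 0L) "" else if (k == 1L) e else paste0(e, k)
  }, ""), collapse = "")
}

#' @export
print.lq_topology <- function(x, ...) {
  cat(sprintf("%s-%d topology: %d atoms (%s), %d bonds\n",
              x$headgroup, x$n_units, nrow(x$atoms), molecular_formula(x),
              nrow(x$bonds)))
  cat("rotatable torsions:", paste(names(x$torsions), collapse = ", "), "\n")
  cat("proton groups:", paste(names(x$proton_groups), collapse = ", "), "\n")
  invisible(x)
}
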