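# Low-level Cartesian geometry: vector helpers, dihedrals, internal-coordinate
# (NeRF) embedding and least-squares superposition.

vnorm <- function(v) sqrt(sum(v * v))

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Signed dihedral angle of four points
#'
#' Standard IUPAC signed torsion over four positions, measured about the
#' p2--p3 axis.
#'
#' @param p1,p2,p3,p4 Numeric length-3 Cartesian coordinates (Angstrom).
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  ang <- rad2deg(atan2(sum(vcross(n1, n2) * b2 / vnorm(b2)),
                       sum(n1 * n2)))
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Bond angle of three points
#'
#' @param p1,p2,p3 Numeric length-3 coordinates; the angle is at `p2`.
#' @return Angle in degrees in [0, 180].
#' @export
bond_angle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  ct <- sum(u * v) / (vnorm(u) * vnorm(v))
  rad2deg(acos(max(-1, min(1, ct))))
}

# Reference R implementation of the natural-extension (NeRF) build used to
# convert internal coordinates to Cartesians.  The compiled version
# (nerf_embed_cpp) is the hot path inside the torsion optimizer; this one is
# kept as the readable definition and for equivalence testing.
nerf_embed_r <- function(ref1, ref2, ref3, r, theta, phi) {
  n <- length(r)
  X <- matrix(0, n, 3L)
  th <- deg2rad(theta)
  ph <- deg2rad(phi)
  for (i in seq_len(n)) {
    if (ref1[i] == 0L) {
      X[i, ] <- c(0, 0, 0)
    } else if (ref2[i] == 0L) {
      X[i, ] <- X[ref1[i], ] + c(r[i], 0, 0)
    } else if (ref3[i] == 0L) {
      j <- X[ref1[i], ]
      k <- X[ref2[i], ]
      u <- (k - j) / vnorm(k - j)
      w <- vcross(c(0, 0, 1), u)
      if (vnorm(w) < 1e-8) w <- c(1, 0, 0) else w <- w / vnorm(w)
      X[i, ] <- j + r[i] * (cos(th[i]) * u + sin(th[i]) * w)
    } else {
      a <- X[ref3[i], ]
      b <- X[ref2[i], ]
      cc <- X[ref1[i], ]
      bc <- (cc - b) / vnorm(cc - b)
      ab <- b - a
      nv <- vcross(ab, bc)
      nv <- nv / vnorm(nv)
      mv <- vcross(nv, bc)
      d2 <- c(-r[i] * cos(th[i]),
              r[i] * sin(th[i]) * cos(ph[i]),
              r[i] * sin(th[i]) * sin(ph[i]))
      X[i, ] <- cc + d2[1L] * bc + d2[2L] * mv + d2[3L] * nv
    }
  }
  X
}

#' Rigid-body least-squares superposition (Kabsch)
#'
#' Superposes `conf_b` onto `conf_a` using the optimal proper rotation and
#' translation computed over a subset of atoms, and reports the RMSD over
#' that subset.
#'
#' @param conf_a,conf_b Conformers (see [embed_conformer()]) or plain
#'   n x 3 coordinate matrices with matching row order.
#' @param subset Atom labels (character) or row indices used for the fit;
#'   default all atoms.  At least three non-collinear atoms are required.
#' @return A list of class `lq_superposition` with elements `rmsd`
#'   (Angstrom, over the subset), `aligned` (a copy of `conf_b` with
#'   transformed coordinates), `rotation` and `translation`.
#' @export
superpose <- function(conf_a, conf_b, subset = NULL) {
  Xa <- conformer_coords(conf_a)
  Xb <- conformer_coords(conf_b)
  if (nrow(Xa) != nrow(Xb))
    stop("conformers have different atom counts")
  idx <- resolve_subset(subset, Xa)
  if (length(idx) < 3L)
    stop("superposition subset must contain at least 3 atoms")
  A <- Xa[idx, , drop = FALSE]
  B <- Xb[idx, , drop = FALSE]
  ca <- colMeans(A)
  cb <- colMeans(B)
  A0 <- sweep(A, 2L, ca)
  B0 <- sweep(B, 2L, cb)
  if (qr(A0)$rank < 2L)
    stop("superposition subset is degenerate (collinear atoms)")
  H <- t(B0) %*% A0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Brot <- sweep(Xb, 2L, cb) %*% t(R)
  Brot <- sweep(Brot, 2L, ca, FUN = "+")
  rmsd <- sqrt(mean(rowSums((Brot[idx, , drop = FALSE] - A)^2)))
  aligned <- conf_b
  if (is.list(conf_b) && !is.null(conf_b$coords)) {
    aligned$coords <- `dimnames<-`(Brot, dimnames(Xb))
  } else {
    aligned <- `dimnames<-`(Brot, dimnames(Xb))
  }
  structure(list(rmsd = rmsd, aligned = aligned, rotation = R,
                 translation = ca - as.vector(cb %*% t(R))),
            class = "lq_superposition")
}

conformer_coords <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.list(x) && !is.null(x$coords)) return(x$coords)
  stop("not a conformer or coordinate matrix")
}

resolve_subset <- function(subset, X) {
  if (is.null(subset)) return(seq_len(nrow(X)))
  if (is.character(subset)) {
    idx <- match(subset, rownames(X))
    if (anyNA(idx))
      stop("unknown atom labels in subset: ",
           paste(subset[is.na(idx)], collapse = ", "))
    idx
  } else {
    as.integer(subset)
  }
}

#' @export
print.lq_superposition <- function(x, ...) {
  cat(sprintf("Rigid-body superposition: RMSD %.4f Angstrom over subset\n",
              x$rmsd))
  invisible(x)
}
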