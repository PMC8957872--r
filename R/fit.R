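# Restrained torsion-space conformer fitting.
#
# This is deliberately NOT a force field.  Bond lengths and angles stay at
# their ideal values; the search space is the backbone torsions, scored by a
# flat-bottom distance-restraint penalty plus a soft-sphere repulsion
# between nonbonded heavy atoms.  Multi-start random torsions followed by
# Nelder-Mead local refinement; fully deterministic given the seed.

#' Fit a conformer to a set of distance restraints
#'
#' Searches torsion space of a lipoquinone topology for a conformer that
#' satisfies flat-bottom distance restraints between proton groups while
#' avoiding steric clashes.  The optimized torsions are the backbone
#' rotatable bonds (`phi`, the allylic `chi_*` and the `tauA_*`/`tauB_*`
#' single bonds); methyl and methoxy rotors stay at their staggered
#' defaults.
#'
#' The penalty is
#' `sum_r w_restraint * max(0, lower_r - d_r, d_r - upper_r)^2 +
#'  w_steric * sum_clash (cutoff - d_ij)^2`,
#' with `d_r` the arithmetic-mean inter-group proton distance and the
#' steric sum over nonbonded heavy-atom pairs closer than `cutoff`
#' (2 A).  Penalty zero means every restraint is satisfied and the
#' conformer is clash-free.
#'
#' @param topology An [`lq_topology`][build_topology()].
#' @param restraints An [`noe_restraints`][restraints_from_table()] object,
#'   or a data frame with columns `group_a`, `group_b`, `lower`, `upper`.
#' @param seed Integer seed for the multi-start draw (required for
#'   reproducibility).
#' @param n_starts Number of random torsion starts (default 24).
#' @param weights Named list: `restraint` (default 1) and `steric`
#'   (default 1) penalty weights; `cutoff` soft-sphere cutoff in
#'   Angstrom (default 2).
#' @param maxit Nelder-Mead iteration cap per start (default 400).
#' @return Object of class `lq_fit`: `conformer` (best found), `penalty`,
#'   `violations` (per-restraint excess in Angstrom), `seed`, `n_starts`,
#'   `feasible` (TRUE when penalty is numerically zero), `start_penalties`.
#' @export
fit_conformer <- function(topology, restraints, seed, n_starts = 24,
                          weights = list(), maxit = 400) {
  stopifnot(inherits(topology, "lq_topology"))
  res <- if (inherits(restraints, "noe_restraints"))
    restraints$restraints else as.data.frame(restraints)
  if (nrow(res)) {
    req <- c("group_a", "group_b", "lower", "upper")
    if (!all(req %in% names(res)))
      stop("restraints need columns ", paste(req, collapse = ", "))
    bad <- which(res$lower > res$upper)
    if (length(bad))
      stop("restraint(s) with lower > upper: row ",
           paste(bad, collapse = ", "))
    unknown <- setdiff(unique(c(res$group_a, res$group_b)),
                       names(topology$proton_groups))
    if (length(unknown))
      stop("restraints reference unknown proton group(s): ",
           paste(unknown, collapse = ", "))
  }
  w <- utils::modifyList(list(restraint = 1, steric = 1, cutoff = 2.0),
                         weights)
  if (missing(seed)) stop("an explicit seed is required")

  opt_names <- backbone_torsions(topology)
  z <- topology$zmat
  has_t <- which(!is.na(z$torsion))
  base_phi <- z$phi0
  tv0 <- topology$torsions
  sp <- topology$steric_pairs
  ga <- lapply(res$group_a, group_indices, top = topology)
  gb <- lapply(res$group_b, group_indices, top = topology)
  ga_flat <- as.integer(unlist(ga))
  gb_flat <- as.integer(unlist(gb))
  ga_off <- c(0L, cumsum(vapply(ga, length, 1L)))
  gb_off <- c(0L, cumsum(vapply(gb, length, 1L)))
  tmap <- match(z$torsion[has_t], names(tv0))
  omap <- match(opt_names, names(tv0))

  penalty_of <- function(theta) {
    tv <- tv0
    tv[omap] <- theta
    phi <- base_phi
    phi[has_t] <- phi[has_t] + tv[tmap]
    X <- nerf_embed_cpp(z$ref1, z$ref2, z$ref3, z$r, z$theta, phi)
    pen <- w$steric * steric_penalty_cpp(X, sp[, 1L], sp[, 2L], w$cutoff)
    if (nrow(res))
      pen <- pen + w$restraint *
        restraint_penalty_cpp(X, ga_flat, ga_off, gb_flat, gb_off,
                              res$lower, res$upper)
    pen
  }

  rs <- local({ set.seed(as.integer(seed) %% .Machine$integer.max)
                matrix(stats::runif(n_starts * length(opt_names),
                                    -180, 180), nrow = n_starts) })
  best <- NULL
  start_pen <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    o <- stats::optim(rs[s, ], penalty_of, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
    start_pen[s] <- o$value
    if (is.null(best) || o$value < best$value) best <- o
    if (best$value <= 1e-12) {
      start_pen <- start_pen[seq_len(s)]
      break
    }
  }

  theta <- wrap_angle(best$par)
  names(theta) <- opt_names
  conf <- embed_conformer(topology, theta)
  viol <- if (nrow(res)) {
    vapply(seq_len(nrow(res)), function(k) {
      d <- group_distance(conf, res$group_a[k], res$group_b[k], mode = "mean")
      max(0, res$lower[k] - d, d - res$upper[k])
    }, 0)
  } else numeric(0)
  structure(list(conformer = conf, penalty = best$value,
                 violations = data.frame(res,
                   excess = viol, stringsAsFactors = FALSE),
                 seed = seed, n_starts = n_starts,
                 feasible = best$value <= 1e-8,
                 start_penalties = start_pen, weights = w),
            class = "lq_fit")
}

backbone_torsions <- function(topology) {
  nm <- names(topology$torsions)
  nm[grepl("^(phi$|chi_|tauA_|tauB_)", nm)]
}

wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y <= -180] <- y[y <= -180] + 360
  y
}

#' @export
print.lq_fit <- function(x, ...) {
  cat(sprintf(
    "restrained torsion fit: penalty %.3g (%s), %d restraint(s), seed %s, %d start(s)\n",
    x$penalty, if (x$feasible) "feasible" else "violated",
    nrow(x$violations), format(x$seed), x$n_starts))
  if (nrow(x$violations) && any(x$violations$excess > 1e-6)) {
    cat("violated restraints:\n")
    print(x$violations[x$violations$excess > 1e-6, ], ...)
  }
  invisible(x)
}
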