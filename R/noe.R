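# NOE cross-peak calibration: volume standardization, strong/medium/weak
# intensity classes, distance bins and the continuous isolated spin-pair
# (r^-6) cross-check.

#' Default calibration configuration
#'
#' Thresholds and bins of the volume-to-distance calibration: normalized
#' volumes classify as strong (> 1.5), medium (0.6 to 1.5, both ends
#' inclusive) or weak (< 0.6); classes map to distance bins strong < 3 A,
#' medium 3-4 A, weak > 4 A.  `contact_floor` (1.8 A, van der Waals H...H
#' contact) closes the strong bin from below and `weak_upper` (5 A, the NOE
#' detection range) closes the weak bin from above; set
#' `weak_upper = Inf` to keep the literal open bin.
#'
#' @param strong_threshold,weak_threshold Class boundaries on normalized
#'   volume.
#' @param contact_floor Lower bound of the strong bin (Angstrom).
#' @param weak_upper Upper bound of the weak bin (Angstrom); may be `Inf`.
#' @param r_ref Reference calibration distance in Angstrom (the known
#'   H_W-H_MN distance, ~3.5 A).
#' @return A list of class `noe_config`.
#' @export
noe_config <- function(strong_threshold = 1.5, weak_threshold = 0.6,
                       contact_floor = 1.8, weak_upper = 5.0, r_ref = 3.5) {
  stopifnot(strong_threshold > weak_threshold, weak_threshold > 0,
            contact_floor > 0, weak_upper > 4 || is.infinite(weak_upper),
            r_ref > 0)
  structure(list(strong_threshold = strong_threshold,
                 weak_threshold = weak_threshold,
                 contact_floor = contact_floor,
                 weak_upper = weak_upper, r_ref = r_ref),
            class = "noe_config")
}

canonical_pair <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

assert_peak_table <- function(peaks) {
  req <- c("group_a", "group_b", "volume")
  miss <- setdiff(req, names(peaks))
  if (length(miss))
    stop("peak table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(peaks$volume) | peaks$volume <= 0)
  if (length(bad))
    stop("nonpositive or non-finite volume in row(s): ",
         paste(bad, collapse = ", "))
  same <- which(peaks$group_a == peaks$group_b)
  if (length(same))
    stop("diagonal peak (group_a == group_b) in row(s): ",
         paste(same, collapse = ", "))
  invisible(peaks)
}

#' Standardize cross-peak volumes against a reference pair
#'
#' Divides every volume integral by the volume of the reference pair
#' (the pair with known distance, H_W-H_MN in the lipoquinone scheme), so
#' the reference maps to exactly 1, and attaches the strong/medium/weak
#' intensity class of each peak.  Pair identity is unordered.
#'
#' @param peaks Data frame with columns `group_a`, `group_b`, `volume` and
#'   optionally `spectrum`, `environment`, `overlap_flag`.
#' @param reference_pair Character length-2: the two group labels of the
#'   reference pair.
#' @param config A [noe_config()].
#' @return The input table (row order preserved) with added columns
#'   `v_norm` and `intensity_class`; class `noe_normalized`.
#' @export
normalize_volumes <- function(peaks, reference_pair = c("H_W", "H_MN"),
                              config = noe_config()) {
  assert_peak_table(peaks)
  stopifnot(length(reference_pair) == 2L)
  key <- canonical_pair(peaks$group_a, peaks$group_b)
  refkey <- canonical_pair(reference_pair[1L], reference_pair[2L])
  iref <- which(key == refkey)
  if (!length(iref))
    stop("reference pair ", reference_pair[1L], "-", reference_pair[2L],
         " not present in the peak table")
  vref <- mean(peaks$volume[iref])
  out <- peaks
  out$v_norm <- peaks$volume / vref
  out$v_norm[iref] <- out$volume[iref] / out$volume[iref]  # exactly 1
  out$intensity_class <- vapply(out$v_norm, classify_intensity, "",
                                config = config)
  attr(out, "reference_pair") <- sort(reference_pair)
  class(out) <- c("noe_normalized", class(peaks))
  out
}

#' Classify a normalized volume as strong, medium or weak
#'
#' Strong for v > 1.5, medium for 0.6 <= v <= 1.5 (closed interval),
#' weak for v < 0.6 (default thresholds).
#'
#' @param v_norm Non-negative normalized volume.
#' @param config A [noe_config()].
#' @return `"strong"`, `"medium"` or `"weak"`.
#' @export
classify_intensity <- function(v_norm, config = noe_config()) {
  if (!is.finite(v_norm) || v_norm < 0)
    stop("v_norm must be a non-negative number")
  if (v_norm > config$strong_threshold) "strong"
  else if (v_norm >= config$weak_threshold) "medium"
  else "weak"
}

#' Distance bounds for an intensity class
#'
#' Strong maps to (contact_floor, 3 A), medium to (3, 4 A), weak to
#' (4 A, weak_upper).
#'
#' @param class `"strong"`, `"medium"` or `"weak"`.
#' @param config A [noe_config()].
#' @return Numeric `c(lower, upper)` in Angstrom (`upper` may be `Inf`).
#' @export
class_to_bounds <- function(class, config = noe_config()) {
  switch(match.arg(class, c("strong", "medium", "weak")),
         strong = c(config$contact_floor, 3.0),
         medium = c(3.0, 4.0),
         weak = c(4.0, config$weak_upper))
}

#' Continuous isolated spin-pair distance
#'
#' The ISPA relation r = r_ref * v_norm^(-1/6): the continuous counterpart
#' of the binned calibration, used as an internal cross-check and for
#' zero-noise round trips.
#'
#' @param v_norm Positive normalized volume.
#' @param r_ref Reference distance in Angstrom (default 3.5).
#' @return Distance in Angstrom.
#' @export
ispa_distance <- function(v_norm, r_ref = 3.5) {
  if (any(!is.finite(v_norm)) || any(v_norm <= 0))
    stop("v_norm must be positive")
  if (!is.finite(r_ref) || r_ref <= 0) stop("r_ref must be positive")
  r_ref * v_norm^(-1 / 6)
}

#' Build distance restraints from a normalized peak table
#'
#' One flat-bottom distance restraint per observed unordered group pair.
#' The reference pair itself is the calibrator and yields no restraint.
#' Peaks flagged `overlap_flag` (solvent/peak overlap, e.g. the
#' acetonitrile reference-peak caveat) are excluded and reported
#' separately.  Duplicate observations of a pair (e.g. NOESY and ROESY)
#' are merged to the narrower bound; if duplicate classes are incompatible
#' (empty intersection) the widest compatible bound is kept and the
#' restraint is flagged with a warning.
#'
#' Optionally, group pairs listed in `expected_pairs` but absent from the
#' table are turned into lower-bound-only "absence" restraints
#' (distance >= `config$weak_upper`), encoding that a pair inside the
#' monitored set showed no cross peak and must lie beyond the NOE
#' detection range.
#'
#' @param normalized A table from [normalize_volumes()].
#' @param config A [noe_config()].
#' @param expected_pairs Optional 2-column matrix / data.frame (or list of
#'   length-2 vectors) of monitored group pairs for absence restraints.
#' @return A list of class `noe_restraints`: `restraints` (data frame with
#'   `group_a`, `group_b`, `lower`, `upper`, `class`, `source`, `conflict`),
#'   `excluded` (overlap-flagged rows), `reference_pair`, `config`.
#' @export
restraints_from_table <- function(normalized, config = noe_config(),
                                  expected_pairs = NULL) {
  if (!inherits(normalized, "noe_normalized"))
    stop("input must come from normalize_volumes()")
  ref <- attr(normalized, "reference_pair")
  key <- canonical_pair(normalized$group_a, normalized$group_b)
  refkey <- canonical_pair(ref[1L], ref[2L])
  ov <- if (!is.null(normalized$overlap_flag))
    isTRUE_vec(normalized$overlap_flag) else rep(FALSE, nrow(normalized))
  excluded <- normalized[ov, , drop = FALSE]
  use <- normalized[!ov & key != refkey, , drop = FALSE]
  ukey <- canonical_pair(use$group_a, use$group_b)

  rows <- lapply(unique(ukey), function(k) {
    sub <- use[ukey == k, , drop = FALSE]
    b <- t(vapply(sub$intensity_class, class_to_bounds, numeric(2L),
                  config = config))
    lo <- max(b[, 1L]); hi <- min(b[, 2L])
    conflict <- FALSE
    if (lo >= hi) {        # incompatible duplicates: keep widest bound
      lo <- min(b[, 1L]); hi <- max(b[, 2L])
      conflict <- TRUE
      warning("conflicting duplicate classes for pair ", k,
              "; widest compatible bound retained", call. = FALSE)
    }
    cls <- if (nrow(sub) == 1L) sub$intensity_class[1L] else
      paste(sort(unique(sub$intensity_class)), collapse = "+")
    src <- if (!is.null(sub$spectrum))
      paste(sort(unique(sub$spectrum)), collapse = "+") else "observed"
    data.frame(group_a = min(sub$group_a[1L], sub$group_b[1L]),
               group_b = max(sub$group_a[1L], sub$group_b[1L]),
               lower = lo, upper = hi, class = cls, source = src,
               conflict = conflict, stringsAsFactors = FALSE)
  })
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group_a = character(0), group_b = character(0),
               lower = numeric(0), upper = numeric(0),
               class = character(0), source = character(0),
               conflict = logical(0))

  if (!is.null(expected_pairs)) {
    ep <- as.matrix(as.data.frame(expected_pairs, stringsAsFactors = FALSE))
    if (is.null(dim(ep)) || ncol(ep) != 2L)
      ep <- matrix(unlist(expected_pairs), ncol = 2L, byrow = TRUE)
    ekey <- canonical_pair(ep[, 1L], ep[, 2L])
    seen <- c(unique(ukey), refkey,
              canonical_pair(excluded$group_a, excluded$group_b))
    absent <- which(!ekey %in% seen & !duplicated(ekey))
    if (length(absent)) {
      lim <- if (is.finite(config$weak_upper)) config$weak_upper else 5.0
      res <- rbind(res, data.frame(
        group_a = pmin(ep[absent, 1L], ep[absent, 2L]),
        group_b = pmax(ep[absent, 1L], ep[absent, 2L]),
        lower = lim, upper = Inf, class = "absent", source = "no-cross-peak",
        conflict = FALSE, stringsAsFactors = FALSE))
    }
  }
  rownames(res) <- NULL
  structure(list(restraints = res, excluded = excluded,
                 reference_pair = ref, config = config),
            class = "noe_restraints")
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Exact distance restraints from a known conformer
#'
#' Builds flat-bottom restraints `d +/- tol` around the true inter-group
#' distances of a conformer.  Mainly for parameter-recovery experiments:
#' unlike the binned calibration, these restraints are guaranteed to be
#' satisfiable by the generating conformer (penalty 0).
#'
#' @param conformer An `lq_conformer`.
#' @param pairs 2-column matrix/data frame of group pairs (default: all
#'   unordered proton-group pairs within `max_distance`).
#' @param tol Half-width of the flat bottom in Angstrom (default 0.5).
#' @param max_distance Only pairs closer than this are restrained
#'   (default 5, the NOE range).
#' @param mode Distance convention (see [group_distance()]).
#' @return A data frame usable as `restraints` in [fit_conformer()].
#' @export
restraints_from_conformer <- function(conformer, pairs = NULL, tol = 0.5,
                                      max_distance = 5.0,
                                      mode = c("mean", "r6")) {
  mode <- match.arg(mode)
  top <- conformer$topology
  if (is.null(pairs)) {
    gn <- names(top$proton_groups)
    pairs <- t(utils::combn(gn, 2L))
  } else pairs <- as.matrix(as.data.frame(pairs, stringsAsFactors = FALSE))
  d <- vapply(seq_len(nrow(pairs)), function(k)
    group_distance(conformer, pairs[k, 1L], pairs[k, 2L], mode = mode), 0)
  keep <- d <= max_distance
  data.frame(group_a = pairs[keep, 1L], group_b = pairs[keep, 2L],
             lower = pmax(0.5, d[keep] - tol), upper = d[keep] + tol,
             class = "exact", source = "conformer",
             stringsAsFactors = FALSE)
}

#' @export
print.noe_restraints <- function(x, ...) {
  cat(sprintf("%d distance restraint(s), %d overlap-excluded peak(s); ",
              nrow(x$restraints), nrow(x$excluded)))
  cat("reference pair:", paste(x$reference_pair, collapse = "-"), "\n")
  if (nrow(x$restraints)) print(x$restraints, ...)
  invisible(x)
}
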