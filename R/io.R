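# Readers and writers for the package's plain-text dialects: peak CSV,
# shift CSV, isotherm CSV with '#key=value' metadata lines, restraint
# JSON and conformer XYZ/PDB.

read_meta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  metalines <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (l in metalines) {
    m <- regmatches(l, regexec("^#\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", l))[[1L]]
    if (length(m) == 3L) kv[[m[2L]]] <- trimws(m[3L])
  }
  kv
}

check_columns <- function(df, req, path) {
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(path, ": missing required column(s): ",
         paste(miss, collapse = ", "))
}

#' Read a NOE cross-peak CSV
#'
#' Dialect: header `group_a,group_b,volume,spectrum,environment,
#' overlap_flag`, with optional leading `#key=value` metadata lines.
#' Malformed rows (nonpositive volume, diagonal pair) are rejected with
#' their row numbers.
#'
#' @param path File path.
#' @return Validated peak data frame with attribute `meta`.
#' @export
read_peak_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  check_columns(df, c("group_a", "group_b", "volume"), path)
  if (is.null(df$spectrum)) df$spectrum <- "NOESY"
  if (is.null(df$environment)) df$environment <- ""
  df$overlap_flag <- if (is.null(df$overlap_flag)) FALSE else
    isTRUE_vec(df$overlap_flag)
  tryCatch(assert_peak_table(df),
           error = function(e) stop(path, ": ", conditionMessage(e),
                                    call. = FALSE))
  attr(df, "meta") <- read_meta_lines(path)
  df
}

#' Write a NOE cross-peak CSV
#'
#' @param peaks Peak data frame (see [read_peak_csv()] for the dialect).
#' @param path Output path.
#' @param meta Optional named list written as `#key=value` header lines.
#' @return `path`, invisibly.
#' @export
write_peak_csv <- function(peaks, path, meta = NULL) {
  cols <- c("group_a", "group_b", "volume", "spectrum", "environment",
            "overlap_flag")
  for (cn in setdiff(cols, names(peaks)))
    peaks[[cn]] <- switch(cn, spectrum = "NOESY", environment = "",
                          overlap_flag = FALSE)
  write_csv_meta(peaks[cols], path, meta)
}

write_csv_meta <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) writeLines(sprintf("#%s=%s", k, meta[[k]]), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a chemical-shift CSV
#'
#' Dialect: `proton,environment,delta_ppm` with optional `#key=value`
#' metadata lines.
#'
#' @param path File path.
#' @return A [shift_table()] with attribute `meta`.
#' @export
read_shift_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  check_columns(df, c("proton", "environment", "delta_ppm"), path)
  tab <- shift_table(df)
  attr(tab, "meta") <- read_meta_lines(path)
  tab
}

#' Write a chemical-shift CSV
#'
#' @param table A [shift_table()] (or compatible data frame).
#' @param path Output path.
#' @param meta Optional named list of `#key=value` header lines.
#' @return `path`, invisibly.
#' @export
write_shift_csv <- function(table, path, meta = NULL) {
  write_csv_meta(as.data.frame(table)[c("proton", "environment",
                                        "delta_ppm")], path, meta)
}

#' Read replicate compression isotherms from CSV
#'
#' Dialect: columns `replicate,area_A2,pressure_mN_m` (or
#' `replicate,area_A2,gamma_mN_m`, converted via [surface_pressure()]),
#' with optional metadata lines `#gamma0=`, `#x=`, `#lipid=`,
#' `#additive=`.
#'
#' @param path File path.
#' @return List of [isotherm_curve()] objects (one per replicate).
#' @export
read_isotherm_csv <- function(path) {
  meta <- read_meta_lines(path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  check_columns(df, c("replicate", "area_A2"), path)
  gamma0 <- if (!is.null(meta$gamma0)) as.numeric(meta$gamma0) else 72.8
  x <- if (!is.null(meta$x)) as.numeric(meta$x) else 1
  lipid <- if (!is.null(meta$lipid)) meta$lipid else ""
  additive <- if (!is.null(meta$additive)) meta$additive else ""
  if (any(!is.finite(df$area_A2)))
    stop(path, ": non-finite area in row(s): ",
         paste(which(!is.finite(df$area_A2)), collapse = ", "))
  lapply(split(df, df$replicate), function(sub) {
    if (!is.null(sub$pressure_mN_m))
      isotherm_curve(sub$area_A2, pressure = sub$pressure_mN_m,
                     gamma0 = gamma0, x = x, lipid = lipid,
                     additive = additive, replicate = sub$replicate[1L])
    else if (!is.null(sub$gamma_mN_m))
      isotherm_curve(sub$area_A2, gamma = sub$gamma_mN_m, gamma0 = gamma0,
                     x = x, lipid = lipid, additive = additive,
                     replicate = sub$replicate[1L])
    else stop(path, ": need a pressure_mN_m or gamma_mN_m column")
  })
}

#' Write replicate isotherms to CSV
#'
#' @param curves List of [isotherm_curve()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isotherm_csv <- function(curves, path) {
  if (inherits(curves, "isotherm_curve")) curves <- list(curves)
  proto <- curves[[1L]]
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(replicate = cv$replicate, area_A2 = cv$area,
               pressure_mN_m = cv$pressure)))
  write_csv_meta(df, path, meta = list(gamma0 = proto$gamma0, x = proto$x,
                                       lipid = proto$lipid,
                                       additive = proto$additive))
}

#' Write distance restraints to JSON
#'
#' Records `{pair, lower_A, upper_A, class, source}` per restraint.
#'
#' @param restraints An [`noe_restraints`][restraints_from_table()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_restraints_json <- function(restraints, path) {
  r <- restraints$restraints
  recs <- lapply(seq_len(nrow(r)), function(i) list(
    pair = c(r$group_a[i], r$group_b[i]),
    lower_A = r$lower[i],
    upper_A = if (is.finite(r$upper[i])) r$upper[i] else NULL,
    class = r$class[i], source = r$source[i]))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write a conformer to XYZ or PDB
#'
#' XYZ: atom count, comment, `element x y z` records.  PDB: HETATM
#' records with CONECT connectivity from the topology bond list.
#' Coordinates are written to 3 decimals.
#'
#' @param conformer An `lq_conformer`.
#' @param path Output path.
#' @param format `"xyz"` or `"pdb"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_conformer <- function(conformer, path, format = NULL) {
  stopifnot(inherits(conformer, "lq_conformer"))
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("xyz", "pdb"))
  X <- conformer$coords
  el <- conformer$topology$atoms$element
  if (format == "xyz") {
    lines <- c(sprintf("%d", nrow(X)),
               sprintf("%s-%d conformer (lipofold)",
                       conformer$topology$headgroup,
                       conformer$topology$n_units),
               sprintf("%-2s %12.3f %12.3f %12.3f", el,
                       X[, 1L], X[, 2L], X[, 3L]))
  } else {
    lines <- sprintf(
      "HETATM%5d %-4s LQN A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(X)), substr(rownames(X), 1L, 4L),
      X[, 1L], X[, 2L], X[, 3L], el)
    b <- conformer$topology$bonds
    conect <- vapply(seq_len(nrow(X)), function(i) {
      nb <- sort(c(b[b[, 1L] == i, 2L], b[b[, 2L] == i, 1L]))
      if (!length(nb)) return(NA_character_)
      paste0("CONECT", sprintf("%5d", i),
             paste0(sprintf("%5d", nb), collapse = ""))
    }, "")
    lines <- c(lines, conect[!is.na(conect)], "END")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an XYZ coordinate file
#'
#' @param path File path.
#' @return List with `element` and `coords` (n x 3 matrix).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1L]))
  recs <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  el <- vapply(recs, `[`, "", 1L)
  X <- t(vapply(recs, function(r) as.numeric(r[2:4]), numeric(3L)))
  list(element = el, coords = X)
}
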