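#' Molecular conformation object
#'
#' A single conformation frame: element symbols plus Cartesian coordinates in
#' Angstrom. This is the unit every other module operates on.
#'
#' @param elements Character vector of element symbols, drawn from
#'   `H, C, N, O, Fe`.
#' @param coords Numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom).
#' @param frame_id Integer frame label (defaults to 0).
#' @return An object of class `cac_structure` with fields `elements`,
#'   `coords` and `frame_id`.
#' @examples
#' h2 <- structure3d(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
#' n_atoms(h2)
#' @export
structure3d <- function(elements, coords, frame_id = 0L) {
  if (is.data.frame(coords)) coords <- as.matrix(coords)
  if (!is.matrix(coords) || ncol(coords) != 3L || !is.numeric(coords)) {
    cac_data_error("coords must be a numeric n x 3 matrix")
  }
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (n < 2L) cac_data_error("a structure needs at least 2 atoms")
  if (length(elements) != n) {
    cac_data_error(sprintf("%d elements but %d coordinate rows", length(elements), n))
  }
  elements <- as.character(elements)
  bad <- setdiff(unique(elements), CAC_ELEMENTS)
  if (length(bad)) {
    cac_data_error(paste0("unknown element symbol(s): ", paste(bad, collapse = ", ")))
  }
  if (!all(is.finite(coords))) cac_data_error("all coordinates must be finite")
  if (anyDuplicated(coords)) {
    i <- which(duplicated(coords))[1L]
    j <- which(apply(coords, 1L, identical, coords[i, ]))[1L]
    cac_geometry_error(sprintf("atoms %d and %d sit at identical coordinates", j, i))
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(elements = elements, coords = coords,
                 frame_id = as.integer(frame_id)),
            class = "cac_structure")
}

#' @export
print.cac_structure <- function(x, ...) {
  cat(sprintf("<cac_structure> frame %d: %d atoms (%s)\n", x$frame_id,
              n_atoms(x), paste(unique(x$elements), collapse = " ")))
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure A `cac_structure`.
#' @return Integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$coords)

#' Spin states of the model
#'
#' The three spin states of the Fe(II) complex with their multiplicities.
#'
#' @return Named integer vector `c(singlet = 1, triplet = 3, quintuplet = 5)`.
#' @export
spin_states <- function() CAC_SPINS

#' @rdname spin_states
#' @param label A spin-state label.
#' @return `spin_multiplicity()` returns the multiplicity for a label.
#' @export
spin_multiplicity <- function(label) {
  label <- match.arg(label, names(CAC_SPINS))
  unname(CAC_SPINS[label])
}

## ---- multi-frame XYZ ------------------------------------------------------

#' Read a multi-frame XYZ file
#'
#' Plain multi-frame XYZ: an atom-count line, a comment line (scanned for a
#' space-separated `frame=<int>` key), then one `element x y z` line per atom.
#' Frames missing the `frame=` key are numbered sequentially from 0.
#'
#' @param path Path to an XYZ file.
#' @return A list of [structure3d()] objects, in file order.
#' @seealso [write_xyz()]
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) cac_io_error(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  seq_id <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) {
      cac_parse_error(sprintf("line %d: expected an atom count, got '%s'", i, lines[i]))
    }
    if (i + 1L + n > length(lines)) {
      cac_parse_error(sprintf("line %d: frame declares %d atoms but the file ends early", i, n))
    }
    comment <- lines[i + 1L]
    m <- regmatches(comment, regexec("(?:^|\\s)frame=(-?[0-9]+)(?:\\s|$)", comment))[[1L]]
    frame_id <- if (length(m)) as.integer(m[2L]) else seq_id
    elements <- character(n)
    coords <- matrix(NA_real_, n, 3L)
    for (k in seq_len(n)) {
      ln <- i + 1L + k
      tok <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
      if (length(tok) < 4L) {
        cac_parse_error(sprintf("line %d: expected 'element x y z'", ln))
      }
      if (!tok[1L] %in% CAC_ELEMENTS) {
        cac_parse_error(sprintf("line %d: unknown element symbol '%s'", ln, tok[1L]))
      }
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(xyz)) {
        cac_parse_error(sprintf("line %d: non-numeric coordinate", ln))
      }
      elements[k] <- tok[1L]
      coords[k, ] <- xyz
    }
    frames[[length(frames) + 1L]] <- structure3d(elements, coords, frame_id)
    seq_id <- seq_id + 1L
    i <- i + 2L + n
  }
  if (!length(frames)) cac_parse_error(paste0("no frames found in ", path))
  frames
}

#' Write structures to a multi-frame XYZ file
#'
#' @param structures Non-empty list of [structure3d()] objects (a single
#'   structure is accepted).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(structures, path) {
  if (inherits(structures, "cac_structure")) structures <- list(structures)
  if (!length(structures)) cac_data_error("no structures to write")
  out <- unlist(lapply(structures, function(s) {
    c(sprintf("%d", n_atoms(s)),
      sprintf("frame=%d", s$frame_id),
      sprintf("%-2s %16.8f %16.8f %16.8f", s$elements,
              s$coords[, 1L], s$coords[, 2L], s$coords[, 3L]))
  }))
  ok <- tryCatch({ writeLines(out, path); TRUE }, error = function(e) FALSE)
  if (!ok) cac_io_error(paste0("cannot write to ", path))
  invisible(path)
}

## ---- charge tables --------------------------------------------------------

CHARGE_COLS <- c("frame", "atom_index", "element",
                 "q_singlet", "q_triplet", "q_quintuplet")

validate_charge_table <- function(df, where = "charge table") {
  missing <- setdiff(CHARGE_COLS, names(df))
  if (length(missing)) {
    cac_format_error(paste0(where, " is missing column(s): ",
                            paste(missing, collapse = ", ")))
  }
  qcols <- grep("^q_", names(df), value = TRUE)
  for (cc in qcols) {
    if (!is.numeric(df[[cc]]) || !all(is.finite(df[[cc]]))) {
      cac_format_error(paste0(where, ": non-finite charge in column ", cc))
    }
  }
  idx_sets <- tapply(df$atom_index, df$frame, function(v) paste(sort(v), collapse = ","))
  if (length(unique(idx_sets)) > 1L) {
    cac_format_error(paste0(where, ": frames do not all cover the same atom indices"))
  }
  df
}

#' Read a per-frame, per-atom, per-spin charge table
#'
#' Wide-format delimited text with header columns `frame`, `atom_index`
#' (0-based), `element`, `q_singlet`, `q_triplet`, `q_quintuplet` (charges in
#' e). Extra columns (for example prediction uncertainties `q_std_*`) are
#' preserved.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator (default comma).
#' @return A data frame ordered by frame then atom index.
#' @seealso [write_charge_table()]
#' @export
read_charge_table <- function(path, sep = ",") {
  if (!file.exists(path)) cac_io_error(paste0("file not found: ", path))
  df <- tryCatch(read.csv(path, sep = sep, stringsAsFactors = FALSE),
                 error = function(e) cac_parse_error(conditionMessage(e)))
  df <- validate_charge_table(df, where = path)
  df[order(df$frame, df$atom_index), , drop = FALSE][, union(CHARGE_COLS, names(df))]
}

#' Write a charge table
#'
#' @param charges Data frame with at least the columns documented in
#'   [read_charge_table()].
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return Invisibly, `path`.
#' @export
write_charge_table <- function(charges, path, sep = ",") {
  charges <- validate_charge_table(charges)
  charges <- charges[order(charges$frame, charges$atom_index), , drop = FALSE]
  ok <- tryCatch({
    write.table(charges, path, sep = sep, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) cac_io_error(paste0("cannot write to ", path))
  invisible(path)
}
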