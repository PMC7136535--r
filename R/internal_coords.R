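#' Geometric primitives on Cartesian points
#'
#' Distance (Angstrom), bond angle (degrees, vertex at `b`, in `[0, 180]`)
#' and signed dihedral (degrees in `(-180, 180]`, the angle between planes
#' `(a, b, c)` and `(b, c, d)` with a right-hand sign convention about the
#' `b -> c` axis; an exactly planar trans arrangement gives +180).
#'
#' @param a,b,c,d Numeric length-3 coordinate vectors (Angstrom).
#' @return A scalar distance, angle or signed dihedral.
#' @examples
#' coord_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))  # 90
#' @name coord_geometry
NULL

#' @rdname coord_geometry
#' @export
coord_distance <- function(a, b) sqrt(sum((as.double(a) - as.double(b))^2))

#' @rdname coord_geometry
#' @export
coord_angle <- function(a, b, c) {
  u <- as.double(a) - as.double(b)
  v <- as.double(c) - as.double(b)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) cac_geometry_error("zero-length bond vector in angle")
  cosq <- min(1, max(-1, sum(u * v) / (nu * nv)))
  acos(cosq) * 180 / pi
}

#' @rdname coord_geometry
#' @export
coord_dihedral <- function(a, b, c, d) {
  b1 <- as.double(b) - as.double(a)
  b2 <- as.double(c) - as.double(b)
  b3 <- as.double(d) - as.double(c)
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) {
    cac_geometry_error("collinear atoms make the dihedral undefined")
  }
  u2 <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * u2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

#' Internal-coordinate descriptor definition
#'
#' A manually chosen set of internal coordinates used as an alternative,
#' chemically interpretable descriptor. The default is the 11-parameter set
#' for the heme-O2 model: eight distances (Fe-N1, Fe-N2, Fe-N3, Fe-N4,
#' Fe-N11, Fe-O12, Fe-O13, O12-O13), one angle (Fe-O12-O13) and two
#' dihedrals (N2-Fe-N1-C10 and N1-Fe-N2-C5), indices referring to the heavy
#' atoms in [heme_atom_table()] order.
#'
#' @param distance_pairs Integer matrix (k x 2) of 1-based atom positions.
#' @param angle_triples Integer matrix (k x 3); the angle vertex is column 2.
#' @param dihedral_quads Integer matrix (k x 4).
#' @param names Optional component names.
#' @return A `cac_internal_def` with a `length` field (11 for the default).
#' @export
internal_coords_definition <- function(distance_pairs = NULL,
                                       angle_triples = NULL,
                                       dihedral_quads = NULL,
                                       names = NULL) {
  if (is.null(distance_pairs) && is.null(angle_triples) && is.null(dihedral_quads)) {
    ## default heme set; positions are heme_atom_table()$atom_index + 1
    distance_pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5),
                            c(1, 12), c(1, 13), c(1, 14), c(13, 14))
    angle_triples <- rbind(c(1, 13, 14))
    dihedral_quads <- rbind(c(3, 1, 2, 11), c(2, 1, 3, 6))
    names <- c("d_Fe_N1", "d_Fe_N2", "d_Fe_N3", "d_Fe_N4", "d_Fe_N11",
               "d_Fe_O12", "d_Fe_O13", "d_O12_O13", "ang_Fe_O12_O13",
               "dih_N2_Fe_N1_C10", "dih_N1_Fe_N2_C5")
  }
  as_mat <- function(m, k) {
    if (is.null(m)) return(matrix(integer(), 0L, k))
    m <- rbind(m)
    if (ncol(m) != k) cac_config_error(sprintf("index matrix must have %d columns", k))
    storage.mode(m) <- "integer"
    m
  }
  distance_pairs <- as_mat(distance_pairs, 2L)
  angle_triples <- as_mat(angle_triples, 3L)
  dihedral_quads <- as_mat(dihedral_quads, 4L)
  len <- nrow(distance_pairs) + nrow(angle_triples) + nrow(dihedral_quads)
  if (is.null(names)) names <- if (len) paste0("ic_", seq_len(len)) else character()
  if (length(names) != len) cac_config_error("names length mismatch")
  structure(list(distance_pairs = distance_pairs, angle_triples = angle_triples,
                 dihedral_quads = dihedral_quads, names = names, length = len),
            class = "cac_internal_def")
}

#' Evaluate internal-coordinate descriptors on a structure
#'
#' Concatenates distances (Angstrom), angles (degrees) and signed dihedrals
#' (degrees) in definition order; the default heme definition yields a
#' length-11 vector. Internal coordinates are invariant to rigid motions by
#' construction.
#'
#' @param structure A [structure3d()].
#' @param definition An [internal_coords_definition()].
#' @return Named numeric vector of length `definition$length`.
#' @export
internal_descriptors <- function(structure, definition = internal_coords_definition()) {
  idx_max <- suppressWarnings(max(definition$distance_pairs,
                                  definition$angle_triples,
                                  definition$dihedral_quads))
  if (is.finite(idx_max) && idx_max > n_atoms(structure)) {
    cac_data_error("definition refers to atoms beyond the structure")
  }
  X <- structure$coords
  each_row <- function(m, f) {  # apply() calls f on empty input for 0 rows
    if (!nrow(m)) numeric() else apply(m, 1L, f)
  }
  v <- c(
    each_row(definition$distance_pairs,
             function(p) coord_distance(X[p[1L], ], X[p[2L], ])),
    each_row(definition$angle_triples,
             function(p) coord_angle(X[p[1L], ], X[p[2L], ], X[p[3L], ])),
    each_row(definition$dihedral_quads,
             function(p) coord_dihedral(X[p[1L], ], X[p[2L], ], X[p[3L], ], X[p[4L], ]))
  )
  stats::setNames(as.double(v), definition$names)
}

#' Internal-coordinate features for a list of frames
#'
#' One row per frame (internal coordinates describe the whole conformation,
#' not a single atom).
#'
#' @inheritParams featurize_frames
#' @param definition An [internal_coords_definition()].
#' @return Data frame with `frame` plus one column per component.
#' @export
internal_frames <- function(structures, definition = internal_coords_definition()) {
  if (inherits(structures, "cac_structure")) structures <- list(structures)
  if (!length(structures)) cac_data_error("no structures")
  rows <- lapply(structures, function(s) {
    v <- internal_descriptors(s, definition)
    cbind(data.frame(frame = s$frame_id), as.data.frame(as.list(v), check.names = FALSE))
  })
  do.call(rbind, rows)
}
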