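#' Symmetry-function parameters
#'
#' Parameters of the atom-centered radial and angular symmetry functions.
#' The defaults are the single-function setting used for the heme-O2 model:
#' a cutoff far beyond the molecular diameter (`rc = 99` Angstrom, so every
#' atom pair contributes), Gaussian width `eta = 1` (1/Angstrom^2), radial
#' shift `rs = 1` Angstrom, angular polarity `lambda = +1` and sharpness
#' `zeta = 1`.
#'
#' @param eta Gaussian width parameter (1/Angstrom^2), >= 0.
#' @param rs Radial shift (Angstrom), >= 0.
#' @param rc Cutoff radius (Angstrom), > 0.
#' @param lambda Angular polarity, -1 or +1.
#' @param zeta Angular sharpness, > 0.
#' @return A `cac_sf_params` list.
#' @export
sf_params <- function(eta = 1, rs = 1, rc = 99, lambda = 1, zeta = 1) {
  if (!is.numeric(rc) || rc <= 0) cac_config_error("rc must be > 0")
  if (!is.numeric(zeta) || zeta <= 0) cac_config_error("zeta must be > 0")
  if (!lambda %in% c(-1, 1)) cac_config_error("lambda must be -1 or +1")
  if (!is.numeric(eta) || eta < 0) cac_config_error("eta must be >= 0")
  if (!is.numeric(rs) || rs < 0) cac_config_error("rs must be >= 0")
  structure(list(eta = as.double(eta), rs = as.double(rs), rc = as.double(rc),
                 lambda = as.double(lambda), zeta = as.double(zeta)),
            class = "cac_sf_params")
}

#' Smooth cosine cutoff function
#'
#' `0.5 * (cos(pi * r / rc) + 1)` for `r <= rc`, exactly 0 beyond the cutoff.
#' Continuous and monotonically non-increasing on `[0, rc]`.
#'
#' @param r Distance(s), Angstrom, >= 0.
#' @param rc Cutoff radius, Angstrom.
#' @return Unitless weight(s) in `[0, 1]`.
#' @export
cutoff_fn <- function(r, rc = 99) {
  if (any(r < 0)) cac_config_error("cutoff_fn: distance must be non-negative")
  if (rc <= 0) cac_config_error("cutoff_fn: rc must be > 0")
  ifelse(r >= rc, 0, 0.5 * (cos(pi * r / rc) + 1))
}

#' Radial symmetry-function term
#'
#' Sum over every atom `j != i` of element `elem` of
#' `exp(-eta * (R_ij - rs)^2) * fc(R_ij)`. Returns 0 when the structure has
#' no such neighbor.
#'
#' @param structure A [structure3d()].
#' @param i Center atom (1-based position in the structure).
#' @param elem Neighbor element label.
#' @param params [sf_params()].
#' @return Unitless non-negative scalar.
#' @export
radial_term <- function(structure, i, elem, params = sf_params()) {
  stopifnot(i >= 1L, i <= n_atoms(structure))
  if (!elem %in% CAC_ELEMENTS) cac_config_error(paste0("unknown element: ", elem))
  js <- which(structure$elements == elem)
  js <- js[js != i]
  if (!length(js)) return(0)
  d <- sqrt(colSums((t(structure$coords[js, , drop = FALSE]) - structure$coords[i, ])^2))
  if (any(d == 0)) {
    cac_geometry_error(sprintf("atoms %d and %d coincide", i, js[which(d == 0)[1L]]))
  }
  sum(exp(-params$eta * (d - params$rs)^2) * cutoff_fn(d, params$rc))
}

#' Angular symmetry-function term
#'
#' Sum over unordered neighbor pairs `{j, k}` (both distinct from the center
#' `i`, elements covering `{elem_j, elem_k}`, each pair counted once) of
#' `2^(1-zeta) * (1 + lambda*cos(theta_jik))^zeta *
#'  exp(-eta*(R_ij^2 + R_ik^2 + R_jk^2)) * fc(R_ij) fc(R_ik) fc(R_jk)`,
#' where `theta_jik` is the angle at the center atom. Symmetric in the two
#' element labels; 0 when no qualifying pair exists.
#'
#' @inheritParams radial_term
#' @param elem_j,elem_k Element labels of the neighbor pair (unordered).
#' @return Unitless scalar (non-negative when `lambda = +1`).
#' @export
angular_term <- function(structure, i, elem_j, elem_k, params = sf_params()) {
  stopifnot(i >= 1L, i <= n_atoms(structure))
  if (!elem_j %in% CAC_ELEMENTS || !elem_k %in% CAC_ELEMENTS) {
    cac_config_error("unknown element label")
  }
  js <- setdiff(which(structure$elements == elem_j), i)
  ks <- setdiff(which(structure$elements == elem_k), i)
  pairs <- if (identical(elem_j, elem_k)) {
    if (length(js) < 2L) return(0)
    t(utils::combn(js, 2L))
  } else {
    if (!length(js) || !length(ks)) return(0)
    as.matrix(expand.grid(js, ks))
  }
  ci <- structure$coords[i, ]
  total <- 0
  for (row in seq_len(nrow(pairs))) {
    j <- pairs[row, 1L]; k <- pairs[row, 2L]
    vj <- structure$coords[j, ] - ci
    vk <- structure$coords[k, ] - ci
    rij <- sqrt(sum(vj^2)); rik <- sqrt(sum(vk^2))
    rjk <- sqrt(sum((structure$coords[j, ] - structure$coords[k, ])^2))
    if (rij == 0 || rik == 0) cac_geometry_error("coincident atoms in angular term")
    cosq <- min(1, max(-1, sum(vj * vk) / (rij * rik)))
    total <- total + (1 + params$lambda * cosq)^params$zeta *
      exp(-params$eta * (rij^2 + rik^2 + rjk^2)) *
      cutoff_fn(rij, params$rc) * cutoff_fn(rik, params$rc) * cutoff_fn(rjk, params$rc)
  }
  2^(1 - params$zeta) * total
}

## ---- descriptor layout ----------------------------------------------------

#' Build the per-atom descriptor layout for a molecular composition
#'
#' The layout lists one radial component per element present in the
#' composition, then one angular component per unordered element pair (in the
#' order induced by `element_order`), excluding pairs that are identically
#' zero for every atom by composition -- i.e. pairs the molecule cannot cover
#' with two distinct neighbors of any center atom.  For the heme-O2 model
#' (9 H, 6 C, 5 N, 2 O, 1 Fe) only the Fe-Fe pair is dropped, giving
#' 5 radial + 14 angular = 19 components.  The layout is a pure function of
#' composition: atom order never affects it.
#'
#' @param elements Character vector of element symbols (one per atom), or a
#'   `cac_structure`.
#' @param element_order Canonical element ordering (default `H, C, N, O, Fe`).
#' @return A `cac_layout` with fields `element_order`, `radial`, `angular`
#'   (2-column matrix of element pairs), `dropped`, `names` and `p`.
#' @export
build_layout <- function(elements, element_order = CAC_ELEMENTS) {
  if (inherits(elements, "cac_structure")) elements <- elements$elements
  if (!length(elements)) cac_data_error("empty composition")
  bad <- setdiff(unique(elements), element_order)
  if (length(bad)) cac_data_error(paste0("element(s) outside element_order: ",
                                         paste(bad, collapse = ", ")))
  counts <- table(factor(elements, levels = element_order))
  present <- element_order[counts > 0L]
  n_total <- length(elements)

  pairs <- list(); dropped <- list()
  for (a in seq_along(present)) {
    for (b in a:length(present)) {
      J <- present[a]; K <- present[b]
      keep <- if (J == K) counts[[J]] >= 2L && n_total >= 3L
              else n_total >= 3L  # both elements present; any third atom centers
      if (keep) pairs[[length(pairs) + 1L]] <- c(J, K)
      else dropped[[length(dropped) + 1L]] <- c(J, K)
    }
  }
  angular <- if (length(pairs)) do.call(rbind, pairs) else matrix(character(), 0L, 2L)
  drop_m <- if (length(dropped)) do.call(rbind, dropped) else matrix(character(), 0L, 2L)
  nm <- c(paste0("radial_", present),
          if (nrow(angular)) paste0("angular_", angular[, 1L], "_", angular[, 2L]))
  structure(list(element_order = present, radial = present, angular = angular,
                 dropped = drop_m, names = nm,
                 p = length(nm), composition = as.integer(counts[present])),
            class = "cac_layout")
}

#' @export
print.cac_layout <- function(x, ...) {
  cat(sprintf("<cac_layout> p = %d (%d radial + %d angular; %d dropped)\n",
              x$p, length(x$radial), nrow(x$angular), nrow(x$dropped)))
  invisible(x)
}

## ---- featurization --------------------------------------------------------

#' Symmetry-function feature vectors for every atom of a structure
#'
#' Computes the full per-atom descriptor matrix in layout order. The
#' implementation is vectorized over neighbor pairs via the pairwise distance
#' and direction-cosine matrices; it is numerically equivalent to summing
#' [radial_term()] / [angular_term()] component by component.
#'
#' @param structure A [structure3d()] whose elements are covered by `layout`.
#' @param layout A [build_layout()] result.
#' @param params [sf_params()].
#' @return Numeric `n_atoms x p` matrix with `layout$names` as column names.
#' @export
featurize <- function(structure, layout, params = sf_params()) {
  if (!inherits(layout, "cac_layout")) cac_config_error("layout must be a cac_layout")
  extra <- setdiff(unique(structure$elements), layout$element_order)
  if (length(extra)) {
    cac_layout_error(paste0("structure contains element(s) not in layout: ",
                            paste(extra, collapse = ", ")))
  }
  X <- structure$coords
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  off <- D[upper.tri(D)]
  if (any(off == 0)) {
    idx <- which(D == 0 & upper.tri(D), arr.ind = TRUE)[1L, ]
    cac_geometry_error(sprintf("degenerate geometry: atoms %d and %d coincide",
                               idx[1L], idx[2L]))
  }
  eta <- params$eta; rs <- params$rs; rc <- params$rc
  lam <- params$lambda; zeta <- params$zeta

  FC <- cutoff_fn(D, rc); diag(FC) <- 0
  elem_idx <- lapply(layout$element_order, function(e) which(structure$elements == e))
  names(elem_idx) <- layout$element_order

  ## radial block: row i, element J -> sum_j in J, j != i
  Wrad <- exp(-eta * (D - rs)^2) * FC
  M <- vapply(layout$radial, function(e) {
    v <- numeric(n); v[elem_idx[[e]]] <- 1; v
  }, numeric(n))
  out <- matrix(0, n, layout$p, dimnames = list(NULL, layout$names))
  out[, seq_along(layout$radial)] <- Wrad %*% M

  if (nrow(layout$angular)) {
    G <- exp(-eta * D^2) * FC  # pairwise exp(-eta R^2) * fc, diagonal zeroed
    pref <- 2^(1 - zeta)
    for (i in seq_len(n)) {
      others <- setdiff(seq_len(n), i)
      V <- X[others, , drop = FALSE] - rep(X[i, ], each = n - 1L)
      r <- D[i, others]
      U <- V / r
      C <- tcrossprod(U)
      C[C > 1] <- 1; C[C < -1] <- -1
      w <- exp(-eta * r^2) * FC[i, others]
      A <- (1 + lam * C)^zeta * tcrossprod(w) * G[others, others, drop = FALSE]
      diag(A) <- 0
      loc <- function(e) which(structure$elements[others] == e)
      for (pp in seq_len(nrow(layout$angular))) {
        J <- layout$angular[pp, 1L]; K <- layout$angular[pp, 2L]
        lj <- loc(J)
        if (J == K) {
          if (length(lj) >= 2L) {
            out[i, length(layout$radial) + pp] <- pref * sum(A[lj, lj]) / 2
          }
        } else {
          lk <- loc(K)
          if (length(lj) && length(lk)) {
            out[i, length(layout$radial) + pp] <- pref * sum(A[lj, lk, drop = FALSE])
          }
        }
      }
    }
  }
  out
}

#' Featurize a list of frames into a long feature table
#'
#' @param structures List of [structure3d()] frames sharing one composition.
#' @param layout Optional [build_layout()]; built from the first frame when
#'   `NULL`.
#' @param params [sf_params()].
#' @return Data frame with `frame`, `atom_index` (0-based), `element` and one
#'   column per descriptor component.
#' @export
featurize_frames <- function(structures, layout = NULL, params = sf_params()) {
  if (inherits(structures, "cac_structure")) structures <- list(structures)
  if (!length(structures)) cac_data_error("no structures")
  if (is.null(layout)) layout <- build_layout(structures[[1L]])
  rows <- lapply(structures, function(s) {
    F <- featurize(s, layout, params)
    data.frame(frame = s$frame_id, atom_index = seq_len(n_atoms(s)) - 1L,
               element = s$elements, F, check.names = FALSE)
  })
  do.call(rbind, rows)
}
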