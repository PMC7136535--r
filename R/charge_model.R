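#' Random-forest configuration
#'
#' Hyperparameters of the per-(atom, spin) tree ensembles. Defaults follow
#' the training protocol for the heme-O2 charge models: `n_trees = 200`,
#' a random half of the frames for training, and `m` (features tried per
#' split) resolved from the feature count `p` -- the classic regression
#' default is `ceiling(p/3)`; for the 19 symmetry functions the best setting
#' found by the m-sweep is `m = 5`.
#'
#' @param n_trees Number of trees `B` per forest (>= 1), default 200.
#' @param m Either an integer count, a fraction of `p` in (0, 1), or one of
#'   `"log2"`, `"sqrt"`, `"third"`, `"all"`. Default `"third"`.
#' @param split_fraction Fraction of frames used for training, in (0, 1).
#' @param seed Master seed; per-(atom, spin) sub-seeds are derived from it
#'   deterministically, so training order never matters.
#' @param min_samples_split Smallest node that may still be split (default 2,
#'   i.e. trees grow until pure).
#' @return A validated `cac_forest_config` list.
#' @export
forest_config <- function(n_trees = 200L, m = "third", split_fraction = 0.5,
                          seed = 1L, min_samples_split = 2L) {
  if (!is.numeric(n_trees) || n_trees < 1L) cac_config_error("n_trees must be >= 1")
  if (!is.numeric(split_fraction) || split_fraction <= 0 || split_fraction >= 1) {
    cac_config_error("split_fraction must lie strictly between 0 and 1")
  }
  if (!is.numeric(min_samples_split) || min_samples_split < 2L) {
    cac_config_error("min_samples_split must be >= 2")
  }
  if (is.character(m)) {
    m <- match.arg(m, c("third", "log2", "sqrt", "all"))
  } else if (!is.numeric(m) || length(m) != 1L || m <= 0) {
    cac_config_error("m must be a positive number or a keyword")
  }
  structure(list(n_trees = as.integer(n_trees), m = m,
                 split_fraction = as.double(split_fraction),
                 seed = as.integer(seed),
                 min_samples_split = as.integer(min_samples_split)),
            class = "cac_forest_config")
}

#' Resolve the per-split feature count m
#'
#' @param m_spec Integer count (capped at `p`), fraction of `p` in (0, 1), or
#'   keyword `"log2"`, `"sqrt"`, `"third"`, `"all"`.
#' @param p Total number of features (>= 1).
#' @return Integer `m` with `1 <= m <= p`.
#' @examples
#' resolve_m(5, 19)      # 5
#' resolve_m(0.2, 19)    # 4
#' resolve_m("third", 19)  # 7
#' @export
resolve_m <- function(m_spec, p) {
  if (!is.numeric(p) || p < 1L) cac_config_error("p must be >= 1")
  p <- as.integer(p)
  if (is.character(m_spec)) {
    m_spec <- match.arg(m_spec, c("third", "log2", "sqrt", "all"))
    return(switch(m_spec,
                  third = max(1L, as.integer(ceiling(p / 3))),
                  log2 = max(1L, as.integer(floor(log2(p)))),
                  sqrt = max(1L, as.integer(floor(sqrt(p)))),
                  all = p))
  }
  if (!is.numeric(m_spec) || length(m_spec) != 1L || !is.finite(m_spec) || m_spec <= 0) {
    cac_config_error("m must be a positive count, a fraction in (0,1), or a keyword")
  }
  if (m_spec < 1) return(max(1L, as.integer(ceiling(m_spec * p))))
  if (m_spec != floor(m_spec)) cac_config_error("integer m must be whole")
  min(as.integer(m_spec), p)
}

#' Split frames into train and test sets
#'
#' Frames are partitioned uniformly at random without replacement by a seeded
#' generator; all atoms of a frame stay on the same side, so an atom's
#' training and test conformations never mix.
#'
#' @param frame_ids Vector of frame ids (>= 2 frames).
#' @param fraction Training fraction in (0, 1); `round(fraction * N)` frames
#'   go to the training side.
#' @param seed Seed for the split.
#' @return List with sorted integer vectors `train` and `test`.
#' @export
split_frames <- function(frame_ids, fraction = 0.5, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    cac_config_error("fraction must lie strictly between 0 and 1")
  }
  frame_ids <- unique(frame_ids)
  N <- length(frame_ids)
  if (N < 2L) cac_data_error("need at least 2 frames to split")
  n_train <- max(1L, min(N - 1L, as.integer(round(fraction * N))))
  train <- with_seed(seed, sort(sample(frame_ids, n_train)))
  list(train = train, test = sort(setdiff(frame_ids, train)))
}

#' Train a single tree ensemble
#'
#' One random forest: `n_trees` trees, each grown on a full-size bootstrap
#' resample with `m`-feature random subsetting at every node,
#' variance-reduction splitting, grown until nodes are pure or smaller than
#' `min_samples_split`. Deterministic given `seed`. Backed by
#' \pkg{ranger} with per-tree predictions kept accessible.
#'
#' @param X Numeric feature matrix (rows = observations).
#' @param y Numeric response (charges, e).
#' @param config A [forest_config()].
#' @param seed Seed for this forest (default `config$seed`).
#' @return A `cac_forest` wrapper around the fitted ensemble.
#' @details Feature columns that are constant across the training set are
#'   excluded from the random candidate pool before `m` is resolved: a split
#'   on them is never valid, and keeping them would let a node go terminal
#'   while an impurity-reducing split still exists, breaking the
#'   grow-to-purity contract (best-split implementations skip constant
#'   predictors for the same reason). If every column is constant the forest
#'   simply predicts bootstrap means.
#' @export
train_forest <- function(X, y, config = forest_config(), seed = config$seed) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) cac_data_error("rows(X) must equal length(y)")
  if (anyNA(X) || anyNA(y) || !all(is.finite(X)) || !all(is.finite(y))) {
    cac_data_error("NaN/Inf in features or charges")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  varying <- which(apply(X, 2L, function(col) any(col != col[1L])))
  keep <- if (length(varying)) varying else 1L
  m <- min(resolve_m(config$m, ncol(X)), length(keep))
  fit <- ranger::ranger(
    x = X[, keep, drop = FALSE], y = as.double(y),
    num.trees = config$n_trees,
    mtry = m,
    min.node.size = config$min_samples_split - 1L,
    replace = TRUE, sample.fraction = 1,
    splitrule = "variance",
    seed = seed, num.threads = 1L, oob.error = FALSE)
  structure(list(fit = fit, m = m, seed = as.integer(seed),
                 n_trees = config$n_trees, features = colnames(X),
                 used = colnames(X)[keep]),
            class = "cac_forest")
}

## per-tree prediction matrix (n x B) for a fitted cac_forest
forest_tree_predictions <- function(forest, X) {
  X <- as.matrix(X)
  colnames(X) <- forest$features
  predict(forest$fit, data = X[, forest$used, drop = FALSE], predict.all = TRUE,
          num.threads = 1L)$predictions
}

## ensemble mean and population-form (denominator B) spread of tree outputs
aggregate_trees <- function(P) {
  q_mean <- rowMeans(P)
  q_std <- sqrt(rowMeans((P - q_mean)^2))
  list(q_mean = q_mean, q_std = q_std)
}

## ---- full per-atom / per-spin model --------------------------------------

#' Train the full conformational-adaptive charge model
#'
#' Trains one independent forest per (atom, spin state): for the 14-atom
#' heme model over three spin states that is 42 forests. Features are
#' computed once per frame and shared by the atom's three spin models;
#' per-forest seeds are fanned out deterministically from `config$seed`.
#'
#' @param structures List of training frames ([structure3d()]).
#' @param charges Charge table data frame covering the same `frame` ids with
#'   all three spin columns.
#' @param scheme Featurization: `"sf"` (atom-centered symmetry functions) or
#'   `"internal"` (the 11 internal coordinates, shared by all atoms).
#' @param config A [forest_config()].
#' @param params [sf_params()] (scheme `"sf"`).
#' @param definition [internal_coords_definition()] (scheme `"internal"`).
#' @param atoms Optional subset of 0-based atom indices to model (default:
#'   every atom present in `charges`).
#' @return A `cac_model` holding the forests plus all featurization metadata
#'   needed to reproduce inputs exactly.
#' @export
train_charge_model <- function(structures, charges,
                               scheme = c("sf", "internal"),
                               config = forest_config(),
                               params = sf_params(),
                               definition = internal_coords_definition(),
                               atoms = NULL) {
  scheme <- match.arg(scheme)
  if (inherits(structures, "cac_structure")) structures <- list(structures)
  if (length(structures) < 2L) cac_data_error("need at least 2 training frames")
  charges <- validate_charge_table(charges)
  sf_ids <- vapply(structures, function(s) s$frame_id, integer(1L))
  missing <- setdiff(sf_ids, unique(charges$frame))
  if (length(missing)) {
    cac_data_error(paste0("frames without charges: ",
                          paste(sort(missing), collapse = ", ")))
  }
  comp <- structures[[1L]]$elements
  same <- vapply(structures, function(s) identical(s$elements, comp), logical(1L))
  if (!all(same)) cac_data_error("all frames must share one composition/atom order")

  atom_tab <- unique(charges[charges$frame == sf_ids[1L], c("atom_index", "element")])
  atom_tab <- atom_tab[order(atom_tab$atom_index), ]
  if (!is.null(atoms)) atom_tab <- atom_tab[atom_tab$atom_index %in% atoms, ]
  if (!nrow(atom_tab)) cac_data_error("no atoms to model")

  layout <- if (scheme == "sf") build_layout(comp) else NULL
  feats <- feature_arrays(structures, scheme, layout, params, definition)

  ## charges indexed [frame, atom] in structure order
  charges <- charges[charges$frame %in% sf_ids, ]
  ord <- order(match(charges$frame, sf_ids), charges$atom_index)
  charges <- charges[ord, ]

  spins <- names(CAC_SPINS)
  forests <- vector("list", nrow(atom_tab))
  names(forests) <- as.character(atom_tab$atom_index)
  for (a in seq_len(nrow(atom_tab))) {
    ai <- atom_tab$atom_index[a]
    Xa <- feats[[as.character(ai)]]
    rows <- charges$atom_index == ai
    forests[[a]] <- lapply(setNames(seq_along(spins), spins), function(si) {
      y <- charges[rows, paste0("q_", spins[si])]
      train_forest(Xa, y, config, seed = derive_seed(config$seed, ai, si))
    })
  }
  structure(list(forests = forests, scheme = scheme, layout = layout,
                 sf_params = params, definition = definition, config = config,
                 atoms = atom_tab, composition = comp,
                 n_train = length(structures)),
            class = "cac_model")
}

## Feature matrices per modelled atom: a named list atom_index -> (frames x p).
feature_arrays <- function(structures, scheme, layout, params, definition) {
  if (scheme == "sf") {
    mats <- lapply(structures, featurize, layout = layout, params = params)
    n_at <- nrow(mats[[1L]])
    out <- lapply(seq_len(n_at) - 1L, function(ai) {
      do.call(rbind, lapply(mats, function(m) m[ai + 1L, , drop = FALSE]))
    })
    names(out) <- as.character(seq_len(n_at) - 1L)
    out
  } else {
    V <- do.call(rbind, lapply(structures, function(s)
      matrix(internal_descriptors(s, definition), nrow = 1L,
             dimnames = list(NULL, definition$names))))
    n_at <- n_atoms(structures[[1L]])
    setNames(rep(list(V), n_at), as.character(seq_len(n_at) - 1L))
  }
}

#' Number of forests in a trained model
#' @param model A `cac_model`.
#' @return Integer count (atoms x spin states).
#' @export
n_forests <- function(model) sum(lengths(model$forests))

#' @export
print.cac_model <- function(x, ...) {
  cat(sprintf("<cac_model> %s features; %d forests (%d atoms x %d spins); B = %d; trained on %d frames\n",
              x$scheme, n_forests(x), nrow(x$atoms), length(x$forests[[1L]]),
              x$config$n_trees, x$n_train))
  invisible(x)
}

#' Predict multi-spin charges for new conformations
#'
#' For every modelled atom and spin state, the predicted charge is the
#' arithmetic mean of the individual tree outputs and the uncertainty is the
#' population-form spread (denominator `B`) of those outputs.
#'
#' @param object A trained `cac_model`.
#' @param structures A frame or list of frames matching the training
#'   composition.
#' @param ... Unused.
#' @return A charge-table data frame with `q_<spin>` means and `q_std_<spin>`
#'   spreads for each (frame, atom).
#' @export
predict.cac_model <- function(object, structures, ...) {
  if (inherits(structures, "cac_structure")) structures <- list(structures)
  if (!length(structures)) cac_data_error("no structures to predict")
  for (s in structures) {
    if (!identical(s$elements, object$composition)) {
      cac_layout_error("structure composition does not match the trained model")
    }
  }
  feats <- feature_arrays(structures, object$scheme, object$layout,
                          object$sf_params, object$definition)
  spins <- names(CAC_SPINS)
  n_f <- length(structures)
  fid <- vapply(structures, function(s) s$frame_id, integer(1L))
  out <- data.frame(frame = rep(fid, times = nrow(object$atoms)),
                    atom_index = rep(object$atoms$atom_index, each = n_f),
                    element = rep(object$atoms$element, each = n_f))
  for (sp in spins) out[[paste0("q_", sp)]] <- NA_real_
  for (sp in spins) out[[paste0("q_std_", sp)]] <- NA_real_
  for (a in seq_len(nrow(object$atoms))) {
    ai <- as.character(object$atoms$atom_index[a])
    rows <- (a - 1L) * n_f + seq_len(n_f)
    for (sp in spins) {
      P <- forest_tree_predictions(object$forests[[ai]][[sp]], feats[[ai]])
      agg <- aggregate_trees(P)
      out[rows, paste0("q_", sp)] <- agg$q_mean
      out[rows, paste0("q_std_", sp)] <- agg$q_std
    }
  }
  out[order(out$frame, out$atom_index), , drop = FALSE]
}

#' Per-tree predictions of one (atom, spin) forest
#'
#' Exposes the individual tree outputs behind [predict.cac_model()], so the
#' ensemble mean/spread aggregation can be recomputed or audited externally.
#'
#' @param model A trained `cac_model`.
#' @param atom_index 0-based atom index.
#' @param spin Spin-state label.
#' @param structures Frame(s) to predict.
#' @return Numeric matrix, one row per frame and one column per tree.
#' @export
tree_predictions <- function(model, atom_index, spin, structures) {
  spin <- match.arg(spin, names(CAC_SPINS))
  if (inherits(structures, "cac_structure")) structures <- list(structures)
  ai <- as.character(atom_index)
  if (!ai %in% names(model$forests)) {
    cac_data_error(paste0("no forest for atom_index ", atom_index))
  }
  feats <- feature_arrays(structures, model$scheme, model$layout,
                          model$sf_params, model$definition)
  forest_tree_predictions(model$forests[[ai]][[spin]], feats[[ai]])
}

## ---- persistence ----------------------------------------------------------

CAC_MODEL_FORMAT <- "cacharge-model"
CAC_MODEL_VERSION <- 1L

#' Save / load a trained charge model
#'
#' The archive is a single compressed file holding a format tag, a format
#' version and the model (forests, layout, parameters, config); loading a
#' file with an unknown tag or version fails loudly. A saved-and-reloaded
#' model reproduces predictions bit-identically.
#'
#' @param model A `cac_model`.
#' @param path Archive path.
#' @return `load_charge_model()` returns the `cac_model`.
#' @export
save_charge_model <- function(model, path) {
  if (!inherits(model, "cac_model")) cac_data_error("not a cac_model")
  ok <- tryCatch({
    saveRDS(list(format = CAC_MODEL_FORMAT, format_version = CAC_MODEL_VERSION,
                 model = model), path, compress = "xz")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) cac_io_error(paste0("cannot write model archive to ", path))
  invisible(path)
}

#' @rdname save_charge_model
#' @export
load_charge_model <- function(path) {
  if (!file.exists(path)) cac_io_error(paste0("file not found: ", path))
  obj <- tryCatch(readRDS(path),
                  error = function(e) cac_io_error(paste0("unreadable model archive: ",
                                                          conditionMessage(e))))
  if (!is.list(obj) || !identical(obj$format, CAC_MODEL_FORMAT)) {
    cac_format_error("not a cacharge model archive")
  }
  if (!identical(obj$format_version, CAC_MODEL_VERSION)) {
    cac_format_error(paste0("unsupported model archive version: ",
                            obj$format_version))
  }
  obj$model
}
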