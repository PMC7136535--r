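#' Prediction metrics for one charge series
#'
#' Errors are `pred - ref`. Reports the mean absolute error, root mean
#' square error, standard deviation of the signed errors (sample convention,
#' denominator n-1; configurable) and the Pearson product-moment correlation.
#' A zero-variance input makes the correlation undefined and raises a
#' `cac_degenerate_error` rather than returning a sentinel.
#'
#' @param pred,ref Equal-length finite numeric vectors (length >= 2), e.
#' @param error_std_denom `"n-1"` (default) or `"n"` for the population form.
#' @return One-row data frame with `mae`, `rmse`, `error_std`, `pearson`.
#' @examples
#' charge_metrics(c(1, 2, 3), c(1.1, 1.9, 3.2))
#' @export
charge_metrics <- function(pred, ref, error_std_denom = c("n-1", "n")) {
  error_std_denom <- match.arg(error_std_denom)
  if (length(pred) != length(ref)) cac_data_error("pred and ref lengths differ")
  if (length(pred) < 2L) cac_data_error("need at least 2 values")
  if (!all(is.finite(pred)) || !all(is.finite(ref))) cac_data_error("non-finite input")
  e <- pred - ref
  n <- length(e)
  es <- if (error_std_denom == "n-1") sd(e) else sqrt(mean((e - mean(e))^2))
  if (sd(pred) == 0 || sd(ref) == 0) {
    cac_degenerate_error("Pearson correlation undefined: zero-variance input")
  }
  data.frame(mae = mean(abs(e)), rmse = sqrt(mean(e^2)),
             error_std = es, pearson = cor(pred, ref))
}

#' Evaluate a trained charge model on held-out frames
#'
#' Computes [charge_metrics()] per (atom, spin state) over all test frames,
#' plus per-spin means of the per-atom values (the "Mean" row of a
#' performance table). Cells with a degenerate (zero-variance) correlation
#' are kept with `pearson = NA` and flagged in the `degenerate` column.
#'
#' @param model A trained `cac_model`.
#' @param structures Held-out frames.
#' @param charges Reference charge table for those frames.
#' @param error_std_denom Passed to [charge_metrics()].
#' @return A `cac_eval` list: `per_atom` (atom x spin metric rows),
#'   `per_spin` (spin means), `n_test`, `scheme`.
#' @export
evaluate_model <- function(model, structures, charges,
                           error_std_denom = c("n-1", "n")) {
  error_std_denom <- match.arg(error_std_denom)
  if (inherits(structures, "cac_structure")) structures <- list(structures)
  if (!length(structures)) cac_data_error("empty test set")
  charges <- validate_charge_table(charges)
  pred <- predict(model, structures)
  key <- function(df) paste(df$frame, df$atom_index)
  idx <- match(key(pred), key(charges))
  if (anyNA(idx)) cac_data_error("test charges do not cover all predicted (frame, atom) pairs")
  spins <- names(CAC_SPINS)
  rows <- list()
  for (a in seq_len(nrow(model$atoms))) {
    ai <- model$atoms$atom_index[a]
    sel <- pred$atom_index == ai
    for (sp in spins) {
      p <- pred[sel, paste0("q_", sp)]
      r <- charges[idx[sel], paste0("q_", sp)]
      met <- tryCatch(cbind(charge_metrics(p, r, error_std_denom), degenerate = FALSE),
                      cac_degenerate_error = function(e) {
                        e2 <- p - r
                        data.frame(mae = mean(abs(e2)), rmse = sqrt(mean(e2^2)),
                                   error_std = sd(e2), pearson = NA_real_,
                                   degenerate = TRUE)
                      })
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(atom_index = ai, element = model$atoms$element[a], spin = sp),
        met)
    }
  }
  per_atom <- do.call(rbind, rows)
  per_spin <- do.call(rbind, lapply(spins, function(sp) {
    d <- per_atom[per_atom$spin == sp, ]
    data.frame(spin = sp, mean_mae = mean(d$mae), mean_rmse = mean(d$rmse),
               mean_error_std = mean(d$error_std),
               mean_pearson = mean(d$pearson, na.rm = TRUE))
  }))
  structure(list(per_atom = per_atom, per_spin = per_spin,
                 n_test = length(structures), scheme = model$scheme),
            class = "cac_eval")
}

#' @export
print.cac_eval <- function(x, digits = 4, ...) {
  cat(sprintf("<cac_eval> %s scheme, %d test frames\n", x$scheme, x$n_test))
  print(format(x$per_atom, digits = digits), row.names = FALSE)
  cat("Per-spin means:\n")
  print(format(x$per_spin, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report as delimited text
#'
#' Writes `per_atom` and appends the per-spin mean rows (atom_index `NA`,
#' element `"Mean"`), mirroring a performance table with its Mean row.
#'
#' @param report A `cac_eval`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_eval_report <- function(report, path) {
  mean_rows <- data.frame(atom_index = NA_integer_, element = "Mean",
                          spin = report$per_spin$spin,
                          mae = report$per_spin$mean_mae,
                          rmse = report$per_spin$mean_rmse,
                          error_std = report$per_spin$mean_error_std,
                          pearson = report$per_spin$mean_pearson,
                          degenerate = FALSE)
  utils::write.csv(rbind(report$per_atom, mean_rows), path, row.names = FALSE)
  invisible(path)
}

## ---- spin-difference statistics ------------------------------------------

#' Spin-difference charge statistics
#'
#' Per-atom differences `d31 = q_triplet - q_singlet` and
#' `d53 = q_quintuplet - q_triplet` across frames, with histograms whose
#' bins are centered on multiples of `bin_width` (so a difference
#' concentrated at 0.1 e lands in the bin centered at 0.1 e).
#'
#' @param charges Charge table with all three spin columns.
#' @param bin_width Histogram bin width (e), default 0.02.
#' @return A `cac_spin_diff` list: `summary` data frame (per atom: mean and
#'   mode-bin center of each difference, sample count) and `histograms`, a
#'   per-atom list of `(bin_left, bin_right, count)` tables.
#' @export
spin_differences <- function(charges, bin_width = 0.02) {
  charges <- validate_charge_table(charges)
  if (bin_width <= 0) cac_config_error("bin_width must be > 0")
  atoms <- unique(charges[, c("atom_index", "element")])
  atoms <- atoms[order(atoms$atom_index), ]
  histo <- function(x) {
    k <- range(round(x / bin_width))
    breaks <- seq((k[1L] - 0.5) * bin_width, (k[2L] + 0.5) * bin_width, by = bin_width)
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    data.frame(bin_left = h$breaks[-length(h$breaks)],
               bin_right = h$breaks[-1L], count = h$counts)
  }
  histograms <- list(); srows <- list()
  for (a in seq_len(nrow(atoms))) {
    d <- charges[charges$atom_index == atoms$atom_index[a], ]
    d31 <- d$q_triplet - d$q_singlet
    d53 <- d$q_quintuplet - d$q_triplet
    h31 <- histo(d31); h53 <- histo(d53)
    mode_center <- function(h) {
      i <- which.max(h$count)
      (h$bin_left[i] + h$bin_right[i]) / 2
    }
    histograms[[as.character(atoms$atom_index[a])]] <-
      list(d31 = h31, d53 = h53, bin_width = bin_width)
    srows[[a]] <- data.frame(atom_index = atoms$atom_index[a],
                             element = atoms$element[a],
                             mean_d31 = mean(d31), mode_d31 = mode_center(h31),
                             mean_d53 = mean(d53), mode_d53 = mode_center(h53),
                             n = nrow(d))
  }
  structure(list(summary = do.call(rbind, srows), histograms = histograms,
                 bin_width = bin_width),
            class = "cac_spin_diff")
}

## ---- descriptor comparison and m sweep -----------------------------------

#' Compare descriptor schemes on an identical split
#'
#' Trains and evaluates a model per scheme on the same frame split and seed,
#' and tabulates per-(atom, spin) RMSE side by side with the improvement of
#' the second scheme over the first (`rmse_delta = rmse[scheme1] -
#' rmse[scheme2]`; positive means the second scheme is better).
#'
#' @param structures All frames.
#' @param charges Charge table for all frames.
#' @param config A [forest_config()] (its seed fixes the split too).
#' @param schemes Two or more of `"sf"`, `"internal"`.
#' @param params,definition Featurization settings.
#' @return A `cac_scheme_comparison` list: `reports` (named `cac_eval`s),
#'   `per_atom` (long table with a `scheme` column) and `rmse_delta`.
#' @export
compare_descriptors <- function(structures, charges, config = forest_config(),
                                schemes = c("sf", "internal"),
                                params = sf_params(),
                                definition = internal_coords_definition()) {
  if (length(schemes) < 2L) cac_config_error("need at least two schemes")
  schemes <- vapply(schemes, match.arg, "", choices = c("sf", "internal"))
  ids <- vapply(structures, function(s) s$frame_id, integer(1L))
  sp <- split_frames(ids, config$split_fraction, config$seed)
  tr <- structures[ids %in% sp$train]
  te <- structures[ids %in% sp$test]
  reports <- lapply(setNames(schemes, schemes), function(sc) {
    m <- train_charge_model(tr, charges[charges$frame %in% sp$train, ],
                            scheme = sc, config = config, params = params,
                            definition = definition)
    evaluate_model(m, te, charges[charges$frame %in% sp$test, ])
  })
  per_atom <- do.call(rbind, lapply(schemes, function(sc)
    cbind(scheme = sc, reports[[sc]]$per_atom)))
  base <- reports[[schemes[1L]]]$per_atom
  alt <- reports[[schemes[2L]]]$per_atom
  rmse_delta <- data.frame(base[, c("atom_index", "element", "spin")],
                           rmse_delta = base$rmse - alt$rmse)
  names(rmse_delta)[4L] <- paste0("rmse_", schemes[1L], "_minus_", schemes[2L])
  structure(list(reports = reports, per_atom = per_atom, rmse_delta = rmse_delta,
                 split = sp),
            class = "cac_scheme_comparison")
}

#' Sweep the per-split feature count m
#'
#' Re-trains the forests of one atom (default Fe) for each candidate `m`
#' under an identical split and seed, and reports the held-out Pearson
#' correlation per spin state -- the diagnostic used to pick `m`.
#'
#' @param structures All frames.
#' @param charges Charge table.
#' @param m_values Vector of m specifications (counts, fractions, keywords).
#' @param config A [forest_config()].
#' @param atom_index 0-based index of the probed atom (default 0 = Fe).
#' @param scheme,params,definition Featurization settings.
#' @return Data frame with `m_spec`, `m`, `spin`, `pearson`.
#' @export
sweep_m <- function(structures, charges, m_values, config = forest_config(),
                    atom_index = 0L, scheme = "sf", params = sf_params(),
                    definition = internal_coords_definition()) {
  if (!length(m_values)) cac_config_error("m_values is empty")
  ids <- vapply(structures, function(s) s$frame_id, integer(1L))
  sp <- split_frames(ids, config$split_fraction, config$seed)
  tr <- structures[ids %in% sp$train]
  te <- structures[ids %in% sp$test]
  out <- list()
  for (mv in m_values) {
    cfg <- config
    cfg$m <- if (is.character(mv) || is.numeric(mv)) mv else
      cac_config_error("invalid m specification")
    model <- train_charge_model(tr, charges[charges$frame %in% sp$train, ],
                                scheme = scheme, config = cfg, params = params,
                                definition = definition, atoms = atom_index)
    rep <- evaluate_model(model, te, charges[charges$frame %in% sp$test, ])
    p <- if (scheme == "sf") model$layout$p else model$definition$length
    out[[length(out) + 1L]] <- data.frame(
      m_spec = as.character(mv), m = resolve_m(cfg$m, p),
      spin = rep$per_atom$spin, pearson = rep$per_atom$pearson)
  }
  do.call(rbind, out)
}
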