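test_that("m resolution covers counts, fractions and keywords", {
  expect_identical(resolve_m(5, 19), 5L)
  expect_identical(resolve_m("all", 19), 19L)
  expect_identical(resolve_m(0.2, 19), 4L)   # ceil(0.2 * 19)
  expect_identical(resolve_m("log2", 19), 4L)
  expect_identical(resolve_m("sqrt", 19), 4L)
  expect_identical(resolve_m("third", 19), 7L)
  expect_identical(resolve_m(50, 19), 19L)   # capped at p
  expect_identical(resolve_m("third", 1), 1L)
  expect_error(resolve_m(0, 19), class = "cac_config_error")
  expect_error(resolve_m(-2, 19), class = "cac_config_error")
  expect_error(resolve_m(2.5, 19), class = "cac_config_error")
})

test_that("frame split partitions deterministically by frame", {
  sp <- split_frames(0:9, 0.5, seed = 4)
  expect_length(sp$train, 5)
  expect_length(sp$test, 5)
  expect_identical(sort(c(sp$train, sp$test)), 0:9)
  expect_identical(split_frames(0:9, 0.5, seed = 4), sp)
  expect_false(identical(split_frames(0:9, 0.5, seed = 5), sp))
  expect_error(split_frames(0:9, 1.0, 1), class = "cac_config_error")
  expect_error(split_frames(0L, 0.5, 1), class = "cac_data_error")
  expect_error(forest_config(split_fraction = 1), class = "cac_config_error")
})

test_that("single forests honour degenerate-data contracts", {
  set.seed(9)
  X <- matrix(runif(40), 20, 2)
  cfg <- forest_config(n_trees = 15, seed = 2)
  ## constant response: every tree predicts it everywhere
  f <- train_forest(X, rep(0.25, 20), cfg)
  P <- cacharge:::forest_tree_predictions(f, matrix(runif(10), 5, 2))
  expect_identical(unique(as.vector(P)), 0.25)
  ## single training row
  f1 <- train_forest(X[1, , drop = FALSE], 0.7, cfg)
  expect_identical(unique(as.vector(cacharge:::forest_tree_predictions(f1, X))), 0.7)
  ## constant features with varying response: predicts near the mean
  fc_ <- train_forest(matrix(1, 20, 2), seq(0, 1, length.out = 20), cfg)
  P2 <- cacharge:::forest_tree_predictions(fc_, matrix(1, 2, 2))
  expect_lt(abs(mean(P2) - 0.5), 0.15)
  ## NaN input is refused
  Xn <- X; Xn[3, 1] <- NaN
  expect_error(train_forest(Xn, runif(20), cfg), class = "cac_data_error")
  ## determinism under a fixed seed
  y <- runif(20)
  g1 <- train_forest(X, y, cfg, seed = 11)
  g2 <- train_forest(X, y, cfg, seed = 11)
  probe <- matrix(runif(20), 10, 2)
  expect_identical(cacharge:::forest_tree_predictions(g1, probe),
                   cacharge:::forest_tree_predictions(g2, probe))
})

test_that("one forest is trained per (atom, spin): 42 for the heme model", {
  ds <- tiny_dataset()
  cfg <- forest_config(n_trees = 4, seed = 1)
  model <- train_charge_model(ds$structures, ds$charges, config = cfg)
  expect_identical(n_forests(model), 42L)
  expect_identical(length(model$forests), 14L)
  expect_true(all(vapply(model$forests, length, 1L) == 3L))
  ## every forest holds exactly B trees
  expect_true(all(vapply(model$forests, function(a)
    all(vapply(a, function(f) f$fit$num.trees, numeric(1)) == 4), TRUE)))
  ## toy molecule with 2 charged atoms -> 6 forests
  model2 <- train_charge_model(ds$structures, ds$charges, config = cfg,
                               atoms = c(0L, 12L))
  expect_identical(n_forests(model2), 6L)
})

test_that("misaligned or incomplete charge tables are rejected", {
  ds <- tiny_dataset()
  cfg <- forest_config(n_trees = 2, seed = 1)
  expect_error(
    train_charge_model(ds$structures, ds$charges[ds$charges$frame > 4, ],
                       config = cfg),
    "frames without charges", class = "cac_data_error")
  no_quint <- ds$charges[, setdiff(names(ds$charges), "q_quintuplet")]
  expect_error(train_charge_model(ds$structures, no_quint, config = cfg),
               class = "cac_format_error")
})

test_that("prediction equals the tree-ensemble mean and population spread", {
  ds <- tiny_dataset()
  model <- train_charge_model(ds$structures[1:20],
                              ds$charges[ds$charges$frame < 20, ],
                              config = forest_config(n_trees = 7, seed = 3))
  probe <- ds$structures[21:26]
  pred <- predict(model, probe)
  expect_identical(nrow(pred), 6L * 14L)
  for (ai in c(0L, 5L, 13L)) {
    for (sp in names(spin_states())) {
      P <- tree_predictions(model, ai, sp, probe)
      expect_identical(ncol(P), 7L)
      rows <- pred$atom_index == ai
      q_mean <- rowMeans(P)
      q_std <- sqrt(rowMeans((P - q_mean)^2))  # denominator B
      expect_lt(max(abs(pred[rows, paste0("q_", sp)] - q_mean)), 1e-12)
      expect_lt(max(abs(pred[rows, paste0("q_std_", sp)] - q_std)), 1e-12)
      ## mean lies inside the tree envelope, spread is non-negative
      expect_true(all(q_mean >= apply(P, 1, min) - 1e-12))
      expect_true(all(q_mean <= apply(P, 1, max) + 1e-12))
      expect_true(all(pred[rows, paste0("q_std_", sp)] >= 0))
    }
  }
})

test_that("hand-built tree outputs reproduce the aggregation formulas", {
  ## {1.0, 1.4, 1.2}: mean 1.2, population std sqrt(0.08/3)
  P <- matrix(c(1.0, 1.4, 1.2), 1, 3)
  agg <- cacharge:::aggregate_trees(P)
  expect_equal(agg$q_mean, 1.2, tolerance = 1e-15)
  expect_equal(agg$q_std, 0.1632993162, tolerance = 1e-9)
  ## all trees agree -> zero spread; B = 1 -> the single output, zero spread
  expect_identical(cacharge:::aggregate_trees(matrix(1.2, 1, 3))$q_std, 0)
  agg1 <- cacharge:::aggregate_trees(matrix(0.7, 1, 1))
  expect_identical(agg1$q_mean, 0.7)
  expect_identical(agg1$q_std, 0)
  ## duplicating every tree changes neither mean nor denominator-B spread
  agg2 <- cacharge:::aggregate_trees(cbind(P, P))
  expect_equal(agg2$q_mean, agg$q_mean, tolerance = 1e-15)
  expect_equal(agg2$q_std, agg$q_std, tolerance = 1e-15)
})

test_that("training is deterministic and order-independent via seed fan-out", {
  ds <- tiny_dataset()
  cfg <- forest_config(n_trees = 5, seed = 8)
  sub <- ds$charges
  m1 <- train_charge_model(ds$structures, sub, config = cfg, atoms = c(0L, 3L))
  m2 <- train_charge_model(ds$structures, sub, config = cfg, atoms = c(3L, 0L))
  probe <- ds$structures[1:3]
  expect_identical(predict(m1, probe), predict(m2, probe))
  p1 <- predict(m1, probe)
  p2 <- predict(train_charge_model(ds$structures, sub, config = cfg,
                                   atoms = c(0L, 3L)), probe)
  expect_identical(p1, p2)
})

test_that("model archives round-trip bit-identically and reject bad files", {
  ds <- tiny_dataset()
  model <- train_charge_model(ds$structures[1:10],
                              ds$charges[ds$charges$frame < 10, ],
                              config = forest_config(n_trees = 3, seed = 2),
                              atoms = 0:2)
  path <- withr::local_tempfile(fileext = ".rds")
  save_charge_model(model, path)
  back <- load_charge_model(path)
  probe <- ds$structures[11:20]
  expect_identical(predict(back, probe), predict(model, probe))
  ## unknown version tag
  saveRDS(list(format = "cacharge-model", format_version = 99L, model = model), path)
  expect_error(load_charge_model(path), "version", class = "cac_format_error")
  ## not an archive at all
  saveRDS(list(a = 1), path)
  expect_error(load_charge_model(path), class = "cac_format_error")
  ## truncated file
  writeLines("not an rds", path)
  expect_error(load_charge_model(path), class = "cac_io_error")
  ## composition mismatch at prediction time
  other <- random_structure(5)
  expect_error(predict(model, other), class = "cac_layout_error")
})

test_that("held-out error does not degrade as the forest grows", {
  ds <- generate_dataset(generator_params(n_frames = 160, seed = 55))
  ids <- vapply(ds$structures, function(s) s$frame_id, integer(1))
  sp <- split_frames(ids, 0.5, 6)
  tr <- ds$structures[ids %in% sp$train]
  te <- ds$structures[ids %in% sp$test]
  ctr <- ds$charges[ds$charges$frame %in% sp$train, ]
  cte <- ds$charges[ds$charges$frame %in% sp$test, ]
  mae_b <- vapply(c(50, 200, 800), function(B) {
    m <- train_charge_model(tr, ctr, config = forest_config(n_trees = B, m = 5, seed = 6),
                            atoms = 0L)
    mean(evaluate_model(m, te, cte)$per_atom$mae)
  }, numeric(1))
  expect_lt(mae_b[2], mae_b[1] * 1.10)
  expect_lt(mae_b[3], mae_b[1] * 1.10)
})
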