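# Label clipping, Kennard-Stone splits, the training loop and metrics.

test_that("label clipping applies the detection window and is idempotent", {
  expect_equal(clip_labels(c(-9.3, -3.8, -6.0, -8, -4)),
               c(-8, -4, -6.0, -8, -4))
  x <- c(-10, -7.77, -4.001)
  expect_identical(clip_labels(clip_labels(x)), clip_labels(x))
  expect_error(clip_labels(c(-6, NA)), class = "pepperm_input_error")
  expect_error(clip_labels(c(-6, Inf)), class = "pepperm_input_error")
})

test_that("Kennard-Stone selection is deterministic and matches the naive rule", {
  toy <- rbind(c(0, 0, 0, 0), c(0, 0, 0, 1), c(1, 1, 1, 1))
  expect_identical(kennard_stone_split(toy, 2 / 3), c(1L, 3L))

  set.seed(21)
  x <- matrix(rbinom(20 * 8, 1, 0.5), 20, 8)
  sel <- kennard_stone_split(x, 0.25)
  expect_identical(sel, kennard_stone_split(x, 0.25))
  expect_identical(sel, as.integer(ks_naive(x, 5)))
  expect_length(sel, 5)

  expect_error(kennard_stone_split(x, 0), class = "pepperm_input_error")
  expect_error(kennard_stone_split(x, 1), class = "pepperm_input_error")
})

test_that("split plans are disjoint, covering and sized as requested", {
  set.seed(33)
  ids <- sprintf("p%02d", 1:40)
  fps <- matrix(rbinom(40 * 16, 1, 0.4), 40, 16)
  plan <- split_plan(ids, fps, test_fraction = 0.05, val_fraction = 0.1,
                     n_folds = 3, seed = 4)
  expect_length(plan$test_ids, 2)                  # ceiling(0.05 * 40)
  expect_true(all(lengths(plan$validation_ids) == 4))
  # pairwise disjoint
  all_val <- unlist(plan$validation_ids)
  expect_identical(anyDuplicated(c(plan$test_ids, all_val)), 0L)
  # train/validation/test partition the ids for each fold
  for (f in 1:3) {
    expect_setequal(c(train_ids(plan, f), plan$validation_ids[[f]],
                      plan$test_ids), ids)
  }
})

test_that("metrics match hand computations and flag degenerate labels", {
  m0 <- evaluate(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m0$mae, 0); expect_equal(m0$mse, 0)
  expect_equal(m0$r, 1); expect_equal(m0$r2, 1)

  m1 <- evaluate(c(1.5, 2.5, 3.5), c(1, 2, 3))
  expect_equal(m1$mae, 0.5)
  expect_equal(m1$mse, 0.25)
  expect_equal(m1$r, 1)
  expect_equal(m1$r2, 1 - 0.75 / 2)

  m2 <- evaluate(c(3, 2, 1), c(1, 2, 3))
  expect_equal(m2$r, -1)

  md <- evaluate(c(1, 2, 3), c(2, 2, 2))
  expect_true(md$degenerate)
  expect_true(is.na(md$r))
  # mse >= mae^2 on random inputs
  set.seed(5)
  for (i in 1:10) {
    m <- evaluate(rnorm(6), rnorm(6))
    expect_gte(m$mse, m$mae^2 - 1e-12)
  }
})

test_that("training is reproducible and collapses to the fusion loss when unweighted", {
  cf <- tiny_config(epochs = 3, patience = 3, batch = 4,
                    gamma_sub = 0, gamma_layer = 0)
  rows <- lapply(1:8, function(i) toy_sample(cf, seed = i))
  f1 <- train_model(rows, rows[1:2], cf, seed = 2)
  f2 <- train_model(rows, rows[1:2], cf, seed = 2)
  expect_identical(f1$history, f2$history)
  expect_equal(f1$history$train_total, f1$history$train_fusion)

  cf2 <- tiny_config(epochs = 2, patience = 2, batch = 4)
  f3 <- train_model(rows, rows[1:2], cf2, seed = 2)
  expect_true(all(f3$history$train_total >= f3$history$train_fusion - 1e-12))
  expect_error(train_model(list(), rows, cf2), class = "pepperm_input_error")
})

test_that("ensemble prediction is the mean of replica outputs, within their range", {
  cf <- tiny_config()
  params <- init_pepperm_params(cf, seed = 19)
  rows <- lapply(1:4, function(i) toy_sample(cf, seed = 100 + i))
  per <- predict_rows(rows, params, cf)
  ens <- predict_ensemble(params, cf, rows)
  expect_equal(ens, mean(per))
  expect_gte(ens, min(per)); expect_lte(ens, max(per))
  expect_equal(predict_ensemble(params, cf, rows[1]), per[1])
  expect_error(predict_ensemble(params, cf, list()),
               class = "pepperm_input_error")
})

test_that("standardizers are fitted on training peptides only (no leakage)", {
  feats <- small_features()
  ids <- vapply(feats$records, `[[`, "", "id")
  cf <- tiny_config(n_max = 128, max_len = 16)
  train_only <- pepperm:::prepare_rows(feats, ids[1:6], cf)
  all_data <- pepperm:::prepare_rows(feats, ids, cf)
  # refitting on all data changes the standardizer, hence the validation
  # features of a held-out peptide
  expect_gt(max(abs(train_only$std_desc$means - all_data$std_desc$means)), 0)
  row_t <- pepperm:::rows_for_ids(train_only$rows, ids[7])[[1]]
  row_a <- pepperm:::rows_for_ids(all_data$rows, ids[7])[[1]]
  expect_gt(max(abs(row_t$desc - row_a$desc)), 0)
  # atom-level features are untouched by the standardizer
  expect_identical(row_t$node, row_a$node)
  expect_identical(row_t$sg, row_a$sg)
})
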