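test_that("parameter count matches the closed-form arithmetic", {
  hp <- hyperparams(conv_filters = 8, conv_width = 4, pool_width = 4,
                    pool_stride = 4, dense_units = 16)
  L <- 100
  m <- build_model(hp, L, seed = 1)
  Lc <- L - 4 + 1                       # 97
  Lq <- (Lc - 4) %/% 4 + 1              # 24
  expected <- (4 * 4 * 8 + 8) +         # conv kernel + bias
    (Lq * 8 * 16 + 16) +                # dense hidden
    (16 * 1 + 1)                        # output unit
  expect_equal(n_params(m), expected)
})

test_that("the best up-DEG grid architecture builds on L = 3000", {
  hp <- hyperparams(conv_filters = c(128, 128), conv_width = 4,
                    pool_width = 4, pool_stride = 4, dropout_rate = 0.25,
                    dense_units = c(64, 128))
  expect_equal(hp$n_conv_layers, 2)
  expect_equal(hp$n_dense_layers, 3)    # output layer counted
  m <- build_model(hp, 3000, seed = 1)
  expect_s3_class(m, "cnn_model")
})

test_that("impossible pooling chains are rejected with the layer named", {
  hp <- hyperparams(conv_filters = 4, conv_width = 4, pool_width = 4,
                    pool_stride = 2000)
  expect_error(build_model(hp, 100), "pool_stride")
  hp2 <- hyperparams(conv_filters = c(4, 4, 4), conv_width = 8,
                     pool_width = 8, pool_stride = 8)
  expect_error(build_model(hp2, 120), "layer 2")
  expect_error(hyperparams(conv_filters = 0), "positive")
  expect_error(hyperparams(dropout_rate = 1), "dropout")
})

test_that("zero-epoch training is rejected", {
  s <- make_spike_set(40, seed = 1)
  hp <- hyperparams(conv_filters = 4, conv_width = 5, pool_width = 4,
                    pool_stride = 4, dense_units = 4)
  m <- build_model(hp, 60, seed = 1)
  expect_error(train(m, s, s, epochs = 0), "epochs")
})

test_that("a 1-conv-layer model learns the deterministic spike", {
  train_s <- make_spike_set(300, pos_frac = 0.25, seed = 2)
  val_s <- make_spike_set(120, pos_frac = 0.25, seed = 3)
  test_s <- make_spike_set(120, pos_frac = 0.25, seed = 4)
  hp <- hyperparams(conv_filters = 8, conv_width = 5, pool_width = 4,
                    pool_stride = 4, dense_units = 8, dropout_rate = 0,
                    learning_rate = 2e-3, epochs = 25, batch_size = 32)
  m <- build_model(hp, 60, seed = 2)
  rec <- train(m, oversample(train_s, seed = 2), val_s,
               test_set = test_s, seed = 2)
  expect_gte(rec$prauc_test, 0.9)
  expect_lt(rec$class_diff, 0.4)
  # consistency of the record with a from-scratch evaluation
  ev <- evaluate(rec$model, test_s)
  expect_equal(ev$prauc_test, rec$prauc_test)
  expect_equal(ev$class_diff,
               abs(ev$acc_class_deg - ev$acc_class_non))
})

test_that("shuffled labels keep the test prAUC near the positive fraction", {
  set.seed(9)
  train_s <- make_spike_set(300, pos_frac = 0.2, seed = 5)
  train_s$label <- sample(train_s$label)   # break the signal
  val_s <- make_spike_set(100, pos_frac = 0.2, seed = 6)
  val_s$label <- sample(val_s$label)
  test_s <- make_spike_set(120, pos_frac = 0.2, seed = 7)
  test_s$label <- sample(test_s$label)
  hp <- hyperparams(conv_filters = 4, conv_width = 5, pool_width = 4,
                    pool_stride = 4, dense_units = 4, dropout_rate = 0,
                    learning_rate = 1e-3, epochs = 5, batch_size = 32)
  rec <- train(build_model(hp, 60, seed = 3), oversample(train_s, seed = 3),
               val_s, test_set = test_s, seed = 3)
  pos_frac <- mean(test_s$label == 0)
  expect_lt(abs(rec$prauc_test - pos_frac), 0.25)
})

test_that("grid search returns one record per point and is deterministic", {
  data <- list(train = oversample(make_spike_set(120, seed = 11), seed = 1),
               validation = make_spike_set(60, seed = 12),
               test = make_spike_set(60, seed = 13))
  grid <- hyper_grid(conv_layers = 1, filters = c(2, 4), conv_width = c(4, 5),
                     pool_width = 4, pool_stride = 4, dense_hidden = 1,
                     dense_units = 4, dropout = c(0, 0.1), epochs = 2)
  expect_length(grid, 8)
  recs <- grid_search(grid, data, seed = 1)
  expect_length(recs, 8)
  df <- as.data.frame(recs)
  expect_equal(nrow(df), 8)
  expect_true(all(is.na(df$error)))
  expect_true(all(df$prauc_test >= 0 & df$prauc_test <= 1))

  # identical grid points give identical metrics under one seed
  recs2 <- grid_search(list(grid[[1]], grid[[1]]), data, seed = 1)
  expect_equal(recs2[[1]]$prauc_test, recs2[[2]]$prauc_test)
  expect_equal(recs2[[1]]$loss, recs2[[2]]$loss)

  # checkpoints make the search resumable
  ck <- withr::local_tempdir()
  r1 <- grid_search(grid[1:2], data, seed = 1, checkpoint_dir = ck)
  expect_length(list.files(ck, pattern = "json$"), 2)
  r2 <- grid_search(grid[1:2], data, seed = 1, checkpoint_dir = ck)
  expect_equal(as.data.frame(r2)$prauc_test, as.data.frame(r1)$prauc_test)

  s <- summary(recs)
  expect_true(is.finite(s$median_prauc_test))
  expect_gte(s$overfit_fraction, 0)
})

test_that("failed grid points are recorded, not fatal", {
  data <- list(train = oversample(make_spike_set(60, seed = 14), seed = 1),
               validation = make_spike_set(40, seed = 15),
               test = make_spike_set(40, seed = 16))
  bad <- hyperparams(conv_filters = 4, conv_width = 5, pool_width = 70,
                     pool_stride = 4, epochs = 1)
  ok <- hyperparams(conv_filters = 4, conv_width = 5, pool_width = 4,
                    pool_stride = 4, epochs = 1)
  recs <- grid_search(list(bad, ok), data, seed = 1)
  df <- as.data.frame(recs)
  expect_false(is.na(df$error[1]))
  expect_true(is.na(df$error[2]))
})

test_that("select_best applies the prAUC filter then the balance rule", {
  fake <- function(prauc, diff) {
    structure(list(hyperparams = hyperparams(conv_filters = 4),
                   prauc_test = prauc, class_diff = diff),
              class = "model_record")
  }
  recs <- structure(list(fake(0.72, 0.4), fake(0.71, 0.3)),
                    class = "model_records")
  expect_equal(select_best(recs)$prauc_test, 0.71)
  recs2 <- structure(list(fake(0.65, 0.1), fake(0.69, 0.05)),
                     class = "model_records")
  expect_message(out <- select_best(recs2), "no model")
  expect_null(out)
  recs3 <- structure(list(fake(0.72, 0.3), fake(0.75, 0.3)),
                     class = "model_records")
  expect_equal(select_best(recs3)$prauc_test, 0.75)
})

test_that("overfit flags follow the prAUC thresholds", {
  expect_equal(degcnn:::.overfit_flag(0.85), "to_deg")
  expect_equal(degcnn:::.overfit_flag(0.15), "to_non")
  expect_equal(degcnn:::.overfit_flag(0.5), "none")
})

test_that("permutation significance is 0 on separable data", {
  data <- list(train = make_spike_set(300, pos_frac = 0.25, seed = 21),
               validation = make_spike_set(100, pos_frac = 0.25, seed = 22),
               test = make_spike_set(100, pos_frac = 0.25, seed = 23))
  hp <- hyperparams(conv_filters = 8, conv_width = 5, pool_width = 4,
                    pool_stride = 4, dense_units = 8, dropout_rate = 0,
                    learning_rate = 2e-3, epochs = 22, batch_size = 32)
  ps <- permutation_significance(hp, data, n_perm = 5, seed = 2)
  expect_gte(ps$observed$prauc_test, 0.85)
  expect_equal(ps$p_value, 0)
  expect_error(permutation_significance(hp, data, n_perm = 0), "n_perm")
})
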