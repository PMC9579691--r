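# SGD training, cross-validation machinery, and transfer initialisation.

test_that("training reduces the loss on separable data and is reproducible", {
  dat <- sim_training_data(n_per_class = 40, k = 10, signal_strength = 2,
                           seed = 5)
  cfg <- backbone_config("cnn_bilstm", window_length = 21,
                         conv_kernel_size = 5, pool_size = 4, seed = 1)
  m <- train_stage1(dat$train, cfg, epochs = 8, batch_size = 16, seed = 3)
  expect_lt(m$log$loss[8], m$log$loss[1])

  m2 <- train_stage1(dat$train, cfg, epochs = 8, batch_size = 16, seed = 3)
  expect_identical(m$params, m2$params)
  expect_identical(m$log, m2$log)

  m3 <- train_stage1(dat$train, cfg, epochs = 8, batch_size = 16, seed = 4)
  expect_false(identical(m$params, m3$params))
})

test_that("zero epochs returns the initialisation unchanged", {
  dat <- sim_training_data(n_per_class = 20, k = 10, seed = 6)
  cfg <- tiny_config(variant = "cnn")
  init <- build_model(cfg, "multitask")
  trained <- train_model(init, dat$train, epochs = 0)
  expect_identical(trained$params, init$params)
})

test_that("CV folds partition the data with per-class balance within one", {
  labels <- rep(c("positive", "negative"), c(53, 47))
  id <- make_cv_folds(labels, folds = 5, seed = 2)
  expect_length(id, 100)
  expect_setequal(unique(id), 1:5)
  for (lb in c("positive", "negative")) {
    sizes <- table(id[labels == lb])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_error(make_cv_folds(rep("positive", 3), folds = 5), "fewer samples")
})

test_that("grid search reports per-fold results and selects the argmax", {
  dat <- sim_training_data(n_per_class = 30, k = 10, signal_strength = 2,
                           seed = 7)
  base <- backbone_config("cnn", window_length = 21, conv_kernel_size = 5,
                          pool_size = 4, dropout_rate = 0, seed = 1)

  one <- grid_search_cv(dat$train, grid = list(conv_kernel_size = 5),
                        config = base, folds = 2, epochs = 1, batch_size = 16,
                        seed = 1)
  expect_identical(nrow(one$table), 2L)  # one combination, two folds

  cv <- grid_search_cv(dat$train,
                       grid = list(conv_kernel_size = c(3, 5),
                                   pool_size = c(2, 4)),
                       config = base, folds = 2, epochs = 1, batch_size = 16,
                       seed = 1)
  # each sample appears in exactly one validation fold
  fold_id <- make_cv_folds(dat$train$label, folds = 2, seed = 1)
  expect_setequal(unique(fold_id), 1:2)
  # the selected combination is the argmax of the emitted table
  recomputed <- cv$table |>
    dplyr::group_by(combo) |>
    dplyr::summarise(m = mean(auroc))
  expect_identical(cv$best$combo,
                   recomputed$combo[which.max(recomputed$m)])
  expect_s3_class(tidy(cv), "tbl_df")

  # invalid combinations are recorded as failed, not fatal
  bad <- grid_search_cv(dat$train, grid = list(conv_kernel_size = c(5, 4)),
                        config = base, folds = 2, epochs = 1,
                        batch_size = 16, seed = 1)
  expect_true(any(bad$table$failed))
  expect_identical(bad$best_config$conv_kernel_size, 5L)
})

test_that("transfer initialisation copies every non-head tensor bit-exactly", {
  dat <- sim_training_data(n_per_class = 24, k = 10, signal_strength = 2,
                           seed = 8)
  cfg <- backbone_config("cnn_bilstm", window_length = 21,
                         conv_kernel_size = 5, pool_size = 4, seed = 1)
  source <- train_stage1(dat$train, cfg, epochs = 2, batch_size = 16, seed = 1)
  target <- transfer_init(source, mode = "classify_only", seed = 99)

  for (nm in setdiff(names(target$params), c("head_class", "head_reg"))) {
    for (w in names(target$params[[nm]])) {
      expect_identical(target$params[[nm]][[w]], source$params[[nm]][[w]],
                       info = paste(nm, w))
    }
  }
  # the classification head is freshly initialised, not copied
  expect_false(identical(target$params$head_class, source$params$head_class))
  expect_identical(target$stage, "stage2")
  expect_null(target$params$head_reg)

  # a scratch model with the same seed differs from the transfer init
  scratch_cfg <- cfg; scratch_cfg$seed <- 99L
  scratch <- build_model(scratch_cfg, "classify_only")
  expect_false(identical(scratch$params$conv$W, target$params$conv$W))
})

test_that("transfer learning runs CV for transfer and scratch strategies", {
  dat <- sim_training_data(n_per_class = 24, k = 10, signal_strength = 2,
                           seed = 9, stage2_shift = 1)
  cfg <- backbone_config("cnn_bilstm", window_length = 21,
                         conv_kernel_size = 5, pool_size = 4, seed = 1)
  source <- train_stage1(dat$train, cfg, epochs = 2, batch_size = 16, seed = 1)

  sim <- dat$sim
  atlas <- sim$positives[sim$truth$stage2[sim$truth$label == "positive"], ]
  s2 <- build_stage2_dataset(atlas, sim$positives, sim$genome, k = 10,
                             threshold = 1, seed = 1)
  res <- transfer_stage2(source, s2$train, epochs_grid = c(1, 2),
                         scratch_grids = list(c(1, 2), c(3, 4)),
                         folds = 2, seed = 1, batch_size = 16)
  expect_setequal(unique(res$cv$strategy), c("transfer", "scratch1", "scratch2"))
  expect_identical(nrow(res$cv), 12L)  # 3 strategies x 2 epochs x 2 folds
  expect_identical(res$model$stage, "stage2")
  expect_identical(res$model$mode, "classify_only")
  expect_identical(nrow(res$best), 3L)
})
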