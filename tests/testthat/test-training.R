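test_that("patient-wise folds balance patients and never split one", {
  recs <- list()
  for (p in 1:9) for (i in 1:2) {
    id <- sprintf("p%d_i%d", p, i)
    recs[[length(recs) + 1L]] <- list(
      image_id = id, patient_id = sprintf("pat%d", p), pixels = NULL,
      annotations = annotation_set(id, 5L, 1L))
  }
  ds <- new_dataset(recs, panel_size = 14L)
  folds <- patient_wise_folds(ds, 3L, seed = 1L)
  pids <- vapply(ds$records, `[[`, "", "patient_id")
  per_fold <- tapply(pids, folds, function(x) length(unique(x)))
  expect_equal(as.vector(per_fold), c(3L, 3L, 3L))
  for (p in unique(pids))
    expect_length(unique(folds[pids == p]), 1L)
  expect_identical(folds, patient_wise_folds(ds, 3L, seed = 1L))
  expect_false(identical(folds, patient_wise_folds(ds, 3L, seed = 2L)))
  expect_error(patient_wise_folds(ds, 10L, seed = 1L), "fewer patients")
})

test_that("validation filtering keeps only low-uncertainty records", {
  ds <- tiny_dataset()  # D values: 0, 0, 3.5, ~3.22, 1, 1
  kept <- filter_validation(ds, tau_val = 2)
  expect_setequal(vapply(kept$records, `[[`, "", "image_id"),
                  c("i1", "i2", "i5", "i6"))
  expect_length(filter_validation(ds, tau_val = Inf), 6L)
  # tau_val = 0 keeps exactly the unanimous-extreme records
  kept0 <- filter_validation(ds, tau_val = 0)
  expect_setequal(vapply(kept0$records, `[[`, "", "image_id"),
                  c("i1", "i2"))
  expect_warning(filter_validation(dataset_subset(ds, 3:4), tau_val = 0),
                 "no records")
})

test_that("early stopping fires after patience epochs without improvement", {
  b <- quick_benchmark()
  split <- patient_wise_folds(b$train$dataset, 3L, seed = 1L)
  tr <- dataset_subset(b$train$dataset, which(split != 1L))
  va <- filter_validation(dataset_subset(b$train$dataset,
                                         which(split == 1L)), 2)
  # zero learning rates freeze the model, so the validation loss is flat
  # from epoch 1: training must stop at epoch 1 + patience
  tc <- train_config(lr_encoder = 0, lr_rest = 0, max_epochs = 20L,
                     patience = 3L)
  fr <- train_fold(tr, va, network_config(), tc, "fine_tune", seed = 2L)
  expect_equal(fr$best_epoch, 1L)
  expect_equal(nrow(fr$history), 4L)
  expect_equal(fr$best_validation_loss, fr$history$val_loss[1])
  # an improving run keeps the argmin of the validation trace
  tc2 <- quick_tc(max_epochs = 4L, patience = 4L)
  fr2 <- train_fold(tr, va, network_config(), tc2, "fine_tune", seed = 2L)
  expect_equal(fr2$best_epoch, which.min(fr2$history$val_loss))
  expect_error(train_fold(tr, dataset_subset(va, integer(0)),
                          network_config(), tc2, "fine_tune"),
               "empty")
})

test_that("cross-validation trains one model per fold, reproducibly", {
  b <- quick_benchmark()
  tc <- quick_tc(max_epochs = 2L, n_folds = 3L)
  cv1 <- crossval(b$train$dataset, network_config(), tc, "proposed",
                  seed = 5L)
  expect_length(cv1, 3L)
  cv2 <- crossval(b$train$dataset, network_config(), tc, "proposed",
                  seed = 5L)
  expect_identical(lapply(cv1, `[[`, "history"),
                   lapply(cv2, `[[`, "history"))
})

test_that("grid search picks the argmin with deterministic tie-breaks", {
  b <- quick_benchmark()
  tc <- quick_tc(max_epochs = 2L, n_folds = 2L, seed_search = 3L)
  gs <- grid_search(b$train$dataset, network_config(), tc, "fine_tune",
                    lr_encoder_grid = c(1e-3, 1e-4),
                    lr_rest_grid = 1e-3)
  expect_equal(nrow(gs$table), 2L)
  best_row <- which.min(gs$table$mean_val_loss)
  expect_equal(gs$lr_encoder, gs$table$lr_encoder[best_row])
  expect_equal(gs$mean_val_loss, min(gs$table$mean_val_loss))
  # single-point grid returns that pair
  gs1 <- grid_search(b$train$dataset, network_config(), tc, "fine_tune",
                     lr_encoder_grid = 1e-3, lr_rest_grid = 5e-4)
  expect_equal(c(gs1$lr_encoder, gs1$lr_rest), c(1e-3, 5e-4))
})

test_that("experiments keep the holdout untouched and patients disjoint", {
  b <- quick_benchmark()
  tc <- quick_tc(max_epochs = 2L, n_folds = 2L)
  expect_error(run_experiment(b$train$dataset, b$train$dataset,
                              network_config(), tc, "proposed"),
               "overlap")
  ex <- run_experiment(b$train$dataset, b$holdout$dataset,
                       network_config(), tc, "proposed")
  expect_true(ex$holdout_untouched_during_training)
  expect_length(ex$metrics, 2L)
  expect_length(ex$mean, 8L)
  expect_length(ex$sd, 8L)
  # holdout was read during evaluation
  expect_gt(access_count(b$holdout$dataset), 0L)
  # metrics-level reproducibility under fixed seeds
  b2 <- quick_benchmark()
  ex2 <- run_experiment(b2$train$dataset, b2$holdout$dataset,
                        network_config(), tc, "proposed")
  expect_identical(ex$mean, ex2$mean)
})

test_that("gated training with an unreachable threshold equals zeroed TRAM", {
  b <- quick_benchmark()
  split <- patient_wise_folds(b$train$dataset, 3L, seed = 1L)
  tr <- dataset_subset(b$train$dataset, which(split != 1L))
  va <- filter_validation(dataset_subset(b$train$dataset,
                                         which(split == 1L)), 2)
  tc <- quick_tc(max_epochs = 3L)
  gated <- train_fold(tr, va, network_config(tau = 10), tc, "proposed",
                      seed = 4L)
  zeroed <- train_fold(tr, va, network_config(zero_privileged = TRUE), tc,
                       "tram_ord", seed = 4L)
  expect_identical(gated$history, zeroed$history)
})
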