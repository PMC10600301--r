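# Training harness: optimiser contracts, pretraining determinism, weight
# transfer, fine-tuning behaviour, grid search, ablation table, metrics.

small_cfg <- function(wfp_epochs = 2L, wfc_epochs = 4L, lr = 0.05,
                      wfc_lr = 1e-3, seed = 1L) {
  train_config(wfp = list(epochs = wfp_epochs, learning_rate = lr),
               wfc = list(epochs = wfc_epochs, learning_rate = wfc_lr,
                          batch_size = 16L),
               seed = seed)
}

small_comp <- function() composition_preset("50/0/50", 4L)

test_that("a zero learning rate leaves parameters unchanged and identical
           seeds give identical loss traces", {
  set <- random_tensor_set(n = 16L, s = 2L, seed = 1L)
  m <- build_model(seed = 1L)
  pre0 <- pretrain_wfp(set, m, small_cfg(wfp_epochs = 1L, lr = 0),
                       small_comp())
  expect_equal(pre0$model$params, m$params)
  pre_a <- pretrain_wfp(set, m, small_cfg(seed = 5L), small_comp())
  pre_b <- pretrain_wfp(set, m, small_cfg(seed = 5L), small_comp())
  expect_identical(pre_a$loss_trace, pre_b$loss_trace)
  expect_equal(pre_a$model$params, pre_b$model$params)
  pre_c <- pretrain_wfp(set, m, small_cfg(seed = 6L), small_comp())
  expect_false(identical(pre_a$loss_trace, pre_c$loss_trace))
})

test_that("weight transfer copies the backbone bit-exactly, reinitialises the
           head, and preserves the encoder's forward map", {
  set <- random_tensor_set(n = 16L, s = 2L, seed = 2L)
  m <- build_model(seed = 3L)
  pre <- pretrain_wfp(set, m, small_cfg(wfp_epochs = 1L), small_comp())
  wfc1 <- transfer_weights(pre$model, seed = 10L)
  wfc2 <- transfer_weights(pre$model, seed = 11L)
  expect_identical(wfc1$params$leads, pre$model$params$leads)
  expect_identical(wfc1$params$sen, pre$model$params$sen)
  expect_identical(wfc1$params$enc, pre$model$params$enc)
  expect_identical(wfc1$state, pre$model$state)
  expect_false(identical(wfc1$params$clf, wfc2$params$clf))
  probe <- array(abs(rnorm(17 * 39 * 11)), c(17, 39, 11))
  expect_equal(wf_forward(wfc1, probe, head = "encode")$r,
               wf_forward(pre$model, probe, head = "encode")$r)
  other <- build_model(wf_model_config(enc_dim = 64L), seed = 1L)
  expect_error(transfer_weights(pre$model,
                                expect_fingerprint = other$fingerprint),
               class = "wf_config_error")
})

test_that("fine-tuning separates an easily separable set and rejects
           single-class training data", {
  set <- random_tensor_set(n = 32L, s = 2L, seed = 4L)
  # plant a large class difference: class-1 tensors get a strong additive
  # component on three leads' alpha rows
  for (i in which(set$y1 == 1L))
    set$x[i, 1:3, 6:10, ] <- set$x[i, 1:3, 6:10, ] + 10
  sp <- split_tensor_set(set, 0.5, seed = 1L)
  m <- build_model(seed = 5L)
  ft <- finetune_wfc(sp$a, m, small_cfg(wfc_epochs = 25L, wfc_lr = 3e-3),
                     test_set = sp$b)
  expect_equal(ft$report$accuracy, 1.0)
  single <- subset_ts <- wavefusion:::subset_tensor_set(set, which(set$y1 == 1L))
  expect_error(finetune_wfc(single, m, small_cfg()), class = "wf_data_error")
})

test_that("label-shuffled data yields chance-level accuracy", {
  set <- random_tensor_set(n = 48L, s = 2L, seed = 6L)
  set$y1 <- wavefusion:::with_seed(7L, sample(set$y1))   # break any structure
  sp <- split_tensor_set(set, 0.5, seed = 2L)
  m <- build_model(seed = 6L)
  ft <- finetune_wfc(sp$a, m, small_cfg(wfc_epochs = 6L), test_set = sp$b)
  # 99% binomial band around 0.5 at n = 24
  expect_gte(ft$report$accuracy, 0.2)
  expect_lte(ft$report$accuracy, 0.8)
})

test_that("grid search reports one row per point and breaks ties toward the
           smallest weight decay", {
  set <- random_tensor_set(n = 16L, s = 2L, seed = 8L)
  sp <- split_tensor_set(set, 0.5, seed = 3L)
  m <- build_model(seed = 7L)
  one <- grid_search(sp$a, sp$b, m, 7e-3, small_cfg(wfc_epochs = 1L))
  expect_equal(one$best_weight_decay, 7e-3)
  expect_equal(nrow(one$results), 1L)
  gs <- grid_search(sp$a, sp$b, m, c(7e-3, 1e-4, 1e-2),
                    small_cfg(wfc_epochs = 1L))
  expect_equal(nrow(gs$results), 3L)
  expect_identical(gs$results$weight_decay, sort(c(7e-3, 1e-4, 1e-2)))
  best <- gs$results$weight_decay[which.max(gs$results$val_accuracy)]
  expect_equal(gs$best_weight_decay, best)
  expect_error(grid_search(sp$a, sp$b, m, numeric(), small_cfg()),
               class = "wf_config_error")
})

test_that("the ablation matrix yields one row per configuration and the
           SEN-off model has unit attention", {
  set <- random_tensor_set(n = 16L, s = 2L, seed = 9L)
  sp <- split_tensor_set(set, 0.5, seed = 4L)
  ab <- run_ablation(sp$a, sp$a, sp$b,
                     cfg = small_cfg(wfp_epochs = 1L, wfc_epochs = 1L),
                     composition = small_comp())
  expect_equal(nrow(ab$table), 4L)
  expect_true(all(c("pretraining", "sen", "accuracy") %in% names(ab$table)))
  off <- which(!ab$table$sen)[1]
  x <- array(set$x[1, , , ], dim(set$x)[-1])
  expect_equal(as.numeric(extract_attention(ab$reports[[off]]$model, x)),
               rep(1, 17))
})

test_that("evaluation metrics match hand-computed confusion arithmetic", {
  # confusion [[40, 10], [5, 45]]
  labels <- rep(c(0L, 1L), each = 50L)
  preds <- c(rep(0L, 40), rep(1L, 10), rep(0L, 5), rep(1L, 45))
  rep_ <- evaluate(preds, labels)
  expect_equal(rep_$accuracy, 0.85)
  expect_equal(unname(rep_$class_accuracy["class0"]), 0.8)
  f1_0 <- 2 * (40 / 45) * (40 / 50) / ((40 / 45) + (40 / 50))
  expect_equal(unname(rep_$f1["class0"]), f1_0, tolerance = 1e-12)
  # perfect predictions
  perfect <- evaluate(labels, labels)
  expect_equal(perfect$accuracy, 1)
  expect_equal(unname(perfect$f1), c(1, 1))
  # all-one-class predictions on balanced labels
  allones <- evaluate(rep(1L, 100), labels)
  expect_equal(allones$accuracy, 0.5)
  expect_error(evaluate(integer(), integer()), class = "wf_data_error")
})
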