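# Training harness: contrastive pretraining (WFP), weight transfer,
# supervised fine-tuning (WFC), weight-decay grid search, component
# ablations and evaluation metrics.

#' Training configuration
#'
#' Defaults follow the published protocol: the projection network is trained
#' for 25 epochs with plain SGD at a fixed learning rate of 0.05 and loss
#' temperature 0.25; the classifier is fine-tuned with Adam at learning rate
#' 1e-4 for 150 epochs, weight decay 7e-3 (grid-searched).
#'
#' @param wfp list: `epochs`, `learning_rate`, `optimizer`, `tau_sac`.
#' @param wfc list: `epochs`, `optimizer`, `learning_rate`, `weight_decay`,
#'   `batch_size`.
#' @param seed master seed for batching, augmentation and initialisation.
#' @return a list of class `wf_train_config`.
#' @export
train_config <- function(wfp = list(), wfc = list(), seed = 1L) {
  wfp_def <- list(epochs = 25L, learning_rate = 0.05, optimizer = "sgd",
                  tau_sac = 0.25)
  wfc_def <- list(epochs = 150L, optimizer = "adam", learning_rate = 1e-4,
                  weight_decay = 7e-3, batch_size = 50L)
  wfp <- utils::modifyList(wfp_def, wfp)
  wfc <- utils::modifyList(wfc_def, wfc)
  if (wfp$epochs < 1 || wfc$epochs < 1 || wfp$learning_rate < 0 ||
      wfc$learning_rate <= 0)
    wf_config_error("epochs must be >= 1 and learning rates nonnegative")
  structure(list(wfp = wfp, wfc = wfc, seed = as.integer(seed)),
            class = "wf_train_config")
}

# ---- optimisers -------------------------------------------------------------

sgd_update <- function(params, grads, lr, weight_decay = 0) {
  tree_map2(function(p, g) p - lr * (g + weight_decay * p), params, grads)
}

adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

adam_update <- function(params, grads, state, lr, weight_decay = 0,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  grads <- tree_map2(function(g, p) g + weight_decay * p, grads, params)
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  step <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                    state$m, state$v)
  list(params = tree_map2(`-`, params, step), state = state)
}

# ---- pretraining (WFP) ------------------------------------------------------

#' Contrastive pretraining of the projection network
#'
#' One epoch cycles over every (subject, class) key; each key's samples are
#' partitioned into positive blocks, so every training sample appears in the
#' positive role once per epoch. Negatives are drawn per the batch
#' composition. Two augmented views per sample are pushed through the
#' encoder and projection head, and the SAC (or SupCon) loss gradient is
#' backpropagated with SGD updates.
#'
#' @param set a `wf_tensor_set` of training samples.
#' @param model a `wf_model`.
#' @param cfg a [train_config()].
#' @param composition a [batch_composition_spec()]; its batch size must be
#'   compatible with the per-key sample counts.
#' @param aug an [augment_config()].
#' @param loss "sac" or "supcon".
#' @return list with the trained `model` and `loss_trace` (mean per-anchor
#'   loss per epoch).
#' @export
pretrain_wfp <- function(set, model, cfg = train_config(),
                         composition = composition_preset("50/0/50", 20L),
                         aug = augment_config(), loss = c("sac", "supcon")) {
  loss <- match.arg(loss)
  index <- data.frame(subject = set$y2, class = set$y1)
  keys <- unique(index)
  n_pos <- composition$counts[1]
  if (n_pos < 1L) wf_config_error("composition must include at least one positive")
  trace <- numeric(cfg$wfp$epochs)
  step <- 0L
  for (ep in seq_len(cfg$wfp$epochs)) {
    ep_losses <- c()
    for (ki in seq_len(nrow(keys))) {
      key <- list(keys$subject[ki], keys$class[ki])
      pool <- which(index$subject == key[[1]] & index$class == key[[2]])
      ord <- with_seed(derive_seed(cfg$seed, "order", ep, ki),
                       sample_from(pool, length(pool)))
      chunks <- split(ord, ceiling(seq_along(ord) / n_pos))
      for (ch in chunks) {
        if (length(ch) < n_pos) {
          extra <- setdiff(pool, ch)
          deficit <- n_pos - length(ch)
          ch <- c(ch, with_seed(derive_seed(cfg$seed, "fill", ep, ki, step),
                                sample_from(extra, deficit,
                                            replace = deficit > length(extra))))
        }
        step <- step + 1L
        idx <- compose_batch(index, key, composition,
                             seed = derive_seed(cfg$seed, "neg", ep, step),
                             positives = ch)
        vb <- build_view_batch(set, idx, aug,
                               seed = derive_seed(cfg$seed, "aug", ep, step))
        fw <- with_seed(derive_seed(cfg$seed, "drop", ep, step),
                        wf_forward(model, vb$x, training = TRUE,
                                   head = "project", keep_cache = TRUE))
        model <- fw$model
        lg <- if (loss == "sac") {
          sac_loss_grad(fw$z, vb$y1, vb$y2, cfg$wfp$tau_sac, reduce = "mean")
        } else {
          supcon_loss_grad(fw$z, vb$y1, cfg$wfp$tau_sac, reduce = "mean")
        }
        bk <- wf_backward(model, fw$cache, lg$grad)
        model$params <- sgd_update(model$params, bk$grads, cfg$wfp$learning_rate)
        ep_losses <- c(ep_losses, lg$loss)
      }
    }
    trace[ep] <- mean(ep_losses)
  }
  list(model = model, loss_trace = trace)
}

#' Transfer pretrained weights into a classifier model
#'
#' Copies the per-lead CNNs, the attention module, the encoder dense layer
#' and the batch-norm running statistics bit-exactly; the projection head is
#' dropped and the 2-node classifier head is freshly initialised.
#'
#' @param model a pretrained `wf_model` (the WFP).
#' @param seed seed for the fresh classifier head.
#' @param expect_fingerprint optional architecture fingerprint that `model`
#'   must match.
#' @return a `wf_model` ready for fine-tuning (the WFC).
#' @export
transfer_weights <- function(model, seed = 1L, expect_fingerprint = NULL) {
  if (!is.null(expect_fingerprint) &&
      !identical(as.character(expect_fingerprint), as.character(model$fingerprint)))
    wf_config_error("architecture fingerprint mismatch during weight transfer")
  wfc <- build_model(model$config, seed = seed)
  wfc$params$leads <- model$params$leads
  wfc$params$sen <- model$params$sen
  wfc$params$enc <- model$params$enc
  wfc$state <- model$state
  wfc
}

# ---- fine-tuning (WFC) ------------------------------------------------------

softmax_ce <- function(logits, labels) {
  p <- softmax_rows(logits)
  b <- nrow(logits)
  one <- cbind(labels == 0L, labels == 1L) * 1
  loss <- -mean(log(pmax(p[cbind(seq_len(b), labels + 1L)], 1e-12)))
  list(loss = loss, dlogits = (p - one) / b)
}

#' Fine-tune the classifier on labelled spectrogram tensors
#'
#' Tensors are fed without augmentation; all weights (including the
#' transferred backbone) are updated with Adam and the configured weight
#' decay.
#'
#' @param train_set a `wf_tensor_set` with both classes present.
#' @param model a `wf_model` (typically from [transfer_weights()]).
#' @param cfg a [train_config()].
#' @param test_set optional held-out `wf_tensor_set` for the final report.
#' @return list: trained `model`, `loss_trace`, and `report` (an `wf_eval`,
#'   when `test_set` is given).
#' @export
finetune_wfc <- function(train_set, model, cfg = train_config(),
                         test_set = NULL) {
  n <- length(train_set$y1)
  if (length(unique(train_set$y1)) < 2L)
    wf_data_error("training set contains a single class")
  bs <- min(cfg$wfc$batch_size, n)
  opt <- adam_init(model$params)
  trace <- numeric(cfg$wfc$epochs)
  for (ep in seq_len(cfg$wfc$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, "ft", ep), sample_from(seq_len(n), n))
    batches <- split(ord, ceiling(seq_along(ord) / bs))
    ep_loss <- 0
    bi <- 0L
    for (bidx in batches) {
      bi <- bi + 1L
      xb <- train_set$x[bidx, , , , drop = FALSE]
      fw <- with_seed(derive_seed(cfg$seed, "ftdrop", ep, bi),
                      wf_forward(model, xb, training = TRUE,
                                 head = "classify", keep_cache = TRUE))
      model <- fw$model
      ce <- softmax_ce(fw$logits, train_set$y1[bidx])
      bk <- wf_backward(model, fw$cache, ce$dlogits)
      upd <- adam_update(model$params, bk$grads, opt, cfg$wfc$learning_rate,
                         cfg$wfc$weight_decay)
      model$params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + ce$loss * length(bidx)
    }
    trace[ep] <- ep_loss / n
  }
  out <- list(model = model, loss_trace = trace)
  if (!is.null(test_set)) {
    pred <- predict_wfc(model, test_set)
    out$report <- evaluate(pred$class, test_set$y1)
  }
  out
}

#' Predict condition labels for spectrogram tensors
#'
#' @param model a trained `wf_model`.
#' @param set a `wf_tensor_set` (or bare tensor array).
#' @return list with `prob` (`n x 2` softmax matrix) and `class` (0/1).
#' @export
predict_wfc <- function(model, set) {
  x <- if (inherits(set, "wf_tensor_set")) set$x else set
  fw <- wf_forward(model, x, training = FALSE, head = "classify")
  p <- softmax_rows(fw$logits)
  list(prob = p, class = as.integer(max.col(p) - 1L))
}

#' Classification report
#'
#' Computes the confusion matrix, per-class F1, per-class accuracy (the
#' recall of that class — the only reading under which the two classes can
#' differ on a shared test set) and overall accuracy.
#'
#' @param predictions predicted labels (0/1).
#' @param labels true labels (0/1).
#' @return a list of class `wf_eval`: `confusion` (rows = truth), `f1`,
#'   `class_accuracy`, `accuracy`.
#' @export
evaluate <- function(predictions, labels) {
  if (length(predictions) == 0L || length(predictions) != length(labels))
    wf_data_error("predictions and labels must be equal-length and non-empty")
  cm <- matrix(0, 2, 2, dimnames = list(truth = c("0", "1"), pred = c("0", "1")))
  for (k in c(0L, 1L)) for (j in c(0L, 1L))
    cm[k + 1L, j + 1L] <- sum(labels == k & predictions == j)
  recall <- diag(cm) / pmax(rowSums(cm), 1)
  precision <- diag(cm) / pmax(colSums(cm), 1)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(list(confusion = cm,
                 f1 = stats::setNames(f1, c("class0", "class1")),
                 class_accuracy = stats::setNames(recall, c("class0", "class1")),
                 accuracy = sum(diag(cm)) / sum(cm)),
            class = "wf_eval")
}

#' @export
print.wf_eval <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.3f\n", x$accuracy))
  cat(sprintf("  class 0: F1 %.3f, accuracy (recall) %.3f\n",
              x$f1[1], x$class_accuracy[1]))
  cat(sprintf("  class 1: F1 %.3f, accuracy (recall) %.3f\n",
              x$f1[2], x$class_accuracy[2]))
  invisible(x)
}

#' Stratified split of a tensor set
#'
#' @param set a `wf_tensor_set`.
#' @param frac fraction assigned to the first part, within every
#'   (subject, class) cell.
#' @param seed integer seed.
#' @return list of two `wf_tensor_set`s (`a`, `b`).
#' @export
split_tensor_set <- function(set, frac = 0.5, seed = 1L) {
  idx_a <- integer()
  cells <- unique(data.frame(s = set$y2, c = set$y1))
  for (i in seq_len(nrow(cells))) {
    pool <- which(set$y2 == cells$s[i] & set$y1 == cells$c[i])
    k <- round(frac * length(pool))
    idx_a <- c(idx_a, with_seed(derive_seed(seed, "split", i),
                                sample_from(pool, k)))
  }
  idx_a <- sort(idx_a)
  list(a = subset_tensor_set(set, idx_a),
       b = subset_tensor_set(set, setdiff(seq_along(set$y1), idx_a)))
}

#' Grid search over weight decay
#'
#' Fine-tunes one model per grid value from the same starting weights and
#' returns the one with the best validation accuracy (ties broken by the
#' smallest weight decay).
#'
#' @param train_set,val_set `wf_tensor_set`s.
#' @param model starting `wf_model`.
#' @param weight_decays numeric grid (>= 1 value).
#' @param cfg a [train_config()].
#' @return list: `best_model`, `best_weight_decay`, `results` (one row per
#'   grid point with validation accuracy).
#' @export
grid_search <- function(train_set, val_set, model, weight_decays,
                        cfg = train_config()) {
  if (!length(weight_decays)) wf_config_error("need at least one grid point")
  weight_decays <- sort(weight_decays)
  runs <- lapply(weight_decays, function(wd) {
    cfg_wd <- cfg
    cfg_wd$wfc$weight_decay <- wd
    ft <- finetune_wfc(train_set, model, cfg_wd, test_set = val_set)
    list(model = ft$model, acc = ft$report$accuracy)
  })
  acc <- vapply(runs, `[[`, 1, "acc")
  best <- which.max(acc)            # first max = smallest weight decay on ties
  list(best_model = runs[[best]]$model,
       best_weight_decay = weight_decays[best],
       results = data.frame(weight_decay = weight_decays,
                            val_accuracy = acc))
}

#' Component ablation harness
#'
#' Runs the factorial ablation over pretraining scheme (subject-aware
#' contrastive, SupCon, or none) and attention module (on / off). "SEN off"
#' replaces every attention weight by 1; "none" fine-tunes from random
#' initialisation.
#'
#' @param pretrain_set,train_set,test_set `wf_tensor_set`s.
#' @param configs data.frame with columns `pretraining`
#'   (`"sac"|"supcon"|"none"`) and `sen` (logical); defaults to the four-row
#'   {SAC, none} x {SEN on, off} matrix.
#' @param cfg a [train_config()].
#' @param composition,aug passed to [pretrain_wfp()].
#' @param model_config base [wf_model_config()] (the `use_sen` field is
#'   overridden per row).
#' @return list: `table` (one row per configuration with the report metrics)
#'   and `reports` (the `wf_eval` objects).
#' @export
run_ablation <- function(pretrain_set, train_set, test_set,
                         configs = expand.grid(pretraining = c("sac", "none"),
                                               sen = c(TRUE, FALSE),
                                               stringsAsFactors = FALSE),
                         cfg = train_config(),
                         composition = composition_preset("50/0/50", 20L),
                         aug = augment_config(),
                         model_config = wf_model_config()) {
  reports <- vector("list", nrow(configs))
  for (i in seq_len(nrow(configs))) {
    mc <- model_config
    mc$use_sen <- isTRUE(configs$sen[i])
    model <- build_model(mc, seed = derive_seed(cfg$seed, "init", i))
    pt <- configs$pretraining[i]
    if (pt %in% c("sac", "supcon")) {
      pre <- pretrain_wfp(pretrain_set, model, cfg, composition, aug, loss = pt)
      model <- transfer_weights(pre$model,
                                seed = derive_seed(cfg$seed, "head", i))
    }
    ft <- finetune_wfc(train_set, model, cfg, test_set = test_set)
    reports[[i]] <- ft$report
    reports[[i]]$model <- ft$model
  }
  tab <- cbind(configs,
               accuracy = vapply(reports, `[[`, 1, "accuracy"),
               f1_class0 = vapply(reports, function(r) r$f1[[1]], 1),
               f1_class1 = vapply(reports, function(r) r$f1[[2]], 1))
  list(table = tab, reports = reports)
}

#' An easy synthetic benchmark dataset
#'
#' Generates a deliberately separable multi-subject dataset: the class
#' effect is a strong alpha-band power modulation confined to five focal
#' posterior leads (P7, P6, PO7, PO8, Oz), with moderate 1/f noise, then
#' preprocesses it into spectrogram tensors. The remaining twelve tensor
#' leads carry no condition signal, which is what makes attention
#' localisation measurable.
#'
#' @param n_subjects number of subjects (default 10).
#' @param trials_per_class trials per condition per subject (default 20).
#' @param class_effect multiplicative band-power effect (default 6).
#' @param noise_scale 1/f noise standard deviation (default 0.5).
#' @param seed master seed.
#' @return a `wf_tensor_set` with attribute `signal_leads`.
#' @export
easy_dataset <- function(n_subjects = 10L, trials_per_class = 20L,
                         class_effect = 6, noise_scale = 0.5, seed = 1L) {
  spec <- synthetic_dataset_spec(n_subjects = n_subjects,
                                 trials_per_class = trials_per_class,
                                 n_leads = 63L, sampling_rate = 500,
                                 epoch_length = 1.2, seed = seed)
  signal_leads <- c("P7", "P6", "PO7", "PO8", "Oz")
  profiles <- make_subject_profiles(spec, class_effect = class_effect,
                                    effect_leads = signal_leads,
                                    noise_scale = noise_scale)
  recs <- generate_dataset(spec, profiles)
  set <- preprocess_dataset(recs)
  attr(set, "signal_leads") <- signal_leads
  set
}
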