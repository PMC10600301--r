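# Subject-aware contrastive (SAC) machinery: tensor augmentation, view-batch
# construction, positive/negative set logic, the SAC loss (with analytic
# gradient for pretraining) and the conventional supervised-contrastive
# (SupCon) baseline, plus the (subject, class)-keyed batch composition
# sampler.
#
# SAC loss, as implemented (anchors i over all views, S(i) = negatives only):
#   L = - sum_i log( (1/|Q(i)|) sum_{q in Q(i)} exp(z_i.z_q/tau)
#                                 / sum_{s in S(i)} exp(z_i.z_s/tau) )
# Positives Q(i): same subject AND same class as the anchor. Negatives:
# opposite class, split into intra-subject N_a(i) (same subject) and
# inter-subject N_r(i) (different subject). Same-class/different-subject
# views belong to no set and do not influence the loss.

#' Augmentation configuration
#'
#' @param pink_noise_scale relative amplitude of 1/f-shaped noise along the
#'   frequency axis (fraction of the tensor RMS).
#' @param gaussian_noise_scale relative amplitude of white Gaussian noise.
#' @param input_dropout_rate fraction of tensor entries zeroed, in [0, 1).
#' @return a list of class `wf_augment_config`. All-zero scales give the
#'   identity augmentation.
#' @export
augment_config <- function(pink_noise_scale = 0.1, gaussian_noise_scale = 0.05,
                           input_dropout_rate = 0.1) {
  if (input_dropout_rate < 0 || input_dropout_rate >= 1)
    wf_config_error("input_dropout_rate must be in [0, 1)")
  if (pink_noise_scale < 0 || gaussian_noise_scale < 0)
    wf_config_error("noise scales must be >= 0")
  structure(list(pink_noise_scale = pink_noise_scale,
                 gaussian_noise_scale = gaussian_noise_scale,
                 input_dropout_rate = input_dropout_rate),
            class = "wf_augment_config")
}

#' Augment a spectrogram tensor
#'
#' Produces one "view": `dropout_mask * (x + pink + gaussian)`. Pink noise is
#' synthesised along the frequency axis with expected power proportional to
#' 1/f; both noise amplitudes are relative to the tensor's RMS. Uses the
#' current RNG stream (seed it with [with_seed()] or `set.seed()` for
#' reproducibility).
#'
#' @param x a `leads x freq x time` tensor.
#' @param cfg an [augment_config()].
#' @param freq_centers frequencies (Hz) of the tensor's frequency rows
#'   (defaults to bin index).
#' @return an array shaped like `x`.
#' @export
augment <- function(x, cfg = augment_config(), freq_centers = NULL) {
  d <- dim(x)
  rms <- sqrt(mean(x^2))
  out <- x
  if (cfg$pink_noise_scale > 0) {
    f <- freq_centers %||% seq_len(d[2])
    amp <- 1 / sqrt(f)
    amp <- amp / sqrt(mean(amp^2))            # unit mean power across rows
    noise <- array(stats::rnorm(prod(d)), d)
    noise <- noise * rep(amp, each = d[1])    # broadcast along freq axis
    out <- out + cfg$pink_noise_scale * rms * noise
  }
  if (cfg$gaussian_noise_scale > 0)
    out <- out + cfg$gaussian_noise_scale * rms * array(stats::rnorm(prod(d)), d)
  if (cfg$input_dropout_rate > 0)
    out <- out * array(stats::runif(prod(d)) >= cfg$input_dropout_rate, d)
  out
}

#' Build a batch of augmented views
#'
#' Every sample in the batch yields two augmented views that inherit its
#' condition label and subject id (views 2k-1 and 2k come from sample k).
#'
#' @param set a `wf_tensor_set` (or list with `x`, `y1`, `y2`).
#' @param idx indices of the N samples forming the batch.
#' @param cfg an [augment_config()].
#' @param seed integer seed for the augmentation draws.
#' @return a list of class `wf_view_batch`: `x` (`2N x leads x freq x time`),
#'   `y1`, `y2`, `provenance` (source sample index per view).
#' @export
build_view_batch <- function(set, idx = seq_along(set$y1),
                             cfg = augment_config(), seed = NULL) {
  n <- length(idx)
  if (n < 1L) wf_config_error("empty batch")
  d <- dim(set$x)[-1]
  views <- array(0, c(2L * n, d))
  with_seed(seed, {
    for (k in seq_len(n)) {
      xi <- array(set$x[idx[k], , , ], d)
      views[2L * k - 1L, , , ] <- augment(xi, cfg, set$freq_centers)
      views[2L * k, , , ] <- augment(xi, cfg, set$freq_centers)
    }
  })
  structure(list(x = views,
                 y1 = rep(set$y1[idx], each = 2L),
                 y2 = rep(set$y2[idx], each = 2L),
                 provenance = rep(idx, each = 2L)),
            class = "wf_view_batch")
}

#' Positive and negative sets for one anchor
#'
#' @param i anchor view index.
#' @param y1 class labels of all views.
#' @param y2 subject ids of all views.
#' @return list with integer index vectors `Q` (same subject, same class),
#'   `N_r` (different subject, different class), `N_a` (same subject,
#'   different class). The anchor belongs to none; same-class/other-subject
#'   views belong to none.
#' @export
contrast_sets <- function(i, y1, y2) {
  others <- setdiff(seq_along(y1), i)
  same_cls <- y1[others] == y1[i]
  same_sub <- y2[others] == y2[i]
  list(Q = others[same_cls & same_sub],
       N_r = others[!same_cls & !same_sub],
       N_a = others[!same_cls & same_sub])
}

# Pairwise similarity matrix z_i . z_j / tau
sim_matrix <- function(Z, tau) tcrossprod(Z) / tau

#' Subject-aware contrastive loss
#'
#' Evaluates the SAC loss over all anchors of a view batch. The denominator
#' ranges over negatives only, and the mean over positives sits inside the
#' log. Anchors with no positive or no negative are skipped with a warning;
#' if every anchor is skipped a training error ("degenerate batch") is
#' raised.
#'
#' @param Z `2N x d` matrix of unit-norm embeddings.
#' @param y1 class labels per view.
#' @param y2 subject ids per view.
#' @param tau positive loss temperature (default 0.25).
#' @param reduce "sum" (the printed form) or "mean" over valid anchors.
#' @return scalar loss (may be negative).
#' @export
sac_loss <- function(Z, y1, y2, tau = 0.25, reduce = c("sum", "mean")) {
  sac_loss_grad(Z, y1, y2, tau, match.arg(reduce), want_grad = FALSE)$loss
}

#' @rdname sac_loss
#' @param want_grad logical; also return `grad`, the `2N x d` gradient of the
#'   loss with respect to `Z` (before re-normalisation).
#' @export
sac_loss_grad <- function(Z, y1, y2, tau = 0.25, reduce = "sum",
                          want_grad = TRUE) {
  if (tau <= 0) wf_config_error("tau must be positive, got %g", tau)
  n <- nrow(Z)
  S <- sim_matrix(Z, tau)
  loss <- 0
  n_valid <- 0L
  grad <- if (want_grad) matrix(0, n, ncol(Z)) else NULL
  coef <- if (want_grad) matrix(0, n, n) else NULL
  skipped <- 0L
  for (i in seq_len(n)) {
    cs <- contrast_sets(i, y1, y2)
    neg <- c(cs$N_r, cs$N_a)
    if (!length(cs$Q) || !length(neg)) {
      skipped <- skipped + 1L
      next
    }
    sq <- S[i, cs$Q]
    sn <- S[i, neg]
    mq <- max(sq); mn <- max(sn)
    lq <- mq + log(sum(exp(sq - mq)))     # log sum exp over positives
    ln <- mn + log(sum(exp(sn - mn)))     # log sum exp over negatives
    loss <- loss + (log(length(cs$Q)) - lq + ln)
    n_valid <- n_valid + 1L
    if (want_grad) {
      pq <- exp(sq - lq)                   # softmax over positives
      pn <- exp(sn - ln)                   # softmax over negatives
      coef[i, cs$Q] <- coef[i, cs$Q] - pq
      coef[i, neg] <- coef[i, neg] + pn
    }
  }
  if (n_valid == 0L)
    wf_training_error("degenerate batch: every anchor lacks positives or negatives")
  if (skipped > 0L)
    warning(sprintf("sac_loss: skipped %d anchor(s) with empty positive or negative set",
                    skipped), call. = FALSE)
  scale <- if (reduce == "mean") 1 / n_valid else 1
  if (want_grad) {
    # d s_ij / d z_i = z_j / tau and d s_ij / d z_j = z_i / tau
    grad <- (coef %*% Z + crossprod(coef, Z)) * (scale / tau)
  }
  list(loss = loss * scale, grad = grad, n_valid = n_valid, skipped = skipped)
}

#' Supervised contrastive (SupCon) baseline loss
#'
#' Conventional supervised-contrastive loss: positives are all same-class
#' views regardless of subject; the denominator ranges over every non-anchor
#' view; the mean over positives sits outside the log.
#'
#' @inheritParams sac_loss
#' @export
supcon_loss <- function(Z, y1, tau = 0.25, reduce = c("sum", "mean")) {
  supcon_loss_grad(Z, y1, tau, match.arg(reduce), want_grad = FALSE)$loss
}

#' @rdname supcon_loss
#' @param want_grad logical; also return the gradient with respect to `Z`.
#' @export
supcon_loss_grad <- function(Z, y1, tau = 0.25, reduce = "sum",
                             want_grad = TRUE) {
  if (tau <= 0) wf_config_error("tau must be positive, got %g", tau)
  n <- nrow(Z)
  S <- sim_matrix(Z, tau)
  loss <- 0
  n_valid <- 0L
  coef <- if (want_grad) matrix(0, n, n) else NULL
  skipped <- 0L
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    pos <- others[y1[others] == y1[i]]
    if (!length(pos)) { skipped <- skipped + 1L; next }
    sa <- S[i, others]
    ma <- max(sa)
    la <- ma + log(sum(exp(sa - ma)))
    loss <- loss + sum(la - S[i, pos]) / length(pos)
    n_valid <- n_valid + 1L
    if (want_grad) {
      pa <- exp(sa - la)
      coef[i, others] <- coef[i, others] + pa
      coef[i, pos] <- coef[i, pos] - 1 / length(pos)
    }
  }
  if (n_valid == 0L)
    wf_training_error("degenerate batch: no anchor has a same-class companion")
  if (skipped > 0L)
    warning(sprintf("supcon_loss: skipped %d anchor(s) without positives", skipped),
            call. = FALSE)
  scale <- if (reduce == "mean") 1 / n_valid else 1
  grad <- if (want_grad) (coef %*% Z + crossprod(coef, Z)) * (scale / tau) else NULL
  list(loss = loss * scale, grad = grad, n_valid = n_valid, skipped = skipped)
}

#' Batch composition specification
#'
#' Fractions of the three batch roles relative to an anchor key
#' `(subject, class)`: positives (same subject, same class), inter-subject
#' negatives (other subject, other class) and intra-subject negatives (same
#' subject, other class). Fractions must sum to 1 and yield integer counts at
#' the given batch size.
#'
#' @param frac_positive,frac_inter_negative,frac_intra_negative role
#'   fractions in [0, 1].
#' @param batch_size number of source samples N per batch.
#' @return a list of class `wf_batch_composition`.
#' @export
batch_composition_spec <- function(frac_positive, frac_inter_negative,
                                   frac_intra_negative, batch_size) {
  fr <- c(frac_positive, frac_inter_negative, frac_intra_negative)
  if (any(fr < 0 | fr > 1)) wf_config_error("fractions must lie in [0, 1]")
  if (abs(sum(fr) - 1) > 1e-9) wf_config_error("fractions must sum to 1")
  counts <- fr * batch_size
  if (any(abs(counts - round(counts)) > 1e-9))
    wf_config_error("fractions do not yield integer counts at batch size %d",
                    batch_size)
  structure(list(frac_positive = frac_positive,
                 frac_inter_negative = frac_inter_negative,
                 frac_intra_negative = frac_intra_negative,
                 batch_size = as.integer(batch_size),
                 counts = as.integer(round(counts))),
            class = "wf_batch_composition")
}

#' Named batch-composition presets
#'
#' Presets labelled `Q/N_r/N_a` percentages: `"50/0/50"` (the best-performing
#' scheme: half positives, half intra-subject negatives, no inter-subject
#' negatives), `"12.5/37.5/50"`, `"25/25/50"`, `"37.5/12.5/50"`, `"45/5/50"`,
#' `"5/45/50"`, and `"supcon"` (the baseline; composition 50/0/50 with the
#' SupCon loss).
#'
#' @param name preset label.
#' @param batch_size batch size N (default 500).
#' @return a `wf_batch_composition`; for `"supcon"` the attribute
#'   `loss = "supcon"` is set.
#' @export
composition_preset <- function(name, batch_size = 500L) {
  table <- list(
    "supcon" = c(50, 0, 50),
    "12.5/37.5/50" = c(12.5, 37.5, 50),
    "25/25/50" = c(25, 25, 50),
    "37.5/12.5/50" = c(37.5, 12.5, 50),
    "45/5/50" = c(45, 5, 50),
    "5/45/50" = c(5, 45, 50),
    "50/0/50" = c(50, 0, 50)
  )
  if (!name %in% names(table))
    wf_config_error("unknown preset '%s'; available: %s", name,
                    paste(names(table), collapse = ", "))
  p <- table[[name]] / 100
  spec <- batch_composition_spec(p[1], p[2], p[3], batch_size)
  attr(spec, "loss") <- if (name == "supcon") "supcon" else "sac"
  spec
}

#' Compose a batch of sample indices for one anchor key
#'
#' Draws, without replacement: `N * frac_positive` samples with the key's
#' subject and class, `N * frac_intra_negative` samples from the same subject
#' with the other class, and `N * frac_inter_negative` samples from other
#' subjects with the other class.
#'
#' @param index data.frame with columns `subject` and `class`, one row per
#'   dataset sample.
#' @param key list or vector `(subject, class)` identifying the anchor group.
#' @param spec a [batch_composition_spec()].
#' @param seed integer seed for the draws.
#' @param positives optional explicit positive indices (used by the training
#'   scheduler to cycle every sample through the positive role); must have
#'   length `N * frac_positive`.
#' @return integer vector of N sample indices.
#' @export
compose_batch <- function(index, key, spec, seed = NULL, positives = NULL) {
  subj <- key[[1]]; cls <- key[[2]]
  pool_pos <- which(index$subject == subj & index$class == cls)
  pool_intra <- which(index$subject == subj & index$class != cls)
  pool_inter <- which(index$subject != subj & index$class != cls)
  need <- spec$counts
  pools <- list(pool_pos, pool_inter, pool_intra)
  roles <- c("positives", "inter-subject negatives", "intra-subject negatives")
  for (j in 1:3) {
    if (length(pools[[j]]) < need[j])
      wf_data_error("insufficient samples for %s of key (subject %s, class %s): need %d, have %d",
                    roles[j], subj, cls, need[j], length(pools[[j]]))
  }
  with_seed(seed, {
    pos <- if (is.null(positives)) sample_from(pool_pos, need[1]) else {
      if (length(positives) != need[1])
        wf_config_error("explicit positives must have length %d", need[1])
      positives
    }
    inter <- if (need[2] > 0) sample_from(pool_inter, need[2]) else integer()
    intra <- if (need[3] > 0) sample_from(pool_intra, need[3]) else integer()
    c(pos, inter, intra)
  })
}
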