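# The WaveFusion network: one lightweight 3-stage CNN (LWCNN) per EEG lead,
# a squeeze-and-excite attention module (SEN) with a temperature-flattened
# sigmoid, a fusion encoder producing a 128-d representation, a projection
# head onto the unit 32-sphere for contrastive pretraining, and a 2-node
# classification head for fine-tuning.
#
# Default LWCNN (input 1 x 39 x 11):
#   conv 5x4 stride 2x1 pad 2x1 -> 16ch, ReLU, 2x2 maxpool, dropout 0.1
#   conv 4x2 stride 2x1 pad 0   -> 16ch, ReLU, 2x2 maxpool, dropout 0.1, BN
#   conv 2x2 stride 1x1 pad 0   -> 32ch, dropout 0.1, BN
# Shape chain: 39x11 -> 16x20x10 -> 16x10x5 -> 16x4x4 -> 16x2x2 -> 32x1x1.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Model configuration for the WaveFusion network
#'
#' @param n_leads number of per-lead CNN branches (default 17, the posterior
#'   montage subset).
#' @param input_h,input_w spectrogram dimensions (frequency bins x time frames).
#' @param sen_hidden bottleneck width of the squeeze-and-excite module.
#' @param enc_dim encoder output dimension.
#' @param proj_dim projection head output dimension (unit-normalised).
#' @param n_classes number of classifier logits.
#' @param tau_attn positive sigmoid temperature of the attention module;
#'   larger values flatten all attention weights toward 0.5.
#' @param dropout dropout rate applied after each convolution stage.
#' @param use_sen logical; FALSE replaces all attention weights by 1
#'   (the "SEN off" ablation).
#' @return a list of class `wf_model_config`.
#' @export
wf_model_config <- function(n_leads = 17L, input_h = 39L, input_w = 11L,
                            sen_hidden = 5L, enc_dim = 128L, proj_dim = 32L,
                            n_classes = 2L, tau_attn = 1, dropout = 0.1,
                            use_sen = TRUE) {
  if (tau_attn <= 0) wf_config_error("tau_attn must be positive, got %g", tau_attn)
  if (dropout < 0 || dropout >= 1) wf_config_error("dropout must be in [0,1)")
  structure(list(
    n_leads = as.integer(n_leads), input_h = as.integer(input_h),
    input_w = as.integer(input_w), sen_hidden = as.integer(sen_hidden),
    enc_dim = as.integer(enc_dim), proj_dim = as.integer(proj_dim),
    n_classes = as.integer(n_classes), tau_attn = tau_attn,
    dropout = dropout, use_sen = isTRUE(use_sen),
    stages = list(
      list(kh = 5L, kw = 4L, sh = 2L, sw = 1L, ph = 2L, pw = 1L,
           out_ch = 16L, bn = FALSE, relu = TRUE, pool = TRUE),
      list(kh = 4L, kw = 2L, sh = 2L, sw = 1L, ph = 0L, pw = 0L,
           out_ch = 16L, bn = TRUE, relu = TRUE, pool = TRUE),
      list(kh = 2L, kw = 2L, sh = 1L, sw = 1L, ph = 0L, pw = 0L,
           out_ch = 32L, bn = TRUE, relu = FALSE, pool = FALSE)
    )
  ), class = "wf_model_config")
}

model_fingerprint <- function(config) {
  cfg <- unclass(config)
  cfg$tau_attn <- NULL     # temperatures are tunable, not architectural
  jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
}

build_lwcnn_layers <- function(config) {
  layers <- list()
  ch <- 1L; h <- config$input_h; w <- config$input_w
  for (s in config$stages) {
    lay <- conv_layer(ch, h, w, s$kh, s$kw, s$sh, s$sw, s$ph, s$pw, s$out_ch)
    h <- lay$out_h; w <- lay$out_w; ch <- s$out_ch
    if (s$pool) { h <- h %/% 2L; w <- w %/% 2L }
    layers[[length(layers) + 1L]] <- lay
  }
  if (h != 1L || w != 1L)
    wf_config_error("LWCNN stages do not reduce %dx%d input to 1x1 (got %dx%d)",
                    config$input_h, config$input_w, h, w)
  attr(layers, "feature_dim") <- ch
  layers
}

#' Build a WaveFusion model with freshly initialised parameters
#'
#' Weights use Kaiming-uniform initialisation, biases are zero, batch-norm
#' starts at unit scale / zero shift with running statistics (0, 1).
#'
#' @param config a [wf_model_config()].
#' @param seed integer seed for the parameter draw.
#' @return an object of class `wf_model`.
#' @export
build_model <- function(config = wf_model_config(), seed = 1L) {
  layers <- build_lwcnn_layers(config)
  fdim <- attr(layers, "feature_dim")
  flat_dim <- config$n_leads * fdim
  dense_init <- function(n_in, n_out) {
    lim <- sqrt(6 / n_in)
    list(W = matrix(runif(n_in * n_out, -lim, lim), n_in, n_out),
         b = numeric(n_out))
  }
  params <- with_seed(seed, {
    leads <- lapply(seq_len(config$n_leads), function(i) {
      list(conv1 = conv_init(layers[[1]]),
           conv2 = conv_init(layers[[2]]),
           bn2 = bn_init(config$stages[[2]]$out_ch),
           conv3 = conv_init(layers[[3]]),
           bn3 = bn_init(config$stages[[3]]$out_ch))
    })
    list(leads = leads,
         sen = list(W1 = dense_init(config$n_leads, config$sen_hidden)$W,
                    b1 = numeric(config$sen_hidden),
                    W2 = dense_init(config$sen_hidden, config$n_leads)$W,
                    b2 = numeric(config$n_leads)),
         enc = dense_init(flat_dim, config$enc_dim),
         proj = dense_init(config$enc_dim, config$proj_dim),
         clf = dense_init(config$enc_dim, config$n_classes))
  })
  state <- list(leads = lapply(seq_len(config$n_leads), function(i) {
    list(bn2 = bn_state_init(config$stages[[2]]$out_ch),
         bn3 = bn_state_init(config$stages[[3]]$out_ch))
  }))
  structure(list(config = config, layers = layers, params = params,
                 state = state, feature_dim = fdim,
                 fingerprint = model_fingerprint(config)),
            class = "wf_model")
}

#' @export
print.wf_model <- function(x, ...) {
  cat(sprintf("WaveFusion model: %d leads x (%dx%d) input, %d parameters\n",
              x$config$n_leads, x$config$input_h, x$config$input_w,
              n_parameters(x$params)))
  cat(sprintf("  SEN %s (tau_attn = %g), encoder %d-d, projection %d-d\n",
              if (x$config$use_sen) "on" else "off", x$config$tau_attn,
              x$config$enc_dim, x$config$proj_dim))
  invisible(x)
}

# ---- per-lead LWCNN ---------------------------------------------------------

lwcnn_forward_cached <- function(model, lead, x, training) {
  p <- model$params$leads[[lead]]
  st <- model$state$leads[[lead]]
  L <- model$layers
  drop <- model$config$dropout
  c1 <- conv_forward(L[[1]], p$conv1, x)
  a1 <- relu(c1$y)
  p1 <- maxpool_forward(a1)
  d1 <- dropout_forward(p1$y, drop, training)
  c2 <- conv_forward(L[[2]], p$conv2, d1$y)
  a2 <- relu(c2$y)
  p2 <- maxpool_forward(a2)
  d2 <- dropout_forward(p2$y, drop, training)
  b2 <- bn_forward(p$bn2, st$bn2, d2$y, training)
  c3 <- conv_forward(L[[3]], p$conv3, b2$y)
  d3 <- dropout_forward(c3$y, drop, training)
  b3 <- bn_forward(p$bn3, st$bn3, d3$y, training)
  u <- matrix(b3$y, dim(x)[1], model$feature_dim)
  list(u = u, state = list(bn2 = b2$state, bn3 = b3$state),
       cache = list(c1 = c1, m1 = c1$y > 0, p1 = p1, d1 = d1,
                    c2 = c2, m2 = c2$y > 0, a2 = a2, p2 = p2, d2 = d2, b2 = b2,
                    c3 = c3, d3 = d3, b3 = b3, x = x))
}

lwcnn_backward_cached <- function(model, lead, cache, du, want_stage2_grad = FALSE) {
  p <- model$params$leads[[lead]]
  L <- model$layers
  b <- nrow(du)
  dy <- array(du, c(b, model$feature_dim, 1L, 1L))
  bb3 <- bn_backward(p$bn3, cache$b3$cache, dy)
  dd3 <- dropout_backward(cache$d3, bb3$dx)
  cb3 <- conv_backward(L[[3]], p$conv3, cache$c3, dd3)
  bb2 <- bn_backward(p$bn2, cache$b2$cache, cb3$dx)
  dd2 <- dropout_backward(cache$d2, bb2$dx)
  da2 <- maxpool_backward(cache$p2, dd2)
  dc2 <- da2 * cache$m2
  cb2 <- conv_backward(L[[2]], p$conv2, cache$c2, dc2)
  dd1 <- dropout_backward(cache$d1, cb2$dx)
  dp1 <- maxpool_backward(cache$p1, dd1)
  dc1 <- dp1 * cache$m1
  cb1 <- conv_backward(L[[1]], p$conv1, cache$c1, dc1)
  out <- list(grads = list(conv1 = list(W = cb1$dW, b = cb1$db),
                           conv2 = list(W = cb2$dW, b = cb2$db),
                           bn2 = list(gamma = bb2$dgamma, beta = bb2$dbeta),
                           conv3 = list(W = cb3$dW, b = cb3$db),
                           bn3 = list(gamma = bb3$dgamma, beta = bb3$dbeta)))
  if (want_stage2_grad) out$dstage2 <- da2
  out
}

as_input_batch <- function(x, n_leads, h, w) {
  d <- dim(x)
  if (length(d) == 3L && all(d == c(n_leads, h, w))) {
    x <- array(x, c(1L, d))
  } else if (!(length(d) == 4L && all(d[2:4] == c(n_leads, h, w)))) {
    wf_config_error("expected input of shape (%d, %d, %d) or (B, %d, %d, %d), got (%s)",
                    n_leads, h, w, n_leads, h, w, paste(d, collapse = ", "))
  }
  x
}

# Full forward pass. head: "project" (WFP), "classify" (WFC), or "encode".
wf_forward <- function(model, x, training = FALSE, head = "project",
                       keep_cache = FALSE) {
  cfg <- model$config
  x <- as_input_batch(x, cfg$n_leads, cfg$input_h, cfg$input_w)
  b <- dim(x)[1]
  U <- array(0, c(b, cfg$n_leads, model$feature_dim))
  lead_caches <- if (keep_cache) vector("list", cfg$n_leads) else NULL
  for (i in seq_len(cfg$n_leads)) {
    fw <- lwcnn_forward_cached(model, i, x[, i, , , drop = FALSE], training)
    U[, i, ] <- fw$u
    if (training) model$state$leads[[i]] <- fw$state
    if (keep_cache) lead_caches[[i]] <- fw$cache
  }
  ps <- model$params$sen
  if (cfg$use_sen) {
    pooled <- matrix(rowMeans(matrix(U, b * cfg$n_leads, model$feature_dim)),
                     b, cfg$n_leads)
    hpre <- sweep(pooled %*% ps$W1, 2L, ps$b1, `+`)
    hh <- relu(hpre)
    a <- sweep(hh %*% ps$W2, 2L, ps$b2, `+`)
    pi_w <- sigmoid(a / cfg$tau_attn)
  } else {
    pooled <- NULL; hh <- NULL; a <- NULL
    pi_w <- matrix(1, b, cfg$n_leads)
  }
  V <- U * as.vector(pi_w)                    # broadcast over feature dim
  Fm <- matrix(V, b, cfg$n_leads * model$feature_dim)
  r <- sweep(Fm %*% model$params$enc$W, 2L, model$params$enc$b, `+`)
  out <- list(model = model, U = U, pi = pi_w, r = r)
  if (head == "project") {
    v <- sweep(r %*% model$params$proj$W, 2L, model$params$proj$b, `+`)
    nv <- sqrt(rowSums(v^2))
    if (any(nv < 1e-12))
      wf_error("wf_numeric_error", "zero-norm embedding before normalisation")
    out$z <- v / nv
  } else if (head == "classify") {
    out$logits <- sweep(r %*% model$params$clf$W, 2L, model$params$clf$b, `+`)
  }
  if (keep_cache) {
    out$cache <- list(x = x, lead_caches = lead_caches, U = U, pooled = pooled,
                      h = hh, a = a, pi = pi_w, Fm = Fm, r = r,
                      v = if (head == "project") v else NULL,
                      nv = if (head == "project") nv else NULL,
                      z = out$z, head = head)
  }
  out
}

# Backward pass from d_head (dZ for "project", dlogits for "classify",
# dr for "encode"). Returns a gradient tree shaped like model$params.
wf_backward <- function(model, cache, d_head, want_stage2_grad = FALSE) {
  cfg <- model$config
  b <- nrow(cache$r)
  pr <- model$params
  if (cache$head == "project") {
    z <- cache$z
    dv <- (d_head - z * rowSums(d_head * z)) / cache$nv
    g_proj <- list(W = crossprod(cache$r, dv), b = colSums(dv))
    dr <- tcrossprod(dv, pr$proj$W)
    g_clf <- tree_zeros_like(pr$clf)
  } else if (cache$head == "classify") {
    g_clf <- list(W = crossprod(cache$r, d_head), b = colSums(d_head))
    dr <- tcrossprod(d_head, pr$clf$W)
    g_proj <- tree_zeros_like(pr$proj)
  } else {
    dr <- d_head
    g_proj <- tree_zeros_like(pr$proj)
    g_clf <- tree_zeros_like(pr$clf)
  }
  g_enc <- list(W = crossprod(cache$Fm, dr), b = colSums(dr))
  dF <- tcrossprod(dr, pr$enc$W)
  dV <- array(dF, c(b, cfg$n_leads, model$feature_dim))
  dU <- dV * as.vector(cache$pi)
  if (cfg$use_sen) {
    dpi <- matrix(rowSums(matrix(dV * cache$U, b * cfg$n_leads, model$feature_dim)),
                  b, cfg$n_leads)
    da <- dpi * cache$pi * (1 - cache$pi) / cfg$tau_attn
    g_sen <- list(W1 = NULL, b1 = NULL, W2 = crossprod(cache$h, da),
                  b2 = colSums(da))
    dh <- tcrossprod(da, pr$sen$W2) * (cache$h > 0)
    g_sen$W1 <- crossprod(cache$pooled, dh)
    g_sen$b1 <- colSums(dh)
    dP <- tcrossprod(dh, pr$sen$W1)
    dU <- dU + array(as.vector(dP) / model$feature_dim,
                     c(b, cfg$n_leads, model$feature_dim))
  } else {
    g_sen <- tree_zeros_like(pr$sen)
  }
  g_leads <- vector("list", cfg$n_leads)
  stage2 <- if (want_stage2_grad) vector("list", cfg$n_leads) else NULL
  for (i in seq_len(cfg$n_leads)) {
    bk <- lwcnn_backward_cached(model, i, cache$lead_caches[[i]],
                                matrix(dU[, i, ], b, model$feature_dim),
                                want_stage2_grad)
    g_leads[[i]] <- bk$grads
    if (want_stage2_grad) stage2[[i]] <- bk$dstage2
  }
  out <- list(grads = list(leads = g_leads, sen = g_sen, enc = g_enc,
                           proj = g_proj, clf = g_clf))
  if (want_stage2_grad) out$stage2_grads <- stage2
  out
}

# ---- user-facing single operations -----------------------------------------

#' Forward pass of one lightweight per-lead CNN
#'
#' @param model a `wf_model`.
#' @param x a 39 x 11 spectrogram (or `B x 39 x 11` batch) for the default
#'   configuration.
#' @param lead which lead branch to use.
#' @param training logical; enables dropout and batch-statistics mode.
#' @return a length-32 feature vector (or `B x 32` matrix).
#' @export
lwcnn_forward <- function(model, x, lead = 1L, training = FALSE) {
  cfg <- model$config
  d <- dim(x)
  if (is.null(d)) wf_config_error("expected a matrix input")
  if (length(d) == 2L) {
    if (!all(d == c(cfg$input_h, cfg$input_w)))
      wf_config_error("expected %dx%d spectrogram, got %dx%d",
                      cfg$input_h, cfg$input_w, d[1], d[2])
    xb <- array(x, c(1L, 1L, d))
    single <- TRUE
  } else if (length(d) == 3L && all(d[2:3] == c(cfg$input_h, cfg$input_w))) {
    xb <- array(x, c(d[1], 1L, d[2], d[3]))
    single <- FALSE
  } else {
    wf_config_error("expected %dx%d spectrogram or batch, got (%s)",
                    cfg$input_h, cfg$input_w, paste(d, collapse = ", "))
  }
  u <- lwcnn_forward_cached(model, lead, xb, training)$u
  if (single) drop(u) else u
}

#' Squeeze-and-excite attention weights
#'
#' Global-averages each lead's feature vector, passes the pooled vector
#' through a bottleneck (ReLU) and expansion dense layer, and applies a
#' temperature-flattened sigmoid: `pi_i = exp(a_i/tau) / (exp(a_i/tau) + 1)`.
#' As `tau_attn` grows, every weight approaches 0.5.
#'
#' @param model a `wf_model`.
#' @param U a `n_leads x feature_dim` matrix (or `B x n_leads x feature_dim`).
#' @param tau_attn optional temperature override; must be positive.
#' @return attention weights in (0,1), one per lead.
#' @export
sen_attention <- function(model, U, tau_attn = NULL) {
  tau <- tau_attn %||% model$config$tau_attn
  if (tau <= 0) wf_config_error("tau_attn must be positive, got %g", tau)
  nl <- model$config$n_leads
  fd <- model$feature_dim
  single <- length(dim(U)) == 2L
  if (single) U <- array(U, c(1L, dim(U)))
  b <- dim(U)[1]
  pooled <- matrix(rowMeans(matrix(U, b * nl, fd)), b, nl)
  ps <- model$params$sen
  hh <- relu(sweep(pooled %*% ps$W1, 2L, ps$b1, `+`))
  a <- sweep(hh %*% ps$W2, 2L, ps$b2, `+`)
  pi_w <- sigmoid(a / tau)
  if (single) drop(pi_w) else pi_w
}

#' Fuse per-lead features into the encoder representation
#'
#' Scales each lead's feature vector by its attention weight, flattens, and
#' applies the encoder dense layer.
#' @param model a `wf_model`.
#' @param U `n_leads x feature_dim` feature matrix (or batch).
#' @param pi attention weights (defaults to all ones).
#' @return a 128-d representation vector (or `B x 128` matrix).
#' @export
fuse_encode <- function(model, U, pi = NULL) {
  nl <- model$config$n_leads
  fd <- model$feature_dim
  single <- length(dim(U)) == 2L
  if (single) U <- array(U, c(1L, dim(U)))
  b <- dim(U)[1]
  if (is.null(pi)) pi <- matrix(1, b, nl)
  if (is.null(dim(pi))) pi <- matrix(pi, b, nl, byrow = single)
  V <- U * as.vector(pi)
  Fm <- matrix(V, b, nl * fd)
  r <- sweep(Fm %*% model$params$enc$W, 2L, model$params$enc$b, `+`)
  if (single) drop(r) else r
}

#' Project a representation onto the unit hypersphere
#'
#' Dense 128 -> 32 map followed by Euclidean normalisation, so cosine
#' similarity between embeddings is their dot product.
#' @param model a `wf_model`.
#' @param r a 128-d representation (or `B x 128` matrix).
#' @return unit-norm 32-d embedding (or `B x 32` matrix).
#' @export
project_embedding <- function(model, r) {
  single <- is.null(dim(r))
  if (single) r <- matrix(r, 1L)
  v <- sweep(r %*% model$params$proj$W, 2L, model$params$proj$b, `+`)
  nv <- sqrt(rowSums(v^2))
  if (any(nv < 1e-12))
    wf_error("wf_numeric_error", "zero-norm embedding before normalisation")
  z <- v / nv
  if (single) drop(z) else z
}

#' Classification logits from a representation
#'
#' @param model a `wf_model`.
#' @param r a 128-d representation (or `B x 128` matrix).
#' @return 2 logits (or `B x 2` matrix); softmax of each row sums to 1.
#' @export
classify_logits <- function(model, r) {
  single <- is.null(dim(r))
  if (single) r <- matrix(r, 1L)
  lg <- sweep(r %*% model$params$clf$W, 2L, model$params$clf$b, `+`)
  if (single) drop(lg) else lg
}

softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}

# ---- checkpoints ------------------------------------------------------------

#' Save / load model checkpoints
#'
#' A checkpoint is a compressed archive of the named parameter arrays and
#' batch-norm state plus a JSON sidecar holding the architecture fingerprint;
#' loading validates the fingerprint so weights are only transferred between
#' structurally identical models.
#' @param model a `wf_model`.
#' @param path file path for the checkpoint (`.rds`); the sidecar is written
#'   next to it as `<path>.json`.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a `wf_model`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(version = 1L, config = model$config, params = model$params,
               state = model$state), path, compress = "gzip")
  jsonlite::write_json(list(version = 1L,
                            fingerprint = as.character(model$fingerprint)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expect_fingerprint optional fingerprint string that the checkpoint
#'   must match (configuration error otherwise).
#' @export
load_checkpoint <- function(path, expect_fingerprint = NULL) {
  obj <- readRDS(path)
  model <- build_model(obj$config, seed = 0L)
  model$params <- obj$params
  model$state <- obj$state
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    fp <- jsonlite::read_json(side)$fingerprint
    if (!identical(fp, as.character(model$fingerprint)))
      wf_config_error("checkpoint fingerprint mismatch")
  }
  if (!is.null(expect_fingerprint) &&
      !identical(as.character(expect_fingerprint), as.character(model$fingerprint)))
    wf_config_error("checkpoint fingerprint does not match the expected architecture")
  model
}
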