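# Shared fixtures: tiny synthetic configurations, random tensor sets, and
# independent oracles used across test files.

# Small-lead synthetic spec for fast generator tests (4 leads, 100 Hz).
tiny_spec <- function(trials_per_class = 30L, seed = 1L, n_subjects = 1L) {
  synthetic_dataset_spec(n_subjects = n_subjects,
                         trials_per_class = trials_per_class,
                         n_leads = 4L, sampling_rate = 100, epoch_length = 1,
                         seed = seed)
}

tiny_leads <- function() c("P7", "P6", "O1", "Cz")

tiny_profiles <- function(spec, class_effect = 1, noise_scale = 0.3,
                          effect_leads = c("P7", "P6", "O1"), ...) {
  make_subject_profiles(spec, class_effect = class_effect,
                        noise_scale = noise_scale,
                        effect_leads = effect_leads,
                        lead_names = tiny_leads(), ...)
}

# Random labelled tensor set (no signal structure) for contrastive/training
# mechanics tests. n samples, s subjects, balanced classes.
random_tensor_set <- function(n = 16L, s = 2L, seed = 1L,
                              n_leads = 17L, h = 39L, w = 11L) {
  wavefusion:::with_seed(seed, {
    structure(list(
      x = array(abs(rnorm(n * n_leads * h * w)), c(n, n_leads, h, w)),
      y1 = rep(c(0L, 1L), length.out = n),
      y2 = rep(seq_len(s), each = ceiling(n / s))[seq_len(n)],
      lead_names = paste0("L", seq_len(n_leads)),
      freq_centers = seq_len(h) * 1.25,
      time_centers = seq(0, 1, length.out = w)
    ), class = "wf_tensor_set")
  })
}

# ---- independent oracles ----------------------------------------------------

# Naive direct 2-D convolution: x (C,H,W), weights in the package's
# (channel-fastest, then dh, then dw) x out_ch layout.
conv2d_naive <- function(x, W, b, kh, kw, sh, sw, ph, pw) {
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2 * ph, d[3] + 2 * pw))
  xp[, ph + seq_len(d[2]), pw + seq_len(d[3])] <- x
  oh <- (dim(xp)[2] - kh) %/% sh + 1L
  ow <- (dim(xp)[3] - kw) %/% sw + 1L
  out_ch <- ncol(W)
  y <- array(0, c(out_ch, oh, ow))
  for (oc in seq_len(out_ch)) {
    for (i in seq_len(oh)) for (j in seq_len(ow)) {
      acc <- 0
      for (dw_ in seq_len(kw)) for (dh_ in seq_len(kh)) for (c in seq_len(d[1])) {
        k <- c + d[1] * (dh_ - 1L) + d[1] * kh * (dw_ - 1L)
        acc <- acc + xp[c, (i - 1L) * sh + dh_, (j - 1L) * sw + dw_] * W[k, oc]
      }
      y[oc, i, j] <- acc + b[oc]
    }
  }
  y
}

maxpool_naive <- function(x) {
  d <- dim(x)
  y <- array(0, c(d[1], d[2] %/% 2L, d[3] %/% 2L))
  for (c in seq_len(d[1])) for (i in seq_len(d[2] %/% 2L)) for (j in seq_len(d[3] %/% 2L))
    y[c, i, j] <- max(x[c, (2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  y
}

# Full eval-mode per-lead CNN oracle (dropout inactive, BN with running stats).
lwcnn_naive <- function(model, x, lead = 1L) {
  p <- model$params$leads[[lead]]
  st <- model$state$leads[[lead]]
  stg <- model$config$stages
  bn_eval <- function(x, par, s, eps = 1e-5) {
    for (c in seq_len(dim(x)[1]))
      x[c, , ] <- par$gamma[c] * (x[c, , ] - s$mean[c]) / sqrt(s$var[c] + eps) +
        par$beta[c]
    x
  }
  a <- conv2d_naive(array(x, c(1L, dim(x))), p$conv1$W, p$conv1$b,
                    stg[[1]]$kh, stg[[1]]$kw, stg[[1]]$sh, stg[[1]]$sw,
                    stg[[1]]$ph, stg[[1]]$pw)
  a <- maxpool_naive(pmax(a, 0))
  a <- conv2d_naive(a, p$conv2$W, p$conv2$b,
                    stg[[2]]$kh, stg[[2]]$kw, stg[[2]]$sh, stg[[2]]$sw,
                    stg[[2]]$ph, stg[[2]]$pw)
  a <- bn_eval(maxpool_naive(pmax(a, 0)), p$bn2, st$bn2)
  a <- conv2d_naive(a, p$conv3$W, p$conv3$b,
                    stg[[3]]$kh, stg[[3]]$kw, stg[[3]]$sh, stg[[3]]$sw,
                    stg[[3]]$ph, stg[[3]]$pw)
  as.vector(bn_eval(a, p$bn3, st$bn3))
}

# Nested-loop scalar SAC loss oracle, straight from the definition.
sac_loss_loop <- function(Z, y1, y2, tau) {
  n <- nrow(Z)
  total <- 0
  for (i in seq_len(n)) {
    qs <- c(); ns <- c()
    for (j in seq_len(n)) {
      if (j == i) next
      if (y1[j] == y1[i] && y2[j] == y2[i]) qs <- c(qs, j)
      if (y1[j] != y1[i]) ns <- c(ns, j)
    }
    if (!length(qs) || !length(ns)) next
    den <- 0
    for (s in ns) den <- den + exp(sum(Z[i, ] * Z[s, ]) / tau)
    num <- 0
    for (q in qs) num <- num + exp(sum(Z[i, ] * Z[q, ]) / tau)
    total <- total - log((num / length(qs)) / den)
  }
  total
}

supcon_loss_loop <- function(Z, y1, tau) {
  n <- nrow(Z)
  total <- 0
  for (i in seq_len(n)) {
    pos <- setdiff(which(y1 == y1[i]), i)
    if (!length(pos)) next
    den <- 0
    for (a in setdiff(seq_len(n), i)) den <- den + exp(sum(Z[i, ] * Z[a, ]) / tau)
    for (p in pos) total <- total - log(exp(sum(Z[i, ] * Z[p, ]) / tau) / den) / length(pos)
  }
  total
}

random_unit_rows <- function(n, d, seed) {
  wavefusion:::with_seed(seed, {
    Z <- matrix(rnorm(n * d), n, d)
    Z / sqrt(rowSums(Z^2))
  })
}

# Minimal EDF writer for the reader round-trip test (2 channels).
write_tiny_edf <- function(path, sig, fs) {
  ns <- nrow(sig)
  n <- ncol(sig)
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeBin(charToRaw(pad(x, w)), con)
  wr("0", 8); wr("test patient", 80); wr("test recording", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8); wr("", 44); wr(1, 8); wr(1, 8); wr(ns, 4)
  for (i in seq_len(ns)) wr(paste0("CH", i), 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(-100, 8)     # phys min
  for (i in seq_len(ns)) wr(100, 8)      # phys max
  for (i in seq_len(ns)) wr(-32768, 8)
  for (i in seq_len(ns)) wr(32767, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(n, 8)
  for (i in seq_len(ns)) wr("", 32)
  dig <- round((sig + 100) / 200 * 65535 - 32768)
  for (i in seq_len(ns))
    writeBin(as.integer(dig[i, ]), con, size = 2L, endian = "little")
  invisible(path)
}
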