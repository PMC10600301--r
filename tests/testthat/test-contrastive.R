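# Contrastive machinery: augmentation statistics, view batches, contrast
# sets, SAC/SupCon losses and their gradients, batch composition.

test_that("augmentation with all-zero scales is the identity and dropout
           zeroes the expected fraction", {
  x <- array(abs(rnorm(17 * 39 * 11)) + 0.5, c(17, 39, 11))
  id_cfg <- augment_config(0, 0, 0)
  expect_identical(augment(x, id_cfg), x)
  drop_cfg <- augment_config(0, 0, 0.1)
  out <- wavefusion:::with_seed(2L, augment(x, drop_cfg))
  frac <- mean(out == 0)
  n <- length(x)
  ci <- qbinom(c(0.005, 0.995), n, 0.1) / n     # 99% binomial interval
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("the pink-noise component has a log-log spectral slope near -1", {
  d <- c(1L, 39L, 1L)
  cfg <- augment_config(pink_noise_scale = 1, gaussian_noise_scale = 0,
                        input_dropout_rate = 0)
  fc <- (1:39) * 1.25
  pw <- wavefusion:::with_seed(5L, {
    draws <- replicate(4000, augment(array(0, d) + 1, cfg, freq_centers = fc) - 1)
    rowMeans(matrix(draws^2, 39, 4000))
  })
  slope <- coef(lm(log(pw) ~ log(fc)))[2]
  expect_gt(slope, -1.15)
  expect_lt(slope, -0.85)
})

test_that("view batches duplicate labels and track provenance", {
  set <- random_tensor_set(n = 8L, s = 2L, seed = 3L)
  vb <- build_view_batch(set, idx = c(2L, 5L, 7L, 8L), seed = 1L)
  expect_equal(dim(vb$x)[1], 8L)
  expect_identical(vb$y1, rep(set$y1[c(2, 5, 7, 8)], each = 2L))
  expect_identical(vb$y2, rep(set$y2[c(2, 5, 7, 8)], each = 2L))
  expect_identical(vb$provenance, rep(c(2L, 5L, 7L, 8L), each = 2L))
  # view pairs share labels by construction
  expect_identical(vb$y1[seq(1, 7, 2)], vb$y1[seq(2, 8, 2)])
  expect_error(build_view_batch(set, integer()), class = "wf_config_error")
})

test_that("contrast sets implement the subject-aware predicates", {
  # 4 views: subject A class 0 x2, subject A class 1 x2
  y1 <- c(0, 0, 1, 1); y2 <- c(1, 1, 1, 1)
  cs <- contrast_sets(1L, y1, y2)
  expect_identical(cs$Q, 2L)
  expect_identical(sort(cs$N_a), c(3L, 4L))
  expect_length(cs$N_r, 0L)
  # brute-force double-loop oracle on random batches
  wavefusion:::with_seed(9L, {
    for (rep in 1:20) {
      n <- sample(4:12, 1)
      y1 <- sample(0:1, n, replace = TRUE)
      y2 <- sample(1:3, n, replace = TRUE)
      i <- sample(n, 1)
      cs <- contrast_sets(i, y1, y2)
      expect_false(i %in% c(cs$Q, cs$N_r, cs$N_a))
      for (j in seq_len(n)) {
        if (j == i) next
        expect_equal(j %in% cs$Q, y1[j] == y1[i] && y2[j] == y2[i])
        expect_equal(j %in% cs$N_r, y1[j] != y1[i] && y2[j] != y2[i])
        expect_equal(j %in% cs$N_a, y1[j] != y1[i] && y2[j] == y2[i])
      }
      # disjointness
      expect_equal(anyDuplicated(c(cs$Q, cs$N_r, cs$N_a)), 0L)
    }
  })
})

test_that("SAC loss reproduces closed-form cases", {
  # identical embeddings, one subject, 2 views per class: each anchor
  # contributes -log(e^{1/tau} / (2 e^{1/tau})) = ln 2
  Z <- matrix(rep(c(1, rep(0, 31)), 4), 4, 32, byrow = TRUE)
  expect_equal(sac_loss(Z, c(0, 0, 1, 1), rep(1, 4), tau = 0.5), 4 * log(2),
               tolerance = 1e-12)
  expect_equal(sac_loss(Z, c(0, 0, 1, 1), rep(1, 4), tau = 0.1), 4 * log(2),
               tolerance = 1e-12)
  # identical positive + orthogonal negative at tau = 1: per-anchor term
  # -log(e^1 / e^0) = -1 (the loss is not bounded below by zero)
  Z2 <- rbind(c(1, rep(0, 31)), c(1, rep(0, 31)), c(0, 1, rep(0, 30)))
  expect_warning(
    l <- sac_loss_grad(Z2, c(0, 0, 1), rep(1, 3), tau = 1, want_grad = FALSE),
    "skipped")
  expect_equal(l$loss, -2)        # two valid anchors, -1 each
  expect_equal(l$n_valid, 2L)
  # fully degenerate batch
  expect_error(
    suppressWarnings(sac_loss(Z, c(0, 0, 0, 0), rep(1, 4), tau = 1)),
    class = "wf_training_error")
})

test_that("vectorised SAC loss matches the nested-loop oracle and its
           gradient passes a finite-difference check", {
  for (rep in 1:25) {
    n <- 2L * sample(3:6, 1)
    Z <- random_unit_rows(n, 8L, seed = 100 + rep)
    y1 <- wavefusion:::with_seed(200 + rep, sample(0:1, n, replace = TRUE))
    y2 <- wavefusion:::with_seed(300 + rep, sample(1:3, n, replace = TRUE))
    ok <- tryCatch({
      l <- suppressWarnings(
        sac_loss_grad(Z, y1, y2, tau = 0.25))
      TRUE
    }, wf_training_error = function(e) FALSE)
    if (!ok) next
    expect_equal(l$loss, sac_loss_loop(Z, y1, y2, tau = 0.25),
                 tolerance = 1e-9)
    # finite differences on a few coordinates
    eps <- 1e-6
    for (k in 1:4) {
      i <- ((k * 7) %% n) + 1L
      j <- ((k * 3) %% ncol(Z)) + 1L
      Zp <- Z; Zp[i, j] <- Zp[i, j] + eps
      Zm <- Z; Zm[i, j] <- Zm[i, j] - eps
      fd <- (sac_loss_loop(Zp, y1, y2, 0.25) -
             sac_loss_loop(Zm, y1, y2, 0.25)) / (2 * eps)
      expect_equal(l$grad[i, j], fd, tolerance = 1e-4)
    }
  }
})

test_that("SAC loss is monotone in positive and negative similarities,
           permutation-invariant, and blind to same-class/other-subject views", {
  n <- 8L
  Z <- random_unit_rows(n, 16L, seed = 77)
  y1 <- c(0, 0, 1, 1, 0, 0, 1, 1)
  y2 <- c(1, 1, 1, 1, 2, 2, 2, 2)
  base <- suppressWarnings(sac_loss(Z, y1, y2, tau = 0.25))
  # pulling a positive pair together decreases the loss
  Zp <- Z
  Zp[2, ] <- Z[2, ] + 0.5 * (Z[1, ] - Z[2, ])
  Zp[2, ] <- Zp[2, ] / sqrt(sum(Zp[2, ]^2))
  expect_lt(suppressWarnings(sac_loss(Zp, y1, y2, 0.25)), base)
  # pushing a negative toward the anchor increases the loss
  Zn <- Z
  Zn[3, ] <- Z[3, ] + 0.5 * (Z[1, ] - Z[3, ])   # view 3 is N_a of anchor 1
  Zn[3, ] <- Zn[3, ] / sqrt(sum(Zn[3, ]^2))
  expect_gt(suppressWarnings(sac_loss(Zn, y1, y2, 0.25)), base)
  # permutation invariance
  perm <- c(5, 2, 8, 1, 3, 7, 4, 6)
  expect_equal(suppressWarnings(sac_loss(Z[perm, ], y1[perm], y2[perm], 0.25)),
               base, tolerance = 1e-10)
  # a same-class/other-subject view contributes nothing to an anchor's term:
  # perturbing view 6 (class 0, subject 3) leaves the per-anchor term of
  # every class-0 anchor unchanged, while opposite-class anchors (which use
  # it as an inter-subject negative) do change
  y2b <- c(1, 1, 1, 1, 2, 3, 2, 2)
  per_anchor <- function(Zm, i) {
    cs <- contrast_sets(i, y1, y2b)
    neg <- c(cs$N_r, cs$N_a)
    s <- tcrossprod(Zm) / 0.25
    log(length(cs$Q)) - log(sum(exp(s[i, cs$Q]))) + log(sum(exp(s[i, neg])))
  }
  Zq <- Z
  Zq[6, ] <- random_unit_rows(1, 16L, seed = 5)[1, ]
  for (i in which(y1 == y1[6])) {
    if (i == 6) next
    expect_equal(per_anchor(Zq, i), per_anchor(Z, i), tolerance = 1e-12)
  }
  expect_false(isTRUE(all.equal(per_anchor(Zq, 3), per_anchor(Z, 3))))
})

test_that("SupCon baseline matches its loop oracle and closed form", {
  # all-identical embeddings, balanced classes: L = 2N log(2N - 1)
  for (N in c(2L, 4L)) {
    Z <- matrix(rep(c(1, rep(0, 15)), 2 * N), 2 * N, 16, byrow = TRUE)
    y1 <- rep(c(0, 1), each = N)
    expect_equal(supcon_loss(Z, y1, tau = 0.3), 2 * N * log(2 * N - 1),
                 tolerance = 1e-10)
  }
  for (rep in 1:10) {
    n <- 2L * sample(3:6, 1)
    Z <- random_unit_rows(n, 8L, seed = 400 + rep)
    y1 <- wavefusion:::with_seed(500 + rep, sample(0:1, n, replace = TRUE))
    l <- tryCatch(suppressWarnings(supcon_loss_grad(Z, y1, tau = 0.25)),
                  wf_training_error = function(e) NULL)
    if (is.null(l)) next
    expect_equal(l$loss, supcon_loss_loop(Z, y1, 0.25), tolerance = 1e-9)
    eps <- 1e-6
    i <- 2L; j <- 3L
    Zp <- Z; Zp[i, j] <- Zp[i, j] + eps
    Zm <- Z; Zm[i, j] <- Zm[i, j] - eps
    fd <- (supcon_loss_loop(Zp, y1, 0.25) - supcon_loss_loop(Zm, y1, 0.25)) / (2 * eps)
    expect_equal(l$grad[i, j], fd, tolerance = 1e-4)
  }
  # single subject: SAC positives coincide with SupCon positives as sets
  y1 <- c(0, 0, 1, 1); y2 <- rep(1, 4)
  for (i in 1:4) {
    cs <- contrast_sets(i, y1, y2)
    supcon_pos <- setdiff(which(y1 == y1[i]), i)
    expect_identical(sort(cs$Q), sort(supcon_pos))
  }
})

test_that("batch composition validates fractions and draws role-correct
           samples without replacement", {
  expect_error(batch_composition_spec(0.5, 0.2, 0.2, 10L),
               class = "wf_config_error")
  expect_error(batch_composition_spec(0.33, 0.33, 0.34, 10L),
               class = "wf_config_error")   # non-integer counts
  spec <- batch_composition_spec(0.25, 0.5, 0.25, 40L)
  expect_identical(spec$counts, c(10L, 20L, 10L))
  index <- data.frame(subject = rep(1:3, each = 40),
                      class = rep(rep(0:1, each = 20), 3))
  idx <- compose_batch(index, list(1L, 0L), spec, seed = 11L)
  expect_length(idx, 40L)
  expect_equal(anyDuplicated(idx), 0L)
  expect_equal(sum(index$subject[idx] == 1 & index$class[idx] == 0), 10L)
  expect_equal(sum(index$subject[idx] == 1 & index$class[idx] == 1), 10L)
  expect_equal(sum(index$subject[idx] != 1 & index$class[idx] == 1), 20L)
  expect_equal(sum(index$subject[idx] != 1 & index$class[idx] == 0), 0L)
  # all-positive composition
  all_pos <- batch_composition_spec(1, 0, 0, 15L)
  idx2 <- compose_batch(index, list(2L, 1L), all_pos, seed = 1L)
  expect_true(all(index$subject[idx2] == 2 & index$class[idx2] == 1))
  # deficit errors name the role
  tiny <- data.frame(subject = c(1, 1), class = c(0, 1))
  err <- tryCatch(compose_batch(tiny, list(1L, 0L), spec, seed = 1L),
                  error = identity)
  expect_s3_class(err, "wf_data_error")
  expect_match(conditionMessage(err), "positives")
})
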