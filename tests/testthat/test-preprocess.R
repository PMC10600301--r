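# Preprocessing: bootstrap averaging, truncation/resampling, STFT, tensor
# assembly, EDF import.

toy_recording <- function(values, fs = 10, leads = c("A", "B")) {
  n_tr <- length(values)
  n <- 4L
  data <- array(0, c(n_tr, length(leads), n))
  for (i in seq_len(n_tr)) data[i, , ] <- values[i]
  wf_recording(data, fs, leads, subject_id = 1L,
               y1 = rep(0L, n_tr))
}

test_that("bootstrap averages are means of valid class subsets", {
  rec <- toy_recording(c(1, 2, 4))
  out <- bootstrap_average(rec, 0L, n_select = 2L, n_out = 6L, rng_seed = 4L)
  expect_equal(dim(out$data), c(6L, 2L, 4L))
  expect_identical(out$y1, rep(0L, 6L))
  # every output trial must equal the mean of one of the 2-subsets {1,2},{1,4},{2,4}
  possible <- c(mean(c(1, 2)), mean(c(1, 4)), mean(c(2, 4)))
  got <- apply(out$data, 1L, function(m) m[1, 1])
  expect_true(all(sapply(got, function(g) any(abs(g - possible) < 1e-12))))
  # with replacement across draws: determinism under the seed
  out2 <- bootstrap_average(rec, 0L, n_select = 2L, n_out = 6L, rng_seed = 4L)
  expect_identical(out$data, out2$data)
  # all trials identical -> every average equals that trial
  rec_id <- toy_recording(c(3, 3, 3))
  out_id <- bootstrap_average(rec_id, 0L, n_select = 2L, n_out = 4L)
  expect_true(all(out_id$data == 3))
})

test_that("bootstrap averaging errors when a class is too small, and the
           two-class default yields 1000 averaged trials", {
  rec <- toy_recording(c(1, 2, 4))
  expect_error(bootstrap_average(rec, 1L, n_select = 2L),
               class = "wf_data_error")
  err <- tryCatch(bootstrap_average(rec, 1L, n_select = 2L),
                  error = identity)
  expect_match(conditionMessage(err), "subject 1")
  expect_match(conditionMessage(err), "class 1")
  big <- wf_recording(array(rnorm(60 * 2 * 4), c(60, 2, 4)), 10, c("A", "B"),
                      1L, rep(c(0L, 1L), each = 30L))
  out <- bootstrap_average_classes(big, n_select = 25L, n_out = 500L)
  expect_equal(dim(out$data)[1], 1000L)
  expect_equal(sum(out$y1 == 0L), 500L)
})

test_that("bootstrap averaging commutes with lead selection", {
  set.seed(8)
  rec <- wf_recording(array(rnorm(6 * 3 * 5), c(6, 3, 5)), 10,
                      c("A", "B", "C"), 1L, rep(0L, 6))
  full <- bootstrap_average(rec, 0L, n_select = 3L, n_out = 4L, rng_seed = 2L)
  sub <- wf_recording(rec$data[, 2L, , drop = FALSE], 10, "B", 1L, rec$y1)
  subavg <- bootstrap_average(sub, 0L, n_select = 3L, n_out = 4L, rng_seed = 2L)
  expect_equal(full$data[, 2L, ], subavg$data[, 1L, ])
})

test_that("truncation and resampling give the expected lengths and preserve
           dominant frequency content", {
  tt <- seq(0, 1.999, by = 1 / 500)
  sig <- sin(2 * pi * 10 * tt)
  rec <- wf_recording(array(rep(sig, each = 1), c(1, 1, length(tt))), 500,
                      "P7", 1L, 0L)
  out <- truncate_and_resample(rec, 0, 1, 100)
  expect_equal(dim(out$data)[3], 100L)
  expect_equal(out$sampling_rate, 100)
  # dominant DFT bin still 10 Hz after anti-aliased decimation
  y <- out$data[1, 1, ]
  p <- Mod(fft(y))[2:50]
  freqs <- (1:49) * 100 / 100
  expect_equal(freqs[which.max(p)], 10)
  # identity case
  idt <- truncate_and_resample(rec, 0, 2, 500)
  expect_equal(idt$data, rec$data)
  expect_error(truncate_and_resample(rec, 1.5, 1, 100), class = "wf_data_error")
})

test_that("default STFT maps 100 samples to a 39 x 11 magnitude array", {
  x <- sin(2 * pi * 10 * seq(0, 0.99, by = 0.01))
  sp <- compute_spectrogram(x, stft_config(), 100)
  expect_equal(dim(sp), c(39L, 11L))
  expect_true(all(sp >= 0))
  fc <- attr(sp, "freq_centers")
  expect_equal(fc[1], 1.25)
  expect_equal(fc[39], 48.75)
  # per-frame argmax lands on the bin whose center is nearest 10 Hz
  nearest <- fc[which.min(abs(fc - 10))]
  expect_true(all(fc[apply(sp, 2L, which.max)] == nearest))
  # all-zero signal -> all-zero output
  expect_true(all(compute_spectrogram(numeric(100), stft_config(), 100) == 0))
  # too-short signal errors
  expect_error(compute_spectrogram(numeric(5), stft_config(80, 10, 0)),
               class = "wf_data_error")
  expect_error(stft_config(hop = 0), class = "wf_config_error")
  expect_error(stft_config(kept_bins = c(1, 60)), class = "wf_config_error")
})

test_that("tensor assembly selects posterior leads in the documented order", {
  leads <- default_montage()$lead_name
  specs <- lapply(seq_along(leads), function(i) matrix(i, 39, 11))
  names(specs) <- leads
  tens <- assemble_tensor(specs)
  expect_equal(dim(tens), c(17L, 39L, 11L))
  expect_identical(attr(tens, "lead_names"), posterior_leads())
  expect_equal(tens[1, 1, 1], which(leads == "P7"))
  # permuting the input lead order leaves the tensor unchanged
  perm <- wavefusion:::with_seed(3L, sample(seq_along(leads)))
  tens2 <- assemble_tensor(specs[perm])
  expect_equal(unclass(tens2), unclass(tens), ignore_attr = TRUE)
  # keeping all leads preserves input order
  all63 <- assemble_tensor(specs, posterior_set = leads)
  expect_equal(dim(all63)[1], 63L)
  expect_error(assemble_tensor(specs, posterior_set = c("P7", "XX9")),
               class = "wf_config_error")
})

test_that("end-to-end preprocessing is deterministic and correctly labelled", {
  spec <- synthetic_dataset_spec(n_subjects = 1L, trials_per_class = 3L,
                                 n_leads = 63L, sampling_rate = 500,
                                 epoch_length = 1.2, seed = 6L)
  rec <- generate_dataset(spec, make_subject_profiles(spec, noise_scale = 0.3))[[1]]
  a <- preprocess_recording(rec)
  b <- preprocess_recording(rec)
  expect_identical(a$x, b$x)
  expect_equal(dim(a$x), c(6L, 17L, 39L, 11L))
  expect_identical(a$y1, rec$y1)
  expect_identical(a$y2, rep(1L, 6L))
  expect_true(all(a$x >= 0))
})

test_that("EDF files round-trip through the reader", {
  fs <- 50
  tt <- seq(0, 0.98, by = 1 / fs)
  sig <- rbind(10 * sin(2 * pi * 5 * tt), 5 * cos(2 * pi * 8 * tt))
  path <- withr::local_tempfile(fileext = ".edf")
  write_tiny_edf(path, sig, fs)
  rec <- read_edf(path)
  expect_s3_class(rec, "wf_recording")
  expect_equal(dim(rec$data), c(1L, 2L, length(tt)))
  expect_equal(rec$sampling_rate, length(tt))
  expect_identical(rec$lead_names, c("CH1", "CH2"))
  # 16-bit quantisation over [-100, 100] is ~0.003 per step
  expect_lt(max(abs(rec$data[1, , ] - sig)), 0.01)
})
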