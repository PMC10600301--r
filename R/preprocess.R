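# Preprocessing: epoched recordings -> 17 x 39 x 11 spectrogram tensors.
#
# STFT dialect. The pipeline targets a 39 x 11 magnitude spectrogram from a
# 1-second, 100-Hz epoch. The default configuration that produces it is:
# window_length = 80 samples (Hann taper), hop = 10 samples (75% overlap
# rounded to the sample grid), symmetric zero boundary padding of 40 samples,
# keeping frequency bins 1..39 (DC and the Nyquist bin dropped). All of it is
# configurable through stft_config().

#' Construct an epoched recording
#'
#' @param data `trials x leads x samples` numeric array (microvolts).
#' @param sampling_rate sampling rate in Hz.
#' @param lead_names lead labels, one per lead axis entry.
#' @param subject_id integer subject identifier.
#' @param y1 per-trial binary condition labels (0/1).
#' @return an object of class `wf_recording`.
#' @export
wf_recording <- function(data, sampling_rate, lead_names, subject_id, y1) {
  if (length(dim(data)) != 3L)
    wf_data_error("recording data must be a trials x leads x samples array")
  if (!all(is.finite(data))) wf_data_error("recording data must be finite")
  if (length(lead_names) != dim(data)[2])
    wf_data_error("lead_names length (%d) != lead axis length (%d)",
                  length(lead_names), dim(data)[2])
  if (length(y1) != dim(data)[1])
    wf_data_error("y1 length (%d) != trial count (%d)", length(y1), dim(data)[1])
  if (!all(y1 %in% c(0L, 1L))) wf_data_error("y1 labels must be 0 or 1")
  structure(list(data = data, sampling_rate = sampling_rate,
                 lead_names = as.character(lead_names),
                 subject_id = as.integer(subject_id),
                 y1 = as.integer(y1)),
            class = "wf_recording")
}

#' @export
print.wf_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("wf_recording: subject %d, %d trials x %d leads x %d samples @ %g Hz (classes: %d/%d)\n",
              x$subject_id, d[1], d[2], d[3], x$sampling_rate,
              sum(x$y1 == 0L), sum(x$y1 == 1L)))
  invisible(x)
}

#' Bootstrap trial averaging
#'
#' Builds `n_out` synthetic trials for one condition, each the arithmetic
#' mean of `n_select` trials of that condition drawn uniformly without
#' replacement within a draw (with replacement across draws). Averaging
#' raises the signal-to-noise ratio of weak condition effects before
#' spectrogram extraction.
#'
#' @param recording a `wf_recording`.
#' @param class_label which condition (0 or 1) to average.
#' @param n_select trials averaged per draw (default 25).
#' @param n_out number of averaged trials to emit (default 500).
#' @param rng_seed integer seed for the draws.
#' @return a `wf_recording` with `n_out` trials, all labelled `class_label`.
#' @export
bootstrap_average <- function(recording, class_label, n_select = 25L,
                              n_out = 500L, rng_seed = 1L) {
  idx <- which(recording$y1 == class_label)
  if (length(idx) < n_select)
    wf_data_error("subject %d has %d trials of class %d; need at least %d",
                  recording$subject_id, length(idx), class_label, n_select)
  d <- dim(recording$data)
  flat <- matrix(recording$data, d[1], d[2] * d[3])   # trials x (lead,sample)
  out <- with_seed(rng_seed, {
    draws <- replicate(n_out, sample_from(idx, n_select),
                       simplify = FALSE)
    t(vapply(draws, function(dr) colMeans(flat[dr, , drop = FALSE]),
             numeric(d[2] * d[3])))
  })
  wf_recording(array(out, c(n_out, d[2], d[3])),
               sampling_rate = recording$sampling_rate,
               lead_names = recording$lead_names,
               subject_id = recording$subject_id,
               y1 = rep(as.integer(class_label), n_out))
}

#' @rdname bootstrap_average
#' @description `bootstrap_average_classes()` averages both conditions and
#'   concatenates them (`n_out` trials per class, class 0 first), the default
#'   yielding 1000 averaged trials per subject.
#' @export
bootstrap_average_classes <- function(recording, n_select = 25L, n_out = 500L,
                                      rng_seed = 1L) {
  r0 <- bootstrap_average(recording, 0L, n_select, n_out,
                          derive_seed(rng_seed, "class0"))
  r1 <- bootstrap_average(recording, 1L, n_select, n_out,
                          derive_seed(rng_seed, "class1"))
  d <- dim(r0$data)
  data <- array(0, c(2L * n_out, d[2], d[3]))
  data[seq_len(n_out), , ] <- r0$data
  data[n_out + seq_len(n_out), , ] <- r1$data
  wf_recording(data, recording$sampling_rate, recording$lead_names,
               recording$subject_id, c(r0$y1, r1$y1))
}

#' Truncate an epoch window and resample
#'
#' Cuts each trial to `[start_s, start_s + duration_s)` and resamples to
#' `target_rate` with an anti-aliasing FIR filter (polyphase resampling when
#' the ratio is not an integer).
#'
#' @param recording a `wf_recording`.
#' @param start_s window start in seconds from trial onset.
#' @param duration_s window length in seconds (default 1).
#' @param target_rate output sampling rate in Hz (default 100).
#' @return a `wf_recording` with `duration_s * target_rate` samples per trial.
#' @export
truncate_and_resample <- function(recording, start_s = 0, duration_s = 1,
                                  target_rate = 100) {
  fs <- recording$sampling_rate
  n <- dim(recording$data)[3]
  i0 <- round(start_s * fs) + 1L
  i1 <- i0 + round(duration_s * fs) - 1L
  if (i0 < 1L || i1 > n)
    wf_data_error("window [%g, %g) s outside trial extent (%g s)",
                  start_s, start_s + duration_s, n / fs)
  cut <- recording$data[, , i0:i1, drop = FALSE]
  if (target_rate == fs) {
    out <- cut
  } else {
    d <- dim(cut)
    q <- fs / target_rate
    n_out <- round(duration_s * target_rate)
    out <- array(0, c(d[1], d[2], n_out))
    for (tr in seq_len(d[1])) {
      for (l in seq_len(d[2])) {
        x <- cut[tr, l, ]
        y <- if (q == round(q)) {
          signal::decimate(x, as.integer(q), ftype = "fir")
        } else {
          signal::resample(x, p = target_rate, q = fs)
        }
        out[tr, l, ] <- y[seq_len(n_out)]
      }
    }
  }
  wf_recording(out, sampling_rate = target_rate,
               lead_names = recording$lead_names,
               subject_id = recording$subject_id, y1 = recording$y1)
}

#' STFT configuration
#'
#' @param window_length analysis window length in samples (default 80).
#' @param hop hop between consecutive frames in samples (default 10,
#'   i.e. 87.5% overlap of the 80-sample window on the padded signal; the
#'   default tuple is the one that maps a 100-sample epoch to 11 frames).
#' @param boundary_padding zeros added at each end of the signal (default 40).
#' @param kept_bins inclusive range of kept frequency-bin indices
#'   (1-based DFT bin number, default `c(1, 39)`: DC and Nyquist dropped).
#' @param window_function taper name: "hann" or "rectangular".
#' @return a list of class `wf_stft_config`.
#' @export
stft_config <- function(window_length = 80L, hop = 10L, boundary_padding = 40L,
                        kept_bins = c(1L, 39L), window_function = "hann") {
  if (hop <= 0 || hop > window_length)
    wf_config_error("need 0 < hop <= window_length")
  if (kept_bins[1] < 0 || kept_bins[2] > window_length / 2 ||
      kept_bins[1] > kept_bins[2])
    wf_config_error("kept_bins must lie within [0, window_length/2]")
  window_function <- match.arg(window_function, c("hann", "rectangular"))
  structure(list(window_length = as.integer(window_length),
                 hop = as.integer(hop),
                 boundary_padding = as.integer(boundary_padding),
                 kept_bins = as.integer(kept_bins),
                 window_function = window_function),
            class = "wf_stft_config")
}

stft_taper <- function(config) {
  n <- config$window_length
  switch(config$window_function,
         hann = 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)),
         rectangular = rep(1, n))
}

#' Magnitude spectrogram of one trial-lead signal
#'
#' Zero-pads the signal at both ends, slides a tapered window, takes the DFT
#' magnitude of each frame and keeps the configured bin range. With the
#' default configuration a 100-sample input yields a 39 x 11 array.
#'
#' @param x numeric vector (one lead of one trial).
#' @param config a [stft_config()].
#' @param sampling_rate sampling rate in Hz (for the frequency axis metadata).
#' @return `freq x time` nonnegative matrix with attributes `freq_centers`
#'   (Hz) and `time_centers` (s).
#' @export
compute_spectrogram <- function(x, config = stft_config(), sampling_rate = 100) {
  n <- length(x)
  pad <- config$boundary_padding
  win <- config$window_length
  xp <- c(numeric(pad), x, numeric(pad))
  np <- length(xp)
  if (np < win)
    wf_data_error("signal of length %d (+%d padding) shorter than window %d",
                  n, 2L * pad, win)
  starts <- seq(1L, np - win + 1L, by = config$hop)
  taper <- stft_taper(config)
  frames <- vapply(starts, function(s) xp[s:(s + win - 1L)] * taper,
                   numeric(win))
  spec <- Mod(stats::mvfft(frames))
  bins <- seq(config$kept_bins[1], config$kept_bins[2]) + 1L  # 1-based rows
  out <- spec[bins, , drop = FALSE]
  attr(out, "freq_centers") <- (bins - 1L) * sampling_rate / win
  attr(out, "time_centers") <- (starts - 1L - pad + (win - 1) / 2) / sampling_rate
  out
}

#' Assemble per-lead spectrograms into the model input tensor
#'
#' Stacks the spectrograms of the requested leads, in exactly the order of
#' `posterior_set` (independent of the input lead order).
#'
#' @param spectrograms named list of equal-shaped `freq x time` matrices, or a
#'   `leads x freq x time` array.
#' @param lead_names lead names of the input (required for the array form).
#' @param posterior_set lead names to keep, in output order (default: the 17
#'   posterior leads).
#' @return `length(posterior_set) x freq x time` array of class `wf_tensor`
#'   with a `lead_names` attribute.
#' @export
assemble_tensor <- function(spectrograms, lead_names = NULL,
                            posterior_set = posterior_leads()) {
  if (is.list(spectrograms)) {
    lead_names <- names(spectrograms)
    shp <- dim(spectrograms[[1]])
    arr <- array(0, c(length(spectrograms), shp))
    for (i in seq_along(spectrograms)) {
      if (!all(dim(spectrograms[[i]]) == shp))
        wf_data_error("spectrogram shapes differ across leads")
      arr[i, , ] <- spectrograms[[i]]
    }
  } else {
    arr <- spectrograms
    if (is.null(lead_names))
      wf_config_error("lead_names required for array input")
  }
  missing <- setdiff(posterior_set, lead_names)
  if (length(missing))
    wf_config_error("leads absent from montage: %s",
                    paste(missing, collapse = ", "))
  sel <- match(posterior_set, lead_names)
  out <- arr[sel, , , drop = FALSE]
  attr(out, "lead_names") <- posterior_set
  class(out) <- c("wf_tensor", class(out))
  out
}

#' End-to-end preprocessing of one recording
#'
#' Truncation/resampling, per-lead STFT and posterior tensor assembly for
#' every trial. Optionally z-scores each tensor.
#'
#' @param recording a `wf_recording`.
#' @param stft a [stft_config()].
#' @param posterior_set lead names kept in the tensor.
#' @param start_s,duration_s,target_rate window and rate passed to
#'   [truncate_and_resample()].
#' @param normalize logical; z-score each tensor (default FALSE).
#' @return a `wf_tensor_set`: list with `x` (`trials x leads x freq x time`
#'   array), `y1`, `y2` (subject id per trial), `lead_names`, `freq_centers`,
#'   `time_centers`.
#' @export
preprocess_recording <- function(recording, stft = stft_config(),
                                 posterior_set = posterior_leads(),
                                 start_s = 0, duration_s = 1,
                                 target_rate = 100, normalize = FALSE) {
  sel <- match(posterior_set, recording$lead_names)
  if (anyNA(sel))
    wf_config_error("leads absent from montage: %s",
                    paste(posterior_set[is.na(sel)], collapse = ", "))
  sub <- wf_recording(recording$data[, sel, , drop = FALSE],
                      recording$sampling_rate, posterior_set,
                      recording$subject_id, recording$y1)
  rec <- truncate_and_resample(sub, start_s, duration_s, target_rate)
  d <- dim(rec$data)
  probe <- compute_spectrogram(rec$data[1, 1, ], stft, target_rate)
  x <- array(0, c(d[1], length(sel), nrow(probe), ncol(probe)))
  for (tr in seq_len(d[1])) {
    for (j in seq_along(sel)) {
      x[tr, j, , ] <- compute_spectrogram(rec$data[tr, j, ], stft,
                                          target_rate)
    }
    if (normalize) {
      m <- mean(x[tr, , , ]); s <- stats::sd(x[tr, , , ])
      if (s > 0) x[tr, , , ] <- (x[tr, , , ] - m) / s
    }
  }
  structure(list(x = x, y1 = rec$y1,
                 y2 = rep(rec$subject_id, d[1]),
                 lead_names = posterior_set,
                 freq_centers = attr(probe, "freq_centers"),
                 time_centers = attr(probe, "time_centers")),
            class = "wf_tensor_set")
}

#' @rdname preprocess_recording
#' @param recordings list of `wf_recording`s (one per subject).
#' @param ... passed to `preprocess_recording`.
#' @export
preprocess_dataset <- function(recordings, ...) {
  sets <- lapply(recordings, preprocess_recording, ...)
  bind_tensor_sets(sets)
}

#' Concatenate tensor sets along the trial axis
#' @param sets list of `wf_tensor_set`s.
#' @return a single `wf_tensor_set`.
#' @export
bind_tensor_sets <- function(sets) {
  ns <- vapply(sets, function(s) dim(s$x)[1], 1L)
  d <- dim(sets[[1]]$x)
  x <- array(0, c(sum(ns), d[2], d[3], d[4]))
  at <- 0L
  for (s in sets) {
    x[at + seq_len(dim(s$x)[1]), , , ] <- s$x
    at <- at + dim(s$x)[1]
  }
  structure(list(x = x, y1 = unlist(lapply(sets, `[[`, "y1")),
                 y2 = unlist(lapply(sets, `[[`, "y2")),
                 lead_names = sets[[1]]$lead_names,
                 freq_centers = sets[[1]]$freq_centers,
                 time_centers = sets[[1]]$time_centers),
            class = "wf_tensor_set")
}

subset_tensor_set <- function(set, idx) {
  structure(list(x = set$x[idx, , , , drop = FALSE], y1 = set$y1[idx],
                 y2 = set$y2[idx], lead_names = set$lead_names,
                 freq_centers = set$freq_centers,
                 time_centers = set$time_centers),
            class = "wf_tensor_set")
}

# ---- EDF import -------------------------------------------------------------

#' Read a European Data Format (EDF) file as an epoched recording
#'
#' Minimal EDF reader: parses the fixed-width ASCII headers and the 16-bit
#' little-endian data records, applies the per-channel physical calibration,
#' and returns the result as a single-"trial" recording (continuous data).
#' Channels must share one sampling rate.
#'
#' @param path path to an uncompressed EDF file.
#' @param subject_id subject id to attach (EDF has no numeric id field).
#' @return a `wf_recording` with one trial.
#' @export
read_edf <- function(path, subject_id = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rd(8); rd(80); rd(80); rd(8); rd(8)           # version, patient, rec, date, time
  rd(8)                                          # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)                  # transducer
  for (i in seq_len(ns)) rd(8)                   # units
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 1)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 1)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 1)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 1)
  for (i in seq_len(ns)) rd(80)                  # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 1L)
  for (i in seq_len(ns)) rd(32)                  # reserved
  if (length(unique(spr)) != 1L)
    wf_data_error("EDF channels have differing sampling rates")
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  sig <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[ch], size = 2L,
                     endian = "little", signed = TRUE)
      sig[ch, (r - 1L) * spr[ch] + seq_len(spr[ch])] <-
        gain[ch] * raw + offset[ch]
    }
  }
  wf_recording(array(sig, c(1L, ns, ncol(sig))),
               sampling_rate = spr[1] / rec_dur,
               lead_names = labels, subject_id = subject_id, y1 = 0L)
}
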