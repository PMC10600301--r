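# Synthetic multi-subject EEG generator. Trials are sums of (a) sinusoidal
# components with per-subject amplitude fingerprints and random phases,
# (b) a class-dependent multiplicative power modulation confined to a
# frequency band and a lead subset, and (c) broadband 1/f ("pink") Gaussian
# noise. Band powers are analytically controllable, which is what makes the
# generator usable as a calibration instrument for the downstream model.

#' Default 63-lead montage
#'
#' Reads the 10-20/10-10 montage shipped with the package: 63 lead names with
#' 2-D unit-disk scalp coordinates (nasion at the top, `y > 0` frontal).
#' @param path optional path to a montage CSV with columns
#'   `lead_name`, `x`, `y`.
#' @return a data.frame with columns `lead_name`, `x`, `y`.
#' @export
default_montage <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "montage_1020_63.csv", package = "wavefusion")
  read_montage(path)
}

#' @rdname default_montage
#' @export
read_montage <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lead_name", "x", "y")
  if (!all(need %in% names(m)))
    wf_config_error("montage CSV must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(m$lead_name))
    wf_data_error("duplicate lead names in montage")
  if (any(m$x^2 + m$y^2 >= 1))
    wf_data_error("montage coordinates must lie strictly inside the unit disk")
  m[need]
}

#' The 17 posterior leads used by the fusion model
#'
#' Parietal, parieto-occipital and occipital labels of the 10-10 system,
#' in the fixed order used for tensor assembly.
#' @return a character vector of 17 lead names.
#' @export
posterior_leads <- function() {
  c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2")
}

#' Specification of a synthetic dataset
#'
#' @param n_subjects number of subjects (default 10).
#' @param trials_per_class trials per condition per subject.
#' @param n_leads number of leads (default 63).
#' @param sampling_rate sampling rate in Hz (default 500); must exceed twice
#'   the highest generated frequency.
#' @param epoch_length epoch duration in seconds.
#' @param seed master seed; per-subject streams are derived from it so adding
#'   a subject does not perturb the others.
#' @param component_freqs frequencies (Hz) of the sinusoidal components.
#' @return a list of class `wf_dataset_spec`.
#' @export
synthetic_dataset_spec <- function(n_subjects = 10L, trials_per_class = 100L,
                                   n_leads = 63L, sampling_rate = 500,
                                   epoch_length = 2, seed = 1L,
                                   component_freqs = seq(2, 30, by = 2)) {
  if (any(c(n_subjects, trials_per_class, n_leads) < 1))
    wf_config_error("all counts must be >= 1")
  if (sampling_rate <= 2 * max(component_freqs))
    wf_config_error("sampling_rate (%g Hz) must exceed twice the highest component frequency (%g Hz)",
                    sampling_rate, max(component_freqs))
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_class = as.integer(trials_per_class),
                 n_leads = as.integer(n_leads), sampling_rate = sampling_rate,
                 epoch_length = epoch_length, seed = as.integer(seed),
                 component_freqs = component_freqs),
            class = "wf_dataset_spec")
}

#' Per-subject generative profile
#'
#' @param subject_id integer subject identifier.
#' @param spec the dataset spec (used for dimensions and the seed stream).
#' @param baseline_spectrum optional `n_leads x n_freqs` matrix of nonnegative
#'   component amplitudes; drawn from a subject-specific log-normal
#'   fingerprint when NULL.
#' @param class_effect multiplicative band-power modulation (>= 0) applied to
#'   class-1 trials; 1 means the two classes are identically distributed.
#' @param effect_band frequency band (Hz) carrying the class effect
#'   (default 8-13 Hz, the alpha band).
#' @param effect_leads lead names carrying the class effect (default: the
#'   posterior montage set).
#' @param noise_scale standard deviation of the broadband 1/f noise.
#' @param lead_names lead labels; defaults to the first `n_leads` montage rows.
#' @return a list of class `wf_subject_profile`.
#' @export
subject_profile <- function(subject_id, spec,
                            baseline_spectrum = NULL,
                            class_effect = 1,
                            effect_band = c(8, 13),
                            effect_leads = posterior_leads(),
                            noise_scale = 1,
                            lead_names = NULL) {
  if (class_effect < 0) wf_config_error("class_effect must be >= 0")
  if (is.null(lead_names))
    lead_names <- default_montage()$lead_name[seq_len(spec$n_leads)]
  nf <- length(spec$component_freqs)
  if (is.null(baseline_spectrum)) {
    baseline_spectrum <- with_seed(
      derive_seed(spec$seed, "profile", subject_id),
      matrix(exp(rnorm(spec$n_leads * nf, mean = 0, sd = 0.35)),
             spec$n_leads, nf)
    )
  }
  if (any(baseline_spectrum < 0))
    wf_config_error("baseline_spectrum entries must be >= 0")
  if (!all(dim(baseline_spectrum) == c(spec$n_leads, nf)))
    wf_config_error("baseline_spectrum must be %d x %d", spec$n_leads, nf)
  structure(list(subject_id = as.integer(subject_id),
                 baseline_spectrum = baseline_spectrum,
                 class_effect = class_effect, effect_band = effect_band,
                 effect_leads = effect_leads, noise_scale = noise_scale,
                 lead_names = lead_names),
            class = "wf_subject_profile")
}

#' @rdname subject_profile
#' @param ... passed on to [subject_profile()] for every subject.
#' @export
make_subject_profiles <- function(spec, ...) {
  lapply(seq_len(spec$n_subjects), function(s) subject_profile(s, spec, ...))
}

# 1/f-shaped Gaussian noise, one row per trial, unit marginal sd before
# scaling. Spectral amplitudes fall as 1/sqrt(f).
pink_noise_rows <- function(n_trials, n, sampling_rate, sd = 1) {
  freqs <- seq(0, n - 1) * sampling_rate / n
  shape <- numeric(n)
  half <- floor(n / 2)
  shape[2:(half + 1)] <- 1 / sqrt(freqs[2:(half + 1)])
  if (n %% 2 == 0) {
    shape[seq(n, half + 2)] <- shape[2:(half)]
  } else {
    shape[seq(n, half + 2)] <- shape[2:(half + 1)]
  }
  w <- matrix(stats::rnorm(n_trials * n), n, n_trials)
  ft <- stats::mvfft(w) * shape
  x <- Re(stats::mvfft(ft, inverse = TRUE)) / n
  x <- x / stats::sd(as.vector(x))
  t(x) * sd
}

#' Generate a multi-subject synthetic EEG dataset
#'
#' @param spec a [synthetic_dataset_spec()].
#' @param profiles list of [subject_profile()]s, one per subject.
#' @return a list of `wf_recording` objects (one per subject), each holding a
#'   `trials x leads x samples` array, per-trial class labels `y1`
#'   (`trials_per_class` zeros followed by `trials_per_class` ones), the
#'   subject id and the sampling rate. Fully reproducible from `spec$seed`.
#' @export
generate_dataset <- function(spec, profiles) {
  if (length(profiles) != spec$n_subjects)
    wf_config_error("expected %d subject profiles, got %d",
                    spec$n_subjects, length(profiles))
  lapply(profiles, function(pr) generate_subject(spec, pr))
}

generate_subject <- function(spec, profile) {
  n <- round(spec$epoch_length * spec$sampling_rate)
  n_tr <- 2L * spec$trials_per_class
  tt <- seq(0, length.out = n, by = 1 / spec$sampling_rate)
  y1 <- rep(c(0L, 1L), each = spec$trials_per_class)
  freqs <- spec$component_freqs
  in_band <- freqs >= profile$effect_band[1] & freqs <= profile$effect_band[2]
  lead_eff <- profile$lead_names %in% profile$effect_leads
  data <- array(0, c(n_tr, spec$n_leads, n))
  with_seed(derive_seed(spec$seed, "subject", profile$subject_id), {
    basis <- do.call(rbind, lapply(freqs, function(f)
      rbind(cos(2 * pi * f * tt), sin(2 * pi * f * tt))))   # (2F) x n
    for (l in seq_len(spec$n_leads)) {
      phases <- matrix(stats::runif(n_tr * length(freqs), 0, 2 * pi),
                       n_tr, length(freqs))
      amp <- profile$baseline_spectrum[l, ]
      # class modulation multiplies band *power*, i.e. amplitude by sqrt()
      gain <- matrix(rep(amp, each = n_tr), n_tr, length(freqs))
      if (lead_eff[l] && any(in_band) && profile$class_effect != 1) {
        gain[y1 == 1L, in_band] <- gain[y1 == 1L, in_band] *
          sqrt(profile$class_effect)
      }
      coef <- matrix(0, n_tr, 2L * length(freqs))
      coef[, seq(1, by = 2, length.out = length(freqs))] <- gain * sin(phases)
      coef[, seq(2, by = 2, length.out = length(freqs))] <- gain * cos(phases)
      sig <- coef %*% basis
      sig <- sig + pink_noise_rows(n_tr, n, spec$sampling_rate,
                                   sd = profile$noise_scale)
      data[, l, ] <- sig
    }
  })
  wf_recording(data, sampling_rate = spec$sampling_rate,
               lead_names = profile$lead_names,
               subject_id = profile$subject_id, y1 = y1)
}

#' Band power of trials at one lead
#'
#' Mean periodogram power inside a frequency band, one value per trial.
#' Used to calibrate the generator (two-sample tests between classes) and to
#' verify that subject fingerprints are decodable.
#' @param recording a `wf_recording`.
#' @param band frequency band in Hz, `c(low, high)`.
#' @param lead lead name or index.
#' @return numeric vector, one band-power value per trial.
#' @export
band_power <- function(recording, band = c(8, 13), lead = 1L) {
  if (is.character(lead)) lead <- match(lead, recording$lead_names)
  n <- dim(recording$data)[3]
  freqs <- seq(0, n - 1) * recording$sampling_rate / n
  keep <- which(freqs >= band[1] & freqs <= band[2] & freqs <= recording$sampling_rate / 2)
  x <- t(recording$data[, lead, ])              # samples x trials
  p <- Mod(stats::mvfft(x))^2 / n
  colMeans(p[keep, , drop = FALSE])
}

# ---- fixture archive I/O ----------------------------------------------------

#' Write / read recording archives
#'
#' One compressed array archive per subject (`subject_<id>.rds`, the
#' `trials x leads x samples` array) plus a JSON sidecar
#' (`subject_<id>.json`) carrying labels, subject id, sampling rate and lead
#' names.
#' @param recordings list of `wf_recording`s.
#' @param dir output directory (created if needed).
#' @return `write_recordings` returns the directory invisibly;
#'   `read_recordings` returns a list of `wf_recording`s.
#' @export
write_recordings <- function(recordings, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in recordings) {
    base <- file.path(dir, sprintf("subject_%02d", rec$subject_id))
    saveRDS(rec$data, paste0(base, ".rds"), compress = "gzip")
    jsonlite::write_json(
      list(subject_id = rec$subject_id, sampling_rate = rec$sampling_rate,
           lead_names = rec$lead_names, y1 = rec$y1),
      paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_recordings
#' @export
read_recordings <- function(dir) {
  sidecars <- sort(list.files(dir, pattern = "^subject_.*\\.json$",
                              full.names = TRUE))
  if (!length(sidecars)) wf_data_error("no recording archives found in %s", dir)
  lapply(sidecars, function(sc) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    data <- readRDS(sub("\\.json$", ".rds", sc))
    wf_recording(data, sampling_rate = meta$sampling_rate,
                 lead_names = meta$lead_names,
                 subject_id = meta$subject_id, y1 = meta$y1)
  })
}
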