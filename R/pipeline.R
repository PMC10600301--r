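# End-to-end pipeline: simulate -> preprocess -> pretrain -> finetune ->
# evaluate -> explain, with YAML-configurable parameters, per-stage artifacts
# under a run directory, and a summary JSON with seeds, metrics and artifact
# checksums.

#' Default run configuration
#'
#' @param preset `"tiny"` (2 subjects x 40 samples, a smoke-test scale that
#'   completes in well under two minutes) or `"paper"` (10 subjects with
#'   bootstrap averaging to 1000 samples each and batch size 500 — the
#'   published protocol scale; expect a long CPU run).
#' @return a nested configuration list of class `wf_run_config`.
#' @export
default_run_config <- function(preset = c("tiny", "paper")) {
  preset <- match.arg(preset)
  cfg <- list(
    seed = 1L,
    synthetic = list(n_subjects = 2L, trials_per_class = 10L, n_leads = 63L,
                     sampling_rate = 500, epoch_length = 1.2,
                     class_effect = 6, noise_scale = 0.5,
                     effect_leads = c("P7", "P6", "PO7", "PO8", "Oz")),
    bootstrap = list(enabled = FALSE, n_select = 25L, n_out = 500L),
    preprocess = list(start_s = 0, duration_s = 1, target_rate = 100,
                      normalize = FALSE),
    model = list(tau_attn = 1, use_sen = TRUE),
    contrastive = list(preset = "50/0/50", batch_size = 10L,
                       pink_noise_scale = 0.1, gaussian_noise_scale = 0.05,
                       input_dropout_rate = 0.1),
    training = list(wfp_epochs = 2L, wfp_learning_rate = 0.05,
                    tau_sac = 0.25, wfc_epochs = 5L,
                    wfc_learning_rate = 1e-4, weight_decay = 7e-3,
                    wfc_batch_size = 20L, train_frac = 0.5)
  )
  if (preset == "paper") {
    cfg$synthetic$n_subjects <- 10L
    cfg$synthetic$trials_per_class <- 60L
    cfg$synthetic$epoch_length <- 2
    cfg$bootstrap$enabled <- TRUE
    cfg$contrastive$batch_size <- 500L
    cfg$training$wfp_epochs <- 25L
    cfg$training$wfc_epochs <- 150L
    cfg$training$wfc_batch_size <- 50L
  }
  cfg$preset <- preset
  structure(cfg, class = "wf_run_config")
}

#' Load a run configuration from YAML
#'
#' Values in the file override the preset defaults; unknown keys are a
#' configuration error.
#' @param path YAML file path.
#' @param preset base preset to merge into.
#' @return a `wf_run_config`.
#' @export
load_run_config <- function(path, preset = "tiny") {
  user <- yaml::read_yaml(path)
  base <- default_run_config(user$preset %||% preset)
  known <- names(base)
  bad <- setdiff(names(user), known)
  if (length(bad))
    wf_config_error("unknown config keys: %s", paste(bad, collapse = ", "))
  structure(utils::modifyList(unclass(base), user), class = "wf_run_config")
}

write_atomic_rds <- function(obj, path) {
  tmp <- paste0(path, ".tmp")
  saveRDS(obj, tmp, compress = "gzip")
  file.rename(tmp, path)
  invisible(path)
}

require_artifact <- function(path, stage) {
  if (!file.exists(path))
    wf_config_error("missing artifact %s: run stage '%s' first",
                    basename(path), stage)
  path
}

#' Run the WaveFusion pipeline
#'
#' Executes the requested stages in canonical order. Each stage reads the
#' previous stage's artifact from `out_dir`, so stages can be re-run
#' individually; a missing upstream artifact raises an error naming the
#' stage to run first.
#'
#' @param config a `wf_run_config` (see [default_run_config()]).
#' @param stages subset of
#'   `c("simulate", "preprocess", "pretrain", "finetune", "evaluate", "explain")`.
#' @param out_dir run directory (created if needed).
#' @return the summary list (also written to `summary.json`), invisibly.
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = c("simulate", "preprocess", "pretrain",
                                    "finetune", "evaluate", "explain"),
                         out_dir = tempfile("wavefusion_run_")) {
  all_stages <- c("simulate", "preprocess", "pretrain", "finetune",
                  "evaluate", "explain")
  stages <- all_stages[all_stages %in% match.arg(stages, all_stages,
                                                 several.ok = TRUE)]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  summary <- list(seed = seed, preset = config$preset %||% "custom",
                  stages = stages)

  tcfg <- train_config(
    wfp = list(epochs = config$training$wfp_epochs,
               learning_rate = config$training$wfp_learning_rate,
               tau_sac = config$training$tau_sac),
    wfc = list(epochs = config$training$wfc_epochs,
               learning_rate = config$training$wfc_learning_rate,
               weight_decay = config$training$weight_decay,
               batch_size = config$training$wfc_batch_size),
    seed = seed)

  sim_path <- file.path(out_dir, "recordings")
  tens_path <- file.path(out_dir, "tensors.rds")
  ckpt_path <- file.path(out_dir, "wfp_checkpoint.rds")
  model_path <- file.path(out_dir, "wfc_model.rds")
  report_path <- file.path(out_dir, "report.json")

  if ("simulate" %in% stages) {
    sc <- config$synthetic
    spec <- synthetic_dataset_spec(sc$n_subjects, sc$trials_per_class,
                                   sc$n_leads, sc$sampling_rate,
                                   sc$epoch_length, seed = seed)
    profiles <- make_subject_profiles(spec, class_effect = sc$class_effect,
                                      effect_leads = sc$effect_leads,
                                      noise_scale = sc$noise_scale)
    recs <- generate_dataset(spec, profiles)
    if (isTRUE(config$bootstrap$enabled)) {
      recs <- lapply(recs, bootstrap_average_classes,
                     n_select = config$bootstrap$n_select,
                     n_out = config$bootstrap$n_out,
                     rng_seed = derive_seed(seed, "bootstrap"))
    }
    write_recordings(recs, sim_path)
    message("simulate: wrote ", length(recs), " subject archives")
  }

  if ("preprocess" %in% stages) {
    require_artifact(file.path(sim_path, "subject_01.json"), "simulate")
    recs <- read_recordings(sim_path)
    pc <- config$preprocess
    set <- preprocess_dataset(recs, start_s = pc$start_s,
                              duration_s = pc$duration_s,
                              target_rate = pc$target_rate,
                              normalize = pc$normalize)
    sp <- split_tensor_set(set, config$training$train_frac,
                           seed = derive_seed(seed, "traintest"))
    holdout <- split_tensor_set(sp$b, 0.5, seed = derive_seed(seed, "valtest"))
    write_atomic_rds(list(train = sp$a, val = holdout$a, test = holdout$b),
                     tens_path)
    message("preprocess: ", length(sp$a$y1), " train / ",
            length(holdout$a$y1), " val / ", length(holdout$b$y1), " test tensors")
  }

  if ("pretrain" %in% stages) {
    require_artifact(tens_path, "preprocess")
    splits <- readRDS(tens_path)
    model <- build_model(wf_model_config(tau_attn = config$model$tau_attn,
                                         use_sen = config$model$use_sen),
                         seed = derive_seed(seed, "init"))
    comp <- composition_preset(config$contrastive$preset,
                               config$contrastive$batch_size)
    aug <- augment_config(config$contrastive$pink_noise_scale,
                          config$contrastive$gaussian_noise_scale,
                          config$contrastive$input_dropout_rate)
    pre <- pretrain_wfp(splits$train, model, tcfg, comp, aug,
                        loss = attr(comp, "loss") %||% "sac")
    save_checkpoint(pre$model, ckpt_path)
    jsonlite::write_json(list(loss_trace = pre$loss_trace),
                         file.path(out_dir, "wfp_loss.json"), digits = NA)
    summary$wfp_final_loss <- pre$loss_trace[length(pre$loss_trace)]
    message("pretrain: final epoch loss ",
            signif(summary$wfp_final_loss, 4))
  }

  if ("finetune" %in% stages) {
    require_artifact(tens_path, "preprocess")
    require_artifact(ckpt_path, "pretrain")
    splits <- readRDS(tens_path)
    wfp <- load_checkpoint(ckpt_path)
    wfc <- transfer_weights(wfp, seed = derive_seed(seed, "head"))
    ft <- finetune_wfc(splits$train, wfc, tcfg, test_set = splits$val)
    save_checkpoint(ft$model, model_path)
    summary$val_accuracy <- ft$report$accuracy
    message("finetune: validation accuracy ", signif(ft$report$accuracy, 4))
  }

  if ("evaluate" %in% stages) {
    require_artifact(tens_path, "preprocess")
    require_artifact(model_path, "finetune")
    splits <- readRDS(tens_path)
    model <- load_checkpoint(model_path)
    pred <- predict_wfc(model, splits$test)
    rep <- evaluate(pred$class, splits$test$y1)
    jsonlite::write_json(list(accuracy = rep$accuracy,
                              f1 = as.list(rep$f1),
                              class_accuracy = as.list(rep$class_accuracy),
                              confusion = rep$confusion),
                         report_path, auto_unbox = TRUE, digits = NA)
    summary$test_accuracy <- rep$accuracy
    message("evaluate: test accuracy ", signif(rep$accuracy, 4))
  }

  if ("explain" %in% stages) {
    require_artifact(tens_path, "preprocess")
    require_artifact(model_path, "finetune")
    splits <- readRDS(tens_path)
    model <- load_checkpoint(model_path)
    for (cls in c(0L, 1L)) {
      i <- which(splits$test$y1 == cls)[1]
      if (is.na(i)) next
      x <- array(splits$test$x[i, , , ], dim(splits$test$x)[-1])
      pi_w <- extract_attention(model, x, lead_names = splits$test$lead_names)
      export_attention(pi_w, file.path(out_dir,
                                       sprintf("attention_class%d.csv", cls)))
      tm <- interpolate_topomap(pi_w, default_montage())
      plot_topomap(tm, file.path(out_dir, sprintf("topomap_class%d.png", cls)),
                   main = sprintf("attention, class %d", cls))
      cam <- class_activation_map(model, x, lead = 1L, class = cls)
      export_cam(cam, file.path(out_dir, sprintf("cam_class%d.csv", cls)))
      plot_cam(cam, file.path(out_dir, sprintf("cam_class%d.png", cls)))
    }
    message("explain: wrote attention and CAM artifacts")
  }

  arts <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  arts <- arts[!grepl("summary\\.json$", arts)]
  summary$checksums <- as.list(tools::md5sum(arts))
  names(summary$checksums) <- basename(arts)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
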