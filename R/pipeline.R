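# Run configuration and the end-to-end pipeline:
# simulate -> preprocess -> (cross-validated) train -> evaluate -> explain.
# One master seed fans out deterministically per stage; completed stages
# whose config hash matches are skipped on re-runs.

#' Default run configuration
#'
#' Nested defaults for every pipeline stage. `simulate` mirrors the study's
#' 15/10/5 training + 2/3/3 holdout volume layout; `preprocess` uses the
#' 10-frame sliding despeckle window; `model`/`train` carry the published
#' architecture and optimization recipe.
#'
#' @return nested named list.
#' @export
default_run_config <- function() {
  list(
    master_seed = 1L,
    output_root = "octbrain_run",
    simulate = list(
      train_volumes = c(NOR = 15L, GBM = 10L, PCNSL = 5L),
      test_volumes = c(NOR = 2L, GBM = 3L, PCNSL = 3L),
      frames_per_volume = 16L,
      n_depth_pixels = 256L, n_lateral_pixels = 512L,
      scan_depth = 2.5, scan_width = 5,
      speckle_shape = 1, noise_floor = 1e-4,
      saturation_probability = 0.02),
    preprocess = list(window = 10L, stride = 1L, sat_threshold = 0.02,
                      target_rows = 128L, target_cols = 256L),
    model = list(stage_filters = c(8L, 16L, 32L, 64L),
                 units_per_stage = c(1L, 2L, 2L, 1L),
                 attention_stages = c(32L, 64L),
                 alpha_init = 0, l2_coefficient = 1e-4),
    train = list(batch_size = 32L, learning_rate = 5e-4, momentum = 0.9,
                 patience_epochs = 10L, max_epochs = 30L,
                 cross_validate = FALSE, n_folds = 5L,
                 augment = list(rotation = 10, translation = 0.05,
                                shear = 0.1, zoom = 0.1)),
    evaluate = list(roc_grid_step = 0.01, tsne_perplexity = 30,
                    gradcam_frames = 6L)
  )
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    key <- if (path == "") nm else paste(path, nm, sep = ".")
    if (!nm %in% names(defaults))
      oct_error("config_error", "unknown configuration key: %s", key)
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]]))
        oct_error("config_error", "key %s must be a mapping", key)
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], key)
    } else {
      v <- user[[nm]]
      if (is.list(v)) v <- unlist(v)
      tmpl <- defaults[[nm]]
      if (is.numeric(tmpl) && !is.numeric(v))
        oct_error("config_error", "key %s must be numeric", key)
      if (!is.null(names(tmpl)) && !is.null(names(v)))
        tmpl[names(v)] <- v
      else tmpl <- if (is.integer(tmpl)) as.integer(v) else v
      defaults[[nm]] <- tmpl
    }
  }
  defaults
}

validate_run_config <- function(cfg) {
  a <- cfg$train$augment
  if (a[["shear"]] > 0.1 || a[["zoom"]] > 0.1)
    oct_error("config_error",
              "train.augment: shear and zoom are capped at a ratio of 0.1")
  if (cfg$preprocess$window < 1)
    oct_error("config_error", "preprocess.window must be >= 1")
  if (cfg$simulate$frames_per_volume < cfg$preprocess$window)
    oct_error("config_error",
              "simulate.frames_per_volume must be >= preprocess.window")
  cfg
}

#' Parse a YAML run configuration
#'
#' Reads a YAML file, fills defaults from [default_run_config()], rejects
#' unknown keys, and validates constraints (including the 0.1 shear/zoom
#' cap).
#'
#' @param path YAML file path.
#' @return validated configuration list of class `run_config`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path))
    oct_error("io_error", "config file not found: %s", path)
  user <- tryCatch(yaml::read_yaml(path), error = function(e)
    oct_error("config_error", "malformed config %s: %s", path,
              conditionMessage(e)))
  cfg <- merge_config(default_run_config(), user %||% list())
  cfg <- validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(x), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

stage_cached <- function(dir, hash) {
  marker <- file.path(dir, ".stage_hash")
  file.exists(marker) && identical(readLines(marker, warn = FALSE), hash)
}

mark_stage <- function(dir, hash) {
  writeLines(hash, file.path(dir, ".stage_hash"))
}

#' Run the full pipeline
#'
#' Executes simulate, preprocess, train (single model or cross-validated),
#' evaluate and explain in order under `config$output_root`, skipping
#' completed stages whose inputs and configuration are unchanged. The fully
#' resolved configuration, a run log, metrics tables (CSV) and figures
#' (PNG) are written next to the outputs.
#'
#' @param config a [parse_config()] result or [default_run_config()]-shaped
#'   list.
#' @param verbose print progress.
#' @return invisibly, a list with `status` (0 on success) and output paths.
#' @export
run_all <- function(config, verbose = FALSE) {
  cfg <- validate_run_config(merge_config(default_run_config(),
                                          unclass(config)))
  root <- cfg$output_root
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(root, "resolved_config.yaml"))
  seed <- cfg$master_seed

  # --- simulate ---
  sim_dir <- file.path(root, "volumes")
  sim_hash <- config_hash(list(cfg$simulate, seed))
  if (stage_cached(sim_dir, sim_hash)) {
    log_event("info", "simulate", "cached, skipping")
    manifest <- read.csv(file.path(sim_dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  } else {
    s <- cfg$simulate
    acq <- acquisition_spec(s$n_depth_pixels, s$n_lateral_pixels,
                            s$scan_width, s$scan_depth,
                            speckle_shape = s$speckle_shape,
                            noise_floor = s$noise_floor,
                            saturation_probability = s$saturation_probability)
    manifest <- generate_dataset(sim_dir, s$train_volumes, s$test_volumes,
                                 s$frames_per_volume, acq,
                                 seed = derive_seed(seed, "simulate"))
    mark_stage(sim_dir, sim_hash)
  }

  # --- preprocess ---
  pre_dir <- file.path(root, "frames")
  dir.create(pre_dir, showWarnings = FALSE)
  pre_hash <- config_hash(list(cfg$preprocess, sim_hash))
  if (stage_cached(pre_dir, pre_hash)) {
    log_event("info", "preprocess", "cached, skipping")
    train_fs <- readRDS(file.path(pre_dir, "train_frames.rds"))
    test_fs <- readRDS(file.path(pre_dir, "test_frames.rds"))
  } else {
    p <- cfg$preprocess
    train_fs <- preprocess_manifest(manifest, "train", p$window, p$stride,
                                    p$sat_threshold, p$target_rows,
                                    p$target_cols)
    test_fs <- preprocess_manifest(manifest, "test", p$window, p$stride,
                                   p$sat_threshold, p$target_rows,
                                   p$target_cols)
    saveRDS(train_fs, file.path(pre_dir, "train_frames.rds"))
    saveRDS(test_fs, file.path(pre_dir, "test_frames.rds"))
    frames_manifest <- data.frame(
      frame_id = sprintf("F%05d", seq_len(n_frames(train_fs) +
                                            n_frames(test_fs))),
      volume_id = c(train_fs$volume_id, test_fs$volume_id),
      label = c(as.character(train_fs$labels), as.character(test_fs$labels)),
      window_start_index = c(train_fs$window_start, test_fs$window_start),
      split = c(rep("train", n_frames(train_fs)),
                rep("test", n_frames(test_fs))))
    write.csv(frames_manifest, file.path(pre_dir, "frames.csv"),
              row.names = FALSE)
    mark_stage(pre_dir, pre_hash)
  }

  # --- train ---
  trn_dir <- file.path(root, "training")
  dir.create(trn_dir, showWarnings = FALSE)
  trn_hash <- config_hash(list(cfg$model, cfg$train, pre_hash))
  mcfg <- model_config(
    input_shape = c(cfg$preprocess$target_rows, cfg$preprocess$target_cols, 1L),
    stage_filters = cfg$model$stage_filters,
    units_per_stage = cfg$model$units_per_stage,
    attention_stages = cfg$model$attention_stages,
    alpha_init = cfg$model$alpha_init,
    l2_coefficient = cfg$model$l2_coefficient)
  tcfg <- train_config(cfg$train$batch_size, cfg$train$learning_rate,
                       cfg$train$momentum, cfg$model$l2_coefficient,
                       cfg$train$patience_epochs, cfg$train$max_epochs,
                       seed = derive_seed(seed, "train"),
                       augment_bounds = as.list(cfg$train$augment))
  plan <- split_by_volume(manifest, cfg$train$n_folds,
                          seed = derive_seed(seed, "split"))
  if (stage_cached(trn_dir, trn_hash)) {
    log_event("info", "train", "cached, skipping")
    model <- load_model(file.path(trn_dir, "model_fold1.rds"))
  } else {
    if (isTRUE(cfg$train$cross_validate)) {
      cv <- run_cross_validation(train_fs, test_fs, plan, mcfg, tcfg,
                                 verbose = verbose)
      for (k in seq_along(cv$folds)) {
        save_model(cv$folds[[k]]$model,
                   file.path(trn_dir, sprintf("model_fold%d.rds", k)))
        write.csv(cv$folds[[k]]$history,
                  file.path(trn_dir, sprintf("history_fold%d.csv", k)),
                  row.names = FALSE)
      }
      model <- cv$folds[[1]]$model
    } else {
      val_vols <- names(plan$fold_of_volume)[plan$fold_of_volume == 1L]
      vidx <- train_fs$volume_id %in% val_vols
      model <- build_model(mcfg, seed = tcfg$seed)
      fit <- train_classifier(model, subset_frames(train_fs, !vidx),
                              subset_frames(train_fs, vidx), tcfg,
                              verbose = verbose)
      model <- fit$model
      save_model(model, file.path(trn_dir, "model_fold1.rds"))
      write.csv(fit$history, file.path(trn_dir, "history_fold1.csv"),
                row.names = FALSE)
    }
    mark_stage(trn_dir, trn_hash)
  }

  # --- evaluate ---
  ev_dir <- file.path(root, "evaluation")
  dir.create(ev_dir, showWarnings = FALSE)
  report <- evaluate_frames(model, test_fs)
  write.csv(as.data.frame(unclass(report$confusion)),
            file.path(ev_dir, "confusion.csv"))
  metrics <- data.frame(
    class = tissue_classes(),
    sensitivity = vapply(report$per_class, function(x) x$sensitivity, 1),
    specificity = vapply(report$per_class, function(x) x$specificity, 1),
    auc = vapply(tissue_classes(), function(cl)
      if (cl %in% names(report$roc)) report$roc[[cl]]$auc else NA_real_, 1))
  write.csv(metrics, file.path(ev_dir, "metrics.csv"), row.names = FALSE)
  for (cl in names(report$roc)) {
    r <- report$roc[[cl]]
    write.csv(data.frame(threshold = r$thresholds,
                         sensitivity = r$sensitivity,
                         specificity = r$specificity),
              file.path(ev_dir, sprintf("roc_%s.csv", cl)), row.names = FALSE)
    plot_roc_band(average_roc_over_folds(list(r)), cl,
                  file.path(ev_dir, sprintf("roc_%s.png", cl)))
  }
  plot_confusion(report$confusion, file.path(ev_dir, "confusion.png"))

  # --- explain ---
  ex_dir <- file.path(root, "explain")
  dir.create(ex_dir, showWarnings = FALSE)
  n_cam <- min(cfg$evaluate$gradcam_frames, n_frames(test_fs))
  cam_idx <- with_seed(derive_seed(seed, "explain"),
                       sample.int(n_frames(test_fs), n_cam))
  for (i in cam_idx) {
    cam <- grad_cam(model, test_fs$x[, , i],
                    as.character(test_fs$labels[i]))
    plot_cam(cam, file.path(ex_dir, sprintf("cam_%03d_%s.png", i,
                                            test_fs$labels[i])))
  }
  all_fs <- bind_frames(train_fs, test_fs)
  emb <- extract_features(model, all_fs)
  pred <- tissue_classes()[max.col(predict_proba(model, all_fs),
                                   ties.method = "first")]
  ep <- tsne_scatter(emb, pred, as.character(all_fs$labels),
                     split = c(rep("train", n_frames(train_fs)),
                               rep("test", n_frames(test_fs))),
                     seed = derive_seed(seed, "tsne"),
                     perplexity = cfg$evaluate$tsne_perplexity)
  plot_embedding(ep, file.path(ex_dir, "tsne.png"))

  lg <- run_log()
  write.csv(lg, file.path(root, "run.log.csv"), row.names = FALSE)
  log_event("info", "run_all", "pipeline complete under %s", root)
  invisible(list(status = 0L, output_root = root, manifest = manifest,
                 report = report, model = model))
}
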