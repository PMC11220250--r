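default_config <- function() {
  list(
    preset = "p300_like",
    n_epochs_per_class = 200L,
    architecture = "eegnet",
    seed = 7L,
    scale = 1,
    enk = list(l = 1L, m = 7L, shared_affine = TRUE),
    train = list(max_epochs = 200L, batch_size = 16L, dropout = 0.25,
                 learning_rate = 0.001, patience = 20L,
                 split = c(0.60, 0.20, 0.20)),
    gradcam = list(enabled = TRUE, target_class = NULL)
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills protocol defaults (learning
#' rate 0.001, patience 20, at most 200 training epochs, 60/20/20 stratified
#' split) and validates every field, collecting all violations — each named
#' by its field path — before failing.
#'
#' @param config Path to a YAML file, or a configuration list.
#' @return The normalized configuration (class `enk_run_config`), or an
#'   error listing every violated field.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stop("config must be a YAML mapping", call. = FALSE)
  cfg <- utils::modifyList(default_config(), config)
  errs <- character()
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  chk(cfg$preset %in% c("p300_like", "conflict_like", "mi_like", "mrcp_like"),
      paste0("preset: unknown preset '", cfg$preset, "'"))
  chk(cfg$architecture %in% c("eegnet", "shallowconvnet", "deepconvnet", "rcnn"),
      paste0("architecture: unknown architecture '", cfg$architecture, "'"))
  chk(is.numeric(cfg$n_epochs_per_class) && cfg$n_epochs_per_class >= 5,
      "n_epochs_per_class: must be a number >= 5")
  chk(is.numeric(cfg$seed), "seed: must be an integer")
  chk(is.numeric(cfg$scale) && cfg$scale > 0, "scale: must be positive")
  tr <- cfg$train
  chk(is.numeric(tr$batch_size) && tr$batch_size >= 2 && tr$batch_size <= 16,
      paste0("train.batch_size: ", tr$batch_size, " outside [2, 16]"))
  chk(is.numeric(tr$dropout) && tr$dropout >= 0.15 && tr$dropout <= 0.75,
      paste0("train.dropout: ", tr$dropout, " outside [0.15, 0.75]"))
  chk(is.numeric(tr$learning_rate) && tr$learning_rate > 0,
      "train.learning_rate: must be positive")
  chk(is.numeric(tr$max_epochs) && tr$max_epochs >= 1,
      "train.max_epochs: must be >= 1")
  chk(is.numeric(tr$patience) && tr$patience >= 1 && tr$patience < tr$max_epochs,
      "train.patience: must be in [1, max_epochs)")
  chk(length(tr$split) == 3 && abs(sum(tr$split) - 1) < 1e-8,
      paste0("train.split: fractions (", paste(tr$split, collapse = ", "),
             ") must be three numbers summing to 1"))
  chk(cfg$enk$m %% 2 == 1, paste0("enk.m: must be odd, got ", cfg$enk$m))
  chk(cfg$enk$l >= 1, "enk.l: must be >= 1")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "enk_run_config")
}

write_manifest <- function(dir, manifest) {
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

report_to_list <- function(r) {
  list(mse = r$mse, f1 = r$f1, per_class_f1 = r$per_class_f1,
       n_test = r$n_test, best_epoch = r$best_epoch,
       config_hash = r$config_hash, warnings = r$warnings)
}

#' Run the full with/without-EnK pipeline
#'
#' Executes simulate -> stratified split -> paired training (EnK off/on) ->
#' evaluation -> Grad-CAM overlays, writing every artifact (epoch container,
#' checkpoints, JSON reports, CSV histories, PNG overlays and a run
#' manifest) under one run directory. The manifest is written before any
#' heavy computation and updated to `done`/`failed` at the end; a run is
#' reproducible from the manifest's config snapshot alone.
#'
#' @param config Path to a YAML configuration or a config list
#'   (see [validate_config()]).
#' @param out Run directory to create.
#' @param overwrite Allow writing into an existing run directory.
#' @param verbose Print progress.
#' @return The run directory, invisibly. The combined report (both arms
#'   plus EnK-minus-base deltas) is at `<out>/report.json`.
#' @export
run_pipeline <- function(config, out, overwrite = FALSE, verbose = FALSE) {
  config_path <- if (is.character(config)) normalizePath(config) else NULL
  cfg <- validate_config(config)
  if (dir.exists(out) && !overwrite)
    stop("run directory ", out, " exists; use overwrite = TRUE", call. = FALSE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    command = "run_pipeline",
    package_version = as.character(utils::packageVersion("enkit")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(cfg),
    seed = cfg$seed,
    input_hashes = if (!is.null(config_path))
      as.list(tools::md5sum(config_path)) else list(),
    outputs = list(epochs = "epochs.h5", report = "report.json",
                   base = "base", enk = "enk", gradcam = "gradcam"),
    status = "running")
  write_manifest(out, manifest)
  result <- tryCatch({
    say <- function(...) if (verbose) message(...)
    say("generating synthetic epochs (preset ", cfg$preset, ", seed ", cfg$seed, ")")
    sspec <- synth_preset(cfg$preset,
                          n_epochs_per_class = as.integer(cfg$n_epochs_per_class),
                          seed = cfg$seed)
    es <- synth_generate(sspec)
    save_epochs(es, file.path(out, "epochs.h5"))
    tcfg <- train_config(max_epochs = cfg$train$max_epochs,
                         batch_size = cfg$train$batch_size,
                         dropout = cfg$train$dropout,
                         learning_rate = cfg$train$learning_rate,
                         patience = cfg$train$patience,
                         split = cfg$train$split, seed = cfg$seed)
    mspec <- model_spec(cfg$architecture,
                        n_channels = sspec$n_channels,
                        n_samples = sspec$n_samples,
                        n_classes = sspec$n_classes,
                        enk_config = cfg$enk,
                        dropout_rate = cfg$train$dropout,
                        scale = cfg$scale)
    say("training paired models (EnK off/on)")
    cmp <- compare_enk(mspec, es, tcfg, verbose = verbose)
    for (arm in c("base", "enk")) {
      armdir <- file.path(out, arm)
      dir.create(armdir, showWarnings = FALSE)
      fit <- if (arm == "base") cmp$fit_base else cmp$fit_enk
      save_checkpoint(fit$net, file.path(armdir, "checkpoint"))
      utils::write.csv(fit$history, file.path(armdir, "history.csv"),
                       row.names = FALSE)
      jsonlite::write_json(report_to_list(cmp[[arm]]),
                           file.path(armdir, "report.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    gdir <- file.path(out, "gradcam")
    dir.create(gdir, showWarnings = FALSE)
    if (isTRUE(cfg$gradcam$enabled)) {
      say("computing Grad-CAM overlays")
      tgt <- cfg$gradcam$target_class %||% (sspec$n_classes - 1L)
      test_es <- es[cmp$split$test]
      ei <- which(test_es$labels == tgt)[1]
      epoch <- test_es$data[ei, , ]
      maps <- list(
        base = gradcam(cmp$fit_base, epoch, target_class = tgt),
        enk = gradcam(cmp$fit_enk, epoch, target_class = tgt))
      for (arm in names(maps))
        overlay(maps[[arm]], epoch, file.path(gdir, paste0("overlay_", arm, ".png")),
                sampling_rate = es$sampling_rate)
      dm <- diff_map(maps$enk, maps$base)
      utils::write.csv(dm$heat, file.path(gdir, "diff.csv"), row.names = FALSE)
    }
    combined <- list(base = report_to_list(cmp$base),
                     enk = report_to_list(cmp$enk),
                     delta = cmp$delta)
    jsonlite::write_json(combined, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    say(sprintf("done: delta MSE %+.4f, delta F1 %+.4f",
                cmp$delta$mse, cmp$delta$f1))
    cmp
  }, error = function(e) {
    manifest$status <<- "failed"
    manifest$error <<- conditionMessage(e)
    write_manifest(out, manifest)
    stop(e)
  })
  manifest$status <- "done"
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  write_manifest(out, manifest)
  invisible(out)
}
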