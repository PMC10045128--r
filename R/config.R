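#' Default pipeline configuration
#'
#' All knobs of the pipeline with their protocol defaults: mini-batch 8,
#' 100 epochs, Adam learning rate 5e-4 decaying linearly to 1e-4 after
#' epoch 20, channel width 64, 6:2:2 subject split, 5 folds, augmentation
#' ranges 0.3 rad shear / 30 degree rotation / 20% zoom / horizontal flips,
#' binarization threshold 0.5.
#'
#' @return A named list of class `ratunet_config`.
#' @export
default_config <- function() {
  structure(list(
    batch_size = 8L,
    epochs = 100L,
    lr_initial = 5e-4,
    lr_final = 1e-4,
    lr_decay_start_epoch = 20L,
    lr_schedule = "linear",
    split_ratios = c(6, 2, 2),
    folds = 5L,
    seed = 1L,
    per_epoch_factor = 10L,
    augment = TRUE,
    dice_eps = 1e-6,
    base_channels = 64L,
    input_size = 128L,
    threshold = 0.5,
    keep_largest_component = FALSE,
    shear_max_rad = 0.3,
    rotation_max_deg = 30,
    zoom_max_frac = 0.2,
    hflip = TRUE,
    bn_momentum = 0.1,
    bn_eps = 1e-5
  ), class = "ratunet_config")
}

.config_checks <- list(
  batch_size = function(v) v >= 1,
  epochs = function(v) v >= 1,
  lr_initial = function(v) v > 0,
  lr_final = function(v) v > 0,
  lr_decay_start_epoch = function(v) v >= 1,
  lr_schedule = function(v) v %in% c("linear", "step"),
  split_ratios = function(v) length(v) == 3 && all(v > 0),
  folds = function(v) v >= 2,
  seed = function(v) is.finite(v),
  per_epoch_factor = function(v) v >= 1,
  augment = function(v) is.logical(v),
  dice_eps = function(v) v >= 0,
  base_channels = function(v) v >= 1,
  input_size = function(v) v %% 32 == 0 && v >= 32,
  threshold = function(v) v >= 0 && v <= 1,
  keep_largest_component = function(v) is.logical(v),
  shear_max_rad = function(v) v >= 0 && v <= 0.3,
  rotation_max_deg = function(v) v >= 0 && v <= 30,
  zoom_max_frac = function(v) v >= 0 && v <= 0.2,
  hflip = function(v) is.logical(v),
  bn_momentum = function(v) v > 0 && v < 1,
  bn_eps = function(v) v > 0
)

#' Load and validate a YAML configuration
#'
#' Reads a YAML file, fills missing keys with [default_config()] values,
#' rejects unknown keys, and range-checks every value.  An empty (or
#' missing-content) file yields the full default configuration.
#'
#' @param path YAML file path.
#' @return A validated `ratunet_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  validate_config(user)
}

#' @param config a partial named list of configuration values.
#' @rdname load_config
#' @export
validate_config <- function(config) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(unclass(defaults), config)
  bad <- character()
  for (nm in names(.config_checks)) {
    ok <- tryCatch(isTRUE(all(.config_checks[[nm]](cfg[[nm]]))),
                   error = function(e) FALSE)
    if (!ok) bad <- c(bad, nm)
  }
  if (length(bad))
    stop("invalid configuration values for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (nm in c("batch_size", "epochs", "lr_decay_start_epoch", "folds",
               "seed", "per_epoch_factor", "base_channels", "input_size"))
    cfg[[nm]] <- as.integer(cfg[[nm]])
  structure(cfg, class = "ratunet_config")
}

#' @rdname load_config
#' @export
dump_config <- function(config, path) {
  stopifnot(inherits(config, "ratunet_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.train_config_from <- function(cfg) {
  train_config(batch_size = cfg$batch_size, epochs = cfg$epochs,
               lr_initial = cfg$lr_initial, lr_final = cfg$lr_final,
               lr_decay_start_epoch = cfg$lr_decay_start_epoch,
               lr_schedule = cfg$lr_schedule,
               split_ratios = cfg$split_ratios, folds = cfg$folds,
               seed = cfg$seed, per_epoch_factor = cfg$per_epoch_factor,
               augment = cfg$augment, dice_eps = cfg$dice_eps)
}

.write_run_manifest <- function(path, command, config, seed, inputs, outputs) {
  jsonlite::write_json(
    list(command = command, config = unclass(config), master_seed = seed,
         inputs = inputs, outputs = outputs,
         package_version = as.character(utils::packageVersion("ratunet")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' End-to-end pipeline smoke run
#'
#' Exercises the whole pipeline at desk scale in a working directory:
#' generates six phantom subjects (64 matrix), computes training-split
#' intensity statistics, trains a width-8 network for two epochs, predicts
#' a mask for every subject and writes a per-subject evaluation CSV with a
#' mean/sd summary, plus a run manifest per stage.  Deterministic given
#' `seed`: a rerun writes a byte-identical evaluation CSV.
#'
#' @param workdir writable working directory (created if absent).
#' @param seed master seed.
#' @return Invisibly, an exit status: 0 on success, 2 for configuration
#'   errors, 3 for data/I-O errors, 4 for training divergence.
#' @export
run_pipeline_smoke <- function(workdir, seed = 1L) {
  status <- tryCatch({
    if (file.exists(workdir) && !dir.exists(workdir))
      stop("workdir exists and is not a directory: ", workdir, call. = FALSE)
    dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(workdir))
      stop("cannot create workdir: ", workdir, call. = FALSE)
    probe <- file.path(workdir, ".write_probe")
    ok <- tryCatch({ writeLines("x", probe); TRUE },
                   error = function(e) FALSE, warning = function(e) FALSE)
    if (!ok) stop("workdir is not writable: ", workdir, call. = FALSE)
    unlink(probe)

    cfg <- validate_config(list(seed = as.integer(seed), epochs = 2L,
                                base_channels = 8L, input_size = 64L,
                                per_epoch_factor = 1L))
    seeds <- withr::with_seed(cfg$seed, sample.int(.Machine$integer.max, 4))

    datadir <- file.path(workdir, "data")
    manifest <- generate_phantom_dataset(6, "DWI", seed = seeds[1],
                                         outdir = datadir, matrix_size = 64L)
    .write_run_manifest(file.path(workdir, "manifest_phantom.json"),
                        "phantom", cfg, seeds[1], list(),
                        list(datadir = datadir))

    subjects <- lapply(seq_len(nrow(manifest)), function(i) {
      list(volume = read_mr_volume(manifest$image_path[i],
                                   subject_id = manifest$subject_id[i]),
           mask = read_mask(manifest$mask_path[i],
                            subject_id = manifest$subject_id[i]))
    })
    names(subjects) <- manifest$subject_id

    split <- split_subjects(manifest$subject_id, cfg$split_ratios, seeds[2])
    stats <- compute_dataset_stats(lapply(subjects[split$train],
                                          `[[`, "volume"))
    norm <- lapply(subjects, function(s) {
      s$volume <- zscore_normalize(s$volume, stats); s
    })

    tc <- .train_config_from(cfg)
    model <- build_runet(cfg$input_size, cfg$base_channels, seed = seeds[3])
    fit <- train_runet(model, subjects_to_slices(norm[split$train]),
                       subjects_to_slices(norm[split$validation]), tc)
    histpath <- file.path(workdir, "history.csv")
    utils::write.csv(fit$history, histpath, row.names = FALSE)
    .write_run_manifest(file.path(workdir, "manifest_train.json"), "train",
                        cfg, cfg$seed, list(datadir = datadir),
                        list(history = histpath))

    pairs <- lapply(norm, function(s) {
      pred <- predict_volume(fit$model, s$volume, cfg$threshold)
      list(sp = pred$mask, gt = s$mask, subject_id = s$mask$subject_id)
    })
    df <- evaluate_cohort(pairs)
    summ <- attr(df, "summary")
    out <- rbind(df,
                 data.frame(subject_id = summ$statistic,
                            summ[, -1, drop = FALSE]))
    evalpath <- file.path(workdir, "evaluation.csv")
    utils::write.csv(out, evalpath, row.names = FALSE)
    .write_run_manifest(file.path(workdir, "manifest_evaluate.json"),
                        "evaluate", cfg, cfg$seed,
                        list(datadir = datadir), list(evaluation = evalpath))
    0L
  }, error = function(e) {
    message("pipeline failure: ", conditionMessage(e))
    if (grepl("diverged", conditionMessage(e))) 4L
    else if (grepl("configuration", conditionMessage(e))) 2L
    else 3L
  })
  invisible(status)
}
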