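# Pipeline orchestration: reproducible end-to-end runs driven by a single
# configuration list (YAML on disk), plus serial two-stage prediction.
# These functions are also the backing for the thin command-line wrapper in
# inst/cli/m6adeep.R.

default_run_config <- function() {
  list(
    out_dir = "m6adeep_run",
    seed = 1,
    genome = NULL, positives = NULL, negatives = NULL,
    k = 300, motif = "GAC", threshold = 0.7, ratio = 0.8, neg_ratio = 1.5,
    variant = "cnn_bilstm", epochs = 60, lr = 0.01, momentum = 0.9,
    batch_size = 64, gate_threshold = 0.5,
    simulate = list(n_pos = 1000, n_neg = 1000, signal_strength = 1)
  )
}

#' Read a pipeline run configuration
#'
#' YAML file whose keys override the documented defaults; unknown keys are
#' an error so typos fail before any computation.
#'
#' @param path Path to a YAML config, or `NULL` for pure defaults.
#' @param overrides Named list applied on top of the file.
#' @return A validated config list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("Config file not found: '%s'.", path))
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0) {
      abort(sprintf("Unknown config key(s): %s.", paste(unknown, collapse = ", ")))
    }
    cfg <- modifyList(cfg, user)
  }
  modifyList(cfg, overrides)
}

write_manifest <- function(dir, name, payload) {
  jsonlite::write_json(payload, file.path(dir, name), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
}

#' Save / load a model checkpoint
#'
#' The checkpoint carries the full weight set, configuration and stage tag;
#' reloading is bit-exact.
#'
#' @param model An `m6a_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` invisibly, or the reloaded model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "m6a_model")) abort("Not an m6a_model checkpoint.")
  model
}

#' Simulate a synthetic fixture directory
#'
#' @param config Run config (uses `out_dir`, `seed`, `k`, `motif`, and the
#'   `simulate` block).
#' @return The fixture directory, invisibly.
#' @export
pipeline_simulate <- function(config) {
  spec <- do.call(synthetic_spec, c(
    config$simulate,
    list(k = config$k, motif = config$motif, seed = config$seed)))
  sim <- simulate_m6a(spec)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fixture(sim, config$out_dir)
  write_manifest(config$out_dir, "manifest.json", list(
    command = "simulate", seed = config$seed, k = config$k,
    motif = config$motif, n_pos = spec$n_pos, n_neg = spec$n_neg,
    signal_strength = spec$signal_strength))
  invisible(config$out_dir)
}

#' Build stage-1 benchmark datasets from a genome and site tables
#'
#' Composes window extraction, redundancy reduction, balancing and the 4:1
#' split, then writes each split (FASTA + TSV) and a manifest of counts.
#'
#' @param config Run config; `genome` and `positives` paths are required,
#'   `negatives` is optional (sampled when absent).
#' @return A list with `train`, `test`, `normalizer`, `manifest`.
#' @export
pipeline_build_datasets <- function(config) {
  for (key in c("genome", "positives")) {
    if (is.null(config[[key]]) || !file.exists(config[[key]])) {
      abort(sprintf("Config key '%s' must point to an existing file.", key))
    }
  }
  genome <- read_genome(config$genome)
  sites <- read_sites(config$positives, source = "positives")
  neg_sites <- if (!is.null(config$negatives)) {
    read_sites(config$negatives, source = "negatives")
  } else {
    NULL
  }
  ds <- build_stage1_dataset(
    sites, genome, motif = config$motif, k = config$k,
    threshold = config$threshold, ratio = config$ratio,
    neg_sites = neg_sites, neg_ratio = config$neg_ratio, seed = config$seed)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (split in c("train", "test")) {
    write_windows_fasta(ds[[split]],
                        file.path(config$out_dir, paste0(split, ".fa")))
    readr::write_tsv(dplyr::select(ds[[split]], -"sequence"),
                     file.path(config$out_dir, paste0(split, ".tsv")),
                     progress = FALSE)
  }
  write_manifest(config$out_dir, "manifest.json", list(
    command = "build-datasets", seed = config$seed, k = config$k,
    motif = config$motif, threshold = config$threshold, ratio = config$ratio,
    counts = setNames(as.list(ds$manifest$count), ds$manifest$step),
    support_min = ds$normalizer$min, support_max = ds$normalizer$max))
  invisible(ds)
}

#' Train the stage-1 model from a run config
#'
#' @param config Run config.
#' @param datasets Result of [pipeline_build_datasets()] (or compatible
#'   list with `train` and `normalizer`).
#' @return The trained model (also checkpointed under `out_dir`).
#' @export
pipeline_train <- function(config, datasets) {
  arch <- backbone_config(variant = config$variant,
                          window_length = 2 * config$k + 1,
                          seed = config$seed)
  model <- train_stage1(datasets$train, arch, epochs = config$epochs,
                        lr = config$lr, momentum = config$momentum,
                        batch_size = config$batch_size, seed = config$seed,
                        normalizer = datasets$normalizer)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  save_model(model, file.path(config$out_dir, "stage1_model.rds"))
  readr::write_tsv(model$log, file.path(config$out_dir, "training_log.tsv"),
                   progress = FALSE)
  write_manifest(config$out_dir, "train_manifest.json", list(
    command = "train", seed = config$seed, variant = config$variant,
    epochs = config$epochs, lr = config$lr, batch_size = config$batch_size,
    final_loss = model$log$loss[nrow(model$log)]))
  invisible(model)
}

#' Evaluate a trained model on a split and write the report
#'
#' @param config Run config (`out_dir`, `gate_threshold` as hard-call
#'   threshold).
#' @param model A trained `m6a_model`.
#' @param data Windows tibble with labels.
#' @return The `m6a_eval` report, invisibly.
#' @export
pipeline_evaluate <- function(config, model, data) {
  ev <- evaluate_model(model, data, threshold = config$gate_threshold)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(tidy(ev), file.path(config$out_dir, "metrics.tsv"),
                   progress = FALSE)
  readr::write_tsv(ev$roc, file.path(config$out_dir, "roc_curve.tsv"),
                   progress = FALSE)
  readr::write_tsv(ev$pr, file.path(config$out_dir, "pr_curve.tsv"),
                   progress = FALSE)
  write_manifest(config$out_dir, "eval_manifest.json",
                 as.list(glance(ev)))
  invisible(ev)
}

#' Serial two-stage prediction
#'
#' Runs the stage-1 model on every window; windows called positive at the
#' gate threshold are passed to the stage-2 model, mirroring the serial
#' low-resolution -> base-resolution design.  Windows gated out keep `NA`
#' in the stage-2 column.
#'
#' @param stage1,stage2 Trained models (stage 2 may be `NULL` to skip the
#'   second stage entirely).
#' @param windows Windows tibble or character vector of sequences of the
#'   models' window length.
#' @param gate_threshold Stage-1 probability required to enter stage 2.
#' @return A tibble with `window`, `p_stage1`, `confidence_stage1`, and
#'   `p_stage2` (NA where gated out).
#' @export
predict_two_stage <- function(stage1, stage2 = NULL, windows,
                              gate_threshold = 0.5) {
  seqs <- if (is.character(windows)) windows else windows$sequence
  p1 <- predict(stage1, seqs)
  out <- tibble(
    window = if (!is.character(windows) && "chrom" %in% names(windows)) {
      sprintf("%s:%d%s", windows$chrom, windows$position, windows$strand)
    } else {
      sprintf("window_%d", seq_along(seqs))
    },
    p_stage1 = p1$p_positive,
    confidence_stage1 = if ("confidence" %in% names(p1)) {
      p1$confidence
    } else {
      rep(NA_real_, length(seqs))
    },
    p_stage2 = NA_real_
  )
  gate <- out$p_stage1 >= gate_threshold
  if (!is.null(stage2) && any(gate)) {
    p2 <- predict(stage2, seqs[gate])
    out$p_stage2[gate] <- p2$p_positive
  }
  out
}

#' Two-stage prediction from files
#'
#' Reads 601-nt (or model-length) windows from a FASTA file, runs
#' [predict_two_stage()], and writes a TSV.
#'
#' @param config Run config (`out_dir`, `gate_threshold`).
#' @param stage1_path,stage2_path Model checkpoints (stage-2 optional).
#' @param fasta Path to a FASTA of prediction windows.
#' @return The predictions tibble, invisibly.
#' @export
pipeline_predict <- function(config, stage1_path, stage2_path = NULL, fasta) {
  stage1 <- load_model(stage1_path)
  stage2 <- if (!is.null(stage2_path)) load_model(stage2_path)
  set <- Biostrings::readBStringSet(fasta)
  seqs <- chartr("Tt", "UU", toupper(as.character(set)))
  seqs <- toupper(seqs)
  preds <- predict_two_stage(stage1, stage2, unname(seqs),
                             gate_threshold = config$gate_threshold)
  preds$window <- names(set)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(preds, file.path(config$out_dir, "predictions.tsv"),
                   progress = FALSE)
  invisible(preds)
}
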