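# End-to-end orchestration: simulate -> train (split/normalize/augment)
# -> predict -> evaluate -> patterns, with every intermediate artifact
# persisted next to a structured-text manifest (content hashes, config
# hash, stage seed, package version), so a run is reproducible and
# resumable and no stage can silently read an artifact from the wrong
# split.

#' Pipeline configuration
#'
#' One global seed deterministically derives every stage seed, so a
#' `(config, seed)` pair fully determines all artifacts of a run.
#'
#' @param sim A [sim_config()] for the synthetic dataset.
#' @param detector A [detector_config()].
#' @param n_days,sites,p_song Dataset size knobs passed to
#'   [generate_dataset()] (fast mode).
#' @param fractions Train/val/test fractions (default 70/20/10).
#' @param augment Balance the training split (default TRUE).
#' @param q_lo,q_hi Normalizer quantiles.
#' @param min_recordings Seasonal exclusion threshold for the patterns
#'   stage.
#' @param seed Global seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), detector = detector_config(),
                            n_days = 7L, sites = "S01", p_song = NULL,
                            fractions = c(train = 0.7, val = 0.2, test = 0.1),
                            augment = TRUE, q_lo = 0.01, q_hi = 0.99,
                            min_recordings = 250L, seed = 1L) {
  structure(list(sim = sim, detector = detector, n_days = n_days,
                 sites = sites, p_song = p_song, fractions = fractions,
                 augment = augment, q_lo = q_lo, q_hi = q_hi,
                 min_recordings = min_recordings, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_seed <- function(config, stage) {
  idx <- match(stage, c("simulate", "train", "predict", "evaluate", "patterns"))
  (config$seed * 1009L + idx * 101L) %% .Machine$integer.max
}

content_hash <- function(obj) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  serialize(obj, con, version = 2L)
  close(con)
  unname(tools::md5sum(tf))
}

write_manifest <- function(dir, stage, config, inputs, outputs, seed) {
  manifest <- list(stage = stage,
                   package_version = as.character(utils::packageVersion("songsieve")),
                   config_hash = content_hash(unclass(config)),
                   seed = seed,
                   inputs = as.list(unname(tools::md5sum(inputs))),
                   input_files = as.list(basename(inputs)),
                   outputs = as.list(unname(tools::md5sum(outputs))),
                   output_files = as.list(basename(outputs)))
  jsonlite::write_json(manifest, file.path(dir, paste0(stage, ".manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path))
    stop("missing artifact '", basename(path), "': run stage '", produced_by,
         "' first", call. = FALSE)
  path
}

#' Run the detection pipeline
#'
#' Executes the requested stages in order against an output directory.
#' Stage dependencies are checked up front: requesting `predict` without a
#' trained model names `train` as the stage to run first, and so on.
#' Artifacts written to `out_dir`: `labels.csv`, per-file feature CSVs
#' under `features/`, `model.json`, `split.csv`, `predictions.csv`,
#' `metrics.csv`, `diel.csv` and `seasonal.csv`, each stage with a
#' JSON manifest.
#'
#' @param config A [pipeline_config()].
#' @param stages Ordered subset of
#'   `c("simulate", "train", "predict", "evaluate", "patterns")`.
#' @param out_dir Output directory (created).
#' @param verbose Log per-stage counts (files, positives, augmented).
#' @return Invisibly, a run report: list of per-stage summaries.
#' @export
run_pipeline <- function(config, stages = c("simulate", "train", "predict",
                                            "evaluate", "patterns"),
                         out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "train", "predict", "evaluate", "patterns")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  feat_dir <- file.path(out_dir, "features")
  labels_path <- file.path(out_dir, "labels.csv")
  model_path <- file.path(out_dir, "model.json")
  pred_path <- file.path(out_dir, "predictions.csv")
  metrics_path <- file.path(out_dir, "metrics.csv")
  report <- list()
  log <- function(...) if (verbose) message(sprintf(...))

  load_features <- function() {
    labels <- read_labels(labels_path)
    paths <- file.path(feat_dir, paste0(labels$file_id, ".csv"))
    feats <- lapply(paths, read_features)
    names(feats) <- labels$file_id
    list(labels = labels, features = feats)
  }

  for (stage in stages) {
    seed <- stage_seed(config, stage)
    if (stage == "simulate") {
      cfg <- config$sim
      cfg$seed <- seed
      ds <- generate_dataset(cfg, n_days = config$n_days, sites = config$sites,
                             mode = "fast", p_song = config$p_song)
      dir.create(feat_dir, showWarnings = FALSE)
      for (id in names(ds$features))
        write_features(ds$features[[id]], file.path(feat_dir, paste0(id, ".csv")))
      write_labels(ds$labels, labels_path)
      report$simulate <- list(n_files = nrow(ds$labels),
                              n_positive = sum(ds$labels$label))
      log("simulate: %d files, %d positive", nrow(ds$labels),
          sum(ds$labels$label))
      write_manifest(out_dir, "simulate", config, character(0),
                     labels_path, seed)
    } else if (stage == "train") {
      require_artifact(labels_path, "simulate")
      d <- load_features()
      split <- make_splits(d$labels, config$fractions, seed = seed)
      norm <- fit_normalizer(d$features[d$labels$file_id[split == "train"]],
                             q_lo = config$q_lo, q_hi = config$q_hi)
      ex <- as_examples(d$features, d$labels, normalizer = norm)
      tr <- subset_examples(ex, split == "train")
      va <- subset_examples(ex, split == "val")
      n_aug <- 0L
      if (config$augment && sum(tr$y) > 0L && sum(tr$y) < sum(tr$y == 0L)) {
        n0 <- length(tr$y)
        tr <- balance_examples(tr, seed = seed)
        n_aug <- length(tr$y) - n0
      }
      model <- build_detector(config$detector,
                              input_shape = dim(d$features[[1L]]))
      model$config$seed <- seed
      model <- train_detector(model, tr, va, seed = seed)
      model$normalizer <- norm
      save_detector(model, model_path)
      split_path <- file.path(out_dir, "split.csv")
      utils::write.csv(data.frame(file_id = d$labels$file_id, split = split),
                       split_path, row.names = FALSE, quote = FALSE)
      report$train <- list(n_train = sum(split == "train"), n_aug = n_aug,
                           epochs_run = nrow(model$history))
      log("train: %d train files (+%d augmented), %d epochs",
          sum(split == "train"), n_aug, nrow(model$history))
      write_manifest(out_dir, "train", config, labels_path,
                     c(model_path, split_path), seed)
    } else if (stage == "predict") {
      require_artifact(model_path, "train")
      d <- load_features()
      model <- load_detector(model_path)
      ex <- as_examples(d$features, d$labels)
      pr <- predict_detector(model, ex)
      write_predictions(pr, pred_path)
      report$predict <- list(n = nrow(pr), n_positive = sum(pr$label))
      log("predict: %d files, %d predicted positive", nrow(pr), sum(pr$label))
      write_manifest(out_dir, "predict", config, c(labels_path, model_path),
                     pred_path, seed)
    } else if (stage == "evaluate") {
      require_artifact(pred_path, "predict")
      split_path <- require_artifact(file.path(out_dir, "split.csv"), "train")
      labels <- read_labels(labels_path)
      pr <- read_predictions(pred_path)
      split <- utils::read.csv(split_path, stringsAsFactors = FALSE)
      test_ids <- split$file_id[split$split == "test"]
      m <- merge(labels, pr, by = "file_id")
      m <- m[m$file_id %in% test_ids, ]
      ms <- compute_metrics(m$label.y, m$label.x)
      tab <- data.frame(metric = c("accuracy", "precision", "recall", "f1"),
                        value = c(ms$accuracy, ms$precision, ms$recall, ms$f1))
      utils::write.csv(tab, metrics_path, row.names = FALSE, quote = FALSE)
      report$evaluate <- list(metrics = ms, n_test = nrow(m))
      log("evaluate: test acc %.3f recall %.3f (n = %d)", ms$accuracy,
          as.numeric(ms$recall), nrow(m))
      write_manifest(out_dir, "evaluate", config, c(labels_path, pred_path),
                     metrics_path, seed)
    } else if (stage == "patterns") {
      require_artifact(pred_path, "predict")
      labels <- read_labels(labels_path)
      pr <- read_predictions(pred_path)
      det <- merge(labels[, c("file_id", "start_datetime")], pr, by = "file_id")
      diel <- diel_distribution(det)
      seas <- seasonal_distribution(det, min_recordings = config$min_recordings)
      diel_path <- file.path(out_dir, "diel.csv")
      seas_path <- file.path(out_dir, "seasonal.csv")
      write_distribution(diel, diel_path)
      write_distribution(seas, seas_path)
      report$patterns <- list(diel = diel, seasonal = seas)
      log("patterns: %d diel bins, %d sampled weeks", 48L,
          sum(!seas$bins$excluded))
      write_manifest(out_dir, "patterns", config, pred_path,
                     c(diel_path, seas_path), seed)
    }
  }
  invisible(report)
}
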