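# Shared in-code fixtures: small seeded synthetic datasets and a helper
# that runs the standard split/normalize/augment/train/evaluate pipeline
# at a configurable scale.

# Fast-mode dataset with uniform occurrence probability (no diel/seasonal
# structure), the setting used for detector experiments.
fixture_dataset <- function(seed = 11, n_days = 5, p_song = 0.1, snr_db = 10) {
  cfg <- sim_config(seed = seed, snr_db = snr_db,
                    diel_profile = rep(0.5, 48),
                    seasonal_profile = rep(0.5, 52))
  generate_dataset(cfg, n_days = n_days, sites = "A", mode = "fast",
                   p_song = p_song)
}

# Split 70/20/10, fit normalizer on train, balance train, train the given
# detector config, return model + splits + test metrics.
fixture_train <- function(ds, config = detector_config(), seed = 2,
                          augment = TRUE, epochs = config$epochs) {
  split <- make_splits(ds$labels, seed = seed)
  norm <- fit_normalizer(ds$features[ds$labels$file_id[split == "train"]])
  ex <- as_examples(ds$features, ds$labels, normalizer = norm)
  tr <- subset_examples(ex, split == "train")
  va <- subset_examples(ex, split == "val")
  te <- subset_examples(ex, split == "test")
  if (augment) tr <- balance_examples(tr, seed = seed + 1)
  model <- build_detector(config, dim(ds$features[[1]]))
  model <- train_detector(model, tr, va, epochs = epochs, seed = seed + 2)
  model$normalizer <- norm
  pred <- predict_detector(model, te)
  list(model = model, split = split, norm = norm, train = tr, val = va,
       test = te, pred = pred,
       metrics = compute_metrics(pred$label, te$y))
}

# A tiny, fully deterministic labels table spanning known times.
fixture_labels <- function(n = 8, start = "2020-03-01 06:00:00") {
  dt <- as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * 1800
  data.frame(file_id = sprintf("f%02d", seq_len(n)), site_id = "A",
             recorder_type = "AM", start_datetime = dt, duration_s = 600,
             label = rep(c(0L, 1L), length.out = n), stringsAsFactors = FALSE)
}
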