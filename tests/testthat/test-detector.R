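# Detector architecture, parameter accounting, training behaviour,
# prediction contracts, and transfer learning.

toy_config <- function(epochs = 200L, ...) {
  detector_config(conv_layers = list(list(filters = 4L, kernel = c(3L, 3L),
                                          stride = c(1L, 1L))),
                  dense_sizes = 8L, dropout_rate = 0, epochs = epochs,
                  batch_size = 8L, ...)
}

test_that("parameter counts equal the per-layer arithmetic oracle", {
  # conv: 4*(3*3+1) = 40; flatten 28*16*4 = 1792; dense: (1792+4)*8+8;
  # output: 8+1  => total 14,425
  m <- build_detector(toy_config(), c(30L, 18L))
  pc <- count_parameters(m)
  expect_identical(unname(pc$per_layer["conv1"]), 40L)
  expect_identical(unname(pc$per_layer["dense1"]), (28L * 16L * 4L + 4L) * 8L + 8L)
  expect_identical(unname(pc$per_layer["output"]), 9L)
  expect_identical(pc$total, 14425L)
})

test_that("the shipped default architecture reports its analytic parameter count", {
  m <- build_detector(detector_config(), c(30L, 18L))
  # hand-computed: conv1 16*(15+1); conv2 32*(16*15+1); conv3 32*(32*9+1);
  # dense1 (11*3*32+4)*64+64; dense2 64*32+32; output 32+1
  by_hand <- 16 * 16 + 32 * 241 + 32 * 289 + 1060 * 64 + 64 + 2080 + 33
  expect_identical(m$parameter_count, as.integer(by_hand))
  expect_identical(m$parameter_count, 87233L)  # near the 84,357 calibration scale
  expect_identical(m$trainable_parameter_count, m$parameter_count)
})

test_that("oversized kernels are rejected with a shape trace", {
  bad <- detector_config(conv_layers = list(
    list(filters = 4L, kernel = c(3L, 19L), stride = c(1L, 1L))))
  expect_error(build_detector(bad, c(30L, 18L)), "does not fit")
  expect_error(build_detector(bad, c(30L, 18L)), "shape trace")
})

test_that("exactly four covariates are wired into the dense head", {
  m <- build_detector(detector_config(), c(30L, 18L))
  conv_out <- prod(m$layers[[3]]$out_shape)
  expect_identical(nrow(m$weights$W_dense1), as.integer(conv_out) + 4L)
  # covariates change the output of an initialized network
  ex <- structure(list(x = list(matrix(stats::runif(540), 30, 18)),
                       y = 0L, covariates = cbind(hour_sin = 0.5, hour_cos = sqrt(0.75),
                                                  week_sin = 1, week_cos = 0),
                       file_id = "a", augmented = FALSE, normalized = TRUE),
                  class = "song_examples")
  ex0 <- ex; ex0$covariates <- ex$covariates * 0
  p1 <- predict_detector(m, ex)$probability
  p2 <- predict_detector(m, ex0)$probability
  expect_false(isTRUE(all.equal(p1, p2)))
})

test_that("a small network overfits 20 separable examples to accuracy 1.0", {
  set.seed(44)
  mk <- function(lbl) {
    m <- matrix(stats::runif(540, 0, 0.3), 30, 18)
    if (lbl == 1) m[10:20, 6:9] <- m[10:20, 6:9] + 0.6
    m
  }
  y <- rep(c(0L, 1L), 10)
  ex <- structure(list(x = lapply(y, mk), y = y,
                       covariates = matrix(0, 20, 4,
                         dimnames = list(NULL, c("hour_sin", "hour_cos",
                                                 "week_sin", "week_cos"))),
                       file_id = sprintf("t%02d", 1:20),
                       augmented = rep(FALSE, 20), normalized = TRUE),
                  class = "song_examples")
  val <- ex; val$file_id <- paste0("v", val$file_id)
  model <- build_detector(toy_config(), c(30L, 18L))
  model <- train_detector(model, ex, val, epochs = 200L, patience = 200L,
                          seed = 5)
  pr <- predict_detector(model, ex)
  expect_identical(pr$label, y)
  h <- model$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
})

test_that("training is deterministic given seed and data", {
  ds <- fixture_dataset(seed = 50, n_days = 2, p_song = 0.15)
  r1 <- fixture_train(ds, toy_config(epochs = 3L), seed = 3)
  r2 <- fixture_train(ds, toy_config(epochs = 3L), seed = 3)
  expect_identical(r1$model$weights, r2$model$weights)
  expect_identical(r1$pred, r2$pred)
})

test_that("prediction contracts: range, threshold convention, batching invariance", {
  ds <- fixture_dataset(seed = 51, n_days = 2, p_song = 0.15)
  r <- fixture_train(ds, toy_config(epochs = 3L), seed = 4)
  pr <- predict_detector(r$model, r$test)
  expect_true(all(pr$probability >= 0 & pr$probability <= 1))
  expect_identical(pr$label, as.integer(pr$probability >= 0.5))
  # probability exactly at threshold labels positive
  expect_identical(as.integer(0.5 >= r$model$config$decision_threshold), 1L)
  # one-by-one inference equals batch inference
  singles <- vapply(seq_along(r$test$y), function(i)
    predict_detector(r$model, subset_examples(r$test, i))$probability,
    numeric(1))
  expect_equal(singles, pr$probability, tolerance = 1e-12)
})

test_that("split hygiene is enforced at training time", {
  ds <- fixture_dataset(seed = 52, n_days = 2, p_song = 0.15)
  ex <- as_examples(ds$features, ds$labels,
                    normalizer = fit_normalizer(ds$features))
  tr <- subset_examples(ex, 1:50)
  va <- subset_examples(ex, 40:60)  # overlap
  m <- build_detector(toy_config(), c(30L, 18L))
  expect_error(train_detector(m, tr, va, epochs = 1L), "share file")
  aug <- balance_examples(subset_examples(ex, 1:60), seed = 1)
  expect_error(train_detector(m, tr, subset_examples(aug, which(aug$augmented)),
                              epochs = 1L), "augmented")
})

test_that("frozen layers are immutable under transfer and counts shrink exactly", {
  ds <- fixture_dataset(seed = 53, n_days = 3, p_song = 0.15)
  src <- fixture_train(ds, toy_config(epochs = 3L), seed = 5)
  tgt <- fixture_dataset(seed = 54, n_days = 3, p_song = 0.15)
  tf <- transfer_detector(src$model, tgt$features, tgt$labels,
                          train_frac = 0.1, val_frac = 0.15,
                          epochs = 3L, seed = 6)
  expect_identical(tf$model$frozen, "conv1")
  expect_identical(tf$model$weights$W_conv1, src$model$weights$W_conv1)
  expect_identical(tf$model$weights$b_conv1, src$model$weights$b_conv1)
  pc <- count_parameters(tf$model)
  expect_identical(pc$trainable, pc$total - unname(pc$per_layer["conv1"]))
  # the unfrozen head did move
  head_keys <- c("W_dense1", "b_dense1", "W_output", "b_output")
  expect_false(identical(tf$model$weights[head_keys],
                         src$model$weights[head_keys]))
  # freeze everything: weights bit-identical to source
  all_layers <- c("conv1", "dense1", "output")
  tf2 <- transfer_detector(src$model, tgt$features, tgt$labels,
                           train_frac = 0.1, val_frac = 0.15,
                           freeze = all_layers, epochs = 2L, seed = 6)
  expect_identical(tf2$model$weights, src$model$weights)
  expect_error(transfer_detector(src$model, tgt$features, tgt$labels,
                                 freeze = "conv9"), "nonexistent")
})

test_that("transfer splits respect the 5/15/80 file fractions", {
  ds <- fixture_dataset(seed = 55, n_days = 5, p_song = 0.2)
  src <- fixture_train(ds, toy_config(epochs = 2L), seed = 7)
  tgt <- fixture_dataset(seed = 56, n_days = 5, p_song = 0.2)
  tf <- transfer_detector(src$model, tgt$features, tgt$labels, epochs = 2L,
                          seed = 8)
  n <- nrow(tgt$labels)
  expect_lte(abs(sum(tf$split == "train") - 0.05 * n), 2)
  expect_lte(abs(sum(tf$split == "val") - 0.15 * n), 2)
  expect_gte(sum(tf$split == "test"), 0.78 * n)
  expect_error(transfer_detector(src$model, tgt$features, tgt$labels,
                                 train_frac = 0.3, val_frac = 0.3), "50%")
})

test_that("a detector survives a save/load round trip bit-for-bit in behaviour", {
  ds <- fixture_dataset(seed = 57, n_days = 2, p_song = 0.15)
  r <- fixture_train(ds, toy_config(epochs = 2L), seed = 9)
  tf <- withr::local_tempfile(fileext = ".json")
  save_detector(r$model, tf)
  back <- load_detector(tf)
  expect_equal(back$weights, r$model$weights, tolerance = 1e-12)
  expect_identical(back$parameter_count, r$model$parameter_count)
  expect_equal(back$normalizer$lo, r$model$normalizer$lo, tolerance = 1e-12)
  p1 <- predict_detector(r$model, r$test)
  p2 <- predict_detector(back, r$test)
  expect_equal(p1$probability, p2$probability, tolerance = 1e-12)
})

test_that("transfer learning recovers performance lost to a recorder gain shift", {
  # controlled simulation: the target recorder is 10 dB more sensitive in
  # every band, so through the source model's normalizer nearly all cells
  # saturate and the unadapted model loses its discrimination; transfer
  # (normalizer refit on 10% of files + retrained dense head over frozen
  # convolutions) should restore F1 while keeping recall high
  ds <- fixture_dataset(seed = 80, n_days = 5, p_song = 0.15)
  src <- fixture_train(ds, detector_config(epochs = 10L), seed = 2)
  f1_wins <- 0L; recall_ok <- 0L; n_seeds <- 5L
  for (sd2 in 81:(80 + n_seeds)) {
    tgt <- fixture_dataset(seed = sd2 + 100, n_days = 5, p_song = 0.15)
    tgt$features <- lapply(tgt$features, function(m) { m[] <- m + 10; m })
    ex <- as_examples(tgt$features, tgt$labels)
    base_pr <- predict_detector(src$model, ex)
    tl <- transfer_detector(src$model, tgt$features, tgt$labels,
                            train_frac = 0.1, val_frac = 0.15,
                            epochs = 10L, seed = sd2)
    te <- tl$split == "test"
    tl_ms <- compute_metrics(
      predict_detector(tl$model, subset_examples(ex, te))$label,
      tgt$labels$label[te])
    base_ms <- compute_metrics(base_pr$label[te], tgt$labels$label[te])
    if (tl_ms$f1 >= base_ms$f1) f1_wins <- f1_wins + 1L
    if (!is.na(tl_ms$recall) && tl_ms$recall >= 0.8) recall_ok <- recall_ok + 1L
  }
  expect_gte(f1_wins, 3L)     # majority of seeds
  expect_gte(recall_ok, 3L)
})
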