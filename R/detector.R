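# The convolution-only song detector. The feature path is a stack of
# convolutional layers (no pooling); the flattened feature map is
# concatenated with the four cyclic temporal covariates and passed through
# fully connected layers to a single sigmoid output trained with binary
# cross-entropy.

#' Detector configuration
#'
#' The shipped default is a stack of three convolutional layers
#' (16 filters 3x5; 32 filters 3x5 with stride 2x2; 32 filters 3x3),
#' flatten + 4 covariates, dense 64 with dropout 0.3, dense 32, sigmoid.
#' On a 30 x 18 input this yields 87,233 trainable parameters, near the
#' ~84k-parameter scale the approach was calibrated at. Non-square kernels
#' expose the time-by-frequency aspect ratio of each filter; every field
#' is externalized because the best values are data-dependent.
#'
#' @param conv_layers List of convolutional layer specs, each a list with
#'   `filters`, `kernel` = c(time, frequency) and `stride` = c(time,
#'   frequency).
#' @param dense_sizes Neuron counts of the fully connected layers before
#'   the output (two by convention).
#' @param dropout_rate Dropout fraction after the first dense layer, in
#'   `[0, 1)`.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Maximum training epochs.
#' @param decision_threshold Probability cutoff for the positive label
#'   (label 1 when probability >= threshold).
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @return A validated list of class `detector_config`.
#' @export
detector_config <- function(conv_layers = list(
                              list(filters = 16L, kernel = c(3L, 5L), stride = c(1L, 1L)),
                              list(filters = 32L, kernel = c(3L, 5L), stride = c(2L, 2L)),
                              list(filters = 32L, kernel = c(3L, 3L), stride = c(1L, 1L))),
                            dense_sizes = c(64L, 32L),
                            dropout_rate = 0.3,
                            learning_rate = 1e-3,
                            batch_size = 32L,
                            epochs = 50L,
                            decision_threshold = 0.5,
                            seed = 42L) {
  if (length(conv_layers) < 1L)
    stop("at least one convolutional layer is required", call. = FALSE)
  for (cl in conv_layers)
    stopifnot(cl$filters >= 1L, length(cl$kernel) == 2L, length(cl$stride) == 2L,
              all(cl$kernel >= 1L), all(cl$stride >= 1L))
  if (length(dense_sizes) < 1L || any(dense_sizes < 1L))
    stop("'dense_sizes' must hold at least one positive size", call. = FALSE)
  if (!(dropout_rate >= 0 && dropout_rate < 1))
    stop("'dropout_rate' must be in [0, 1)", call. = FALSE)
  if (!(decision_threshold > 0 && decision_threshold < 1))
    stop("'decision_threshold' must be in (0, 1)", call. = FALSE)
  structure(list(conv_layers = conv_layers,
                 dense_sizes = as.integer(dense_sizes),
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 decision_threshold = decision_threshold,
                 seed = as.integer(seed)),
            class = "detector_config")
}

#' Build (and initialize) a song detector
#'
#' Lays out the layer stack for the given input shape, validates that every
#' kernel fits its feature map (reporting a layer-by-layer shape trace when
#' it does not), and initializes weights (He-scaled, seeded).
#'
#' @param config A [detector_config()].
#' @param input_shape `c(T, B)`: intervals by bands (default `c(30, 18)`).
#' @return A `detector_model`: layers, weights, parameter counts, empty
#'   freeze state, and a slot for the attached normalizer.
#' @export
build_detector <- function(config = detector_config(), input_shape = c(30L, 18L)) {
  shape <- c(input_shape, 1L)
  layers <- list()
  trace <- sprintf("input: %dx%dx%d", shape[1], shape[2], shape[3])
  for (i in seq_along(config$conv_layers)) {
    cl <- config$conv_layers[[i]]
    name <- paste0("conv", i)
    plan <- tryCatch(conv_plan(shape, cl$kernel, cl$stride, cl$filters),
                     error = function(e)
                       stop("layer ", name, ": ", conditionMessage(e),
                            "\nshape trace so far:\n  ",
                            paste(trace, collapse = "\n  "), call. = FALSE))
    layers[[length(layers) + 1L]] <-
      c(plan["S"], plan["K"], plan["ohow"],
        list(name = name, type = "conv", filters = cl$filters,
             kernel = cl$kernel, stride = cl$stride,
             in_shape = shape, out_shape = plan$out_shape))
    shape <- plan$out_shape
    trace <- c(trace, sprintf("%s: %dx%dx%d", name, shape[1], shape[2], shape[3]))
  }
  flat <- prod(shape)
  layers[[length(layers) + 1L]] <- list(name = "concat", type = "concat",
                                        n_covariates = 4L)
  in_dim <- flat + 4L
  for (i in seq_along(config$dense_sizes)) {
    name <- paste0("dense", i)
    layers[[length(layers) + 1L]] <-
      list(name = name, type = "dense", in_dim = in_dim,
           out_dim = config$dense_sizes[i],
           dropout = if (i == 1L) config$dropout_rate else 0)
    in_dim <- config$dense_sizes[i]
  }
  layers[[length(layers) + 1L]] <- list(name = "output", type = "output",
                                        in_dim = in_dim, out_dim = 1L)
  weights <- withr::with_seed(config$seed, {
    w <- list()
    for (ly in layers) {
      if (ly$type == "conv") {
        w[[paste0("W_", ly$name)]] <- he_init(ly$K, ly$filters, ly$K)
        w[[paste0("b_", ly$name)]] <- numeric(ly$filters)
      } else if (ly$type %in% c("dense", "output")) {
        w[[paste0("W_", ly$name)]] <- he_init(ly$in_dim, ly$out_dim, ly$in_dim)
        w[[paste0("b_", ly$name)]] <- numeric(ly$out_dim)
      }
    }
    w
  })
  model <- structure(list(config = config, input_shape = as.integer(input_shape),
                          layers = layers, weights = weights,
                          frozen = character(0), normalizer = NULL,
                          history = NULL, provenance = list()),
                     class = "detector_model")
  model$parameter_count <- count_parameters(model)$total
  model$trainable_parameter_count <- count_parameters(model)$trainable
  model
}

#' Parameter counts of a detector
#'
#' Analytic per-layer counts (`prod(dim(W)) + length(b)`); the trainable
#' count excludes frozen layers.
#'
#' @param model A `detector_model`.
#' @return List with `per_layer`, `total` and `trainable`.
#' @export
count_parameters <- function(model) {
  per <- integer(0)
  for (ly in model$layers) {
    if (ly$type == "concat") next
    n <- length(model$weights[[paste0("W_", ly$name)]]) +
      length(model$weights[[paste0("b_", ly$name)]])
    per[ly$name] <- n
  }
  list(per_layer = per, total = sum(per),
       trainable = sum(per[setdiff(names(per), model$frozen)]))
}

#' @export
print.detector_model <- function(x, ...) {
  cat("<detector_model>\n")
  for (ly in x$layers) {
    if (ly$type == "conv")
      cat(sprintf("  %s: %d filters %dx%d stride %dx%d -> %dx%dx%d%s\n",
                  ly$name, ly$filters, ly$kernel[1], ly$kernel[2],
                  ly$stride[1], ly$stride[2], ly$out_shape[1], ly$out_shape[2],
                  ly$out_shape[3],
                  if (ly$name %in% x$frozen) " [frozen]" else ""))
    else if (ly$type == "concat")
      cat("  concat: + 4 cyclic temporal covariates\n")
    else
      cat(sprintf("  %s: %d -> %d%s%s\n", ly$name, ly$in_dim, ly$out_dim,
                  if (!is.null(ly$dropout) && isTRUE(ly$dropout > 0))
                    sprintf(" (dropout %.2f)", ly$dropout) else "",
                  if (ly$name %in% x$frozen) " [frozen]" else ""))
  }
  cat(sprintf("  parameters: %d total, %d trainable\n",
              x$parameter_count, x$trainable_parameter_count))
  if (!is.null(x$normalizer)) cat("  normalizer: attached\n")
  invisible(x)
}

check_split_disjoint <- function(train, val) {
  strip <- function(id) sub("#aug[0-9]+$", "", id)
  if (any(val$augmented))
    stop("augmented examples must not enter a validation or test split",
         call. = FALSE)
  shared <- intersect(strip(train$file_id), strip(val$file_id))
  if (length(shared) > 0L)
    stop("train and validation splits share file(s): ",
         paste(utils::head(shared, 3), collapse = ", "), call. = FALSE)
}

#' Train a song detector
#'
#' Minimizes binary cross-entropy with Adam on minibatches; after each
#' epoch the validation loss is evaluated and the weights with the best
#' validation loss so far are retained (early stopping with the given
#' patience). Training is deterministic given the seed.
#'
#' @param model A `detector_model` from [build_detector()].
#' @param train,val `song_examples` (normalized), disjoint by file;
#'   augmented examples are rejected in `val`.
#' @param epochs,batch_size,learning_rate,patience Training
#'   hyperparameters; defaults come from the model config (patience 10).
#' @param seed Seed for shuffling and dropout (default: model config seed).
#' @param verbose Print per-epoch losses.
#' @return The trained `detector_model` with a `history` data frame
#'   (`epoch`, `train_loss`, `val_loss`, `val_accuracy`).
#' @export
train_detector <- function(model, train, val,
                           epochs = model$config$epochs,
                           batch_size = model$config$batch_size,
                           learning_rate = model$config$learning_rate,
                           patience = 10L,
                           seed = model$config$seed,
                           verbose = FALSE) {
  if (length(train$y) == 0L || length(val$y) == 0L)
    stop("empty training or validation split", call. = FALSE)
  check_split_disjoint(train, val)
  if (length(unique(train$y)) == 1L)
    warning("single-class training set: consider augmentation/balancing",
            call. = FALSE)
  tr <- examples_arrays(train)
  va <- examples_arrays(val)
  thr <- model$config$decision_threshold
  withr::with_seed(seed, {
    state <- adam_init(model$weights)
    best <- list(loss = Inf, weights = model$weights, epoch = 0L)
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0), val_accuracy = numeric(0))
    n <- nrow(tr$X)
    wait <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        fw <- nn_forward(model, tr$X[idx, , drop = FALSE],
                         tr$cov[idx, , drop = FALSE],
                         training = TRUE, caches = TRUE)
        gr <- nn_backward(model, fw, tr$X[idx, , drop = FALSE], tr$y[idx])
        up <- adam_step(model$weights, gr, state, learning_rate, model$frozen)
        model$weights <- up$weights
        state <- up$state
        ep_loss <- ep_loss + bce_loss(fw$prob, tr$y[idx]); nb <- nb + 1L
      }
      vf <- nn_forward(model, va$X, va$cov)
      vloss <- bce_loss(vf$prob, va$y)
      vacc <- mean((vf$prob >= thr) == (va$y == 1))
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                     val_loss = vloss, val_accuracy = vacc))
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  val_acc %.3f",
                        ep, ep_loss / nb, vloss, vacc))
      if (vloss < best$loss - 1e-9) {
        best <- list(loss = vloss, weights = model$weights, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    model$weights <- best$weights
    model$history <- hist
    model$provenance <- c(model$provenance,
                          list(list(event = "train", epochs_run = nrow(hist),
                                    best_epoch = best$epoch,
                                    n_train = n, n_val = length(va$y),
                                    seed = seed)))
  })
  model
}

#' Predict song probabilities and labels
#'
#' @param model A trained `detector_model`.
#' @param examples `song_examples`; if not yet normalized, the model's
#'   attached normalizer is applied (an error if none is attached).
#' @param threshold Decision threshold (default: model config); the label
#'   is 1 when probability >= threshold.
#' @return Data frame with `file_id`, `probability` and `label`.
#' @export
predict_detector <- function(model, examples,
                             threshold = model$config$decision_threshold) {
  if (!isTRUE(examples$normalized)) {
    if (is.null(model$normalizer))
      stop("examples are not normalized and the model has no attached normalizer",
           call. = FALSE)
    examples$x <- lapply(examples$x, apply_normalizer, norm = model$normalizer)
    examples$normalized <- TRUE
  }
  if (!all(dim(examples$x[[1L]]) == model$input_shape))
    stop("feature shape ", paste(dim(examples$x[[1L]]), collapse = "x"),
         " does not match model input ",
         paste(model$input_shape, collapse = "x"), call. = FALSE)
  ar <- examples_arrays(examples)
  fw <- nn_forward(model, ar$X, ar$cov)
  data.frame(file_id = examples$file_id, probability = fw$prob,
             label = as.integer(fw$prob >= threshold),
             stringsAsFactors = FALSE)
}

#' Adapt a trained detector to a new dataset (transfer learning)
#'
#' Reuses the source model's weights, freezes the requested layers
#' (default: all convolutional layers, so only the fully connected head is
#' retrained), refits the normalizer on the small training fraction of the
#' new dataset, and retrains the unfrozen layers at a reduced learning
#' rate. Only `train_frac` + `val_frac` of the files are touched; the
#' remainder is reserved as a test set and returned with the split
#' assignment.
#'
#' @param model A trained `detector_model` (with or without a normalizer).
#' @param features Named list of raw (dB) feature matrices of the new
#'   dataset.
#' @param labels Labels data frame for the new dataset.
#' @param train_frac,val_frac File fractions used for retraining (defaults
#'   0.05 and 0.15); together they must leave at least half the files for
#'   testing.
#' @param freeze `"conv"` (default), `"none"`, or a character vector of
#'   layer names to freeze; unknown names are an error.
#' @param learning_rate Retraining learning rate (default: a third of the
#'   model's).
#' @param epochs Maximum retraining epochs (default 30).
#' @param augment Balance the transfer training split by slice-shuffle
#'   augmentation (default TRUE).
#' @param q_lo,q_hi Normalizer quantiles for the refit.
#' @param seed Seed (default: model config seed).
#' @return List with `model` (adapted detector), `split` (character vector
#'   per file: train/val/test) and `labels` (the input table with the
#'   split attached).
#' @export
transfer_detector <- function(model, features, labels,
                              train_frac = 0.05, val_frac = 0.15,
                              freeze = "conv",
                              learning_rate = model$config$learning_rate / 3,
                              epochs = 30L, augment = TRUE,
                              q_lo = 0.01, q_hi = 0.99,
                              seed = model$config$seed) {
  if (train_frac + val_frac > 0.5)
    stop("train_frac + val_frac must leave at least 50% of files for testing",
         call. = FALSE)
  layer_names <- vapply(model$layers, `[[`, "", "name")
  layer_names <- layer_names[layer_names != "concat"]
  frozen <- if (identical(freeze, "conv")) grep("^conv", layer_names, value = TRUE)
            else if (identical(freeze, "none")) character(0)
            else freeze
  unknown <- setdiff(frozen, layer_names)
  if (length(unknown) > 0L)
    stop("freeze spec names nonexistent layer(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  model$frozen <- frozen
  model$trainable_parameter_count <- count_parameters(model)$trainable
  split <- make_splits(labels, c(train = train_frac, val = val_frac,
                                 test = 1 - train_frac - val_frac),
                       seed = seed)
  norm <- fit_normalizer(features[labels$file_id[split == "train"]],
                         q_lo = q_lo, q_hi = q_hi)
  ex <- as_examples(features, labels, normalizer = norm)
  tr <- subset_examples(ex, split == "train")
  va <- subset_examples(ex, split == "val")
  if (augment && sum(tr$y) > 0L && sum(tr$y) < sum(tr$y == 0L))
    tr <- balance_examples(tr, seed = seed)
  pre <- model$weights
  model <- train_detector(model, tr, va, epochs = epochs,
                          learning_rate = learning_rate, seed = seed)
  for (nm in frozen)  # freeze contract: bit-identical weights
    stopifnot(identical(pre[[paste0("W_", nm)]],
                        model$weights[[paste0("W_", nm)]]),
              identical(pre[[paste0("b_", nm)]],
                        model$weights[[paste0("b_", nm)]]))
  model$normalizer <- norm
  model$provenance <- c(model$provenance,
                        list(list(event = "transfer", frozen = frozen,
                                  train_frac = train_frac, val_frac = val_frac,
                                  learning_rate = learning_rate)))
  labels$split <- split
  list(model = model, split = split, labels = labels)
}
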