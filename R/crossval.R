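# File-grouped, label-stratified splitting and k-fold cross-validation of
# the full detection pipeline (normalizer fit, augmentation and training
# happen inside each fold's training portion only, so no statistic leaks
# into the held-out fold).

#' Stratified file-grouped fold assignment
#'
#' Files of each class are shuffled and dealt round-robin over folds, so
#' fold sizes differ by at most one file per class and every file lands in
#' exactly one fold.
#'
#' @param labels Labels data frame with `file_id` and `label`.
#' @param k Number of folds (>= 2).
#' @param seed Seed for the shuffle.
#' @return Integer vector of fold ids (1..k), one per row of `labels`.
#' @export
make_folds <- function(labels, k = 10L, seed = 1L) {
  if (k < 2L) stop("'k' must be >= 2", call. = FALSE)
  if (anyDuplicated(labels$file_id))
    stop("duplicated file_id in labels: folds would leak between splits",
         call. = FALSE)
  if (any(table(labels$label) < k))
    stop("fewer files than folds in at least one class", call. = FALSE)
  fold <- integer(nrow(labels))
  withr::with_seed(seed, {
    cursor <- 0L  # continuous deal across classes keeps overall sizes within 1
    for (cl in unique(labels$label)) {
      idx <- sample(which(labels$label == cl))
      fold[idx] <- ((cursor + seq_along(idx) - 1L) %% k) + 1L
      cursor <- cursor + length(idx)
    }
  })
  fold
}

#' Stratified file-grouped train/validation/test assignment
#'
#' @param labels Labels data frame with `file_id` and `label`.
#' @param fractions Named fractions summing to 1 (default
#'   `c(train = 0.7, val = 0.2, test = 0.1)`).
#' @param seed Seed.
#' @return Character vector of split names, one per row.
#' @export
make_splits <- function(labels,
                        fractions = c(train = 0.7, val = 0.2, test = 0.1),
                        seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("'fractions' must sum to 1", call. = FALSE)
  if (anyDuplicated(labels$file_id))
    stop("duplicated file_id in labels", call. = FALSE)
  split <- character(nrow(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels$label)) {
      idx <- sample(which(labels$label == cl))
      n <- length(idx)
      counts <- floor(fractions * n)
      rem <- n - sum(counts)
      if (rem > 0) {  # give leftovers to the largest fractions
        extra <- order(fractions * n - counts, decreasing = TRUE)[seq_len(rem)]
        counts[extra] <- counts[extra] + 1L
      }
      split[idx] <- rep(names(fractions), counts)
    }
  })
  split
}

#' Cross-validate the detection pipeline
#'
#' File-grouped, label-stratified k-fold cross-validation. For each fold,
#' the remaining k-1 folds form the training portion: a fresh normalizer
#' is fit on it, an inner validation split is carved out for early
#' stopping, the training split is (optionally) balanced by slice-shuffle
#' augmentation, a detector is trained, and the held-out fold is
#' evaluated at its natural class balance.
#'
#' @param features Named list of raw (dB) feature matrices.
#' @param labels Labels data frame (`file_id`, `start_datetime`, `label`).
#' @param k Number of folds (default 10).
#' @param config A [detector_config()].
#' @param augment Balance each fold's training split (default TRUE).
#' @param q_lo,q_hi Normalizer quantiles.
#' @param epochs Maximum epochs per fold (default: config).
#' @param inner_val_frac Fraction of training files held out for early
#'   stopping (default 0.15).
#' @param seed Seed for fold assignment and training.
#' @param trainer,predictor Optional overrides for the fold model:
#'   `trainer(train_examples, val_examples, fold_seed)` must return an
#'   object that `predictor(object, test_examples)` maps to 0/1 labels.
#'   Used to audit the fold bookkeeping with cheap stand-in models.
#' @return List of class `crossval_result`: `fold` assignment, `metrics`
#'   (list of `metric_set`), `summary` (data frame with mean and sd per
#'   metric, the "value +/- sd" layout), and `predictions` (per-file
#'   predicted labels from the fold in which the file was held out).
#' @export
cross_validate <- function(features, labels, k = 10L,
                           config = detector_config(), augment = TRUE,
                           q_lo = 0.01, q_hi = 0.99,
                           epochs = config$epochs,
                           inner_val_frac = 0.15,
                           seed = 1L,
                           trainer = NULL, predictor = NULL) {
  fold <- make_folds(labels, k = k, seed = seed)
  metrics <- vector("list", k)
  preds <- data.frame(file_id = labels$file_id,
                      probability = NA_real_, label = NA_integer_,
                      fold = fold, stringsAsFactors = FALSE)
  for (f in seq_len(k)) {
    test_rows <- fold == f
    tr_labels <- labels[!test_rows, , drop = FALSE]
    fold_seed <- (seed * 1000L + f) %% .Machine$integer.max
    inner <- make_splits(tr_labels,
                         c(train = 1 - inner_val_frac, val = inner_val_frac),
                         seed = fold_seed)
    if (is.null(trainer)) {
      norm <- fit_normalizer(features[tr_labels$file_id[inner == "train"]],
                             q_lo = q_lo, q_hi = q_hi)
      ex_all <- as_examples(features, labels, normalizer = norm)
      names(ex_all$x) <- labels$file_id
      tr <- subset_examples(ex_all, which(!test_rows)[inner == "train"])
      va <- subset_examples(ex_all, which(!test_rows)[inner == "val"])
      te <- subset_examples(ex_all, which(test_rows))
      if (augment && sum(tr$y) > 0L && sum(tr$y) < sum(tr$y == 0L))
        tr <- balance_examples(tr, seed = fold_seed)
      model <- build_detector(config,
                              input_shape = dim(features[[1L]]))
      model$config$seed <- fold_seed
      model <- train_detector(model, tr, va, epochs = epochs, seed = fold_seed)
      model$normalizer <- norm
      pr <- predict_detector(model, te)
    } else {
      ex_all <- as_examples(features, labels)
      tr <- subset_examples(ex_all, which(!test_rows)[inner == "train"])
      va <- subset_examples(ex_all, which(!test_rows)[inner == "val"])
      te <- subset_examples(ex_all, which(test_rows))
      obj <- trainer(tr, va, fold_seed)
      pr <- predictor(obj, te)
      if (!is.data.frame(pr))
        pr <- data.frame(file_id = te$file_id, probability = NA_real_,
                         label = as.integer(pr), stringsAsFactors = FALSE)
    }
    metrics[[f]] <- compute_metrics(pr$label, labels$label[test_rows])
    preds$probability[test_rows] <- pr$probability
    preds$label[test_rows] <- pr$label
  }
  metric_names <- c("accuracy", "precision", "recall", "f1")
  tab <- sapply(metric_names, function(mn)
    vapply(metrics, function(ms) as.numeric(ms[[mn]]), numeric(1)))
  summary <- data.frame(metric = metric_names,
                        mean = colMeans(tab, na.rm = TRUE),
                        sd = apply(tab, 2, stats::sd, na.rm = TRUE),
                        row.names = NULL)
  structure(list(fold = fold, metrics = metrics, summary = summary,
                 predictions = preds, k = k),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("<crossval_result> %d folds\n", x$k))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Per-fold metric table of a cross-validation result
#'
#' One row per fold plus a summary row with mean and sd per metric.
#'
#' @param cv A `crossval_result`.
#' @return Data frame with columns `fold`, `accuracy`, `precision`,
#'   `recall`, `f1`; the last two rows are `mean` and `sd`.
#' @export
crossval_table <- function(cv) {
  rows <- lapply(seq_along(cv$metrics), function(f) {
    ms <- cv$metrics[[f]]
    data.frame(fold = as.character(f), accuracy = ms$accuracy,
               precision = as.numeric(ms$precision),
               recall = as.numeric(ms$recall), f1 = ms$f1)
  })
  tab <- do.call(rbind, rows)
  rbind(tab,
        data.frame(fold = "mean", accuracy = mean(tab$accuracy, na.rm = TRUE),
                   precision = mean(tab$precision, na.rm = TRUE),
                   recall = mean(tab$recall, na.rm = TRUE),
                   f1 = mean(tab$f1, na.rm = TRUE)),
        data.frame(fold = "sd", accuracy = stats::sd(tab$accuracy[seq_along(cv$metrics)], na.rm = TRUE),
                   precision = stats::sd(tab$precision[seq_along(cv$metrics)], na.rm = TRUE),
                   recall = stats::sd(tab$recall[seq_along(cv$metrics)], na.rm = TRUE),
                   f1 = stats::sd(tab$f1[seq_along(cv$metrics)], na.rm = TRUE)))
}
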