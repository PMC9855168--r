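# The labelled-example container handed to the detector: a normalized
# T x B matrix per recording, its binary song label, the four cyclic
# temporal covariates, and bookkeeping (origin file, augmentation flag)
# used to keep augmented copies out of validation and test splits.

#' Assemble labelled examples from features and a labels table
#'
#' @param features Named list of feature matrices (names are file ids), in
#'   dB (un-normalized) or already normalized.
#' @param labels Labels data frame with `file_id`, `start_datetime` and
#'   `label` columns (see [read_labels()]).
#' @param normalizer Optional [fit_normalizer()] result applied to every
#'   matrix.
#' @return A `song_examples` object: list with `x` (list of matrices),
#'   `y` (integer 0/1), `covariates` (n x 4 matrix), `file_id`,
#'   `augmented` (logical) and `normalized` (flag).
#' @export
as_examples <- function(features, labels, normalizer = NULL) {
  if (is.null(names(features)))
    stop("'features' must be a named list (names = file ids)", call. = FALSE)
  miss <- setdiff(labels$file_id, names(features))
  if (length(miss) > 0L)
    stop("features missing for file(s): ", paste(utils::head(miss, 3), collapse = ", "),
         call. = FALSE)
  x <- features[labels$file_id]
  if (!is.null(normalizer)) x <- lapply(x, apply_normalizer, norm = normalizer)
  structure(list(x = x,
                 y = as.integer(labels$label),
                 covariates = temporal_covariates(labels$start_datetime),
                 file_id = labels$file_id,
                 augmented = rep(FALSE, nrow(labels)),
                 normalized = !is.null(normalizer)),
            class = "song_examples")
}

#' @export
print.song_examples <- function(x, ...) {
  cat(sprintf("<song_examples> %d examples (%d positive, %d augmented), %s\n",
              length(x$y), sum(x$y), sum(x$augmented),
              if (isTRUE(x$normalized)) "normalized" else "raw dB"))
  invisible(x)
}

#' @export
length.song_examples <- function(x) length(x$y)

#' Subset labelled examples
#'
#' @param examples A `song_examples` object.
#' @param idx Integer or logical index.
#' @return A `song_examples` with the selected examples.
#' @export
subset_examples <- function(examples, idx) {
  structure(list(x = examples$x[idx], y = examples$y[idx],
                 covariates = examples$covariates[idx, , drop = FALSE],
                 file_id = examples$file_id[idx],
                 augmented = examples$augmented[idx],
                 normalized = examples$normalized),
            class = "song_examples")
}

# stack examples into dense arrays for the network
examples_arrays <- function(examples) {
  n <- length(examples$y)
  flat <- vapply(examples$x, function(m) as.vector(unclass(m)),
                 numeric(length(examples$x[[1L]])))
  list(X = t(flat), cov = examples$covariates, y = as.numeric(examples$y),
       shape = dim(examples$x[[1L]]))
}
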