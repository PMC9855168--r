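# Per-band quantile normalization to [0, 1]. Values in the tails of a
# band's training distribution are truncated to 0 and 1; the rest are
# rescaled linearly. Thresholds are fit on training data only and travel
# with the trained model so that inference never re-estimates them.

#' Fit per-band quantile normalization thresholds
#'
#' For each retained band, the `(q_lo, q_hi)` empirical quantiles over all
#' training cells of that band become the truncation thresholds `(lo, hi)`.
#'
#' @param matrices A `feature_matrix`, or a list of them (all sharing one
#'   band set).
#' @param q_lo,q_hi Quantile probabilities, `0 <= q_lo < q_hi <= 1`
#'   (defaults 0.01 and 0.99).
#' @return A `song_normalizer`: list with `lo`, `hi` (dB per band),
#'   `q_lo`, `q_hi`, `band_indices`, `n_matrices`, `n_cells`.
#' @export
fit_normalizer <- function(matrices, q_lo = 0.01, q_hi = 0.99) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  if (!is.list(matrices) || length(matrices) == 0L)
    stop("'matrices' must be a nonempty list of feature matrices", call. = FALSE)
  if (!(q_lo >= 0 && q_lo < q_hi && q_hi <= 1))
    stop("need 0 <= q_lo < q_hi <= 1", call. = FALSE)
  B <- ncol(matrices[[1L]])
  cn <- colnames(matrices[[1L]])
  for (m in matrices)
    if (ncol(m) != B) stop("all matrices must share one band set", call. = FALSE)
  stacked <- do.call(rbind, lapply(matrices, unclass))
  lo <- unname(apply(stacked, 2, stats::quantile, probs = q_lo, names = FALSE))
  hi <- unname(apply(stacked, 2, stats::quantile, probs = q_hi, names = FALSE))
  idx <- if (!is.null(cn)) as.integer(sub("^band_", "", cn)) else seq_len(B)
  structure(list(lo = lo, hi = hi, q_lo = q_lo, q_hi = q_hi,
                 band_indices = idx, n_matrices = length(matrices),
                 n_cells = nrow(stacked)),
            class = "song_normalizer")
}

#' @export
print.song_normalizer <- function(x, ...) {
  cat(sprintf("<song_normalizer> %d bands, quantiles (%g, %g), fit on %d matrices (%d cells/band)\n",
              length(x$lo), x$q_lo, x$q_hi, x$n_matrices, x$n_cells))
  invisible(x)
}

#' Apply quantile normalization to a feature matrix
#'
#' Cells at or below the band's `lo` threshold map to 0, cells at or above
#' `hi` map to 1, and the rest map linearly onto `(0, 1)`. A degenerate band
#' (`lo == hi`, e.g. a constant band) maps to 0.5 everywhere.
#'
#' @param fm A `feature_matrix` (dB) whose band set matches the normalizer.
#' @param norm A `song_normalizer` from [fit_normalizer()].
#' @return A matrix of the same shape with all values in `[0, 1]`; the
#'   `normalized` attribute is set.
#' @export
apply_normalizer <- function(fm, norm) {
  if (!inherits(norm, "song_normalizer"))
    stop("'norm' must be a song_normalizer", call. = FALSE)
  if (ncol(fm) != length(norm$lo))
    stop("band set mismatch: matrix has ", ncol(fm), " bands, normalizer ",
         length(norm$lo), call. = FALSE)
  cn <- colnames(fm)
  if (!is.null(cn)) {
    idx <- as.integer(sub("^band_", "", cn))
    if (!all(idx == norm$band_indices))
      stop("band set mismatch: matrix bands differ from normalizer bands",
           call. = FALSE)
  }
  lo <- matrix(norm$lo, nrow(fm), ncol(fm), byrow = TRUE)
  hi <- matrix(norm$hi, nrow(fm), ncol(fm), byrow = TRUE)
  span <- hi - lo
  out <- (unclass(fm) - lo) / ifelse(span > 0, span, 1)
  out[span == 0] <- 0.5
  out <- pmin(pmax(out, 0), 1)
  dim(out) <- dim(fm)
  dimnames(out) <- dimnames(fm)
  attrs <- attributes(fm)
  for (a in setdiff(names(attrs), c("dim", "dimnames", "class")))
    attr(out, a) <- attrs[[a]]
  class(out) <- class(fm)
  attr(out, "normalized") <- TRUE
  out
}
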