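# Slice-and-shuffle augmentation. A song-bearing T x B matrix is cut into
# equal time slices (a 30 x 18 matrix yields six 5 x 18 portions, each
# covering 100 s) which are randomly rearranged into a novel matrix. The
# frequency axis is untouched, so per-band value multisets are preserved;
# a slice is wide enough to contain a song or a recognisable portion of
# one, so the song label is preserved too. Augmented copies of positives
# are appended to a training set until half of it is positive.

#' Shuffle the time slices of a feature matrix
#'
#' @param m A T x B matrix (normalized features); `T` must be divisible by
#'   `slice_len`.
#' @param slice_len Rows per slice (default 5, i.e. 100 s of 20-s
#'   intervals).
#' @param perm Optional explicit permutation of the slices (default: drawn
#'   uniformly over all orders, identity included).
#' @param seed Optional seed.
#' @return A matrix of the same shape whose time slices are `perm` of the
#'   input's, with the `augmented` attribute set.
#' @export
slice_shuffle <- function(m, slice_len = 5L, perm = NULL, seed = NULL) {
  slice_len <- as.integer(slice_len)
  T_ <- nrow(m)
  if (T_ %% slice_len != 0L)
    stop("matrix has ", T_, " rows, not divisible by slice_len = ", slice_len,
         "; pad or crop to a multiple first", call. = FALSE)
  n_slices <- T_ %/% slice_len
  run <- function() {
    p <- if (is.null(perm)) sample.int(n_slices) else as.integer(perm)
    if (length(p) != n_slices || !setequal(p, seq_len(n_slices)))
      stop("'perm' must be a permutation of 1..", n_slices, call. = FALSE)
    rows <- as.vector(vapply(p, function(s) (s - 1L) * slice_len + seq_len(slice_len),
                             integer(slice_len)))
    out <- m[rows, , drop = FALSE]
    attrs <- attributes(m)
    for (a in setdiff(names(attrs), c("dim", "dimnames", "class")))
      attr(out, a) <- attrs[[a]]
    class(out) <- class(m)
    attr(out, "augmented") <- TRUE
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Balance a training set by augmenting positive examples
#'
#' Appends slice-shuffled variants of the song-bearing (positive) examples
#' -- cycling through them, drawing a fresh permutation each time -- until
#' positives equal negatives, i.e. half the set is positive. Negatives are
#' never modified. Intended for training splits only; validation and test
#' sets keep their natural class balance.
#'
#' @param examples A `song_examples` object (see [as_examples()]).
#' @param slice_len Rows per slice (default 5).
#' @param seed Optional seed for the permutations and cycling order.
#' @return A `song_examples` with appended augmented positives
#'   (`augmented` flag set; file ids suffixed `#augN`). Returned unchanged
#'   if positives already equal or outnumber negatives.
#' @export
balance_examples <- function(examples, slice_len = 5L, seed = NULL) {
  y <- examples$y
  pos <- which(y == 1L)
  if (length(pos) == 0L)
    stop("no positive examples: class balance unattainable", call. = FALSE)
  n_add <- sum(y == 0L) - length(pos)
  if (n_add <= 0L) return(examples)
  run <- function() {
    src <- rep(pos, length.out = n_add)
    new_x <- vector("list", n_add)
    for (i in seq_len(n_add))
      new_x[[i]] <- slice_shuffle(examples$x[[src[i]]], slice_len = slice_len)
    names(new_x) <- NULL
    structure(list(
      x = c(examples$x, new_x),
      y = c(y, rep(1L, n_add)),
      covariates = rbind(examples$covariates,
                         examples$covariates[src, , drop = FALSE]),
      file_id = c(examples$file_id,
                  paste0(examples$file_id[src], "#aug", seq_len(n_add))),
      augmented = c(examples$augmented, rep(TRUE, n_add)),
      normalized = examples$normalized),
      class = "song_examples")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
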