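# Third-octave band energy features: each recording is reduced to a
# T x B matrix (T consecutive 20-s intervals, B retained bands), the unit
# the detector consumes. A 600-s file at the default settings becomes a
# 30 x 18 matrix, several thousand times smaller than the waveform.

#' Welch-averaged power spectrum of one interval
#'
#' Averaged periodograms over Hann-windowed segments with 50% overlap.
#' Scaling is chosen so that the sum of the two-sided spectrum over all
#' frequency bins estimates the mean-square (power) of the signal, which
#' makes band powers directly comparable and bounded by total frame power.
#'
#' @param x Numeric samples of one interval.
#' @param rate Sample rate (Hz).
#' @param segment Segment length in samples (default 8192).
#' @return List with `freq` (Hz, one-sided) and `power` (per-bin power,
#'   one-sided with interior bins doubled).
#' @keywords internal
welch_power <- function(x, rate, segment = 8192L) {
  n <- length(x)
  segment <- min(as.integer(segment), n)
  hop <- max(1L, segment %/% 2L)
  starts <- seq(1L, n - segment + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(segment) - 1L) / segment)  # periodic Hann
  idx <- outer(seq_len(segment) - 1L, starts, "+")
  segs <- matrix(x[idx], nrow = segment) * w
  spec <- stats::mvfft(segs)
  p2 <- rowMeans(Mod(spec)^2) / (segment * sum(w^2))  # two-sided, sums to ~mean(x^2)
  half <- segment %/% 2L + 1L
  pow <- p2[seq_len(half)]
  if (segment > 2L) pow[2:(half - 1L)] <- 2 * pow[2:(half - 1L)]
  list(freq = (seq_len(half) - 1L) * rate / segment, power = pow)
}

#' Extract a time-by-band matrix of third-octave band energies
#'
#' Splits a mono waveform into consecutive non-overlapping intervals
#' (default 20 s; a trailing partial interval is discarded), estimates the
#' power spectrum of each interval by Welch-averaged periodograms, sums
#' power within each retained one-third-octave band, and reports
#' `10 * log10(power + eps)` in dB.
#'
#' Bands whose upper edge exceeds the Nyquist frequency cannot be observed
#' at the given sample rate: they are set to the dB floor, recorded in the
#' `masked_bands` attribute, and a warning is raised.
#'
#' @param samples Mono waveform (numeric vector) or the list returned by
#'   [read_wav()].
#' @param rate Sample rate in Hz (ignored if `samples` came from
#'   [read_wav()]).
#' @param interval_s Interval length in seconds (default 20).
#' @param bands A [band_set()] (default bands 26..43).
#' @param eps Power floor added before the log (default 1e-12).
#' @param segment Welch segment length in samples.
#' @return A `feature_matrix`: numeric matrix with one row per interval and
#'   one column per band (dB), with attributes `interval_s`, `band_set`,
#'   `rate`, `eps` and `masked_bands`.
#' @examples
#' x <- sin(2 * pi * 1000 * seq(0, 40, by = 1 / 8000))
#' fm <- extract_features(x, rate = 8000, interval_s = 20)
#' dim(fm)  # 2 intervals x 18 bands
#' @export
extract_features <- function(samples, rate = NULL, interval_s = 20,
                             bands = band_set(), eps = 1e-12,
                             segment = 8192L) {
  if (is.list(samples) && !is.null(samples$samples)) {
    rate <- samples$rate
    samples <- samples$samples
  }
  if (is.null(rate)) stop("'rate' must be given", call. = FALSE)
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("'samples' must be a nonempty numeric vector (mono)", call. = FALSE)
  if (is.matrix(samples))
    stop("multi-channel input not supported: down-mix to mono first", call. = FALSE)
  n_int <- floor(length(samples) / (interval_s * rate))
  if (n_int < 1L)
    stop("waveform shorter than one interval (", interval_s, " s)", call. = FALSE)
  nyq <- rate / 2
  masked <- bands$band_indices[bands$edge_frequencies[, "upper"] > nyq]
  if (length(masked) > 0L)
    warning("sample rate ", rate, " Hz cannot resolve band(s) ",
            paste(masked, collapse = ", "), "; set to the dB floor",
            call. = FALSE)
  nper <- as.integer(interval_s * rate)
  B <- length(bands$band_indices)
  vals <- matrix(10 * log10(eps), nrow = n_int, ncol = B)
  # bands tile the axis: assign bins to bands with one findInterval
  breaks <- c(bands$edge_frequencies[, "lower"],
              bands$edge_frequencies[B, "upper"])
  for (i in seq_len(n_int)) {
    seg <- samples[((i - 1L) * nper + 1L):(i * nper)]
    wp <- welch_power(seg, rate, segment)
    bin_band <- findInterval(wp$freq, breaks, left.open = FALSE)
    keep <- bin_band >= 1L & bin_band <= B & wp$freq < nyq
    if (any(keep)) {
      bp <- rowsum(wp$power[keep], group = bin_band[keep])
      vals[i, as.integer(rownames(bp))] <- 10 * log10(bp[, 1] + eps)
    }
  }
  if (length(masked) > 0L)
    vals[, bands$band_indices %in% masked] <- 10 * log10(eps)
  dimnames(vals) <- list(NULL, paste0("band_", bands$band_indices))
  structure(vals,
            class = c("feature_matrix", "matrix", "array"),
            interval_s = interval_s, band_set = bands, rate = rate,
            eps = eps, masked_bands = masked)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d intervals x %d bands (%g-s intervals, bands %d..%d)\n",
              nrow(x), ncol(x), attr(x, "interval_s"),
              min(attr(x, "band_set")$band_indices),
              max(attr(x, "band_set")$band_indices)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), , drop = FALSE], digits = 4)
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}

#' Export a feature matrix as delimited text
#'
#' One row per interval, one column per band, plus an `interval` index
#' column; readable by any spreadsheet or data tool.
#'
#' @param fm A `feature_matrix` (or plain matrix with band columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(fm, path) {
  df <- data.frame(interval = seq_len(nrow(fm)), unclass(fm)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#'
#' @param path CSV path.
#' @param interval_s Interval length to attach (default 20).
#' @return A `feature_matrix`.
#' @export
read_features <- function(path, interval_s = 20) {
  df <- utils::read.csv(path, check.names = FALSE)
  bcols <- grep("^band_", names(df), value = TRUE)
  idx <- as.integer(sub("^band_", "", bcols))
  m <- as.matrix(df[, bcols, drop = FALSE])
  dimnames(m) <- list(NULL, bcols)
  structure(m, class = c("feature_matrix", "matrix", "array"),
            interval_s = interval_s, band_set = band_set(idx),
            rate = NA_real_, eps = 1e-12, masked_bands = integer(0))
}
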