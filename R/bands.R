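#' One-third-octave band centre frequency
#'
#' Centre frequency of band `n` in the base-ten one-third-octave system,
#' in which band `n` is centred at `10^(n/10)` Hz, so band 30 is the 1 kHz
#' reference band and successive bands are spaced by a factor of
#' `10^(1/10)` (~ `2^(1/3)`).
#'
#' @param n Integer band index (vectorised).
#' @return Centre frequency in Hz.
#' @examples
#' band_center(30)   # 1000 Hz
#' band_center(26:43)
#' @export
band_center <- function(n) {
  if (!is.numeric(n) || any(!is.finite(n)) || any(n != round(n)))
    stop("band index 'n' must be integer-valued", call. = FALSE)
  10^(n / 10)
}

#' One-third-octave band edge frequencies
#'
#' Lower and upper edges of band `n`: `center * 10^(-1/20)` and
#' `center * 10^(1/20)`. Adjacent bands tile the frequency axis without
#' gaps (the upper edge of band `n` equals the lower edge of band `n + 1`),
#' and the geometric mean of the edges is the centre frequency.
#'
#' @param n Integer band index (vectorised).
#' @return A two-column matrix with columns `lower` and `upper`, one row per
#'   band, in Hz.
#' @examples
#' band_edges(30)  # c(891.25, 1122.02) Hz
#' @export
band_edges <- function(n) {
  ctr <- band_center(n)
  cbind(lower = ctr * 10^(-1 / 20), upper = ctr * 10^(1 / 20))
}

#' Define a retained set of one-third-octave bands
#'
#' The default set keeps the 18 bands from the 26th to the 43rd
#' (~398 Hz to ~20 kHz), spanning from below the fundamental frequency of
#' indri song phrases up to the presumed upper bound of the species'
#' hearing range.
#'
#' @param band_indices Integer band indices, strictly increasing.
#' @return An object of class `band_set`: a list with `band_indices`,
#'   `center_frequencies` (Hz) and `edge_frequencies` (two-column matrix, Hz).
#' @examples
#' bs <- band_set()
#' length(bs$band_indices)  # 18
#' @export
band_set <- function(band_indices = 26:43) {
  if (length(band_indices) < 1L)
    stop("'band_indices' must be nonempty", call. = FALSE)
  if (any(diff(band_indices) <= 0))
    stop("'band_indices' must be strictly increasing", call. = FALSE)
  ctr <- band_center(band_indices)
  out <- list(
    band_indices = as.integer(band_indices),
    center_frequencies = ctr,
    edge_frequencies = band_edges(band_indices)
  )
  class(out) <- "band_set"
  out
}

#' @export
print.band_set <- function(x, ...) {
  cat(sprintf("<band_set> %d one-third-octave bands (%d..%d), %.1f Hz .. %.1f Hz\n",
              length(x$band_indices), min(x$band_indices), max(x$band_indices),
              x$edge_frequencies[1, "lower"],
              x$edge_frequencies[nrow(x$edge_frequencies), "upper"]))
  invisible(x)
}

#' Band index whose edges contain a frequency
#'
#' Inverse of [band_center()]: maps a frequency to the index of the
#' one-third-octave band containing it (`round(10 * log10(f))`).
#'
#' @param freq Frequency in Hz, positive.
#' @return Integer band index.
#' @export
band_of <- function(freq) {
  if (any(freq <= 0)) stop("'freq' must be positive", call. = FALSE)
  as.integer(round(10 * log10(freq)))
}
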