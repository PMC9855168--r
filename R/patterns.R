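# Diel and seasonal calling-activity distributions. "Probability" is the
# per-bin positive rate (positives / recordings in the bin), not a density
# normalized over bins -- which is why sparsely sampled weeks need the
# minimum-recordings exclusion rule.

new_activity_distribution <- function(axis, bins, excluded_recordings = 0L) {
  structure(list(axis = axis, bin_count = nrow(bins), bins = bins,
                 excluded_recordings = excluded_recordings),
            class = "activity_distribution")
}

#' @export
print.activity_distribution <- function(x, ...) {
  cat(sprintf("<activity_distribution> %s, %d bins, %d recordings (%d excluded)\n",
              x$axis, x$bin_count, sum(x$bins$n_recordings) + x$excluded_recordings,
              x$excluded_recordings))
  invisible(x)
}

#' Diel (24-h) song-activity distribution
#'
#' Bins detections by recording start time into 48 30-min bins (bin index
#' `floor((hour * 60 + minute) / 30)`, matching the recording schedule) and
#' reports the positive rate per bin. Every start time maps to exactly one
#' bin; there are no exclusions on the diel axis.
#'
#' @param detections Data frame with `start_datetime` (POSIXct) and
#'   `label` (0/1; predicted or manual).
#' @return An `activity_distribution` with a `bins` data frame:
#'   `bin_index` (0..47), `bin_label` (clock time), `n_recordings`,
#'   `n_positive`, `probability` (NA for unsampled bins), `excluded`.
#' @export
diel_distribution <- function(detections) {
  if (nrow(detections) == 0L) stop("empty detection table", call. = FALSE)
  lt <- as.POSIXlt(detections$start_datetime)
  bin <- (lt$hour * 60 + lt$min) %/% 30
  idx <- 0:47
  n <- tabulate(bin + 1L, nbins = 48L)
  npos <- vapply(idx, function(b) sum(detections$label[bin == b] == 1), 0)
  bins <- data.frame(bin_index = idx,
                     bin_label = sprintf("%02d:%02d", idx %/% 2, (idx %% 2) * 30),
                     n_recordings = n, n_positive = npos,
                     probability = ifelse(n > 0, npos / n, NA_real_),
                     excluded = FALSE, stringsAsFactors = FALSE)
  new_activity_distribution("diel", bins)
}

#' Seasonal (52-week) song-activity distribution
#'
#' Bins detections by week of year, `week = min(floor((day_of_year - 1) /
#' 7), 51)` (terminal clamping, so day 365/366 falls in week 51). Weeks
#' with fewer than `min_recordings` recordings are flagged "unsampled":
#' they carry no probability and their recordings are dropped from the
#' computation.
#'
#' @param detections Data frame with `start_datetime` and `label`.
#' @param min_recordings Exclusion threshold (default 250, ~40 h of
#'   10-min recordings); scale down for small synthetic runs.
#' @return An `activity_distribution` with `bins` (`bin_index` 0..51) and
#'   the count of excluded recordings.
#' @export
seasonal_distribution <- function(detections, min_recordings = 250L) {
  if (nrow(detections) == 0L) stop("empty detection table", call. = FALSE)
  lt <- as.POSIXlt(detections$start_datetime)
  week <- pmin(lt$yday %/% 7, 51)
  idx <- 0:51
  n <- tabulate(week + 1L, nbins = 52L)
  npos <- vapply(idx, function(w) sum(detections$label[week == w] == 1), 0)
  excl <- n < min_recordings
  bins <- data.frame(bin_index = idx, bin_label = paste0("week_", idx + 1L),
                     n_recordings = ifelse(excl, 0L, n),
                     n_positive = ifelse(excl, 0L, npos),
                     probability = ifelse(!excl & n > 0, npos / n, NA_real_),
                     excluded = excl, stringsAsFactors = FALSE)
  new_activity_distribution("seasonal", bins, excluded_recordings = sum(n[excl]))
}

#' Aggregate activity distributions across cross-validation folds
#'
#' Per bin, the mean and (sample) standard deviation of the fold
#' probabilities, over the folds in which the bin was sampled. A bin
#' excluded in any fold is reported as excluded, with the count of
#' contributing folds alongside.
#'
#' @param distributions List of `activity_distribution`s sharing one axis
#'   and bin count (e.g. one per fold test set).
#' @return An `activity_distribution` whose `bins` gain `fold_mean`,
#'   `fold_sd` and `n_folds` columns (`probability` is set to the fold
#'   mean).
#' @export
aggregate_folds <- function(distributions) {
  if (length(distributions) == 0L) stop("no distributions", call. = FALSE)
  axes <- vapply(distributions, `[[`, "", "axis")
  if (length(unique(axes)) != 1L)
    stop("cannot aggregate distributions with mixed axes: ",
         paste(unique(axes), collapse = ", "), call. = FALSE)
  nb <- vapply(distributions, `[[`, 0L, "bin_count")
  if (length(unique(nb)) != 1L) stop("bin counts differ", call. = FALSE)
  nbin <- nb[1L]
  probs <- vapply(distributions, function(d) d$bins$probability, numeric(nbin))
  excl <- vapply(distributions, function(d) as.logical(d$bins$excluded),
                 logical(nbin))
  nrec <- vapply(distributions, function(d) as.numeric(d$bins$n_recordings),
                 numeric(nbin))
  npos <- vapply(distributions, function(d) as.numeric(d$bins$n_positive),
                 numeric(nbin))
  contributing <- rowSums(!is.na(probs))
  bins <- distributions[[1L]]$bins
  bins$n_recordings <- rowSums(nrec)
  bins$n_positive <- rowSums(npos)
  bins$fold_mean <- ifelse(contributing > 0, rowMeans(probs, na.rm = TRUE),
                           NA_real_)
  bins$fold_sd <- apply(probs, 1, function(p)
    if (sum(!is.na(p)) >= 2) stats::sd(p, na.rm = TRUE) else NA_real_)
  bins$n_folds <- contributing
  bins$excluded <- rowSums(excl) > 0
  bins$probability <- bins$fold_mean
  out <- new_activity_distribution(axes[1L], bins,
                                   excluded_recordings =
                                     sum(vapply(distributions, `[[`, 0L,
                                                "excluded_recordings")))
  out$n_distributions <- length(distributions)
  out
}

#' Export an activity distribution as delimited text
#'
#' @param dist An `activity_distribution`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(dist, path) {
  utils::write.csv(dist$bins, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
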