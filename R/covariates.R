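# Cyclic temporal covariates. Hour of day and week of year are periodic:
# encoding each on the unit circle (sine and cosine of its phase angle)
# preserves the adjacency of 23:30 and 00:00, and of week 51 and week 0,
# which a raw linear encoding would break.

#' Encode a periodic value on the unit circle
#'
#' Maps `value` to the angle `2 * pi * value / period` and returns its sine
#' and cosine. The two components always satisfy `sin^2 + cos^2 = 1`, and
#' the encoding is continuous across the period boundary.
#'
#' @param value Numeric value(s) of the periodic quantity.
#' @param period The period (e.g. 24 for hours, 52 for weeks); positive.
#' @return A matrix with columns `sin` and `cos`, one row per value.
#' @examples
#' encode_cyclic(0, 24)   # (0, 1)
#' encode_cyclic(6, 24)   # (1, 0)
#' @export
encode_cyclic <- function(value, period) {
  if (period <= 0) stop("'period' must be positive", call. = FALSE)
  angle <- 2 * pi * value / period
  cbind(sin = sin(angle), cos = cos(angle))
}

#' Four cyclic temporal covariates of a recording start
#'
#' Hour of day (hour + minute/60, period 24) and week of year
#' (`min(floor((day_of_year - 1) / 7), 51)`, period 52 -- the same 52-week
#' binning the seasonal activity distribution uses), each sine/cosine
#' encoded.
#'
#' @param start_datetime POSIXct vector (recorder local time).
#' @return Matrix with columns `hour_sin`, `hour_cos`, `week_sin`,
#'   `week_cos`, one row per datetime.
#' @export
temporal_covariates <- function(start_datetime) {
  lt <- as.POSIXlt(start_datetime)
  hour <- lt$hour + lt$min / 60
  week <- pmin(lt$yday %/% 7, 51)
  h <- encode_cyclic(hour, 24)
  w <- encode_cyclic(week, 52)
  out <- cbind(h[, "sin"], h[, "cos"], w[, "sin"], w[, "cos"])
  colnames(out) <- c("hour_sin", "hour_cos", "week_sin", "week_cos")
  out
}
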