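# Tabular I/O. All tables are plain CSV with a header; datetimes are
# ISO-8601 without timezone and are interpreted as recorder local time
# (field deployments log naive local clock time; no timezone math is ever
# applied). Writing is canonical, so a read/write round trip is lossless
# byte-for-byte.

LABELS_COLUMNS <- c("file_id", "site_id", "recorder_type", "start_datetime",
                    "duration_s", "label")

parse_datetime <- function(x) {
  clean <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(strptime(clean, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  short <- is.na(out)
  if (any(short))
    out[short] <- as.POSIXct(strptime(clean[short], "%Y-%m-%d %H:%M",
                                      tz = "UTC"))
  out
}

format_datetime <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' Read a labels table
#'
#' Expected schema: `file_id,site_id,recorder_type,start_datetime,
#' duration_s,label` with ISO-8601 datetimes. Malformed rows are reported
#' with their line numbers. Datetimes carry no timezone and are taken as
#' recorder local time.
#'
#' @param path CSV path.
#' @return Data frame with parsed `start_datetime` (POSIXct) and integer
#'   `label`.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  missing <- setdiff(LABELS_COLUMNS, names(df))
  if (length(missing) > 0L)
    stop("labels table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad_label <- !(df$label %in% c("0", "1"))
  if (any(bad_label))
    stop("invalid label (must be 0 or 1) at line(s): ",
         paste(utils::head(line[bad_label], 5), collapse = ", "), call. = FALSE)
  dt <- suppressWarnings(parse_datetime(df$start_datetime))
  if (anyNA(dt))
    stop("unparseable start_datetime at line(s): ",
         paste(utils::head(line[is.na(dt)], 5), collapse = ", "), call. = FALSE)
  dur <- suppressWarnings(as.numeric(df$duration_s))
  if (anyNA(dur) || any(dur <= 0))
    stop("invalid duration_s at line(s): ",
         paste(utils::head(line[is.na(dur) | dur <= 0], 5), collapse = ", "),
         call. = FALSE)
  data.frame(file_id = df$file_id, site_id = df$site_id,
             recorder_type = df$recorder_type, start_datetime = dt,
             duration_s = dur, label = as.integer(df$label),
             stringsAsFactors = FALSE)
}

#' Write a labels table
#'
#' @param labels Data frame in the [read_labels()] schema.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  out <- data.frame(file_id = labels$file_id, site_id = labels$site_id,
                    recorder_type = labels$recorder_type,
                    start_datetime = format_datetime(labels$start_datetime),
                    duration_s = labels$duration_s, label = labels$label,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-file predictions
#'
#' @param predictions Data frame with `file_id`, `probability`, `label`
#'   (the output of [predict_detector()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.csv(predictions[, c("file_id", "probability", "label")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read predictions written by [write_predictions()]
#'
#' @param path CSV path.
#' @return Data frame with `file_id`, `probability`, `label`.
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("file_id", "probability", "label"), names(df))
  if (length(missing) > 0L)
    stop("predictions table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df$label <- as.integer(df$label)
  df
}
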