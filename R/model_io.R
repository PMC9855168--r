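# Model bundle: a single structured-text (JSON) file holding a versioned
# header, the full configuration, every weight tensor as a named array
# with its dimensions, the freeze state, and the attached normalizer, so
# a trained detector travels as one self-contained artifact.

BUNDLE_FORMAT <- "songsieve-detector/1"

#' Save a detector to a single-file text bundle
#'
#' @param model A `detector_model`.
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
save_detector <- function(model, path) {
  ser_w <- lapply(model$weights, function(w)
    list(dim = if (is.null(dim(w))) length(w) else dim(w),
         data = as.numeric(w)))
  bundle <- list(
    format = BUNDLE_FORMAT,
    package_version = as.character(utils::packageVersion("songsieve")),
    config = unclass(model$config),
    input_shape = model$input_shape,
    frozen = model$frozen,
    weights = ser_w,
    normalizer = if (!is.null(model$normalizer)) unclass(model$normalizer),
    provenance = model$provenance
  )
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' Load a detector bundle written by [save_detector()]
#'
#' Rebuilds the layer stack from the stored configuration and restores
#' weights, freeze state and normalizer.
#'
#' @param path Bundle path.
#' @return A `detector_model`.
#' @export
load_detector <- function(path) {
  bundle <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE,
                               simplifyMatrix = FALSE)
  if (!identical(bundle$format, BUNDLE_FORMAT))
    stop("unrecognized model bundle format: ", bundle$format, call. = FALSE)
  cfgl <- bundle$config
  conv <- lapply(cfgl$conv_layers, function(cl)
    list(filters = as.integer(cl$filters), kernel = as.integer(cl$kernel),
         stride = as.integer(cl$stride)))
  cfg <- detector_config(conv_layers = conv,
                         dense_sizes = as.integer(cfgl$dense_sizes),
                         dropout_rate = cfgl$dropout_rate,
                         learning_rate = cfgl$learning_rate,
                         batch_size = cfgl$batch_size,
                         epochs = cfgl$epochs,
                         decision_threshold = cfgl$decision_threshold,
                         seed = cfgl$seed)
  model <- build_detector(cfg, input_shape = as.integer(bundle$input_shape))
  for (k in names(bundle$weights)) {
    w <- bundle$weights[[k]]
    arr <- array(as.numeric(w$data), dim = as.integer(w$dim))
    if (length(w$dim) == 1L) arr <- as.numeric(arr)
    model$weights[[k]] <- arr
  }
  model$frozen <- as.character(bundle$frozen %||% character(0))
  model$trainable_parameter_count <- count_parameters(model)$trainable
  if (!is.null(bundle$normalizer)) {
    nm <- bundle$normalizer
    model$normalizer <- structure(
      list(lo = as.numeric(nm$lo), hi = as.numeric(nm$hi),
           q_lo = nm$q_lo, q_hi = nm$q_hi,
           band_indices = as.integer(nm$band_indices),
           n_matrices = nm$n_matrices, n_cells = nm$n_cells),
      class = "song_normalizer")
  }
  model$provenance <- bundle$provenance
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
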