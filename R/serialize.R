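# Structured-text (JSON) model persistence: layer sizes, all weights, the
# training configuration, the fitted scaler and the selected band.

MODEL_FORMAT_VERSION <- 1L

#' Save a trained detector to a JSON file
#'
#' Stores the encoder stack, softmax head, training configuration, feature
#' scaler and selected frequency band with full numeric precision and a
#' format-version field; [load_model()] round-trips deterministically.
#'
#' @param net a `stacked_net` (softmax head optional).
#' @param path output path.
#' @param config optional [ae_config()] stored alongside.
#' @param scaler optional [fit_scaler()] result.
#' @param band optional selected [band()].
#' @return `path`, invisibly.
#' @export
save_model <- function(net, path, config = NULL, scaler = NULL, band = NULL) {
  stopifnot(inherits(net, "stacked_net"))
  obj <- list(
    format_version = MODEL_FORMAT_VERSION,
    layer_sizes = net$layer_sizes,
    classes = net$classes,
    layers = lapply(net$layers, function(l) {
      list(W = as.vector(l$W), dim = dim(l$W), b = l$b)
    }),
    softmax = if (!is.null(net$softmax)) {
      list(W = as.vector(net$softmax$W), dim = dim(net$softmax$W),
           b = net$softmax$b)
    },
    config = if (!is.null(config)) unclass(config),
    scaler = if (!is.null(scaler)) unclass(scaler),
    band = if (!is.null(band)) unclass(band)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a detector saved with [save_model()]
#'
#' @param path JSON file written by [save_model()].
#' @return list with `net` (`stacked_net`) and, when present, `config`,
#'   `scaler`, `band`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version > MODEL_FORMAT_VERSION) {
    stop_rsae("unsupported model format version in ", path)
  }
  rebuild <- function(l) list(W = matrix(l$W, l$dim[1L], l$dim[2L]), b = l$b)
  layers <- if (is.data.frame(obj$layers)) {
    lapply(seq_len(nrow(obj$layers)), function(i) rebuild(lapply(obj$layers, `[[`, i)))
  } else {
    lapply(obj$layers, rebuild)
  }
  softmax <- if (!is.null(obj$softmax)) rebuild(obj$softmax)
  net <- new_stacked_net(layers, softmax, as.integer(obj$layer_sizes))
  out <- list(net = net)
  if (!is.null(obj$config)) {
    out$config <- structure(obj$config, class = "ae_config")
  }
  if (!is.null(obj$scaler)) {
    out$scaler <- structure(list(offset = obj$scaler$offset,
                                 range = obj$scaler$range),
                            class = "feature_scaler")
  }
  if (!is.null(obj$band)) {
    out$band <- structure(list(name = obj$band$name, lb = obj$band$lb,
                               ub = obj$band$ub), class = "freq_band")
  }
  out
}
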