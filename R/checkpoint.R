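#' Save and load model checkpoints
#'
#' A checkpoint is a single serialized container with the network weights
#' (and, for distilled students, the adapter bank) plus a JSON sidecar
#' carrying the model specification and training configuration so runs can be
#' reproduced and validated without deserializing the weights.
#'
#' @param object a `ggenet_fit`, `ggenet_distill_fit`, or `ggenet_network`.
#' @param path checkpoint file path (conventionally `.rds`); the sidecar is
#'   written to `<path>.json`.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   the restored object.
#' @export
save_checkpoint <- function(object, path) {
  spec <- if (inherits(object, "ggenet_network")) object$spec else object$spec
  saveRDS(object, path)
  sidecar <- list(class = class(object)[1],
                  spec = unclass(spec),
                  config = if (!inherits(object, "ggenet_network")) object$config,
                  classes = if (!inherits(object, "ggenet_network")) object$classes,
                  parameters = count_parameters(
                    if (inherits(object, "ggenet_network")) object else object$network))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  readRDS(path)
}
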