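#' Save / load a fitted counterfactual model
#'
#' Writes a trained model to a directory as text: `metadata.json` with the
#' learner kind, seed and hyperparameters, and `model.json` holding the full
#' object (coefficients, baselines, tree structures, network weights) in
#' jsonlite's lossless R serialization format.
#'
#' @param model a `svt_cfmodel`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "svt_cfmodel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(kind = model$kind, seed = model$seed,
               grid_length = length(model$grid),
               package = "survite", format = 1L)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(jsonlite::serializeJSON(model, digits = NA),
             file.path(dir, "model.json"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  f <- file.path(dir, "model.json")
  if (!file.exists(f)) stop("load_model: no model.json in ", dir)
  model <- jsonlite::unserializeJSON(paste(readLines(f), collapse = "\n"))
  if (!inherits(model, "svt_cfmodel")) stop("load_model: not a svt_cfmodel")
  model
}
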