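#' Save a trained model as a JSON checkpoint
#'
#' Single text file holding the model configuration, the initialization seed,
#' vocabulary metadata and every parameter array (shape + values at full
#' double precision), so a reloaded model reproduces predictions exactly.
#'
#' @param fit A fit from \code{\link{train_model}} (needs \code{params} and
#'   \code{model_cfg}).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
save_checkpoint <- function(fit, path) {
  params <- fit$params
  obj <- list(
    format = "backsplicer-checkpoint-v1",
    config = unclass(fit$model_cfg),
    seed = attr(params, "seed"),
    vocabulary = list(K = fit$model_cfg$K, size = 4L^fit$model_cfg$K + 1L,
                      pad_index = 4L^fit$model_cfg$K, order = "ACGT base-4"),
    params = lapply(unclass(params), function(w) {
      list(dim = if (is.null(dim(w))) length(w) else dim(w), data = as.vector(w))
    })
  )
  # digits = I(17) guarantees an exact double round-trip (digits = NA does not)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17)), path, useBytes = TRUE)
  invisible(path)
}

#' Load a JSON checkpoint
#'
#' @param path Checkpoint path written by \code{\link{save_checkpoint}}.
#' @return A list with \code{params} and \code{model_cfg}, usable wherever a
#'   \code{\link{train_model}} fit is accepted.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "backsplicer-checkpoint-v1"))
    stop("not a recognized checkpoint file: ", path)
  cfg <- do.call(model_config, obj$config)
  params <- lapply(obj$params, function(p) {
    d <- as.integer(p$dim)
    if (length(d) == 2L) matrix(p$data, d[1L], d[2L])
    else if (length(d) == 1L && d == 1L) as.numeric(p$data)
    else as.numeric(p$data)
  })
  # scalar bias stays scalar
  params$head.bp <- as.numeric(params$head.bp)
  attr(params, "seed") <- obj$seed
  class(params) <- "model_params"
  attr(params, "config") <- cfg
  list(params = params, model_cfg = cfg)
}
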