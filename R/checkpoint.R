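#' Save a trained checkpoint as JSON
#'
#' Serializes the parameter arrays (shape-tagged, full double precision),
#' the transformer configuration, the feature names the model was trained
#' on, and a version header, so that incompatible checkpoints fail loudly
#' at load or predict time. Plain text: checkpoints are diffable and
#' portable.
#'
#' @param checkpoint A checkpoint list from [trainModel()].
#' @param path Output path (conventionally \code{.json}).
#' @return Invisibly, \code{path}.
#' @seealso [loadCheckpoint()]
#' @export
saveCheckpoint <- function(checkpoint, path) {
  if (!identical(checkpoint$version, "graphema-checkpoint-1"))
    stop("not a checkpoint object")
  encode <- function(x) {
    if (is.list(x)) return(lapply(x, encode))
    list(.array = TRUE, dim = if (is.null(dim(x))) length(x) else dim(x),
         data = as.vector(x))
  }
  obj <- list(
    version = checkpoint$version,
    config = unclass(checkpoint$config),
    nodeFeatureNames = checkpoint$nodeFeatureNames,
    edgeFeatureNames = checkpoint$edgeFeatureNames,
    bestEpoch = checkpoint$bestEpoch,
    bestValLoss = checkpoint$bestValLoss,
    seed = checkpoint$seed,
    params = encode(checkpoint$params))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a checkpoint saved by [saveCheckpoint()]
#'
#' @param path Path to the JSON checkpoint.
#' @return A checkpoint list usable by [predictSubgraph()] and
#'   [predictPool()].
#' @export
loadCheckpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$version, "graphema-checkpoint-1"))
    stop("incompatible checkpoint (version header: ",
         if (is.null(obj$version)) "absent" else obj$version, ")")
  decode <- function(x) {
    if (is.list(x) && isTRUE(x$.array)) {
      v <- as.numeric(unlist(x$data))
      d <- as.integer(unlist(x$dim))
      if (length(d) > 1L) dim(v) <- d
      return(v)
    }
    if (is.list(x)) return(lapply(x, decode))
    x
  }
  cfg <- lapply(obj$config, unlist)
  config <- transformerConfig(cfg$nLayers, cfg$nHeads, cfg$dNode,
                              cfg$dEdge, cfg$dK, cfg$dropout, cfg$seed)
  list(version = obj$version,
       params = decode(obj$params),
       config = config,
       nodeFeatureNames = as.character(unlist(obj$nodeFeatureNames)),
       edgeFeatureNames = as.character(unlist(obj$edgeFeatureNames)),
       bestEpoch = unlist(obj$bestEpoch),
       bestValLoss = unlist(obj$bestValLoss),
       seed = unlist(obj$seed))
}
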