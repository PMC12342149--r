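#' Read a pairwise similarity matrix
#'
#' Reads a CSV/TSV file whose header row and first column both list decoy
#' identifiers in the same order, and returns a validated
#' [PairwiseMatrix-class]. Asymmetric input (pairwise TM-scores may be
#' normalized by either structure) is symmetrized as \eqn{(M + M^T)/2};
#' disagreement beyond \code{warnAsym} triggers a warning.
#'
#' @param path Path to the CSV/TSV file (delimiter auto-detected from the
#'   extension: \code{.tsv}/\code{.tab} use tab, anything else comma).
#' @param metricName Metric name; see [PairwiseMatrix-class].
#' @param warnAsym Asymmetry warning tolerance (default 0.05).
#' @return A [PairwiseMatrix-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(matrix(c(1, .7, .7, 1), 2,
#'           dimnames = list(c("a", "b"), c("a", "b"))), f)
#' readPairwiseMatrix(f, "tm")
#' @export
readPairwiseMatrix <- function(path, metricName, warnAsym = 0.05) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("pairwise matrix file needs an id column plus at least one value column")
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (nrow(vals) != ncol(vals))
    stop("non-square pairwise matrix: ", nrow(vals), " rows x ",
         ncol(vals), " value columns")
  if (anyDuplicated(ids))
    stop("duplicate decoy ids in pairwise matrix")
  if (!identical(colnames(vals), ids))
    stop("header ids and first-column ids disagree (order must match)")
  if (!is.numeric(vals) || anyNA(vals))
    stop("pairwise matrix contains non-numeric or NaN cells")
  if (metricName %in% .BOUNDED_METRICS &&
      (any(vals < 0) || any(vals > 1)))
    stop(metricName, " similarity values outside [0, 1]")
  PairwiseMatrix(metricName, ids, vals, warnAsym = warnAsym)
}

#' Write a pairwise similarity matrix
#'
#' Inverse of [readPairwiseMatrix()]: header row and first column carry the
#' decoy ids.
#'
#' @param x A [PairwiseMatrix-class].
#' @param path Output path (\code{.tsv}/\code{.tab} write tab-separated).
#' @return Invisibly, \code{path}.
#' @export
writePairwiseMatrix <- function(x, path) {
  stopifnot(is(x, "PairwiseMatrix"))
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- data.frame(decoy_id = x@ids, x@values, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a single-model score table
#'
#' Reads a two-column tab-separated file (\code{decoy_id}, score) with a
#' header row into a [ScoreTable-class].
#'
#' @param path Path to the TSV file.
#' @param scoreName Score name; see [ScoreTable-class].
#' @return A [ScoreTable-class].
#' @export
readScoreTable <- function(path, scoreName) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("score table needs two columns: decoy_id and score")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate decoy_id in score table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  raw <- df[[2L]]
  scores <- suppressWarnings(as.numeric(raw))
  bad <- !is.na(raw) & raw != "" & is.na(scores)
  if (any(bad))
    stop("non-numeric score for decoy ", paste(ids[bad], collapse = ", "))
  ScoreTable(scoreName, setNames(scores, ids))
}

#' Write a single-model score table
#'
#' @param x A [ScoreTable-class].
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeScoreTable <- function(x, path) {
  stopifnot(is(x, "ScoreTable"))
  df <- data.frame(decoy_id = names(x@scores), score = unname(x@scores))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read true TM-score labels
#'
#' Two-column TSV (\code{decoy_id}, \code{true_tm}) with header.
#'
#' @param path Path to the TSV file.
#' @return Named numeric vector of labels in [0, 1].
#' @export
readLabels <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate decoy_id in label file")
  y <- as.numeric(df[[2L]])
  if (anyNA(y) || any(y < 0) || any(y > 1))
    stop("true TM-score labels must be numbers in [0, 1]")
  setNames(y, ids)
}

#' Write per-decoy quality predictions
#'
#' Writes a CSV with columns \code{target_id}, \code{decoy_id},
#' \code{predicted_score}, \code{std}, \code{n_subgraphs}; scores are
#' printed with enough digits to round-trip within 1e-6. Row order is the
#' pool order of the prediction set.
#'
#' @param pred A [PredictionSet-class].
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @seealso [readPredictions()]
#' @export
writePredictions <- function(pred, path) {
  stopifnot(is(pred, "PredictionSet"))
  if (length(pred@decoyIds) == 0L)
    stop("empty PredictionSet")
  df <- data.frame(
    target_id = pred@targetId,
    decoy_id = pred@decoyIds,
    predicted_score = sprintf("%.8f", pred@scores),
    std = sprintf("%.8f", pred@std),
    n_subgraphs = pred@nSubgraphs)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-decoy quality predictions
#'
#' @param path CSV written by [writePredictions()].
#' @return A [PredictionSet-class].
#' @export
readPredictions <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("target_id", "decoy_id", "predicted_score", "std", "n_subgraphs")
  if (!all(need %in% colnames(df)))
    stop("prediction CSV must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L)
    stop("empty prediction CSV")
  if (length(unique(df$target_id)) != 1L)
    stop("prediction CSV must cover exactly one target")
  PredictionSet(df$target_id[1L], df$decoy_id,
                as.numeric(df$predicted_score), as.numeric(df$std),
                as.integer(df$n_subgraphs))
}

#' Read a target manifest
#'
#' A manifest is a YAML (or JSON) key-value file describing one target:
#' \code{target_id}, \code{native_length}, optional \code{labels} path, a
#' \code{matrices} map (metric name to file path) and a \code{scores} map
#' (score name to file path). Paths are resolved relative to the manifest's
#' directory.
#'
#' @param path Path to the manifest file.
#' @return A list with elements \code{pool} ([DecoyPool-class]),
#'   \code{matrices} (named list of [PairwiseMatrix-class]) and
#'   \code{scores} (named list of [ScoreTable-class]).
#' @export
readTargetManifest <- function(path) {
  man <- yaml::read_yaml(path)
  need <- c("target_id", "native_length", "matrices")
  if (!all(need %in% names(man)))
    stop("manifest must define: ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p)
    if (file.exists(p)) p else file.path(base, p)
  matrices <- lapply(names(man$matrices), function(metric)
    readPairwiseMatrix(resolve(man$matrices[[metric]]), metric))
  names(matrices) <- names(man$matrices)
  if (!("tm" %in% names(matrices)))
    stop("manifest must provide a 'tm' pairwise matrix")
  scores <- list()
  if (!is.null(man$scores)) {
    scores <- lapply(names(man$scores), function(sn)
      readScoreTable(resolve(man$scores[[sn]]), sn))
    names(scores) <- names(man$scores)
  }
  ids <- matrices[["tm"]]@ids
  lengths <- rep(as.integer(man$native_length), length(ids))
  if (!is.null(man$lengths)) {
    ldf <- read.delim(resolve(man$lengths), stringsAsFactors = FALSE)
    lmap <- setNames(as.integer(ldf[[2L]]), as.character(ldf[[1L]]))
    if (!all(ids %in% names(lmap)))
      stop("length file missing decoys: ",
           paste(setdiff(ids, names(lmap)), collapse = ", "))
    lengths <- unname(lmap[ids])
  }
  y <- rep(NA_real_, length(ids))
  if (!is.null(man$labels)) {
    lab <- readLabels(resolve(man$labels))
    y <- unname(lab[ids])
  }
  pool <- DecoyPool(man$target_id, as.integer(man$native_length), ids,
                    lengths = lengths, trueTM = y)
  list(pool = pool, matrices = matrices, scores = scores)
}
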