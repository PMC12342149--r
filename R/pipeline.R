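#' Load a run configuration
#'
#' Reads a YAML (or JSON) run configuration and fills defaults. Top-level
#' keys: \code{out_dir} (required), \code{seed}, \code{variant},
#' \code{data_dir}, \code{checkpoint}, \code{n_test_targets}, and nested
#' maps \code{synth} (\code{n_targets}, \code{scenario_mix}),
#' \code{sampler}, \code{transformer}, \code{training},
#' \code{aggregation} whose entries override the corresponding
#' constructor defaults.
#'
#' @param path Path to the config file.
#' @return A validated config list of class \code{"RunConfig"}.
#' @export
loadRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  runConfig(raw)
}

#' @rdname loadRunConfig
#' @param config A named list with the same keys as the YAML layout.
#' @export
runConfig <- function(config = list()) {
  if (is.null(config$out_dir))
    stop("config field missing: out_dir")
  defaults <- list(seed = 1L, variant = "basic",
                   data_dir = file.path(config$out_dir, "data"),
                   checkpoint = file.path(config$out_dir,
                                          "checkpoint.json"),
                   n_test_targets = 2L,
                   synth = list(n_targets = 8L,
                                scenario_mix = c("central_tendency",
                                                 "recoverable", "balanced",
                                                 "easy_high_pss")),
                   sampler = list(), transformer = list(),
                   training = list(), aggregation = list())
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  for (k in names(defaults$synth))
    if (is.null(config$synth[[k]])) config$synth[[k]] <- defaults$synth[[k]]
  if (!(config$variant %in% c("basic", "gcp", "advanced")))
    stop("config field invalid: variant must be basic/gcp/advanced, got ",
         config$variant)
  structure(config, class = "RunConfig")
}

.camel <- function(x) gsub("_(\\w)", "\\U\\1", x, perl = TRUE)

.makeCfg <- function(constructor, overrides, seed = NULL) {
  args <- overrides
  names(args) <- .camel(names(args))
  if (!is.null(seed) && is.null(args$seed)) args$seed <- seed
  do.call(constructor, args)
}

.targetDirs <- function(dataDir) {
  dirs <- list.dirs(dataDir, recursive = FALSE)
  dirs[file.exists(file.path(dirs, "manifest.yaml"))]
}

.writeSynthTarget <- function(tgt, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (metric in names(tgt$matrices))
    writePairwiseMatrix(tgt$matrices[[metric]],
                        file.path(dir, paste0(metric, ".csv")))
  for (sn in names(tgt$scores))
    writeScoreTable(tgt$scores[[sn]],
                    file.path(dir, paste0(sn, ".tsv")))
  lab <- data.frame(decoy_id = tgt$pool@decoyIds,
                    true_tm = sprintf("%.8f", tgt$pool@trueTM))
  utils::write.table(lab, file.path(dir, "labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  clu <- data.frame(decoy_id = names(tgt$cluster),
                    cluster = unname(tgt$cluster))
  utils::write.table(clu, file.path(dir, "clusters.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  man <- list(
    target_id = tgt$pool@targetId,
    native_length = tgt$pool@nativeLength,
    labels = "labels.tsv",
    matrices = setNames(
      as.list(paste0(names(tgt$matrices), ".csv")), names(tgt$matrices)),
    scores = setNames(
      as.list(paste0(names(tgt$scores), ".tsv")), names(tgt$scores)))
  yaml::write_yaml(man, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

.loadTarget <- function(dir) {
  ds <- readTargetManifest(file.path(dir, "manifest.yaml"))
  cluPath <- file.path(dir, "clusters.tsv")
  if (file.exists(cluPath)) {
    clu <- read.delim(cluPath, stringsAsFactors = FALSE)
    ds$cluster <- setNames(as.integer(clu[[2L]]), clu[[1L]])
  }
  ds
}

.prepareTarget <- function(ds, variant, samplerCfg) {
  spec <- featureSpec(variant)
  graph <- buildModelGraph(ds$pool, ds$matrices, ds$scores, spec)
  sam <- sampleSubgraphs(graph, ds$matrices$tm, ds$matrices$qs, samplerCfg)
  list(target = ds$pool@targetId, graph = graph,
       subgraphs = sam$subgraphs, mode = sam$mode,
       labels = trueTM(ds$pool))
}

#' Run a pipeline stage
#'
#' Executes one stage of the pipeline over the run configuration and
#' writes its artifacts plus a machine-readable run manifest (command,
#' config, seed, package version) under \code{out_dir} so a run can be
#' reproduced exactly.
#'
#' Stages: \code{"synth"} writes a synthetic benchmark under
#' \code{data_dir} (one directory per target with matrices, score tables,
#' labels and a manifest); \code{"build-graph"} builds the model graph for
#' each target and writes a graph summary; \code{"sample"} writes a
#' subgraph manifest (one line per subgraph listing its node ids);
#' \code{"baseline-pss"} writes consensus-baseline prediction CSVs;
#' \code{"train"} holds out \code{n_test_targets} targets, trains a model
#' on the rest and saves the checkpoint plus the training log;
#' \code{"predict"} predicts every target with the checkpoint;
#' \code{"evaluate"} scores predictions against labels per target;
#' \code{"all"} runs synth, train, predict, evaluate in order.
#'
#' @param config A [runConfig()] list (or plain list with the same keys).
#' @param command Stage name.
#' @return Invisibly, a list of the stage's main artifacts (paths or
#'   data.frames); \code{"evaluate"} returns the per-target metric table.
#' @export
runPipeline <- function(config,
                        command = c("all", "synth", "build-graph",
                                    "sample", "baseline-pss", "train",
                                    "predict", "evaluate")) {
  command <- match.arg(command)
  if (!inherits(config, "RunConfig")) config <- runConfig(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(command = command,
                   config = unclass(config),
                   package_version =
                     as.character(utils::packageVersion("GraphEMA")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  if (command == "all") {
    runPipeline(config, "synth")
    runPipeline(config, "train")
    runPipeline(config, "predict")
    return(runPipeline(config, "evaluate"))
  }

  samplerCfg <- .makeCfg(samplerConfig, config$sampler, config$seed)

  if (command == "synth") {
    bench <- generateBenchmark(config$synth$n_targets,
                               config$synth$scenario_mix,
                               seed = config$seed)
    for (tgt in bench$targets)
      .writeSynthTarget(tgt, file.path(config$data_dir,
                                       tgt$pool@targetId))
    write.csv(bench$manifest,
              file.path(config$data_dir, "benchmark_manifest.csv"),
              row.names = FALSE)
    return(invisible(list(manifest = bench$manifest)))
  }

  dirs <- .targetDirs(config$data_dir)
  if (!length(dirs))
    stop("no target manifests under data_dir: ", config$data_dir)

  if (command == "build-graph") {
    rows <- lapply(dirs, function(d) {
      ds <- .loadTarget(d)
      g <- buildModelGraph(ds$pool, ds$matrices, ds$scores,
                           featureSpec(config$variant))
      data.frame(target_id = ds$pool@targetId, n_nodes = length(g@ids),
                 n_edges = nrow(g@edgeIndex),
                 n_node_features = ncol(g@nodeFeatures))
    })
    out <- do.call(rbind, rows)
    write.csv(out, file.path(config$out_dir, "graphs.csv"),
              row.names = FALSE)
    return(invisible(list(graphs = out)))
  }

  if (command == "sample") {
    paths <- character()
    for (d in dirs) {
      ds <- .loadTarget(d)
      prep <- .prepareTarget(ds, config$variant, samplerCfg)
      lines <- vapply(prep$subgraphs, function(s)
        paste(s$ids, collapse = "\t"), "")
      p <- file.path(config$out_dir,
                     paste0(prep$target, "_subgraphs.txt"))
      writeLines(lines, p)
      paths <- c(paths, p)
    }
    return(invisible(list(manifests = paths)))
  }

  if (command == "baseline-pss") {
    paths <- character()
    for (d in dirs) {
      ds <- .loadTarget(d)
      ps <- pssScores(ds$matrices$tm, ds$pool@targetId)
      p <- file.path(config$out_dir,
                     paste0(ds$pool@targetId, "_pss.csv"))
      writePredictions(ps, p)
      paths <- c(paths, p)
    }
    return(invisible(list(predictions = paths)))
  }

  if (command == "train") {
    datasets <- lapply(dirs, .loadTarget)
    ids <- vapply(datasets, function(ds) ds$pool@targetId, "")
    labeled <- vapply(datasets, function(ds)
      !anyNA(ds$pool@trueTM), TRUE)
    if (!all(labeled))
      stop("targets without labels cannot be trained on: ",
           paste(ids[!labeled], collapse = ", "))
    set.seed(.deriveSeed(config$seed, 700L))
    ord <- sample(seq_along(datasets))
    nTest <- min(config$n_test_targets, length(datasets) - 2L)
    testIdx <- ord[seq_len(nTest)]
    valIdx <- ord[nTest + 1L]
    trainIdx <- setdiff(ord, c(testIdx, valIdx))
    prep <- lapply(datasets, .prepareTarget, config$variant, samplerCfg)
    ck <- trainModel(prep[trainIdx], prep[valIdx],
                     .makeCfg(transformerConfig, config$transformer,
                              config$seed),
                     .makeCfg(trainingConfig, config$training,
                              config$seed))
    saveCheckpoint(ck, config$checkpoint)
    write.csv(ck$log, file.path(config$out_dir, "training_log.csv"),
              row.names = FALSE)
    split <- data.frame(target_id = ids[c(trainIdx, valIdx, testIdx)],
                        role = c(rep("train", length(trainIdx)),
                                 "validation",
                                 rep("test", length(testIdx))))
    write.csv(split, file.path(config$out_dir, "target_split.csv"),
              row.names = FALSE)
    return(invisible(list(checkpoint = config$checkpoint,
                          split = split, log = ck$log)))
  }

  if (command == "predict") {
    ck <- loadCheckpoint(config$checkpoint)
    agg <- .makeCfg(aggregationConfig, config$aggregation)
    paths <- character()
    for (d in dirs) {
      ds <- .loadTarget(d)
      g <- buildModelGraph(ds$pool, ds$matrices, ds$scores,
                           featureSpec(config$variant))
      pr <- repeatAndAverage(g, ds$matrices$tm, ds$matrices$qs, ck,
                             samplerCfg, agg$nRepeats, agg$method,
                             ds$pool@targetId)
      p <- file.path(config$out_dir,
                     paste0(ds$pool@targetId, "_pred.csv"))
      writePredictions(pr, p)
      paths <- c(paths, p)
    }
    return(invisible(list(predictions = paths)))
  }

  # evaluate
  rows <- list()
  for (d in dirs) {
    ds <- .loadTarget(d)
    p <- file.path(config$out_dir, paste0(ds$pool@targetId, "_pred.csv"))
    if (!file.exists(p)) next
    pr <- readPredictions(p)
    y <- trueTM(ds$pool)[pr@decoyIds]
    rows[[length(rows) + 1L]] <-
      evaluateTarget(unname(y), predScores(pr), ds$pool@targetId)
  }
  if (!length(rows))
    stop("no prediction CSVs found under out_dir; run 'predict' first")
  perTarget <- do.call(rbind, rows)
  write.csv(perTarget, file.path(config$out_dir,
                                 "per_target_metrics.csv"),
            row.names = FALSE)
  summary <- data.frame(
    corr_p = mean(perTarget$corr_p, na.rm = TRUE),
    corr_s = mean(perTarget$corr_s, na.rm = TRUE),
    ranking_loss = mean(perTarget$ranking_loss, na.rm = TRUE),
    auc = mean(perTarget$auc, na.rm = TRUE))
  write.csv(summary, file.path(config$out_dir, "summary_metrics.csv"),
            row.names = FALSE)
  invisible(list(perTarget = perTarget, summary = summary))
}
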