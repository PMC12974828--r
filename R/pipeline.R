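#' Derive a stage seed from the global seed
#'
#' Every stochastic pipeline stage draws its seed deterministically from the
#' global seed and the stage name, so stages can be re-run in isolation.
#'
#' @param global_seed Integer global seed.
#' @param stage Stage name (string).
#' @return Integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) * 10007 + h * 97) %% 2147483399)
}

#' Pipeline configuration
#'
#' Assembles the per-stage configurations into one validated object.  The
#' stage order is fixed (pruning, then resampling, then augmentation, then
#' pooling replacement and the final training); individual stages can be
#' disabled but not reordered.
#'
#' @param data Either `list(synthetic = synthetic_spec(...))` or
#'   `list(directory = "path")` (exactly one).
#' @param model An [xception_config()].
#' @param sparsity A [sparsity_config()].
#' @param strategy An [imbalance_strategy()] (used when resampling).
#' @param smote A [smote_config()].
#' @param augment An [augment_config()].
#' @param train A [train_config()].
#' @param pooling_k Avg-TopK `K` used when replacing max pooling (default 3).
#' @param stages Named logical list enabling `prune`, `resample`, `augment`,
#'   `pooling` (all `TRUE` by default).
#' @param seed Global seed (fanned out per stage via [stage_seed()]).
#' @param output_dir Run directory for artifacts.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(data, model = xception_micro_config(),
                            sparsity = sparsity_config(),
                            strategy = imbalance_strategy("multiplier", k = 2),
                            smote = smote_config(),
                            augment = augment_config(),
                            train = train_config(),
                            pooling_k = 3L,
                            stages = list(),
                            seed = 1L,
                            output_dir = tempfile("dermcnn_run_")) {
  has_synth <- !is.null(data$synthetic)
  has_dir <- !is.null(data$directory)
  if (has_synth == has_dir) {
    stop("config$data must name exactly one source: synthetic or directory")
  }
  stages <- modifyList(list(prune = TRUE, resample = TRUE, augment = TRUE,
                            pooling = TRUE), stages)
  structure(list(data = data, model = model, sparsity = sparsity,
                 strategy = strategy, smote = smote, augment = augment,
                 train = train, pooling_k = as.integer(pooling_k),
                 stages = stages, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with sections mirroring [pipeline_config()]'s
#'   arguments (scalar fields; `data: {synthetic: {...}}` or
#'   `data: {directory: path}`).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  data <- y$data
  if (!is.null(data$synthetic)) {
    data$synthetic <- do.call(synthetic_spec, data$synthetic)
  }
  args <- list(data = data)
  if (!is.null(y$model)) args$model <- do.call(xception_config, y$model)
  if (!is.null(y$sparsity)) args$sparsity <- do.call(sparsity_config, y$sparsity)
  if (!is.null(y$strategy)) args$strategy <- do.call(imbalance_strategy, y$strategy)
  if (!is.null(y$smote)) args$smote <- do.call(smote_config, y$smote)
  if (!is.null(y$augment)) args$augment <- do.call(augment_config, y$augment)
  if (!is.null(y$train)) args$train <- do.call(train_config, y$train)
  for (f in c("pooling_k", "stages", "seed", "output_dir")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  do.call(pipeline_config, args)
}

write_metrics_json <- function(metrics, extra = list(), path) {
  obj <- c(list(accuracy = metrics$accuracy, precision = metrics$precision,
                recall = metrics$recall, f1 = metrics$f1,
                confusion = unclass(metrics$confusion)), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Validate an emitted JSON artifact
#'
#' Structural check against the field descriptors shipped under
#' `inst/schemas/`: all required fields must be present.
#'
#' @param path Path to the JSON artifact.
#' @param schema Schema name: `"graph"`, `"metrics"` or `"prune_result"`.
#' @return `TRUE` invisibly; errors listing missing fields otherwise.
#' @export
validate_artifact_json <- function(path, schema) {
  sfile <- system.file("schemas", paste0(schema, ".json"), package = "dermcnn")
  if (!nzchar(sfile)) stop("unknown schema: ", schema)
  sch <- jsonlite::fromJSON(sfile)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  missing <- setdiff(sch$required, names(doc))
  if (length(missing)) {
    stop(sprintf("%s does not validate against schema '%s': missing %s",
                 path, schema, paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

log_line <- function(log_path, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  cat(line, "\n", sep = "", file = log_path, append = TRUE)
  message(line)
}

#' Run the full pipeline
#'
#' Executes generate/load, train/test split, baseline training, sparsity
#' profiling, pruning with retraining, SMOTE resampling (training split
#' only), augmentation-based class equalisation, max-pool replacement by
#' Avg-TopK, final training and test-set evaluation, in that fixed order.
#' Every stage writes its artifact (graph JSON, profile CSV, manifest CSVs,
#' metrics JSON, history CSV) into the run directory together with a log of
#' the resolved seeds; a stage failure aborts with the stage name, leaving
#' prior artifacts in place.
#'
#' @param config A [pipeline_config()].
#' @return The run directory path, invisibly; all artifacts are plain text.
#'   Attributes `"final_metrics"`, `"baseline_metrics"` and
#'   `"pruned_metrics"` carry the corresponding [evaluate_model()] results
#'   (`pruned_metrics` is `NULL` when the prune stage is disabled).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  cat("", file = log_path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_line(log_path, "stage '%s' FAILED: %s", name, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  yaml::write_yaml(list(seed = config$seed, stages = config$stages,
                        pooling_k = config$pooling_k),
                   file.path(out, "config_resolved.yaml"))

  dataset <- stage("data", {
    if (!is.null(config$data$synthetic)) {
      generate_dataset(config$data$synthetic)
    } else {
      read_image_directory(config$data$directory)
    }
  })
  utils::write.csv(manifest(dataset), file.path(out, "dataset_manifest.csv"),
                   row.names = FALSE)
  log_line(log_path, "data: %d items, %d classes", n_items(dataset),
           length(dataset$class_names))

  sp <- stage("split", split_train_test(dataset, 0.8,
                                        stage_seed(config$seed, "split")))
  train_set <- sp$train; test_set <- sp$test
  log_line(log_path, "split: %d train / %d test (seed %d)",
           n_items(train_set), n_items(test_set),
           stage_seed(config$seed, "split"))

  tcfg <- config$train
  tcfg$seed <- stage_seed(config$seed, "train_baseline")
  baseline <- stage("baseline_train", {
    g <- build_xception(config$model)
    m <- init_model(g, seed = tcfg$seed)
    train_model(m, train_set, tcfg)
  })
  graph_to_json(baseline$model$graph, file.path(out, "baseline_graph.json"))
  base_metrics <- evaluate_model(baseline$model, test_set)
  write_metrics_json(base_metrics,
                     list(epochs_run = baseline$epochs_run),
                     file.path(out, "baseline_metrics.json"))
  utils::write.csv(baseline$history, file.path(out, "baseline_history.csv"),
                   row.names = FALSE)
  log_line(log_path, "baseline: accuracy %.2f%%", base_metrics$accuracy)

  model <- baseline$model
  pruned_metrics <- NULL
  if (isTRUE(config$stages$prune)) {
    pr <- stage("prune", {
      bseed <- stage_seed(config$seed, "profile_batch")
      old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(bseed)
      bidx <- sample(n_items(train_set), config$sparsity$batch_size)
      vb <- train_set$images[, , , bidx, drop = FALSE] / 255
      tcfg$seed <- stage_seed(config$seed, "train_pruned")
      prune_and_retrain(model, train_set, vb, config$sparsity, tcfg)
    })
    utils::write.csv(as.data.frame(pr$profile), file.path(out, "profile.csv"),
                     row.names = FALSE)
    graph_to_json(pr$model$graph, file.path(out, "pruned_graph.json"))
    jsonlite::write_json(unclass(pr$result), file.path(out, "prune_result.json"),
                         auto_unbox = TRUE, digits = NA)
    pruned_metrics <- evaluate_model(pr$model, test_set)
    write_metrics_json(pruned_metrics, path = file.path(out, "pruned_metrics.json"))
    log_line(log_path, "pruned-retrained: accuracy %.2f%%", pruned_metrics$accuracy)
    log_line(log_path, "prune: cut %s, %d -> %d parameters",
             pr$result$cut_layer_id, pr$result$parameters_before,
             pr$result$parameters_after)
    model <- pr$model
  }

  if (isTRUE(config$stages$resample)) {
    train_set <- stage("resample", {
      cfg <- config$smote
      cfg$seed <- stage_seed(config$seed, "resample")
      if (cfg$space == "feature") {
        stop("feature-space resampling is supported via extract_features(); the image pipeline uses pixel space")
      }
      resample(train_set, config$strategy, cfg)
    })
    utils::write.csv(manifest(train_set), file.path(out, "resample_manifest.csv"),
                     row.names = FALSE)
    log_line(log_path, "resample: now %d items", n_items(train_set))
  }

  if (isTRUE(config$stages$augment)) {
    train_set <- stage("augment", {
      targets <- rep(max(class_counts(train_set)),
                     length(train_set$class_names))
      balance_with_augmentation(train_set, targets, config$augment,
                                seed = stage_seed(config$seed, "augment"))
    })
    utils::write.csv(manifest(train_set), file.path(out, "augment_manifest.csv"),
                     row.names = FALSE)
    log_line(log_path, "augment: equalized to %d items", n_items(train_set))
  }

  final_graph <- model$graph
  if (isTRUE(config$stages$pooling)) {
    final_graph <- stage("pooling", replace_max_pooling(final_graph,
                                                        config$pooling_k))
    log_line(log_path, "pooling: max_pool -> avg_topk_pool (K = %d)",
             config$pooling_k)
  }

  tcfg$seed <- stage_seed(config$seed, "train_final")
  final <- stage("final_train", {
    m <- init_model(final_graph, seed = tcfg$seed)
    train_model(m, train_set, tcfg)
  })
  graph_to_json(final$model$graph, file.path(out, "final_graph.json"))
  utils::write.csv(final$history, file.path(out, "final_history.csv"),
                   row.names = FALSE)
  metrics <- stage("evaluate", evaluate_model(final$model, test_set))
  write_metrics_json(metrics, list(epochs_run = final$epochs_run),
                     file.path(out, "final_metrics.json"))
  log_line(log_path, "final: accuracy %.2f%%, F1 %.2f%%", metrics$accuracy,
           metrics$f1)
  validate_artifact_json(file.path(out, "final_metrics.json"), "metrics")
  validate_artifact_json(file.path(out, "final_graph.json"), "graph")

  res <- invisible(out)
  attr(res, "final_metrics") <- metrics
  attr(res, "baseline_metrics") <- base_metrics
  attr(res, "pruned_metrics") <- pruned_metrics
  res
}
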