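# One driver wiring the stages: simulate -> preprocess -> train (dann |
# lspin) -> evaluate -> interpret. A single config (R list or YAML file)
# describes a run; every intermediate artifact is written to the run
# directory together with a manifest of content hashes, and an identical
# config reproduces identical metrics.

.PIPELINE_STAGES <- c("simulate", "preprocess", "train_dann", "train_lspin",
                      "evaluate", "interpret")

#' Read a pipeline run configuration
#'
#' @param path YAML file with keys `stages`, `seed` and per-stage sections
#'   (`synthetic`, `preprocess`, `dann`, `lspin`).
#' @return a named list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

.validateRunConfig <- function(config) {
  stages <- config$stages
  if (is.null(stages) || !length(stages))
    stop("config error: 'stages' must list at least one stage")
  unknown <- setdiff(stages, .PIPELINE_STAGES)
  if (length(unknown))
    stop("config error: unknown stage(s): ", paste(unknown, collapse = ", "))
  # stage order is fixed: dropping/normalizing happen inside preprocess, and
  # training stages cannot precede it
  ord <- match(stages, .PIPELINE_STAGES)
  if (is.unsorted(ord))
    stop("config error: stages must follow the pipeline order: ",
         paste(.PIPELINE_STAGES, collapse = " -> "))
  needsData <- intersect(stages,
                         c("preprocess", "train_dann", "train_lspin"))
  if (length(needsData) && !"simulate" %in% stages &&
      is.null(config$data))
    stop("config error: stages ", paste(needsData, collapse = ", "),
         " need either a 'simulate' stage or a 'data' CSV path")
  if (!is.null(config$data) && !file.exists(config$data))
    stop("config error: data file not found: ", config$data)
  invisible(TRUE)
}

.syntheticFromConfig <- function(sc, seed) {
  sc <- as.list(sc)
  cohort <- sc$cohort %||% "broad"
  shift <- if (!is.null(sc$shift_magnitude) && sc$shift_magnitude != 0)
    strongShiftSpec(magnitude = sc$shift_magnitude)
  else domainShiftSpec()
  if (cohort == "broad")
    broadCohortConfig(shift = shift,
                      classEffectSize = sc$class_effect_size %||% 3,
                      missingRate = sc$missing_rate %||% 0,
                      seed = sc$seed %||% seed)
  else if (cohort == "subclass")
    subclassCohortConfig(classEffectSize = sc$class_effect_size %||% 3,
                         missingRate = sc$missing_rate %||% 0.00073,
                         seed = sc$seed %||% seed)
  else stop("config error: synthetic$cohort must be 'broad' or 'subclass'")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.dannFromConfig <- function(dc, seed) {
  dc <- as.list(dc)
  dannConfig(hidden = as.integer(dc$hidden %||% c(32L, 16L)),
             activations = dc$activations %||% "relu",
             lambda = dc$lambda %||% 0,
             learningRate = dc$learning_rate %||% 0.05,
             dropout = dc$dropout %||% 0,
             weightDecay = dc$weight_decay %||% 0,
             batchSize = dc$batch_size %||% 64L,
             epochs = dc$epochs %||% 100L,
             optimizer = dc$optimizer %||% "sgd",
             lambdaSchedule = dc$lambda_schedule %||% "fixed",
             seed = as.integer(dc$seed %||% seed))
}

.lspinFromConfig <- function(lc, seed) {
  lc <- as.list(lc)
  lspinConfig(gatingHidden = as.integer(lc$gating_hidden %||% c(50L, 50L, 50L)),
              predictionHidden = as.integer(lc$prediction_hidden %||% c(40L, 20L)),
              sigma = lc$sigma %||% 0.5,
              lambda1 = lc$lambda1 %||% 0.01047,
              lambda2 = lc$lambda2 %||% 0,
              learningRate = lc$learning_rate %||% 0.0599,
              epochs = as.integer(lc$epochs %||% 1000L),
              batchSize = as.integer(lc$batch_size %||% 64L),
              optimizer = lc$optimizer %||% "sgd",
              seed = as.integer(lc$seed %||% seed))
}

.metricsToList <- function(r) {
  list(accuracy = r@accuracy, risk = r@risk,
       macro_precision = r@macroPrecision, macro_recall = r@macroRecall,
       macro_f1 = r@macroF1, confusion = unname(r@confusion))
}

#' Run the full pipeline
#'
#' Executes the configured stages in order, failing fast on config errors
#' before any training starts. Every artifact (cohort CSV, ground-truth
#' JSON, split CSVs, model RDS, history CSV, metrics JSON, gate-matrix CSV,
#' clustered heatmap) is written under `outDir`, plus `manifest.json`
#' listing each output file with its MD5 content hash and the seeds used.
#'
#' @param config a named list (see [readRunConfig()]) or a YAML path.
#' @param outDir run directory (created if needed; default a fresh temporary
#'   directory).
#' @return invisibly, the run directory.
#' @export
runPipeline <- function(config, outDir = tempfile("neurotype-run-")) {
  if (is.character(config)) config <- readRunConfig(config)
  .validateRunConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages
  artifacts <- character()
  emit <- function(path) artifacts <<- c(artifacts, path)

  table <- NULL
  truth <- NULL
  if ("simulate" %in% stages) {
    scfg <- .syntheticFromConfig(config$synthetic, seed)
    cohort <- generateCohort(scfg)
    table <- cohort$table
    truth <- cohort$truth
    paths <- writeCohort(cohort, file.path(outDir, "cohort.csv"))
    emit(paths[["table"]])
    emit(paths[["truth"]])
  } else if (!is.null(config$data)) {
    table <- loadFeatureTable(config$data)
  }

  split <- NULL
  if ("preprocess" %in% stages) {
    pc <- as.list(config$preprocess)
    rowsIn <- ncol(table)
    excluded <- 0L
    if (!is.null(pc$merge_map)) {
      table <- mergeLines(table, pc$merge_map)
      excluded <- metadata(table)$linesExcluded
    }
    dropped <- dropIncomplete(table)
    table <- dropped$table
    stopifnot(rowsIn == ncol(table) + excluded + dropped$nDropped)
    split <- splitData(table,
                       fractions = unlist(pc$fractions %||%
                                            c(0.6797, 0.1201, 0.2002)),
                       stratifyOn = unlist(pc$stratify_on %||%
                                             c("organism", "broad_label")),
                       seed = as.integer(pc$seed %||% seed))
    split <- normalizeSplit(split)
    counts <- list(rows_in = rowsIn, excluded_by_merge = excluded,
                   n_dropped = dropped$nDropped,
                   train = ncol(split@train),
                   validation = ncol(split@validation),
                   test = ncol(split@test))
    jsonlite::write_json(counts, file.path(outDir, "preprocess_counts.json"),
                         auto_unbox = TRUE, digits = NA)
    emit(file.path(outDir, "preprocess_counts.json"))
    for (part in c("train", "validation", "test")) {
      p <- file.path(outDir, paste0(part, ".csv"))
      writeFeatureTable(slot(split, part), p)
      emit(p)
    }
  }

  metrics <- list()
  dannFit <- NULL
  if ("train_dann" %in% stages) {
    dcfg <- .dannFromConfig(config$dann, seed)
    dannFit <- trainDANN(dcfg, split)
    saveRDS(dannFit$model, file.path(outDir, "dann_model.rds"))
    data.table::fwrite(dannFit$history,
                       file.path(outDir, "dann_history.csv"))
    emit(file.path(outDir, "dann_model.rds"))
    emit(file.path(outDir, "dann_history.csv"))
  }

  lspinFit <- NULL
  if ("train_lspin" %in% stages) {
    lcfg <- .lspinFromConfig(config$lspin, seed)
    lspinFit <- trainLSPIN(lcfg, split)
    saveRDS(lspinFit$model, file.path(outDir, "lspin_model.rds"))
    data.table::fwrite(lspinFit$history,
                       file.path(outDir, "lspin_history.csv"))
    emit(file.path(outDir, "lspin_model.rds"))
    emit(file.path(outDir, "lspin_history.csv"))
  }

  if ("evaluate" %in% stages) {
    if (!is.null(dannFit)) {
      perDomain <- evaluatePerDomain(dannFit$model, split)
      metrics$dann <- lapply(perDomain, .metricsToList)
    }
    if (!is.null(lspinFit)) {
      pred <- predictSubclass(lspinFit$model, split@test)
      truthLab <- subclassLabel(split@test)
      lv <- lspinFit$model@classLevels
      m <- confusionCounts(match(truthLab, lv) - 1L,
                           as.integer(pred) - 1L, length(lv))
      metrics$lspin <- .metricsToList(classificationMetrics(m))
    }
    jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    emit(file.path(outDir, "metrics.json"))
  }

  if ("interpret" %in% stages) {
    if (is.null(lspinFit))
      stop("config error: 'interpret' requires the train_lspin stage")
    Z <- gateMatrix(lspinFit$model, split@test)
    data.table::fwrite(as.data.frame(Z), file.path(outDir, "gate_matrix.csv"),
                       row.names = TRUE)
    emit(file.path(outDir, "gate_matrix.csv"))
    cl <- clusterGateMatrix(Z)
    png <- file.path(outDir, "gate_heatmap.png")
    if (requireNamespace("pheatmap", quietly = TRUE)) {
      grDevices::png(png, width = 900, height = 700)
      pheatmap::pheatmap(Z[cl$rowOrder, cl$colOrder, drop = FALSE],
                         cluster_rows = FALSE, cluster_cols = FALSE,
                         show_rownames = FALSE,
                         color = grDevices::gray.colors(64, 0, 1),
                         main = "Inference gate matrix (black = muted)")
      grDevices::dev.off()
    } else {
      grDevices::png(png, width = 900, height = 700)
      graphics::image(t(Z[rev(cl$rowOrder), cl$colOrder, drop = FALSE]),
                      col = grDevices::gray.colors(64, 0, 1), axes = FALSE,
                      main = "Inference gate matrix (black = muted)")
      grDevices::dev.off()
    }
    emit(png)
  }

  manifest <- list(
    seed = seed,
    stages = stages,
    config = config,
    files = lapply(artifacts, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  message("pipeline complete: ", outDir)
  invisible(outDir)
}
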