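#' Build and validate a pipeline run configuration
#'
#' Collects every stage setting in one validated list. The accepted
#' structure is also published, as a JSON-schema document, at
#' `system.file("schema", "run_config_schema.json", package = "RorschachMap")`;
#' [validateRunConfig()] enforces it before any stage runs.
#'
#' @param input `"fixture"` for the bundled cohort, a path to a cohort CSV,
#'   or a [cohortSpec()] to sample from.
#' @param stages character vector of stages to run, a subset of
#'   `c("describe", "validate", "mds", "som", "autocm", "graph")`.
#' @param mdsMetric distance metric for the projection stage.
#' @param somConfig,autocmConfig stage configurations (seeds inside them are
#'   overridden by the fan-out from `seed`).
#' @param seed global seed; per-stage seeds are derived at fixed offsets so
#'   any stage can be reproduced in isolation.
#' @param outDir optional directory for stage artifacts (embedding CSV,
#'   assignment CSV, association CSV, GraphML); created if needed.
#' @param topK number of strongest association edges echoed in the report.
#' @return a validated `runConfig` list.
#' @export
runConfig <- function(input = "fixture",
                      stages = c("describe", "validate", "mds", "som",
                                 "autocm", "graph"),
                      mdsMetric = c("manhattan", "euclidean"),
                      somConfig = RorschachMap::somConfig(),
                      autocmConfig = RorschachMap::autoCMConfig(),
                      seed = 1L, outDir = NULL, topK = 5L) {
  cfg <- list(input = input, stages = stages,
              mdsMetric = match.arg(mdsMetric),
              somConfig = somConfig, autocmConfig = autocmConfig,
              seed = as.integer(seed), outDir = outDir,
              topK = as.integer(topK))
  class(cfg) <- "runConfig"
  validateRunConfig(cfg)
  cfg
}

#' @rdname runConfig
#' @param config a `runConfig` list to check.
#' @return `validateRunConfig` returns `config` invisibly, or stops with the
#'   first schema violation.
#' @export
validateRunConfig <- function(config) {
  schema <- jsonlite::read_json(system.file(
    "schema", "run_config_schema.json", package = "RorschachMap",
    mustWork = TRUE))
  req <- unlist(schema$required)
  missing <- setdiff(req, names(config))
  if (length(missing))
    stop("config is missing required field(s): ",
         paste(missing, collapse = ", "))
  allowed <- unlist(schema$properties$stages$items$enum)
  if (length(config$stages) == 0L)
    stop("nothing to run: no stages enabled")
  bad <- setdiff(config$stages, allowed)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!(identical(config$input, "fixture") ||
        (is.character(config$input) && length(config$input) == 1L) ||
        inherits(config$input, "cohortSpec")))
    stop("input must be 'fixture', a file path, or a cohortSpec")
  if (!config$mdsMetric %in% unlist(schema$properties$mdsMetric$enum))
    stop("mdsMetric must be 'manhattan' or 'euclidean'")
  if (!is.numeric(config$seed) || length(config$seed) != 1L)
    stop("seed must be a single integer")
  if (!is.list(config$somConfig) || !is.list(config$autocmConfig))
    stop("somConfig and autocmConfig must be config lists")
  invisible(config)
}

.stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: load -> validate -> describe -> scale -> projection
#' and SOM on the coding variables -> indicator augmentation -> contractive
#' map -> spanning-tree extraction -> export. Each enabled stage's outputs
#' are collected into a machine-readable report; any stage failure aborts
#' with an error naming the stage. With the same config and seed the report
#' is identical apart from its timestamp.
#'
#' @param config a [runConfig()] list.
#' @return a `runReport` list; see [writeReport()].
#' @examples
#' \donttest{
#' rep <- runPipeline(runConfig(stages = c("describe", "validate", "mds")))
#' rep$separation
#' }
#' @export
runPipeline <- function(config = runConfig()) {
  validateRunConfig(config)
  co <- .stageTry("load", {
    if (inherits(config$input, "cohortSpec"))
      sampleCohort(config$input, seed = .stageSeed(config$seed, "synthetic"))
    else if (identical(config$input, "fixture"))
      rorschachFixture()
    else readCohort(config$input)
  })
  report <- list(
    software = list(package = "RorschachMap",
                    version = as.character(packageVersion("RorschachMap"))),
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = .echoConfig(config),
    nSubjects = length(subjectIds(co)),
    nVariables = length(variableNames(co)),
    groups = as.list(table(as.character(cohortGroups(co)))))
  outDir <- config$outDir
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  if ("describe" %in% config$stages) {
    st <- .stageTry("describe", describeCohort(co))
    st$mean <- round(st$mean, 2)
    st$sd <- round(st$sd, 2)
    report$descriptives <- st
  }
  if ("validate" %in% config$stages) {
    pv <- .stageTry("validate", validateProtocol(co))
    report$validation <- list(violations = violationTable(pv),
                              ruleCounts = as.list(pv@ruleCounts))
  }
  sco <- .stageTry("scale", scaleCohort(co))
  if ("mds" %in% config$stages) {
    emb <- .stageTry("mds", projectCohort(sco, metric = config$mdsMetric))
    sep <- .stageTry("mds", linearSeparation(emb, cohortGroups(co)))
    report$separation <- list(
      misplacedCount = sep@misplacedCount,
      misplacedIds = sep@misplacedIds,
      stress = round(embeddingStress(emb), 4))
    if (!is.null(outDir)) {
      df <- data.frame(subject_id = subjectIds(co),
                       group = as.character(cohortGroups(co)),
                       embeddingCoords(emb))
      f <- file.path(outDir, "embedding.csv")
      write.csv(df, f, row.names = FALSE)
      report$artifacts$embedding <- f
    }
  }
  if ("som" %in% config$stages) {
    scfg <- config$somConfig
    scfg$seed <- .stageSeed(config$seed, "som")
    fit <- .stageTry("som", trainSOM(sco, scfg))
    asg <- .stageTry("som", assignClasses(fit, sco))
    report$som <- list(sharedClasses = classSharingCount(asg),
                       occupancy = asg@occupancy,
                       finalQuantError = round(utils::tail(fit@qe, 1), 4))
    if (!is.null(outDir)) {
      df <- data.frame(subject_id = subjectIds(co),
                       group = as.character(cohortGroups(co)),
                       class = unname(classLabels(asg)[subjectIds(co)]))
      f <- file.path(outDir, "som_classes.csv")
      write.csv(df, f, row.names = FALSE)
      report$artifacts$somClasses <- f
    }
  }
  needA <- any(c("autocm", "graph") %in% config$stages)
  if (needA) {
    acfg <- config$autocmConfig
    acfg$seed <- .stageSeed(config$seed, "autocm")
    aug <- .stageTry("autocm", scaleCohort(appendGroupIndicators(co)))
    fit <- .stageTry("autocm", trainAutoCM(aug, acfg))
    a <- associationMatrix(fit)
    report$autocm <- list(
      units = length(variableNames(aug)),
      epochs = trainingEpochs(fit),
      converged = isConverged(fit),
      maxResidual = max(acfg$C - fit@v[fit@active]) / acfg$C,
      topEdges = .topEdges(a, config$topK))
    if (!is.null(outDir)) {
      f <- file.path(outDir, "associations.csv")
      write.csv(round(a@.Data, 6), f)
      report$artifacts$associations <- f
    }
    if ("graph" %in% config$stages) {
      tree <- .stageTry("graph", minimumSpanningTree(a))
      mrg <- .stageTry("graph", mrgAugment(tree, a))
      report$graph <- list(
        nodes = length(graphNodes(mrg)),
        edges = nrow(graphEdges(mrg)),
        kind = graphKind(mrg),
        indicatorNeighbours = list(
          INPH = .neighbours(mrg, "INPH"),
          DEMENZA = .neighbours(mrg, "DEMENZA")))
      if (!is.null(outDir)) {
        f <- file.path(outDir, "variable_graph.graphml")
        exportGraph(mrg, f, "graphml")
        report$artifacts$graph <- f
      }
    }
  }
  class(report) <- "runReport"
  report
}

.neighbours <- function(g, node) {
  e <- graphEdges(g)
  sort(unique(c(e$v[e$u == node], e$u[e$v == node])))
}

.topEdges <- function(a, k) {
  m <- a@.Data
  idx <- which(upper.tri(m), arr.ind = TRUE)
  e <- data.frame(u = rownames(m)[idx[, 1]], v = rownames(m)[idx[, 2]],
                  strength = m[idx], stringsAsFactors = FALSE)
  e <- e[order(-e$strength, e$u, e$v), , drop = FALSE][seq_len(min(k, nrow(e))), ]
  e$strength <- round(e$strength, 2)
  rownames(e) <- NULL
  e
}

.echoConfig <- function(config) {
  cfg <- unclass(config)
  cfg$input <- if (inherits(cfg$input, "cohortSpec")) "cohortSpec" else cfg$input
  cfg
}

#' Write a pipeline report
#'
#' Always writes JSON (via jsonlite, keeping the full structure); a compact
#' human-readable text summary can be added. Quantities that the clinical
#' tables print at two decimals are rounded to two decimals in the report.
#'
#' @param report a `runReport` from [runPipeline()].
#' @param path output path without extension (`.json` / `.txt` appended).
#' @param formats subset of `c("json", "txt")`.
#' @return character vector of files written, invisibly.
#' @export
writeReport <- function(report, path, formats = c("json")) {
  formats <- match.arg(formats, c("json", "txt"), several.ok = TRUE)
  written <- character()
  if ("json" %in% formats) {
    f <- paste0(path, ".json")
    jsonlite::write_json(unclass(report), f, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null", pretty = TRUE)
    written <- c(written, f)
  }
  if ("txt" %in% formats) {
    f <- paste0(path, ".txt")
    con <- file(f, "w")
    on.exit(close(con))
    writeLines(sprintf("RorschachMap pipeline report (%s)", report$generated),
               con)
    writeLines(sprintf("subjects: %d  variables: %d", report$nSubjects,
                       report$nVariables), con)
    if (!is.null(report$descriptives)) {
      nr <- report$descriptives
      writeLines(sprintf("mean responses: %.2f (min %d, max %d)",
                         nr$mean[1], nr$min[1], nr$max[1]), con)
    }
    if (!is.null(report$separation))
      writeLines(sprintf("linear separation: %d misplaced (%s)",
                         report$separation$misplacedCount,
                         paste(report$separation$misplacedIds,
                               collapse = ", ")), con)
    if (!is.null(report$som))
      writeLines(sprintf("SOM shared classes: %d", report$som$sharedClasses),
                 con)
    if (!is.null(report$graph))
      writeLines(sprintf("graph: %d nodes, %d edges (%s)",
                         report$graph$nodes, report$graph$edges,
                         report$graph$kind), con)
    written <- c(written, f)
  }
  invisible(written)
}
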