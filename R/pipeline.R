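# End-to-end experiment orchestration: simulate -> preprocess -> networks
# (with and without the cerebellar node subset) -> metrics -> permutation
# feature selection -> MLDA leave-one-out discrimination, from one config.

CONTRASTS <- c("mixed_vs_nc", "tpd_vs_nc", "ntpd_vs_nc", "tpd_vs_ntpd")
TEMPLATES <- c("with_cerebellum", "without_cerebellum")

#' Build an experiment configuration
#'
#' Bundles the stage settings of a full experiment. The defaults mirror the
#' analysis design the package implements: temporal preprocessing dropping 5
#' volumes and bandpassing 0.01-0.1 Hz, Bonferroni-thresholded positive
#' networks at family-wise alpha 0.05, 100-network small-world normalization
#' (summarized on 5 subjects per group to keep the descriptive summary
#' affordable), permutation feature selection at uncorrected p < 0.05, and
#' nested leave-one-out MLDA over all four group contrasts for both the
#' with- and without-cerebellum template arms.
#'
#' @param cohort A [CohortConfig-class].
#' @param prep List: `drop`, `lowHz`, `highHz`.
#' @param net List: `alpha`, `positiveOnly`.
#' @param metrics List: `nNulls`, `smallworldSubjectsPerGroup`.
#' @param selection List: `nPermutations`, `alpha`, `metrics` (subset of
#'   `eLocal`, `eNodal`, `cNode`, `lNode`).
#' @param classify List: `contrasts`, `mode`, `nPermutations`.
#' @param templates Character subset of `with_cerebellum`,
#'   `without_cerebellum`.
#' @param seed Master seed for the metric/selection/classification stages
#'   (the cohort has its own seed inside `cohort`).
#' @return A classed list (`ExperimentConfig`).
#' @export
experimentConfig <- function(cohort = cohortConfig(),
                             prep = list(drop = 5L, lowHz = 0.01,
                                         highHz = 0.1),
                             net = list(alpha = 0.05, positiveOnly = TRUE),
                             metrics = list(nNulls = 100L,
                                            smallworldSubjectsPerGroup = 5L),
                             selection = list(nPermutations = 1000L,
                                              alpha = 0.05,
                                              metrics = c("eLocal", "eNodal")),
                             classify = list(contrasts = CONTRASTS,
                                             mode = "nested",
                                             nPermutations = 1000L),
                             templates = TEMPLATES,
                             seed = 1L) {
  stopifnot(is(cohort, "CohortConfig"),
            all(templates %in% TEMPLATES), length(templates) >= 1,
            all(classify$contrasts %in% CONTRASTS),
            length(classify$contrasts) >= 1,
            all(selection$metrics %in% c("eLocal", "eNodal", "cNode",
                                         "lNode")),
            classify$mode %in% c("nested", "paper_faithful"))
  structure(list(cohort = cohort, prep = prep, net = net, metrics = metrics,
                 selection = selection, classify = classify,
                 templates = templates, seed = as.integer(seed)),
            class = "ExperimentConfig")
}

#' Read an experiment configuration from YAML
#'
#' The document mirrors the [experimentConfig()] argument structure, with a
#' `cohort` block holding [cohortConfig()] fields.
#'
#' @param path YAML file path.
#' @return An `ExperimentConfig`.
#' @export
readExperimentConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cohortArgs <- y$cohort
  if (is.null(cohortArgs)) cohortArgs <- list()
  if (!is.null(cohortArgs$nPerGroup))
    cohortArgs$nPerGroup <- unlist(cohortArgs$nPerGroup)
  if (!is.null(cohortArgs$effectDelta))
    cohortArgs$effectDelta <- unlist(cohortArgs$effectDelta)
  cohort <- do.call(cohortConfig, cohortArgs)
  base <- unclass(experimentConfig(cohort = cohort))
  for (f in c("prep", "net", "metrics", "selection", "classify"))
    if (!is.null(y[[f]])) base[[f]] <- utils::modifyList(base[[f]], y[[f]])
  if (!is.null(y$templates)) base$templates <- unlist(y$templates)
  if (!is.null(y$seed)) base$seed <- as.integer(y$seed)
  do.call(experimentConfig, base)   # revalidates the merged settings
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Subject subset + relabeling for one contrast. The positive class is the
# patient group (mixed patients are relabeled "PD"); for the subtype
# contrast the tremor-dominant group is taken as positive.
.contrastSpec <- function(contrast) {
  switch(contrast,
    mixed_vs_nc = list(groups = c("NC", "TPD", "NTPD"),
                       relabel = c(TPD = "PD", NTPD = "PD"),
                       positive = "PD"),
    tpd_vs_nc = list(groups = c("NC", "TPD"), relabel = NULL,
                     positive = "TPD"),
    ntpd_vs_nc = list(groups = c("NC", "NTPD"), relabel = NULL,
                      positive = "NTPD"),
    tpd_vs_ntpd = list(groups = c("TPD", "NTPD"), relabel = NULL,
                       positive = "TPD"),
    stop("unknown contrast: ", contrast))
}

#' Run a full experiment
#'
#' Executes every stage for each template arm: cohort simulation, temporal
#' preprocessing, network construction (the without-cerebellum arm removes
#' the masked nodes before correlation, so its Bonferroni test count uses the
#' smaller node set), per-node metrics, a small-world summary on a subject
#' subset, and permutation-selected MLDA leave-one-out discrimination for
#' each requested contrast and metric. Deterministic under the config seeds.
#'
#' @param config An `ExperimentConfig` from [experimentConfig()].
#' @param outDir Optional directory; when given, intermediate artifacts and
#'   the report are written there.
#' @param verbose Log stage timing to stderr.
#' @return An `ExperimentReport`: list with `performance` (one row per
#'   template x contrast x metric), `smallworld` (per template x group),
#'   `selectedNodes` (per template x contrast x metric, whole-sample
#'   descriptive selection), `features`, `metadata` and `provenance`.
#' @export
runExperiment <- function(config, outDir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "ExperimentConfig"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    s <- Sys.time()
    r <- tryCatch(force(expr),
                  error = function(e) stop("stage [", name, "] failed: ",
                                           conditionMessage(e), call. = FALSE))
    say("stage %-12s %6.1fs", name, as.numeric(Sys.time() - s, units = "secs"))
    r
  }

  meta <- makeCohort(config$cohort)
  subjects <- stage("simulate", simulateCohort(config$cohort))
  cleaned <- stage("preprocess", lapply(subjects, function(s)
    preprocessSubject(s, drop = config$prep$drop, lowHz = config$prep$lowHz,
                      highHz = config$prep$highHz)))

  cerebMask <- seq_len(config$cohort@nRois) %in% config$cohort@cerebellumNodes
  perf <- list(); sw <- list(); selNodes <- list(); features <- list()

  for (template in config$templates) {
    keep <- if (template == "without_cerebellum") !cerebMask else
      rep(TRUE, length(cerebMask))
    armMask <- cerebMask[keep]
    nets <- stage(paste0("net:", substr(template, 1, 7)),
      lapply(cleaned, function(x)
        buildNetwork(x[, keep, drop = FALSE], alpha = config$net$alpha,
                     positiveOnly = config$net$positiveOnly,
                     cerebellumMask = armMask)))

    if (!is.null(outDir)) {
      ndir <- file.path(outDir, "networks", template)
      dir.create(ndir, recursive = TRUE, showWarnings = FALSE)
      for (i in seq_along(nets))
        writeNetworkMatrix(nets[[i]],
                           file.path(ndir, paste0(meta$subjectId[i], ".tsv")))
    }

    nodal <- stage(paste0("metrics:", substr(template, 1, 7)),
      lapply(nets, function(nw) networkMetrics(nw, nNulls = 0L)$nodal))
    metricMats <- list()
    for (mname in c("eNodal", "eLocal", "cNode", "lNode")) {
      mat <- do.call(rbind, lapply(nodal, function(df) df[[mname]]))
      colnames(mat) <- nodal[[1]]$node
      rownames(mat) <- meta$subjectId
      metricMats[[mname]] <- mat
    }
    features[[template]] <- metricMats

    # descriptive small-world summary on a per-group subject subset
    swSeed <- deriveSeed(config$seed, 300L + match(template, TEMPLATES))
    nPer <- config$metrics$smallworldSubjectsPerGroup
    swRows <- stage(paste0("smallworld:", substr(template, 1, 7)), {
      rows <- list()
      for (g in GROUP_LEVELS) {
        idx <- utils::head(which(meta$group == g), nPer)
        for (i in idx) {
          gm <- networkMetrics(nets[[i]], nNulls = config$metrics$nNulls,
                               seed = deriveSeed(swSeed, i))$global
          rows[[length(rows) + 1L]] <-
            cbind(data.frame(template = template, group = g,
                             subjectId = meta$subjectId[i]), gm)
        }
      }
      do.call(rbind, rows)
    })
    sw[[template]] <- swRows

    for (contrast in config$classify$contrasts) {
      spec <- .contrastSpec(contrast)
      rows <- meta$group %in% spec$groups
      cmeta <- meta[rows, , drop = FALSE]
      if (!is.null(spec$relabel)) {
        hit <- cmeta$group %in% names(spec$relabel)
        cmeta$group[hit] <- spec$relabel[cmeta$group[hit]]
      }
      for (mname in config$selection$metrics) {
        se <- featureTable(metricMats[[mname]][rows, , drop = FALSE], cmeta)
        cseed <- deriveSeed(config$seed,
                            1000L * match(template, TEMPLATES) +
                            100L * match(contrast, CONTRASTS) +
                            match(mname, c("eNodal", "eLocal", "cNode",
                                           "lNode")))
        preds <- stage(sprintf("loocv:%s:%s", contrast, mname),
          loocv(se, positiveClass = spec$positive,
                mode = config$classify$mode,
                nPermutations = config$classify$nPermutations,
                alpha = config$selection$alpha, seed = cseed))
        pm <- performanceMetrics(preds, spec$positive)
        perf[[length(perf) + 1L]] <-
          cbind(data.frame(template = template, contrast = contrast,
                           metric = mname, mode = config$classify$mode),
                pm)
        # whole-sample descriptive selection (which nodes differ)
        resAll <- permutationTest(
          featureMatrix(residualize(se))[cmeta$group != spec$positive, ,
                                         drop = FALSE],
          featureMatrix(residualize(se))[cmeta$group == spec$positive, ,
                                         drop = FALSE],
          nPermutations = config$selection$nPermutations,
          seed = deriveSeed(cseed, 2L), alpha = config$selection$alpha)
        selNodes[[sprintf("%s|%s|%s", template, contrast, mname)]] <-
          selectedFeatures(resAll)
      }
    }
  }

  report <- structure(list(
    performance = do.call(rbind, perf),
    smallworld = do.call(rbind, sw),
    selectedNodes = selNodes,
    features = features,
    metadata = meta,
    provenance = list(
      seed = config$seed, cohortSeed = config$cohort@seed,
      configHash = stableHash(paste(deparse(config), collapse = "")),
      package = as.character(utils::packageVersion("brainNetDx")),
      elapsedSec = as.numeric(Sys.time() - t0, units = "secs"))),
    class = "ExperimentReport")
  rownames(report$performance) <- NULL
  rownames(report$smallworld) <- NULL
  if (!is.null(outDir)) writeExperimentReport(report, outDir)
  report
}

#' Summarize small-world coefficients per group and template
#'
#' Mean and SD of gamma, lambda and sigma across the summarized subjects,
#' with a flag for mean sigma > 1 (the small-world signature).
#'
#' @param report An `ExperimentReport`.
#' @return data.frame with one row per template x group.
#' @export
summarizeSmallworld <- function(report) {
  sw <- report$smallworld
  out <- do.call(rbind, lapply(split(sw, list(sw$template, sw$group),
                                     drop = TRUE), function(d)
    data.frame(template = d$template[1], group = d$group[1],
               n = nrow(d),
               gammaMean = mean(d$gamma), gammaSd = stats::sd(d$gamma),
               lambdaMean = mean(d$lambda), lambdaSd = stats::sd(d$lambda),
               sigmaMean = mean(d$sigma), sigmaSd = stats::sd(d$sigma),
               smallWorld = mean(d$sigma) > 1)))
  rownames(out) <- NULL
  out[order(out$template, match(out$group, GROUP_LEVELS)), ]
}

#' Write an experiment report to disk
#'
#' Emits `report.json` (machine-readable), `performance.csv` and
#' `smallworld.csv` (tables mirroring the performance-grid layout),
#' `selected_nodes.csv` and `metadata.csv`, plus a small manifest.
#'
#' @param report An `ExperimentReport`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
writeExperimentReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$performance, file.path(dir, "performance.csv"),
                   row.names = FALSE)
  utils::write.csv(summarizeSmallworld(report),
                   file.path(dir, "smallworld.csv"), row.names = FALSE)
  sel <- do.call(rbind, lapply(names(report$selectedNodes), function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    nodes <- report$selectedNodes[[k]]
    if (!length(nodes)) return(NULL)
    data.frame(template = parts[1], contrast = parts[2], metric = parts[3],
               node = nodes, stringsAsFactors = FALSE)
  }))
  utils::write.csv(sel %||% data.frame(), file.path(dir, "selected_nodes.csv"),
                   row.names = FALSE)
  writeMetadata(report$metadata, file.path(dir, "metadata.csv"))
  for (template in names(report$features))
    for (mname in names(report$features[[template]]))
      utils::write.csv(report$features[[template]][[mname]],
                       file.path(dir, sprintf("features_%s_%s.csv",
                                              template, mname)))
  payload <- list(performance = report$performance,
                  smallworld = summarizeSmallworld(report),
                  selectedNodes = report$selectedNodes,
                  provenance = report$provenance)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- data.frame(
    file = c("report.json", "performance.csv", "smallworld.csv",
             "selected_nodes.csv", "metadata.csv"))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @export
print.ExperimentReport <- function(x, ...) {
  cat("ExperimentReport\n")
  cat(sprintf("  %d performance cells, %d small-world rows, %.1fs elapsed\n",
              nrow(x$performance), nrow(x$smallworld),
              x$provenance$elapsedSec))
  print(x$performance[, c("template", "contrast", "metric", "sensitivity",
                          "specificity", "accuracy")])
  invisible(x)
}
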