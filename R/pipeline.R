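#' @include synthetic.R
NULL

#' Compute a named feature (or feature group) from a suite
#'
#' Resolves the naming conventions used throughout the package:
#' `Diff-{nobin|bin}[-cor|-cvm]-{1|2|3|4|all}` for the proposed weighted
#' dynamic features of the differential dynamic subnetwork;
#' `Static-{nobin|bin}[-cvm]-{...}` for their static counterparts on the
#' weighted static member; `DegC-wt`, `ClusC-wt`, `CloseC-wt`, `BetwC-wt`,
#' `EigenC-wt` for the existing weighted centrality comparators on the
#' non-differential dynamic; and the group name `"centralities"` for all
#' five of those.
#'
#' @param suite a [SubnetworkSuite].
#' @param name feature name (see above).
#' @param roundingDecimals raw-weight distinctness.
#' @param genes genes to extract (default: all).
#' @return a [FeatureMatrix], or a named list of them for a group name.
#' @export
featureByName <- function(suite, name, roundingDecimals = 2L, genes = NULL) {
  centralNames <- c("DegC-wt", "ClusC-wt", "CloseC-wt", "BetwC-wt",
                    "EigenC-wt")
  if (name == "centralities")
    return(weightedCentralityFeatures(suite@wNetwalkDynamicNondiff, genes))
  if (name %in% centralNames)
    return(weightedCentralityFeatures(suite@wNetwalkDynamicNondiff,
                                      genes)[[name]])
  m <- regmatches(name, regexec(
    "^(Diff|Static)-(nobin|bin)(-cor|-cvm)?-(1|2|3|4|all)$", name))[[1]]
  if (!length(m))
    stop("unknown feature name '", name, "'; valid names are ",
         "Diff-{nobin|bin}[-cor|-cvm]-{1|2|3|4|all}, the Static- ",
         "counterparts, 'centralities', or one of: ",
         paste(centralNames, collapse = ", "), call. = FALSE)
  prefix <- m[2]
  encoding <- if (m[3] == "bin") "binned" else "raw"
  approach <- switch(m[4], "-cor" = 2L, "-cvm" = 3L, 1L)
  type <- if (m[5] == "all") "ALL" else paste0("T", m[5])
  if (prefix == "Static")
    return(staticCounterpartFeatures(suite@wNetwalkStaticStar, approach,
                                     type, encoding, roundingDecimals, genes))
  dyn <- suite@wNetwalkDynamic
  f <- if (approach == 1L) {
    approach1Features(dyn, type, buildVocabulary(dyn, encoding,
                                                 roundingDecimals), genes)
  } else if (approach == 2L) {
    approach2Features(dyn, type, buildVocabulary(dyn, encoding,
                                                 roundingDecimals), genes)
  } else {
    approach3Features(dyn, type, encoding, genes)
  }
  f@meta$name <- name
  f@meta$source <- "wNetWalk-Dynamic"
  f
}

#' Evaluate feature groups on a suite and compare their best models
#'
#' For each named feature group, runs the model grid
#' (features x reductions x classifiers) by cross-validation, selects the
#' best model by AUPR, compares it to a seeded label-permutation baseline,
#' and cross-tabulates the groups' true-positive and novel predictions
#' (Jaccard index, raw overlap, BH-adjusted hypergeometric p-value) plus
#' the cancer-validation precision of each group's novel predictions.
#'
#' @param suite a [SubnetworkSuite].
#' @param labels a [LabelSet] (see [assembleLabels()]).
#' @param featureGroups named list; each element a character vector of
#'   feature names (see [featureByName()]).
#' @param cancer character vector of cancer-related genes (optional).
#' @param cv a [cvConfig()].
#' @param reductions,classifiers grid axes (see [evaluateModelGrid()]).
#' @param nBaselineDraws permutation draws for the random baseline.
#' @param adjustMethod p-value adjustment method.
#' @param roundingDecimals raw-weight distinctness for the features.
#' @return a report list with per-group `grid` summaries, best models,
#'   baseline p-values, `overlaps` and `cancerValidation`.
#' @export
evaluateSuite <- function(suite, labels, featureGroups, cancer = character(),
                          cv = cvConfig(), reductions = c("None", "PCA"),
                          classifiers = c("LR", "NB", "SVM_rbf"),
                          nBaselineDraws = 30L, adjustMethod = "BH",
                          roundingDecimals = 2L) {
  genes <- c(positives(labels), negatives(labels))
  groups <- list()
  for (gname in names(featureGroups)) {
    fl <- list()
    for (fn in featureGroups[[gname]]) {
      f <- featureByName(suite, fn, roundingDecimals, genes)
      if (is.list(f) && !is(f, "FeatureMatrix")) fl <- c(fl, f)
      else fl[[fn]] <- f
    }
    grid <- evaluateModelGrid(fl, labels, cv, reductions, classifiers)
    best <- grid$results[[grid$best]]
    baseline <- randomBaseline(fl[[best@model$feature]], labels,
                               predictiveModel(best@model$feature,
                                               best@model$reduction,
                                               best@model$classifier),
                               cv, nBaselineDraws)
    groups[[gname]] <- list(
      grid = grid$summary, best = grid$best, result = best,
      baselineAupr = baseline$aupr,
      pVsBaseline = compareToBaseline(mean(best@metrics$aupr),
                                      baseline$aupr),
      truePositives = intersect(predictedPositives(best),
                                positives(labels)),
      novel = novelPredictions(best, labels))
  }
  ov <- .overlapReport(groups, labels, adjustMethod)
  cval <- vapply(groups, function(g)
    suppressMessages(cancerValidation(g$novel, cancer)), numeric(1))
  pAdj <- adjustPvalues(vapply(groups, `[[`, numeric(1), "pVsBaseline"),
                        method = adjustMethod)
  for (gname in names(groups)) groups[[gname]]$pVsBaselineAdjusted <-
    as.numeric(pAdj[gname])
  list(groups = groups, overlaps = ov, cancerValidation = cval,
       labels = list(nPositives = length(positives(labels)),
                     nNegatives = length(negatives(labels))))
}

# pairwise overlap tables over groups: true positives against the positive
# universe, novel predictions against the negative universe
.overlapReport <- function(groups, labels, adjustMethod) {
  gn <- names(groups)
  mk <- function(field, universe) {
    if (length(gn) < 2L) return(NULL)
    pairs <- utils::combn(gn, 2)
    df <- data.frame(a = pairs[1, ], b = pairs[2, ],
                     jaccard = NA_real_, overlap = NA_integer_,
                     p = NA_real_)
    for (i in seq_len(ncol(pairs))) {
      sa <- intersect(groups[[pairs[1, i]]][[field]], universe)
      sb <- intersect(groups[[pairs[2, i]]][[field]], universe)
      df$jaccard[i] <- suppressWarnings(jaccardIndex(sa, sb))
      df$overlap[i] <- length(intersect(sa, sb))
      df$p[i] <- hypergeometricOverlapTest(sa, sb, universe)
    }
    df$pAdjusted <- adjustPvalues(df$p, method = adjustMethod)
    df
  }
  list(truePositives = mk("truePositives", positives(labels)),
       novel = mk("novel", negatives(labels)))
}

#' Serialize a suite to disk (edge-list TSVs plus a JSON manifest)
#'
#' Static members become one TSV each; dynamic members one TSV per
#' snapshot under a member directory, the age label in the filename. The
#' manifest records per-member node and edge counts and the construction
#' parameters.
#'
#' @param suite a [SubnetworkSuite].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeSuite <- function(suite, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(members = list(),
                   params = list(
                     restart = suite@params$walk$restart,
                     tolerance = suite@params$walk$tolerance,
                     maxIterations = suite@params$walk$maxIterations,
                     thresholdFraction = suite@params$thresholdFraction,
                     option = suite@params$option,
                     combine = suite@params$combine))
  for (m in .suiteMembers) {
    g <- slot(suite, m)
    if (is(g, "DynamicNetwork")) {
      sub <- file.path(dir, m)
      dir.create(sub, showWarnings = FALSE)
      for (i in seq_along(g@snapshots))
        writeEdgeList(g@snapshots[[i]],
                      file.path(sub, paste0(g@ages[i], ".tsv")))
      manifest$members[[m]] <- list(
        dynamic = TRUE, weighted = g@weighted, ages = g@ages,
        nodes = vapply(g@snapshots, igraph::gorder, numeric(1)),
        edges = vapply(g@snapshots, igraph::gsize, numeric(1)))
    } else {
      writeEdgeList(g, file.path(dir, paste0(m, ".tsv")))
      manifest$members[[m]] <- list(
        dynamic = FALSE,
        weighted = "weight" %in% igraph::edge_attr_names(g),
        nodes = igraph::gorder(g), edges = igraph::gsize(g))
    }
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a suite written by [writeSuite()]
#' @param dir the suite directory.
#' @return a [SubnetworkSuite].
#' @export
readSuite <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  slots <- list()
  for (m in .suiteMembers) {
    info <- manifest$members[[m]]
    if (isTRUE(info$dynamic)) {
      agesLab <- unlist(info$ages)
      snaps <- lapply(agesLab, function(a)
        readEdgeList(file.path(dir, m, paste0(a, ".tsv")),
                     weighted = isTRUE(info$weighted)))
      slots[[m]] <- DynamicNetwork(snaps, agesLab,
                                   weighted = isTRUE(info$weighted))
    } else {
      slots[[m]] <- readEdgeList(file.path(dir, paste0(m, ".tsv")),
                                 weighted = isTRUE(info$weighted))
    }
  }
  pp <- manifest$params
  slots$params <- list(
    walk = walkParams(pp$restart, pp$tolerance, pp$maxIterations),
    thresholdFraction = pp$thresholdFraction, option = pp$option,
    epsilon = NULL, combine = pp$combine)
  do.call(methods::new, c(list("SubnetworkSuite"), slots))
}

#' Resolve a run configuration
#'
#' Reads a YAML (or JSON) configuration file, fills defaults, and returns
#' the resolved configuration; every pipeline command writes the resolved
#' configuration back next to its outputs for provenance.
#'
#' @param path configuration file, or `NULL` for pure defaults.
#' @param overrides named list overriding file values.
#' @return named list of class `runConfig`.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    stopIfNot(file.exists(path), paste0("config file not found: ", path))
    cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
           else yaml::read_yaml(path)
  }
  cfg <- utils::modifyList(cfg, overrides)
  defaults <- list(
    seed = 1L, output_dir = "dynagenet_run",
    network = NULL, expression = NULL,
    positives = NULL, aging_sources = list(), cancer = NULL,
    walk = list(restart = 0.15, tolerance = 1e-10, max_iterations = 10000L),
    threshold_fraction = 0.25, option = "option2",
    rounding_decimals = 2L,
    features = list("wNetWalk-Dynamic Proposed" = c("Diff-nobin-2"),
                    "wNetWalk-Dynamic Existing" = "centralities"),
    cv = list(folds = 5L, repeats = 10L),
    reductions = c("None", "PCA"),
    classifiers = c("LR", "NB", "SVM_rbf"),
    baseline_draws = 30L, adjust_method = "BH",
    synthetic = list())
  merged <- utils::modifyList(defaults, cfg)
  # feature groups are one user choice, not a set of defaults to extend:
  # an explicit 'features' entry replaces the default list wholesale
  if (!is.null(cfg$features)) merged$features <- cfg$features
  cfg <- merged
  class(cfg) <- "runConfig"
  cfg
}

.writeResolvedConfig <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(cfg), file.path(dir, "resolved_config.yaml"))
}

#' Pipeline commands
#'
#' `cmdSimulate()` writes a synthetic study; `cmdInfer()` builds and
#' writes the eight-member suite; `cmdFeatures()` extracts and writes the
#' requested feature matrices; `cmdEvaluate()` runs the model grids and
#' writes the JSON evaluation report. Each command writes the resolved
#' configuration next to its outputs.
#'
#' @param cfg a [readRunConfig()] list.
#' @return the primary output of the command, invisibly (the simulation,
#'   the suite, the feature list, the report).
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
cmdSimulate <- function(cfg) {
  syn <- do.call(syntheticConfig,
                 utils::modifyList(list(seed = cfg$seed), cfg$synthetic))
  sim <- simulateAgingStudy(syn)
  out <- file.path(cfg$output_dir, "synthetic")
  writeSyntheticData(sim, out)
  .writeResolvedConfig(cfg, cfg$output_dir)
  invisible(sim)
}

.loadInputs <- function(cfg) {
  stopIfNot(!is.null(cfg$network) && !is.null(cfg$expression),
            "config must set 'network' and 'expression' input paths")
  list(net = readEdgeList(cfg$network),
       expr = readExpressionTable(cfg$expression))
}

#' @rdname pipeline
#' @export
cmdInfer <- function(cfg) {
  inp <- .loadInputs(cfg)
  suite <- buildSuite(inp$net, inp$expr,
                      params = walkParams(cfg$walk$restart,
                                          cfg$walk$tolerance,
                                          cfg$walk$max_iterations),
                      thresholdFraction = cfg$threshold_fraction,
                      option = cfg$option)
  writeSuite(suite, file.path(cfg$output_dir, "suite"))
  .writeResolvedConfig(cfg, cfg$output_dir)
  invisible(suite)
}

#' @rdname pipeline
#' @param suite optionally a prebuilt [SubnetworkSuite]; read from
#'   `output_dir/suite` otherwise.
#' @export
cmdFeatures <- function(cfg, suite = NULL) {
  suite <- suite %||% readSuite(file.path(cfg$output_dir, "suite"))
  fdir <- file.path(cfg$output_dir, "features")
  dir.create(fdir, showWarnings = FALSE, recursive = TRUE)
  fl <- list()
  for (fn in unique(unlist(cfg$features))) {
    f <- featureByName(suite, fn, cfg$rounding_decimals)
    fs <- if (is(f, "FeatureMatrix")) stats::setNames(list(f), fn) else f
    for (nm in names(fs)) {
      writeFeatureMatrix(fs[[nm]], file.path(fdir, paste0(nm, ".tsv")))
      fl[[nm]] <- fs[[nm]]
    }
  }
  .writeResolvedConfig(cfg, cfg$output_dir)
  invisible(fl)
}

#' @rdname pipeline
#' @export
cmdEvaluate <- function(cfg, suite = NULL) {
  suite <- suite %||% readSuite(file.path(cfg$output_dir, "suite"))
  stopIfNot(!is.null(cfg$positives), "config must set 'positives'")
  pos <- readGeneList(cfg$positives)
  sources <- c(list(pos), lapply(cfg$aging_sources, readGeneList))
  labels <- assembleLabels(pos, sources, suite)
  cancer <- if (!is.null(cfg$cancer)) readGeneList(cfg$cancer)
            else character()
  report <- evaluateSuite(
    suite, labels, cfg$features, cancer,
    cv = cvConfig(cfg$cv$folds, cfg$cv$repeats, cfg$seed),
    reductions = unlist(cfg$reductions),
    classifiers = unlist(cfg$classifiers),
    nBaselineDraws = cfg$baseline_draws,
    adjustMethod = cfg$adjust_method,
    roundingDecimals = cfg$rounding_decimals)
  json <- .reportToJson(report)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(json, file.path(cfg$output_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  .writeResolvedConfig(cfg, cfg$output_dir)
  invisible(report)
}

.reportToJson <- function(report) {
  list(
    labels = report$labels,
    groups = lapply(report$groups, function(g) list(
      best = g$best,
      grid = g$grid,
      meanAupr = mean(g$result@metrics$aupr),
      precisionRecallF = as.list(suppressWarnings(
        precisionRecallF(g$result))),
      pVsBaseline = g$pVsBaseline,
      pVsBaselineAdjusted = g$pVsBaselineAdjusted,
      nPredictions = length(predictedPositives(g$result)),
      nTruePositives = length(g$truePositives),
      novel = g$novel)),
    overlaps = report$overlaps,
    cancerValidation = as.list(report$cancerValidation))
}
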