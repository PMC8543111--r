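#' @include prediction.R
NULL

#' Configuration of the synthetic aging study generator
#'
#' Defaults emulate a desk-scale version of the study design the package
#' targets: a heavy-tailed PPI network, an age series of expression with a
#' monotone trend planted in a subset of "aging" genes, and a roughly 1:5
#' positive:negative label imbalance.
#'
#' @param nGenes number of genes (>= 10).
#' @param edgesPerGene preferential-attachment edges added per new node
#'   (controls the edge target, roughly `edgesPerGene * nGenes`).
#' @param nAges number of ages in the expression series (>= 2).
#' @param nAgingGenes number of planted aging-related genes (< nGenes).
#' @param effectSize log-fold expression change of planted genes across
#'   the full age range (0 = no signal).
#' @param noiseSd additive Gaussian noise on the expression scale.
#' @param negativesPerPositive negatives sampled per planted positive.
#' @param cancerRatePos,cancerRateNeg probability that a positive
#'   (resp. negative) gene is also in the synthetic cancer list.
#' @param seed integer seed; the whole study is deterministic given it.
#' @return named list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(nGenes = 300L, edgesPerGene = 2L, nAges = 10L,
                            nAgingGenes = 30L, effectSize = 2,
                            noiseSd = 0.5, negativesPerPositive = 5L,
                            cancerRatePos = 0.3, cancerRateNeg = 0.1,
                            seed = 1L) {
  stopIfNot(nGenes >= 10L, "need at least 10 genes")
  stopIfNot(nAges >= 2L, "need at least 2 ages")
  stopIfNot(nAgingGenes < nGenes, "nAgingGenes must be below nGenes")
  stopIfNot(effectSize >= 0, "effectSize must be non-negative")
  stopIfNot(noiseSd > 0, "noiseSd must be positive")
  stopIfNot(edgesPerGene >= 1L && edgesPerGene < nGenes,
            "infeasible edge target")
  structure(list(nGenes = as.integer(nGenes),
                 edgesPerGene = as.integer(edgesPerGene),
                 nAges = as.integer(nAges),
                 nAgingGenes = as.integer(nAgingGenes),
                 effectSize = effectSize, noiseSd = noiseSd,
                 negativesPerPositive = as.integer(negativesPerPositive),
                 cancerRatePos = cancerRatePos,
                 cancerRateNeg = cancerRateNeg,
                 seed = as.integer(seed)),
            class = "syntheticConfig")
}

#' Generate a synthetic entire PPI network
#'
#' Seeded undirected preferential-attachment (Barabási–Albert) graph,
#' reduced to its largest connected component, so degrees are
#' heavy-tailed as in real PPI networks.
#'
#' @param cfg a [syntheticConfig()].
#' @return connected unweighted `igraph` with gene names `g0001`, ...
#' @export
generateEntireNetwork <- function(cfg) {
  set.seed(cfg$seed)
  g <- igraph::sample_pa(cfg$nGenes, m = cfg$edgesPerGene, directed = FALSE)
  igraph::V(g)$name <- sprintf("g%04d", seq_len(cfg$nGenes))
  g <- igraph::simplify(g)
  largestConnectedComponent(g)
}

#' Planted aging-related genes of a synthetic study
#'
#' A seeded sample of network genes that receive the monotone age trend.
#'
#' @param net the synthetic network.
#' @param cfg a [syntheticConfig()].
#' @return character vector of planted genes.
#' @export
plantedGenes <- function(net, cfg) {
  set.seed(cfg$seed + 1L)
  sort(sample(igraph::V(net)$name, cfg$nAgingGenes))
}

#' Generate a synthetic age-series expression table
#'
#' Baseline expression is i.i.d. lognormal per gene; planted genes get a
#' monotone exponential age trend of total magnitude `effectSize` (on the
#' log scale) so their activity and propagated edge weights drift with
#' age; additive Gaussian noise everywhere. Activity flags come from the
#' default per-age-mean rule. The signal acts on expression only — any
#' label signal in downstream features must survive the propagation and
#' feature-extraction pipeline.
#'
#' @param net the synthetic network.
#' @param cfg a [syntheticConfig()].
#' @return an [ExpressionSeries] over the network genes.
#' @export
generateExpression <- function(net, cfg) {
  genes <- sort(igraph::V(net)$name)
  planted <- plantedGenes(net, cfg)
  set.seed(cfg$seed + 2L)
  baseline <- stats::rlnorm(length(genes), meanlog = log(5), sdlog = 0.5)
  names(baseline) <- genes
  trend <- ifelse(genes %in% planted, cfg$effectSize, 0)
  agesLab <- sprintf("age%02d", seq_len(cfg$nAges))
  frac <- (seq_len(cfg$nAges) - 1) / (cfg$nAges - 1)
  m <- vapply(seq_len(cfg$nAges), function(a) {
    baseline * exp(trend * frac[a]) +
      stats::rnorm(length(genes), sd = cfg$noiseSd)
  }, numeric(length(genes)))
  dimnames(m) <- list(genes, agesLab)
  ExpressionSeries(m)
}

#' Generate synthetic labels and a synthetic cancer list
#'
#' Positives are the planted genes; negatives a seeded sample of
#' non-planted genes (`negativesPerPositive` per positive); the synthetic
#' cancer list includes each positive with probability `cancerRatePos`
#' and each negative with probability `cancerRateNeg`.
#'
#' @param cfg a [syntheticConfig()].
#' @param planted the planted gene set.
#' @param net the synthetic network.
#' @return list with `labels` (a [LabelSet]) and `cancer` (character).
#' @export
generateLabels <- function(cfg, planted, net) {
  genes <- igraph::V(net)$name
  set.seed(cfg$seed + 3L)
  nNeg <- min(cfg$negativesPerPositive * length(planted),
              length(setdiff(genes, planted)))
  neg <- sort(sample(setdiff(genes, planted), nNeg))
  cancer <- c(planted[stats::runif(length(planted)) < cfg$cancerRatePos],
              neg[stats::runif(length(neg)) < cfg$cancerRateNeg])
  list(labels = LabelSet(planted, neg), cancer = sort(cancer))
}

#' Generate a full synthetic aging study
#'
#' Network, expression series, labels and cancer list in one seeded call.
#'
#' @param cfg a [syntheticConfig()].
#' @return list with `network`, `expr`, `labels`, `cancer`, `planted`,
#'   `config`.
#' @export
simulateAgingStudy <- function(cfg = syntheticConfig()) {
  net <- generateEntireNetwork(cfg)
  expr <- generateExpression(net, cfg)
  planted <- plantedGenes(net, cfg)
  lab <- generateLabels(cfg, planted, net)
  list(network = net, expr = expr, labels = lab$labels,
       cancer = lab$cancer, planted = planted, config = cfg)
}

#' Write a synthetic study to disk in the package's input formats
#'
#' Emits `network.tsv`, `expression.tsv`, `aging_positives.txt`,
#' `non_aging_negatives.txt`, `cancer_genes.txt` and a
#' `ground_truth.json` manifest.
#'
#' @param sim a [simulateAgingStudy()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeSyntheticData <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeEdgeList(sim$network, file.path(dir, "network.tsv"))
  writeExpressionTable(sim$expr, file.path(dir, "expression.tsv"))
  writeGeneList(positives(sim$labels), file.path(dir, "aging_positives.txt"))
  writeGeneList(negatives(sim$labels),
                file.path(dir, "non_aging_negatives.txt"))
  writeGeneList(sim$cancer, file.path(dir, "cancer_genes.txt"))
  jsonlite::write_json(
    list(planted = sim$planted, config = unclass(sim$config)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
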