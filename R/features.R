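#' @include subnetworks.R
NULL

#' Construct a FeatureMatrix
#' @param genes character vector (row order).
#' @param values numeric matrix, one row per gene.
#' @param meta named list of metadata; `length` defaults to `ncol(values)`.
#' @return a [FeatureMatrix].
#' @export
FeatureMatrix <- function(genes, values, meta = list()) {
  meta$length <- meta$length %||% ncol(values)
  methods::new("FeatureMatrix", genes = as.character(genes),
               values = values, meta = meta)
}

.nbTypes <- c("T1", "T2", "T3", "T4")

# classify every edge of g by the sorted BFS distances of its endpoints
# from v: T1 = {0,1}, T2 = {1,1}, T3 = {1,2}, T4 = {2,2}.  Two-hop
# neighbors are nodes at distance exactly 2.
.edgeTypeMasks <- function(d, el) {
  du <- d[el[, 1]]; dv <- d[el[, 2]]
  a <- pmin(du, dv); b <- pmax(du, dv)
  list(T1 = a == 0 & b == 1,
       T2 = a == 1 & b == 1,
       T3 = a == 1 & b == 2,
       T4 = a == 2 & b == 2)
}

#' Edges of one neighborhood type around a node
#'
#' Four edge neighborhoods of a node v: `T1` edges from v to its one-hop
#' neighbors, `T2` edges among one-hop neighbors, `T3` edges between
#' one-hop and two-hop neighbors, `T4` edges among two-hop neighbors
#' (two-hop means shortest-path distance exactly 2 from v, hop counts
#' ignore edge weights).
#'
#' @param snap an `igraph` snapshot.
#' @param v a node name in `snap`.
#' @param type `"T1"`, `"T2"`, `"T3"` or `"T4"`.
#' @return an igraph edge sequence (possibly empty).
#' @export
neighborhoodEdges <- function(snap, v, type = .nbTypes) {
  type <- match.arg(type)
  stopIfNot(v %in% igraph::V(snap)$name, paste0("node '", v, "' not in snapshot"))
  d <- as.numeric(igraph::distances(snap, v = v, weights = NA))
  el <- igraph::as_edgelist(snap, names = FALSE)
  if (!nrow(el)) return(igraph::E(snap)[integer(0)])
  masks <- .edgeTypeMasks(d, el)
  igraph::E(snap)[which(masks[[type]])]
}

# for each requested gene, the weights of its four neighborhood edge sets
# in one snapshot; genes absent from the snapshot get four empty sets
.snapshotNeighborhoodWeights <- function(snap, genes) {
  nodes <- igraph::V(snap)$name
  present <- intersect(genes, nodes)
  out <- rep(list(list(T1 = numeric(0), T2 = numeric(0),
                       T3 = numeric(0), T4 = numeric(0))), length(genes))
  names(out) <- genes
  if (!length(present) || igraph::gsize(snap) == 0L) return(out)
  w <- igraph::E(snap)$weight
  if (is.null(w)) w <- rep(1, igraph::gsize(snap))
  el <- igraph::as_edgelist(snap, names = FALSE)
  dmat <- igraph::distances(snap, v = present, weights = NA)
  for (gidx in seq_along(present)) {
    masks <- .edgeTypeMasks(dmat[gidx, ], el)
    out[[present[gidx]]] <- lapply(masks, function(m) w[m])
  }
  out
}

#' Weight vocabulary of a weighted dynamic subnetwork
#'
#' The ordered set of distinct edge weights the count-based features are
#' defined over. `raw` rounds every weight (half away from zero) to
#' `roundingDecimals` decimals and takes the sorted distinct values over
#' all snapshots jointly; `binned` uses 200 fixed half-open bins of width 1
#' spanning [-100, 100] (the last bin closed at 100).
#'
#' @param dyn weighted [DynamicNetwork].
#' @param encoding `"raw"` or `"binned"`.
#' @param roundingDecimals decimals for raw-weight distinctness.
#' @return list of class `WeightVocabulary` with fields `encoding`,
#'   `values`, `W` and `roundingDecimals`.
#' @export
buildVocabulary <- function(dyn, encoding = c("raw", "binned"),
                            roundingDecimals = 2L) {
  encoding <- match.arg(encoding)
  stopIfNot(dyn@weighted, "vocabulary needs a weighted dynamic network")
  if (encoding == "binned") {
    return(structure(list(encoding = "binned", values = 0:199, W = 200L,
                          roundingDecimals = NA_integer_),
                     class = "WeightVocabulary"))
  }
  allW <- unlist(lapply(dyn@snapshots, function(g) igraph::E(g)$weight))
  vals <- sort(unique(roundHalfAway(allW, roundingDecimals)))
  structure(list(encoding = "raw", values = vals, W = length(vals),
                 roundingDecimals = as.integer(roundingDecimals)),
            class = "WeightVocabulary")
}

#' Bin index of a differential weight
#'
#' Bins of width 1 over [-100, 100], half-open `[a, a+1)`, with 100
#' assigned to the last bin: `floor(w + 100)`, capped at 199.
#'
#' @param w numeric vector in [-100, 100].
#' @return integer vector of bin indices in 0..199.
#' @examples
#' binIndex(c(-100, -0.5, 100))  # 0, 99, 199
#' @export
binIndex <- function(w) {
  stopIfNot(all(is.finite(w) & w >= -100 & w <= 100),
            "weights must lie in [-100, 100]")
  pmin(as.integer(floor(w + 100)), 199L)
}

#' Count vector of a weight multiset against a vocabulary
#'
#' Entry k is the number of weights equal (after rounding or binning) to
#' vocabulary entry k; entries sum to the number of weights.
#'
#' @param w numeric vector of edge weights.
#' @param vocab a [buildVocabulary()] result.
#' @return integer vector of length `vocab$W`.
#' @export
weightCountVector <- function(w, vocab) {
  if (!length(w)) return(integer(vocab$W))
  if (vocab$encoding == "binned") {
    idx <- binIndex(w) + 1L
  } else {
    idx <- match(roundHalfAway(w, vocab$roundingDecimals), vocab$values)
    stopIfNot(!anyNA(idx), "weight not present in the vocabulary")
  }
  tabulate(idx, nbins = vocab$W)
}

# shared gene universe of a dynamic network (union over snapshots)
.dynGenes <- function(dyn) {
  sort(unique(unlist(lapply(dyn@snapshots, function(g) igraph::V(g)$name))))
}

# nbw[[snapshot]][[gene]][[type]] -> weights
.collectNeighborhoods <- function(dyn, genes) {
  lapply(dyn@snapshots, .snapshotNeighborhoodWeights, genes = genes)
}

#' Approach 1: concatenated per-snapshot weight-count features
#'
#' For each gene, the count vector of its neighborhood edge weights
#' against the vocabulary, concatenated over the N snapshots (length
#' `W * N`). Type `"ALL"` concatenates, within each snapshot, the four
#' per-type count vectors (length `W * 4 * N`). A gene absent from a
#' snapshot contributes a zero block.
#'
#' @param dyn weighted [DynamicNetwork].
#' @param type `"T1"`..`"T4"` or `"ALL"`.
#' @param vocab a [buildVocabulary()] result.
#' @param genes genes to extract (default: all nodes of the dynamic).
#' @return a [FeatureMatrix].
#' @export
approach1Features <- function(dyn, type = c(.nbTypes, "ALL"), vocab,
                              genes = NULL) {
  type <- match.arg(type)
  genes <- genes %||% .dynGenes(dyn)
  nSnap <- length(dyn@snapshots)
  nbw <- .collectNeighborhoods(dyn, genes)
  types <- if (type == "ALL") .nbTypes else type
  width <- vocab$W * length(types) * nSnap
  vals <- matrix(0, nrow = length(genes), ncol = width)
  for (gi in seq_along(genes)) {
    blocks <- unlist(lapply(seq_len(nSnap), function(s) {
      unlist(lapply(types, function(tt)
        weightCountVector(nbw[[s]][[genes[gi]]][[tt]], vocab)))
    }))
    vals[gi, ] <- blocks
  }
  rownames(vals) <- genes
  FeatureMatrix(genes, vals,
                meta = list(approach = 1L, neighborhood = type,
                            encoding = vocab$encoding, N = nSnap,
                            W = vocab$W, length = width))
}

#' Approach 2: snapshot-pair correlations of weight counts
#'
#' For each gene and neighborhood type, the Pearson correlation of the
#' per-snapshot weight-count vectors between every pair of snapshots; the
#' feature is the upper triangle (pairs (i, j), i < j, ordered by i then
#' j), length `N * (N - 1) / 2`. A pair involving a zero-variance count
#' vector contributes 0. Type `"ALL"` concatenates the four per-type
#' vectors.
#'
#' @inheritParams approach1Features
#' @return a [FeatureMatrix].
#' @export
approach2Features <- function(dyn, type = c(.nbTypes, "ALL"), vocab,
                              genes = NULL) {
  type <- match.arg(type)
  nSnap <- length(dyn@snapshots)
  stopIfNot(nSnap >= 2L, "approach 2 needs at least two snapshots")
  genes <- genes %||% .dynGenes(dyn)
  nbw <- .collectNeighborhoods(dyn, genes)
  types <- if (type == "ALL") .nbTypes else type
  perType <- nSnap * (nSnap - 1L) / 2L
  ut <- which(upper.tri(matrix(0, nSnap, nSnap)), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  vals <- matrix(0, nrow = length(genes), ncol = perType * length(types))
  for (gi in seq_along(genes)) {
    feat <- unlist(lapply(types, function(tt) {
      counts <- vapply(seq_len(nSnap), function(s)
        as.numeric(weightCountVector(nbw[[s]][[genes[gi]]][[tt]], vocab)),
        numeric(vocab$W))
      if (vocab$W == 1L) counts <- matrix(counts, nrow = 1L)
      cm <- suppressWarnings(stats::cor(counts))
      cm[!is.finite(cm)] <- 0
      cm[ut]
    }))
    vals[gi, ] <- feat
  }
  rownames(vals) <- genes
  FeatureMatrix(genes, vals,
                meta = list(approach = 2L, neighborhood = type,
                            encoding = vocab$encoding, N = nSnap,
                            W = vocab$W, length = ncol(vals)))
}

#' Two-sample Cramér–von Mises statistic
#'
#' `T = n * m / (n + m)^2 * (sum over both samples of (Fa(x) - Fb(x))^2)`
#' with `Fa`, `Fb` the empirical CDFs evaluated at the sample points.
#' Symmetric in its arguments and 0 for identical samples.
#'
#' @param a,b non-empty numeric samples.
#' @return the statistic (a non-negative scalar).
#' @export
cramerVonMises <- function(a, b) {
  stopIfNot(length(a) > 0L && length(b) > 0L,
            "both samples must be non-empty")
  n <- length(a); m <- length(b)
  sa <- sort(a); sb <- sort(b)
  pts <- c(sa, sb)
  fa <- findInterval(pts, sa) / n
  fb <- findInterval(pts, sb) / m
  n * m / (n + m)^2 * sum((fa - fb)^2)
}

#' Approach 3: deviation of neighborhood weights from the global
#' weight distribution
#'
#' For each gene, snapshot and neighborhood type, the Cramér–von Mises
#' distance between the gene's neighborhood edge weights in that snapshot
#' and the pooled edge weights of the whole weighted dynamic subnetwork
#' (all edges, all snapshots); length N per type. An empty neighborhood
#' contributes 0 (no evidence of deviation). Type `"ALL"` concatenates
#' the four per-type vectors (length 4N). With `encoding = "binned"` the
#' samples are the bin indices of the weights.
#'
#' @inheritParams approach1Features
#' @param encoding `"raw"` (weights as-is) or `"binned"` (bin indices).
#' @return a [FeatureMatrix].
#' @export
approach3Features <- function(dyn, type = c(.nbTypes, "ALL"),
                              encoding = c("raw", "binned"), genes = NULL) {
  type <- match.arg(type)
  encoding <- match.arg(encoding)
  genes <- genes %||% .dynGenes(dyn)
  nSnap <- length(dyn@snapshots)
  nbw <- .collectNeighborhoods(dyn, genes)
  pooled <- unlist(lapply(dyn@snapshots, function(g) igraph::E(g)$weight))
  enc <- if (encoding == "binned") function(w) as.numeric(binIndex(w))
         else identity
  pooled <- sort(enc(pooled))
  types <- if (type == "ALL") .nbTypes else type
  vals <- matrix(0, nrow = length(genes), ncol = nSnap * length(types))
  for (gi in seq_along(genes)) {
    feat <- unlist(lapply(types, function(tt) {
      vapply(seq_len(nSnap), function(s) {
        w <- nbw[[s]][[genes[gi]]][[tt]]
        if (!length(w)) 0 else cramerVonMises(enc(w), pooled)
      }, numeric(1))
    }))
    vals[gi, ] <- feat
  }
  rownames(vals) <- genes
  FeatureMatrix(genes, vals,
                meta = list(approach = 3L, neighborhood = type,
                            encoding = encoding, N = nSnap, W = NA_integer_,
                            length = ncol(vals)))
}

.featureName <- function(prefix, approach, encoding, type) {
  encTag <- if (encoding == "binned") "bin" else "nobin"
  mid <- switch(as.character(approach), "1" = "", "2" = "-cor", "3" = "-cvm")
  typeTag <- if (type == "ALL") "all" else sub("T", "", type)
  paste0(prefix, "-", encTag, mid, "-", typeTag)
}

#' All 30 proposed weighted dynamic features
#'
#' The full grid {approach 1, 2, 3} x {T1..T4, ALL} x {raw, binned} of
#' weighted dynamic node features, named in the `Diff-{nobin|bin}`
#' convention (approach 1 unmarked, approach 2 `-cor`, approach 3 `-cvm`,
#' neighborhood `1`..`4` or `all`): 15 raw and 15 binned feature matrices.
#'
#' @param dyn the weighted differential [DynamicNetwork].
#' @param roundingDecimals raw-weight distinctness (see
#'   [buildVocabulary()]).
#' @param genes genes to extract (default: all).
#' @return named list of 30 [FeatureMatrix] objects.
#' @export
allProposedFeatures <- function(dyn, roundingDecimals = 2L, genes = NULL) {
  out <- list()
  for (encoding in c("raw", "binned")) {
    vocab <- buildVocabulary(dyn, encoding, roundingDecimals)
    for (type in c(.nbTypes, "ALL")) {
      f1 <- approach1Features(dyn, type, vocab, genes)
      f2 <- approach2Features(dyn, type, vocab, genes)
      f3 <- approach3Features(dyn, type, encoding, genes)
      for (f in list(f1, f2, f3)) {
        nm <- .featureName("Diff", f@meta$approach, encoding, type)
        f@meta$name <- nm
        f@meta$source <- "wNetWalk-Dynamic"
        out[[nm]] <- f
      }
    }
  }
  out
}

#' Static counterpart of a proposed weighted dynamic feature
#'
#' Treats a weighted static network as a one-snapshot dynamic network and
#' extracts the same feature. Approaches 1 and 3 are defined (per-type
#' lengths W and 1); an approach-2 request has no snapshot pairs at N = 1
#' and falls back to its approach-1 counterpart with a message.
#'
#' @param stat weighted `igraph` (e.g. the weighted static suite member).
#' @param approach 1, 2 or 3.
#' @param type `"T1"`..`"T4"` or `"ALL"`.
#' @param encoding `"raw"` or `"binned"`.
#' @param roundingDecimals raw-weight distinctness.
#' @param genes genes to extract (default: all).
#' @return a [FeatureMatrix] named in the `Static-` convention.
#' @export
staticCounterpartFeatures <- function(stat, approach = 1L,
                                      type = c(.nbTypes, "ALL"),
                                      encoding = c("raw", "binned"),
                                      roundingDecimals = 2L, genes = NULL) {
  type <- match.arg(type)
  encoding <- match.arg(encoding)
  dyn1 <- DynamicNetwork(list(stat), ages = "static", weighted = TRUE)
  eff <- approach
  if (approach == 2L) {
    message("approach 2 is undefined for a single snapshot; ",
            "using the approach-1 counterpart")
    eff <- 1L
  }
  f <- if (eff == 1L) {
    vocab <- buildVocabulary(dyn1, encoding, roundingDecimals)
    approach1Features(dyn1, type, vocab, genes)
  } else {
    approach3Features(dyn1, type, encoding, genes)
  }
  f@meta$name <- .featureName("Static", eff, encoding, type)
  f@meta$source <- "wNetWalk-Static*"
  f
}

# Onnela geometric-mean weighted clustering coefficient
.onnelaClustering <- function(g) {
  n <- igraph::gorder(g)
  if (n == 0L) return(numeric(0))
  A <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  mx <- max(A)
  if (mx > 0) A <- (A / mx)^(1 / 3)
  numer <- diag(A %*% A %*% A)
  k <- igraph::degree(g)
  out <- ifelse(k >= 2, numer / (k * (k - 1)), 0)
  names(out) <- igraph::V(g)$name
  out
}

#' Existing weighted dynamic centrality features
#'
#' The five comparator features on a weighted dynamic subnetwork: weighted
#' degree (strength), weighted clustering coefficient (Onnela
#' geometric-mean variant), weighted closeness and betweenness with edge
#' length 1/weight, and eigenvector centrality of the weighted adjacency.
#' Each feature is the per-snapshot value concatenated over the N
#' snapshots. Intended for the non-differential normalized dynamic, whose
#' weights are strictly positive. Disconnected snapshots use the harmonic
#' closeness variant (per reachable set) with a message.
#'
#' @param dyn weighted [DynamicNetwork] with strictly positive weights.
#' @param genes genes to extract (default: all).
#' @return named list of 5 [FeatureMatrix] objects (`DegC-wt`, `ClusC-wt`,
#'   `CloseC-wt`, `BetwC-wt`, `EigenC-wt`).
#' @export
weightedCentralityFeatures <- function(dyn, genes = NULL) {
  stopIfNot(dyn@weighted, "centrality comparators need a weighted dynamic")
  genes <- genes %||% .dynGenes(dyn)
  nSnap <- length(dyn@snapshots)
  mats <- list("DegC-wt" = NULL, "ClusC-wt" = NULL, "CloseC-wt" = NULL,
               "BetwC-wt" = NULL, "EigenC-wt" = NULL)
  for (nm in names(mats))
    mats[[nm]] <- matrix(0, nrow = length(genes), ncol = nSnap,
                         dimnames = list(genes, NULL))
  for (s in seq_len(nSnap)) {
    g <- dyn@snapshots[[s]]
    w <- igraph::E(g)$weight
    stopIfNot(all(w > 0), "centrality comparators need positive weights")
    nodes <- igraph::V(g)$name
    vals <- list()
    vals[["DegC-wt"]] <- igraph::strength(g)
    vals[["ClusC-wt"]] <- .onnelaClustering(g)
    if (igraph::is_connected(g)) {
      cl <- igraph::closeness(g, weights = 1 / w, normalized = TRUE)
    } else {
      message("snapshot ", s, " is disconnected; using harmonic closeness")
      cl <- igraph::harmonic_centrality(g, weights = 1 / w, normalized = TRUE)
    }
    vals[["CloseC-wt"]] <- cl
    vals[["BetwC-wt"]] <- igraph::betweenness(g, weights = 1 / w)
    vals[["EigenC-wt"]] <- igraph::eigen_centrality(g, weights = w)$vector
    for (nm in names(mats)) {
      v <- vals[[nm]]
      hit <- intersect(genes, nodes)
      mats[[nm]][hit, s] <- v[hit]
    }
  }
  out <- list()
  for (nm in names(mats))
    out[[nm]] <- FeatureMatrix(genes, mats[[nm]],
      meta = list(name = nm, approach = NA_integer_, neighborhood = NA,
                  encoding = "raw", N = nSnap, W = NA_integer_,
                  length = nSnap, source = "wNetWalk-Dynamic-nondiff"))
  out
}

#' Write a FeatureMatrix (and its metadata) to disk
#'
#' TSV with a `gene` column plus the feature columns, and a sidecar JSON
#' file `<path>.meta.json` holding the metadata block.
#'
#' @param fm a [FeatureMatrix].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureMatrix <- function(fm, path) {
  df <- data.frame(gene = fm@genes, fm@values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(fm@meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}
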