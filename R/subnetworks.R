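#' @include netwalk.R
NULL

#' Construct a DynamicNetwork
#'
#' @param snapshots list of `igraph` snapshots, already in age order.
#' @param ages age labels, one per snapshot.
#' @param weighted logical; if missing, inferred from the first non-empty
#'   snapshot.
#' @return a [DynamicNetwork].
#' @export
DynamicNetwork <- function(snapshots, ages = as.character(seq_along(snapshots)),
                           weighted = NA) {
  if (is.na(weighted)) {
    weighted <- FALSE
    for (g in snapshots)
      if (igraph::gsize(g) > 0L) {
        weighted <- "weight" %in% igraph::edge_attr_names(g)
        break
      }
  }
  methods::new("DynamicNetwork", snapshots = snapshots,
               ages = as.character(ages), weighted = weighted)
}

#' Induced subgraph on the active genes of one age
#'
#' Keeps the active genes present in the entire network and every entire
#' network edge with both endpoints active. Active genes absent from the
#' network are ignored with a warning.
#'
#' @param entire the entire network (`igraph`).
#' @param active character vector of active genes.
#' @return unweighted `igraph` snapshot.
#' @export
inducedSnapshot <- function(entire, active) {
  nodes <- igraph::V(entire)$name
  extra <- setdiff(active, nodes)
  if (length(extra))
    warning(length(extra), " active gene(s) absent from the network, ignored")
  igraph::induced_subgraph(entire, intersect(active, nodes))
}

#' Induced dynamic aging-specific subnetwork
#'
#' One induced snapshot per age of the expression series, in age order. An
#' age with no active genes yields an empty snapshot (retained, with a
#' warning).
#'
#' @param entire the entire network.
#' @param expr an [ExpressionSeries].
#' @return unweighted [DynamicNetwork].
#' @export
buildInducedDynamic <- function(entire, expr) {
  am <- activeMatrix(expr)
  snaps <- lapply(ages(expr), function(a) {
    act <- rownames(am)[am[, a]]
    if (!length(intersect(act, igraph::V(entire)$name)))
      warning("age '", a, "' has no active network genes; empty snapshot")
    suppressWarnings(inducedSnapshot(entire, act))
  })
  DynamicNetwork(snaps, ages(expr), weighted = FALSE)
}

#' Aggregate a dynamic network into its static counterpart
#'
#' Union of nodes and edges over all snapshots: an interaction is kept if
#' it is present in any snapshot. Weights, if any, are discarded.
#'
#' @param dyn a [DynamicNetwork].
#' @return unweighted `igraph`.
#' @export
aggregateStatic <- function(dyn) {
  allNodes <- unique(unlist(lapply(dyn@snapshots,
                                   function(g) igraph::V(g)$name)))
  ets <- lapply(dyn@snapshots, edgeTable)
  et <- unique(do.call(rbind, lapply(ets, function(x) x[, c("from", "to")])))
  igraph::graph_from_data_frame(et, directed = FALSE,
                                vertices = data.frame(name = allNodes))
}

#' Keep only highly weighted edges of a snapshot
#'
#' `top_k` keeps the `k` highest-weighted edges (all edges tied with the
#' k-th weight are kept, so the result can minimally exceed `k`);
#' `min_weight` keeps edges with weight at or above the cutoff. Nodes of
#' the result are the endpoints of the kept edges; weights are discarded.
#'
#' @param ws weighted `igraph` snapshot.
#' @param rule `"top_k"` or `"min_weight"`.
#' @param k number of edges to keep (`top_k`).
#' @param minWeight weight cutoff (`min_weight`).
#' @return unweighted `igraph`.
#' @export
thresholdSnapshot <- function(ws, rule = c("top_k", "min_weight"), k = NULL,
                              minWeight = NULL) {
  rule <- match.arg(rule)
  w <- igraph::E(ws)$weight
  stopIfNot(!is.null(w), "thresholdSnapshot needs a weighted snapshot")
  if (rule == "top_k") {
    stopIfNot(!is.null(k), "top_k rule needs k")
    if (k > length(w)) {
      warning("k exceeds the edge count; keeping all edges")
      keep <- rep(TRUE, length(w))
    } else if (k <= 0L) {
      keep <- rep(FALSE, length(w))
    } else {
      cut <- sort(w, decreasing = TRUE)[k]
      keep <- w >= cut
    }
  } else {
    stopIfNot(!is.null(minWeight), "min_weight rule needs minWeight")
    keep <- w >= minWeight
  }
  sub <- igraph::subgraph_from_edges(ws, which(keep), delete.vertices = TRUE)
  igraph::delete_edge_attr(sub, "weight")
}

#' Normalize edge weights jointly over all snapshots to [0.01, 1]
#'
#' Linear map `w' = 0.01 + 0.99 * (w - min) / (max - min)` with min and max
#' taken over every snapshot jointly, so weights stay comparable across
#' ages. All-equal weights degenerate to 1 with a warning.
#'
#' @param dyn weighted [DynamicNetwork].
#' @return weighted [DynamicNetwork] with weights in [0.01, 1].
#' @export
normalizeWeightsGlobal <- function(dyn) {
  stopIfNot(dyn@weighted, "normalizeWeightsGlobal needs a weighted dynamic")
  allW <- unlist(lapply(dyn@snapshots, function(g) igraph::E(g)$weight))
  stopIfNot(length(allW) > 0L, "no edges to normalize")
  lo <- min(allW); hi <- max(allW)
  snaps <- lapply(dyn@snapshots, function(g) {
    w <- igraph::E(g)$weight
    igraph::E(g)$weight <- if (hi == lo) {
      rep(1, length(w))
    } else {
      0.01 + 0.99 * (w - lo) / (hi - lo)
    }
    g
  })
  if (hi == lo) warning("all weights equal; normalized to 1")
  DynamicNetwork(snaps, dyn@ages, weighted = TRUE)
}

# same map for a single weighted static network
normalizeWeightsStatic <- function(g) {
  w <- igraph::E(g)$weight
  lo <- min(w); hi <- max(w)
  igraph::E(g)$weight <- if (hi == lo) rep(1, length(w))
    else 0.01 + 0.99 * (w - lo) / (hi - lo)
  g
}

#' Differential edge weight between two consecutive snapshots
#'
#' Percentage change of a normalized edge weight from snapshot i to
#' snapshot i+1: `(w2 - w1) * 100 / (w2 + w1)`. Antisymmetric under
#' argument swap, zero for equal weights and bounded in [-100, 100] for
#' strictly positive inputs.
#'
#' @param w1,w2 strictly positive weights (vectors recycle).
#' @return numeric vector of differential weights.
#' @examples
#' differentialWeight(0.2, 0.6)  # 50
#' @export
differentialWeight <- function(w1, w2) {
  stopIfNot(all(is.finite(w1) & w1 > 0) && all(is.finite(w2) & w2 > 0),
            "differential weights need strictly positive inputs")
  (w2 - w1) * 100 / (w2 + w1)
}

#' Differential weighted dynamic subnetwork
#'
#' From N normalized snapshots over a common edge set, builds N - 1
#' differential snapshots whose edge weights are the percentage changes
#' between consecutive ages ([differentialWeight()]).
#'
#' @param norm normalized weighted [DynamicNetwork] (see
#'   [normalizeWeightsGlobal()]), N >= 2 snapshots, identical edge sets.
#' @return weighted [DynamicNetwork] with N - 1 snapshots labeled
#'   `"age_i-age_{i+1}"`.
#' @export
buildDifferentialDynamic <- function(norm) {
  n <- length(norm@snapshots)
  stopIfNot(n >= 2L, "need at least two snapshots")
  keys <- lapply(norm@snapshots, edgeKeys)
  for (i in seq_len(n - 1L))
    stopIfNot(length(keys[[i]]) == length(keys[[i + 1L]]) &&
                all(keys[[i + 1L]] %in% keys[[i]]),
              "snapshots must share one edge set")
  snaps <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    g <- norm@snapshots[[i]]
    et <- edgeTable(g)
    w1 <- et$weight
    w2 <- edgeTable(norm@snapshots[[i + 1L]])$weight[
      match(keys[[i]], keys[[i + 1L]])]
    out <- igraph::graph_from_data_frame(
      data.frame(from = et$from, to = et$to,
                 weight = differentialWeight(w1, w2)),
      directed = FALSE,
      vertices = data.frame(name = igraph::V(g)$name))
    snaps[[i]] <- out
  }
  DynamicNetwork(snaps,
                 paste(norm@ages[-n], norm@ages[-1L], sep = "-"),
                 weighted = TRUE)
}

#' Collapse an expression series over all ages
#'
#' Produces a single pseudo-age series: the value is the mean (or max) of
#' the measured values over ages, and a gene is active if it is active at
#' any one or more ages.
#'
#' @param expr an [ExpressionSeries].
#' @param combine `"mean"` (default) or `"max"`.
#' @return an [ExpressionSeries] with one age, `"aggregate"`.
#' @export
aggregateExpression <- function(expr, combine = c("mean", "max")) {
  combine <- match.arg(combine)
  m <- exprValues(expr)
  f <- if (combine == "mean") function(x) mean(x, na.rm = TRUE)
       else function(x) max(x, na.rm = TRUE)
  v <- apply(m, 1L, function(x) if (all(is.na(x))) NA_real_ else f(x))
  a <- apply(activeMatrix(expr), 1L, any)
  a[is.na(v)] <- FALSE
  ev <- matrix(v, ncol = 1L, dimnames = list(rownames(m), "aggregate"))
  av <- matrix(a, ncol = 1L, dimnames = list(rownames(m), "aggregate"))
  methods::new("ExpressionSeries", ages = "aggregate", expr = ev, active = av)
}

#' Build all eight (sub)network variants
#'
#' From an entire PPI network and an age-series expression table, builds:
#' the entire network (largest connected component); the induced dynamic
#' subnetwork and its static aggregate; the propagation-based dynamic
#' subnetwork thresholded to its top edges per age and its two unweighted
#' static counterparts (aggregate, and a threshold of the weighted static
#' matched to the aggregate's edge count); the weighted differential
#' dynamic subnetwork, its non-differential normalized counterpart, and the
#' weighted static counterpart. The weighted variants keep every entire
#' network edge.
#'
#' @param entire `igraph`; reduced to its largest connected component.
#' @param expr an [ExpressionSeries].
#' @param params a [walkParams()] list.
#' @param thresholdFraction fraction of entire-network edges kept per age
#'   when thresholding the propagated snapshots (default 0.25).
#' @param option activity assignment for the walk (see
#'   [assignActivities()]).
#' @param epsilon dummy activity value; see [assignActivities()].
#' @param combine value rule for [aggregateExpression()].
#' @return a [SubnetworkSuite].
#' @export
buildSuite <- function(entire, expr, params = walkParams(),
                       thresholdFraction = 0.25,
                       option = "option2", epsilon = NULL,
                       combine = "mean") {
  entire <- largestConnectedComponent(entire)
  stopIfNot(length(ages(expr)) >= 2L, "need at least two ages")

  inducedDynamic <- buildInducedDynamic(entire, expr)
  inducedStatic <- aggregateStatic(inducedDynamic)

  rawSnaps <- lapply(ages(expr), function(a)
    netwalkWeightSnapshot(entire, expr, a, option = option, params = params,
                          epsilon = epsilon))
  rawDyn <- DynamicNetwork(rawSnaps, ages(expr), weighted = TRUE)

  k <- max(1L, round(thresholdFraction * igraph::gsize(entire)))
  nwSnaps <- lapply(rawSnaps, thresholdSnapshot, rule = "top_k", k = k)
  netwalkDynamic <- DynamicNetwork(nwSnaps, ages(expr), weighted = FALSE)
  netwalkStatic <- aggregateStatic(netwalkDynamic)

  nondiff <- normalizeWeightsGlobal(rawDyn)
  wNetwalkDynamic <- buildDifferentialDynamic(nondiff)

  aggExpr <- aggregateExpression(expr, combine = combine)
  wStaticRaw <- netwalkWeightSnapshot(entire, aggExpr, "aggregate",
                                      option = option, params = params,
                                      epsilon = epsilon)
  kStar <- igraph::gsize(netwalkStatic)
  netwalkStaticStar <- thresholdSnapshot(wStaticRaw, rule = "top_k", k = kStar)
  if (igraph::gsize(netwalkStaticStar) > kStar)
    message("ties at the cut weight: NetWalk-Static* keeps ",
            igraph::gsize(netwalkStaticStar), " edges (target ", kStar, ")")
  wNetwalkStaticStar <- normalizeWeightsStatic(wStaticRaw)

  methods::new("SubnetworkSuite",
    entire = entire,
    inducedDynamic = inducedDynamic,
    inducedStatic = inducedStatic,
    netwalkDynamic = netwalkDynamic,
    netwalkStatic = netwalkStatic,
    netwalkStaticStar = netwalkStaticStar,
    wNetwalkDynamic = wNetwalkDynamic,
    wNetwalkDynamicNondiff = nondiff,
    wNetwalkStaticStar = wNetwalkStaticStar,
    params = list(walk = params, thresholdFraction = thresholdFraction,
                  option = option, epsilon = epsilon, combine = combine))
}

#' Node sets and sizes of a suite
#'
#' `suiteNodeSets()` returns, per member, the genes the member contains (a
#' dynamic member contains the union of its snapshot nodes);
#' `suiteSizes()` the Table-style node and edge counts (dynamic members
#' report the mean over snapshots).
#'
#' @param suite a [SubnetworkSuite].
#' @return `suiteNodeSets()`: named list of character vectors;
#'   `suiteSizes()`: data.frame with columns `member`, `nodes`, `edges`.
#' @export
suiteNodeSets <- function(suite) {
  out <- lapply(.suiteMembers, function(m) {
    g <- slot(suite, m)
    if (is(g, "DynamicNetwork"))
      unique(unlist(lapply(g@snapshots, function(s) igraph::V(s)$name)))
    else igraph::V(g)$name
  })
  names(out) <- .suiteMembers
  out
}

#' @rdname suiteNodeSets
#' @export
suiteSizes <- function(suite) {
  rows <- lapply(.suiteMembers, function(m) {
    g <- slot(suite, m)
    if (is(g, "DynamicNetwork")) {
      data.frame(member = m,
                 nodes = mean(vapply(g@snapshots, igraph::gorder, numeric(1))),
                 edges = mean(vapply(g@snapshots, igraph::gsize, numeric(1))))
    } else {
      data.frame(member = m, nodes = igraph::gorder(g),
                 edges = igraph::gsize(g))
    }
  })
  do.call(rbind, rows)
}
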