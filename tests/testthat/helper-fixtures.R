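# -- small graph builders ----------------------------------------------------

toyGraph <- function(edges, weights = NULL, nodes = NULL) {
  df <- data.frame(from = edges[c(TRUE, FALSE)], to = edges[c(FALSE, TRUE)],
                   stringsAsFactors = FALSE)
  if (!is.null(weights)) df$weight <- weights
  verts <- if (is.null(nodes)) NULL else data.frame(name = nodes)
  igraph::graph_from_data_frame(df, directed = FALSE, vertices = verts)
}

triangleGraph <- function(w = NULL) toyGraph(c("a","b", "a","c", "b","c"), w)

pathGraph <- function(nodes = c("a", "b", "c"), w = NULL) {
  e <- as.vector(rbind(nodes[-length(nodes)], nodes[-1]))
  toyGraph(e, w)
}

starGraph <- function(center = "h", leaves = c("x", "y", "z"), w = NULL) {
  toyGraph(as.vector(rbind(center, leaves)), w)
}

randomConnectedGraph <- function(n, p = 0.15) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  g
}

tinyExpr <- function(m) ExpressionSeries(m)

# a small weighted dynamic network with a common edge set and seeded weights
randomWeightedDynamic <- function(nNodes = 12, nSnaps = 3, range = c(-100, 100)) {
  g <- randomConnectedGraph(nNodes, 0.3)
  snaps <- lapply(seq_len(nSnaps), function(i) {
    igraph::E(g)$weight <- stats::runif(igraph::gsize(g), range[1], range[2])
    g
  })
  DynamicNetwork(snaps, sprintf("a%d", seq_len(nSnaps)), weighted = TRUE)
}

withr_local_tempfile <- function(envir = parent.frame()) {
  f <- tempfile()
  withr::defer(unlink(f), envir = envir)
  f
}

# -- independent oracles -----------------------------------------------------

# union-find connected components
ufComponents <- function(nodes, edgePairs) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (length(edgePairs))
    for (i in seq_len(nrow(edgePairs))) {
      ra <- find(edgePairs[i, 1]); rb <- find(edgePairs[i, 2])
      if (ra != rb) parent[[ra]] <- rb
    }
  split(nodes, vapply(nodes, find, character(1)))
}

# brute-force two-sample Cramer-von Mises, straight from the formula
bruteCvm <- function(a, b) {
  n <- length(a); m <- length(b)
  Fa <- function(x) mean(a <= x)
  Fb <- function(x) mean(b <= x)
  s <- sum(vapply(a, function(x) (Fa(x) - Fb(x))^2, numeric(1))) +
       sum(vapply(b, function(x) (Fa(x) - Fb(x))^2, numeric(1)))
  n * m / (n + m)^2 * s
}

# brute-force step-wise AUPR: walk every distinct threshold
bruteAupr <- function(scores, truth) {
  th <- sort(unique(scores), decreasing = TRUE)
  prevR <- 0; area <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(sel & truth)
    P <- tp / sum(sel)
    R <- tp / sum(truth)
    area <- area + P * (R - prevR)
    prevR <- R
  }
  area
}

# exhaustive hypergeometric upper tail by enumerating all draws (|U| small)
bruteHyper <- function(a, b, universe) {
  k <- length(intersect(a, b))
  draws <- utils::combn(universe, length(b))
  hits <- apply(draws, 2, function(d) length(intersect(d, a)) >= k)
  mean(hits)
}

# Benjamini-Hochberg step-up, written out
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# dense linear solve of the restart-walk fixed point
denseStationary <- function(tm, q, r) {
  n <- length(q)
  A <- diag(n) - (1 - r) * t(as.matrix(tm))
  as.numeric(solve(A, r * q))
}
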