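#' @include utils.R AllClasses.R
NULL

#' Read an undirected PPI edge list from a TSV file
#'
#' Expects one interaction per line, `gene1<TAB>gene2` (optionally a third,
#' numeric weight column when `weighted = TRUE`). Lines starting with `#`
#' are comments. The pair (u, v) is identified with (v, u); duplicate
#' unweighted edges are collapsed, duplicate weighted edges are an error,
#' and self-loops are dropped with a message reporting their count.
#'
#' @param path path to the TSV file.
#' @param weighted logical; read a third column of edge weights.
#' @return an undirected `igraph` (edge attribute `weight` when weighted).
#' @examples
#' f <- tempfile()
#' writeLines(c("a\tb", "b\tc"), f)
#' g <- readEdgeList(f)
#' igraph::gsize(g)  # 2
#' @export
readEdgeList <- function(path, weighted = FALSE) {
  raw <- readLines(path)
  keep <- which(!grepl("^\\s*#", raw) & nzchar(trimws(raw)))
  need <- if (weighted) 3L else 2L
  parts <- strsplit(raw[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < need)
  if (length(bad))
    stop(sprintf("malformed line %d: expected %d tab-separated fields, got %d",
                 keep[bad[1]], need, nf[bad[1]]), call. = FALSE)
  from <- vapply(parts, `[[`, character(1), 1L)
  to <- vapply(parts, `[[`, character(1), 2L)
  w <- NULL
  if (weighted) {
    wchr <- vapply(parts, `[[`, character(1), 3L)
    w <- suppressWarnings(as.numeric(wchr))
    bad <- which(!is.finite(w))
    if (length(bad))
      stop(sprintf("non-numeric weight '%s' on line %d", wchr[bad[1]],
                   keep[bad[1]]), call. = FALSE)
  }
  loops <- from == to
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    from <- from[!loops]; to <- to[!loops]
    if (weighted) w <- w[!loops]
  }
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    if (weighted)
      stop("duplicate weighted edge: ", sub("\r", " - ", key[dup][1]),
           call. = FALSE)
    a <- a[!dup]; b <- b[!dup]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE), directed = FALSE)
  if (weighted) igraph::E(g)$weight <- w[!duplicated(key)]
  g
}

#' Write an edge list TSV
#'
#' Inverse of [readEdgeList()]: writes `gene1<TAB>gene2[<TAB>weight]` with
#' each unordered pair stored once (lexicographically smaller gene first).
#'
#' @param g an undirected `igraph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(g, path) {
  et <- edgeTable(g)
  lines <- if (is.null(et$weight)) {
    paste(et$from, et$to, sep = "\t")
  } else {
    paste(et$from, et$to, format(et$weight, digits = 17, scientific = TRUE,
                                 trim = TRUE), sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Largest connected component of a network
#'
#' Returns the vertex-induced subgraph on the largest component. When
#' several components tie for the largest size, the component containing
#' the lexicographically smallest member node is taken, so the result is
#' deterministic.
#'
#' @param g an `igraph`.
#' @return the `igraph` induced on the largest component.
#' @export
largestConnectedComponent <- function(g) {
  stopIfNot(igraph::gorder(g) > 0L, "network is empty")
  comp <- igraph::components(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    anchors <- vapply(best, function(k)
      min(igraph::V(g)$name[comp$membership == k]), character(1))
    best <- best[which.min(match(anchors, sort(anchors)))]
  }
  igraph::induced_subgraph(g, which(comp$membership == best))
}

#' Construct an ExpressionSeries
#'
#' @param expr numeric gene x age matrix with rownames (genes) and colnames
#'   (age labels, in age order).
#' @param activityRule how to call a gene active at an age, given the
#'   expression column for that age. Either a function
#'   `function(x) logical`, or one of `"age-mean"` (active when measured and
#'   at or above the per-age mean over measured genes; the default) or
#'   `"age-zscore"` (active when the within-age z-score is at least
#'   `zThreshold`).
#' @param zThreshold z-score cutoff for `"age-zscore"`.
#' @return an [ExpressionSeries].
#' @export
ExpressionSeries <- function(expr, activityRule = "age-mean", zThreshold = 1) {
  stopIfNot(is.matrix(expr) && is.numeric(expr),
            "expr must be a numeric matrix")
  stopIfNot(!is.null(rownames(expr)) && !is.null(colnames(expr)),
            "expr needs gene rownames and age colnames")
  rule <- if (is.function(activityRule)) activityRule
  else switch(match.arg(activityRule, c("age-mean", "age-zscore")),
    "age-mean" = function(x) !is.na(x) & x >= mean(x, na.rm = TRUE),
    "age-zscore" = function(x) {
      m <- mean(x, na.rm = TRUE); s <- stats::sd(x, na.rm = TRUE)
      if (!is.finite(s) || s == 0) return(rep(FALSE, length(x)))
      !is.na(x) & (x - m) / s >= zThreshold
    })
  active <- apply(expr, 2L, function(x) {
    a <- rule(x)
    a[is.na(a) | is.na(x)] <- FALSE
    a
  })
  if (is.null(dim(active)))  # single-gene edge case
    active <- matrix(active, nrow = nrow(expr), dimnames = dimnames(expr))
  dimnames(active) <- dimnames(expr)
  methods::new("ExpressionSeries", ages = colnames(expr), expr = expr,
               active = active)
}

#' Read a gene x age expression table
#'
#' TSV with a header row of age labels and gene identifiers in the first
#' column. Empty cells and `NA` are missing measurements; a gene with an
#' all-missing row is retained and is inactive at every age.
#'
#' @inheritParams ExpressionSeries
#' @param path path to the TSV file.
#' @return an [ExpressionSeries].
#' @export
readExpressionTable <- function(path, activityRule = "age-mean",
                                zThreshold = 1) {
  raw <- readLines(path)
  stopIfNot(length(raw) >= 2L, "expression table needs a header and data rows")
  header <- strsplit(raw[1], "\t", fixed = TRUE)[[1]]
  agesLab <- header[-1]
  parts <- strsplit(raw[-1], "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != length(header))
  if (length(bad))
    stop(sprintf("ragged row on line %d: %d fields, expected %d",
                 bad[1] + 1L, nf[bad[1]], length(header)), call. = FALSE)
  genes <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(genes))
    stop("duplicate gene row: ", genes[duplicated(genes)][1], call. = FALSE)
  vals <- t(vapply(parts, function(p) {
    suppressWarnings(as.numeric(p[-1]))
  }, numeric(length(agesLab))))
  if (length(agesLab) == 1L) vals <- matrix(vals, ncol = 1L)
  dimnames(vals) <- list(genes, agesLab)
  ExpressionSeries(vals, activityRule = activityRule, zThreshold = zThreshold)
}

#' Write an ExpressionSeries back to TSV
#' @param es an [ExpressionSeries].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeExpressionTable <- function(es, path) {
  m <- exprValues(es)
  lines <- c(paste(c("gene", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               v <- m[i, ]
               paste(c(rownames(m)[i],
                       ifelse(is.na(v), "NA",
                              format(v, digits = 17, trim = TRUE))),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain gene list (one symbol per line)
#'
#' De-duplicates while preserving case; an empty file yields an empty set
#' with a warning.
#'
#' @param path path to the text file.
#' @return character vector of gene identifiers.
#' @export
readGeneList <- function(path) {
  raw <- trimws(readLines(path))
  genes <- unique(raw[nzchar(raw)])
  if (!length(genes)) warning("gene list '", path, "' is empty")
  genes
}

#' @rdname readGeneList
#' @param genes character vector to write.
#' @export
writeGeneList <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Construct a LabelSet
#' @param positives,negatives disjoint character vectors of gene ids.
#' @return a [LabelSet].
#' @export
LabelSet <- function(positives, negatives) {
  methods::new("LabelSet", positives = unique(as.character(positives)),
               negatives = unique(as.character(negatives)))
}
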