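#' @include AllGenerics.R
NULL

#' Accessors for dynAgeNet S4 containers
#'
#' `ages()` returns the ordered age labels; `snapshots()` the list of igraph
#' snapshots of a [DynamicNetwork]; `nSnapshots()` its length;
#' `isWeighted()` the weighted flag; `exprValues()`/`activeMatrix()` the
#' expression and activity matrices of an [ExpressionSeries]; `geneIds()`
#' the gene identifiers; `positives()`/`negatives()` the classes of a
#' [LabelSet]; `featureValues()`/`featureMeta()` the matrix and metadata of
#' a [FeatureMatrix]; `suiteMember()` one member of a [SubnetworkSuite] by
#' name; `cvMetrics()` the per-repeat accuracy table and
#' `predictedPositives()` the aggregated predicted-positive gene set of a
#' [PredictionResult].
#'
#' @param x the object.
#' @param name for `suiteMember()`: one of `"entire"`, `"inducedDynamic"`,
#'   `"inducedStatic"`, `"netwalkDynamic"`, `"netwalkStatic"`,
#'   `"netwalkStaticStar"`, `"wNetwalkDynamic"`, `"wNetwalkDynamicNondiff"`,
#'   `"wNetwalkStaticStar"`.
#' @return See the individual descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("ages", "DynamicNetwork", function(x) x@ages)

#' @rdname accessors
#' @export
setMethod("ages", "ExpressionSeries", function(x) x@ages)

#' @rdname accessors
#' @export
setMethod("snapshots", "DynamicNetwork", function(x) x@snapshots)

#' @rdname accessors
#' @export
setMethod("nSnapshots", "DynamicNetwork", function(x) length(x@snapshots))

#' @rdname accessors
#' @export
setMethod("isWeighted", "DynamicNetwork", function(x) x@weighted)

#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionSeries", function(x) x@expr)

#' @rdname accessors
#' @export
setMethod("activeMatrix", "ExpressionSeries", function(x) x@active)

#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionSeries", function(x) rownames(x@expr))

#' @rdname accessors
#' @export
setMethod("geneIds", "FeatureMatrix", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("positives", "LabelSet", function(x) x@positives)

#' @rdname accessors
#' @export
setMethod("negatives", "LabelSet", function(x) x@negatives)

#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("featureMeta", "FeatureMatrix", function(x) x@meta)

.suiteMembers <- c("entire", "inducedDynamic", "inducedStatic",
                   "netwalkDynamic", "netwalkStatic", "netwalkStaticStar",
                   "wNetwalkDynamic", "wNetwalkDynamicNondiff",
                   "wNetwalkStaticStar")

#' @rdname accessors
#' @export
setMethod("suiteMember", "SubnetworkSuite", function(x, name) {
  name <- match.arg(name, .suiteMembers)
  slot(x, name)
})

#' @rdname accessors
#' @export
setMethod("cvMetrics", "PredictionResult", function(x) x@metrics)

#' @rdname accessors
#' @export
setMethod("predictedPositives", "PredictionResult", function(x) {
  # a gene counts as predicted aging-related when a strict majority of CV
  # repeats call it positive
  calls <- rowSums(x@predicted) > ncol(x@predicted) / 2
  x@genes[calls]
})

setMethod("show", "ExpressionSeries", function(object) {
  cat("ExpressionSeries:", nrow(object@expr), "genes x",
      length(object@ages), "ages\n")
  cat("  active calls:", sum(object@active), "of",
      length(object@active), "\n")
  invisible(NULL)
})

setMethod("show", "DynamicNetwork", function(object) {
  ns <- length(object@snapshots)
  cat("DynamicNetwork:", ns, "snapshots,",
      if (object@weighted) "weighted" else "unweighted", "\n")
  if (ns) {
    v <- vapply(object@snapshots, igraph::gorder, numeric(1))
    e <- vapply(object@snapshots, igraph::gsize, numeric(1))
    cat(sprintf("  mean size: %.1f nodes; %.1f edges\n", mean(v), mean(e)))
  }
  invisible(NULL)
})

setMethod("show", "LabelSet", function(object) {
  cat("LabelSet:", length(object@positives), "aging-related,",
      length(object@negatives), "non-aging-related genes\n")
  invisible(NULL)
})

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix", sprintf("'%s':", object@meta$name %||% "?"),
      length(object@genes), "genes x", ncol(object@values), "features\n")
  invisible(NULL)
})

setMethod("show", "SubnetworkSuite", function(object) {
  cat("SubnetworkSuite with", length(.suiteMembers), "members\n")
  for (m in .suiteMembers) {
    g <- slot(object, m)
    if (is(g, "DynamicNetwork")) {
      cat(sprintf("  %-24s dynamic, %d snapshots\n", m, length(g@snapshots)))
    } else {
      cat(sprintf("  %-24s %d nodes; %d edges\n", m,
                  igraph::gorder(g), igraph::gsize(g)))
    }
  }
  invisible(NULL)
})

setMethod("show", "PredictionResult", function(object) {
  cat("PredictionResult:", length(object@genes), "labeled genes,",
      ncol(object@scores), "CV repeats\n")
  cat(sprintf("  mean AUPR %.3f, precision %.3f, recall %.3f, F %.3f\n",
              mean(object@metrics$aupr), mean(object@metrics$precision),
              mean(object@metrics$recall), mean(object@metrics$fscore)))
  invisible(NULL)
})
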