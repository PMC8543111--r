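#' @import methods
#' @importFrom igraph is_igraph gorder gsize V E edge_attr is_weighted
NULL

setOldClass("igraph")

#' ExpressionSeries: gene expression across an ordered series of ages
#'
#' Container for a gene x age expression matrix together with per-age
#' activity calls ("is this gene significantly expressed at this age?").
#' Missing measurements are `NA` in `expr` and force `active = FALSE`.
#'
#' @slot ages character vector of age labels, in increasing age order.
#' @slot expr numeric matrix, genes in rows, ages in columns (may contain
#'   `NA` for unmeasured gene/age combinations).
#' @slot active logical matrix of the same dimension; `TRUE` only where a
#'   finite expression value is present.
#'
#' @seealso [readExpressionTable()], [aggregateExpression()]
#' @export
setClass("ExpressionSeries",
  representation(ages = "character", expr = "matrix", active = "matrix"))

setValidity("ExpressionSeries", function(object) {
  msg <- character()
  if (!is.numeric(object@expr)) msg <- c(msg, "expr must be numeric")
  if (!is.logical(object@active)) msg <- c(msg, "active must be logical")
  if (!identical(dim(object@expr), dim(object@active)))
    msg <- c(msg, "expr and active must have identical dimensions")
  if (ncol(object@expr) != length(object@ages))
    msg <- c(msg, "number of columns must equal number of ages")
  if (anyDuplicated(object@ages))
    msg <- c(msg, "age labels must be unique")
  if (anyDuplicated(rownames(object@expr)))
    msg <- c(msg, "gene identifiers must be unique")
  if (any(object@active & is.na(object@expr)))
    msg <- c(msg, "a gene cannot be active at an age with missing expression")
  if (length(msg)) msg else TRUE
})

#' DynamicNetwork: an age-ordered sequence of network snapshots
#'
#' A dynamic (sub)network is a list of igraph snapshots, one per age label,
#' all either weighted (edge attribute `weight`) or unweighted.
#'
#' @slot snapshots list of `igraph` objects.
#' @slot ages character vector of age labels, one per snapshot, strictly
#'   ordered (their order is the age order).
#' @slot weighted logical scalar; must agree with every snapshot.
#'
#' @seealso [buildInducedDynamic()], [buildDifferentialDynamic()]
#' @export
setClass("DynamicNetwork",
  representation(snapshots = "list", ages = "character", weighted = "logical"))

setValidity("DynamicNetwork", function(object) {
  msg <- character()
  if (length(object@snapshots) != length(object@ages))
    msg <- c(msg, "one age label per snapshot is required")
  if (anyDuplicated(object@ages))
    msg <- c(msg, "age labels must be unique")
  if (length(object@weighted) != 1L || is.na(object@weighted))
    msg <- c(msg, "weighted must be TRUE or FALSE")
  ok <- vapply(object@snapshots, igraph::is_igraph, logical(1))
  if (!all(ok)) {
    msg <- c(msg, "every snapshot must be an igraph object")
  } else if (length(object@snapshots) && length(object@weighted) == 1L &&
             !is.na(object@weighted)) {
    hasw <- vapply(object@snapshots,
                   function(g) "weight" %in% igraph::edge_attr_names(g),
                   logical(1))
    empt <- vapply(object@snapshots, function(g) igraph::gsize(g) == 0L,
                   logical(1))
    if (object@weighted && !all(hasw | empt))
      msg <- c(msg, "weighted DynamicNetwork requires edge weights in every non-empty snapshot")
    if (!object@weighted && any(hasw & !empt))
      msg <- c(msg, "unweighted DynamicNetwork must not carry edge weights")
  }
  if (length(msg)) msg else TRUE
})

#' LabelSet: aging-related (positive) and non-aging-related (negative) genes
#'
#' @slot positives character vector of aging-related gene identifiers.
#' @slot negatives character vector of non-aging-related gene identifiers;
#'   disjoint from `positives`.
#'
#' @seealso [assembleLabels()]
#' @export
setClass("LabelSet",
  representation(positives = "character", negatives = "character"))

setValidity("LabelSet", function(object) {
  msg <- character()
  if (anyDuplicated(object@positives) || anyDuplicated(object@negatives))
    msg <- c(msg, "label sets must not contain duplicates")
  if (length(intersect(object@positives, object@negatives)))
    msg <- c(msg, "positives and negatives must be disjoint")
  if (length(msg)) msg else TRUE
})

#' FeatureMatrix: per-gene numeric feature vectors with provenance metadata
#'
#' @slot genes character vector of gene identifiers (row order of `values`).
#' @slot values numeric matrix, one row per gene.
#' @slot meta named list with at least `name`, `approach`, `neighborhood`,
#'   `encoding`, `N`, `W`, `source` and `length`; `length` must equal
#'   `ncol(values)`.
#'
#' @export
setClass("FeatureMatrix",
  representation(genes = "character", values = "matrix", meta = "list"))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@genes))
    msg <- c(msg, "one row per gene is required")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "gene identifiers must be unique")
  if (!is.null(object@meta$length) &&
      object@meta$length != ncol(object@values))
    msg <- c(msg, "declared feature length disagrees with the matrix width")
  if (length(msg)) msg else TRUE
})

#' SubnetworkSuite: the eight (sub)network variants built from one entire
#' PPI network and one expression series
#'
#' Members: the entire network; induced dynamic/static subnetworks; the
#' thresholded propagation-based dynamic subnetwork and its two unweighted
#' static counterparts; the weighted differential dynamic subnetwork, its
#' non-differential (normalized) counterpart, and the weighted static
#' counterpart.
#'
#' @slot entire unweighted `igraph`; largest connected component of the input.
#' @slot inducedDynamic,netwalkDynamic unweighted [DynamicNetwork]s.
#' @slot inducedStatic,netwalkStatic,netwalkStaticStar unweighted `igraph`s.
#' @slot wNetwalkDynamic weighted [DynamicNetwork] of differential snapshots
#'   (N - 1 snapshots for N ages).
#' @slot wNetwalkDynamicNondiff weighted [DynamicNetwork] of globally
#'   normalized snapshots (N snapshots).
#' @slot wNetwalkStaticStar weighted `igraph` (normalized weights).
#' @slot params list of construction parameters (walk, threshold, epsilon).
#'
#' @seealso [buildSuite()]
#' @export
setClass("SubnetworkSuite",
  representation(
    entire = "igraph",
    inducedDynamic = "DynamicNetwork",
    inducedStatic = "igraph",
    netwalkDynamic = "DynamicNetwork",
    netwalkStatic = "igraph",
    netwalkStaticStar = "igraph",
    wNetwalkDynamic = "DynamicNetwork",
    wNetwalkDynamicNondiff = "DynamicNetwork",
    wNetwalkStaticStar = "igraph",
    params = "list"))

setValidity("SubnetworkSuite", function(object) {
  msg <- character()
  n <- length(object@wNetwalkDynamicNondiff@snapshots)
  if (n >= 2L && length(object@wNetwalkDynamic@snapshots) != n - 1L)
    msg <- c(msg, "differential dynamic must have one snapshot fewer than the normalized dynamic")
  if (!object@wNetwalkDynamic@weighted || !object@wNetwalkDynamicNondiff@weighted)
    msg <- c(msg, "wNetwalk dynamics must be weighted")
  if (object@inducedDynamic@weighted || object@netwalkDynamic@weighted)
    msg <- c(msg, "induced and thresholded dynamics must be unweighted")
  if (length(msg)) msg else TRUE
})

#' PredictionResult: cross-validated predictions and accuracy for one model
#'
#' @slot scores numeric matrix (genes x repeats) of out-of-fold scores.
#' @slot predicted logical matrix (genes x repeats) of out-of-fold hard calls.
#' @slot genes character vector of labeled genes (row order).
#' @slot truth logical vector; `TRUE` for aging-related genes.
#' @slot metrics data.frame with one row per repeat: `aupr`, `precision`,
#'   `recall`, `fscore`.
#' @slot model list describing the model (feature, reduction, classifier).
#'
#' @export
setClass("PredictionResult",
  representation(scores = "matrix", predicted = "matrix", genes = "character",
                 truth = "logical", metrics = "data.frame", model = "list"))

setValidity("PredictionResult", function(object) {
  msg <- character()
  if (nrow(object@scores) != length(object@genes) ||
      nrow(object@predicted) != length(object@genes))
    msg <- c(msg, "scores and predictions need one row per labeled gene")
  if (length(object@truth) != length(object@genes))
    msg <- c(msg, "truth needs one entry per labeled gene")
  if (length(msg)) msg else TRUE
})
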