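#' @include AllClasses.R
NULL

#' @export
setGeneric("ages", function(x) standardGeneric("ages"))

#' @export
setGeneric("snapshots", function(x) standardGeneric("snapshots"))

#' @export
setGeneric("nSnapshots", function(x) standardGeneric("nSnapshots"))

#' @export
setGeneric("isWeighted", function(x) standardGeneric("isWeighted"))

#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @export
setGeneric("activeMatrix", function(x) standardGeneric("activeMatrix"))

#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @export
setGeneric("positives", function(x) standardGeneric("positives"))

#' @export
setGeneric("negatives", function(x) standardGeneric("negatives"))

#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @export
setGeneric("featureMeta", function(x) standardGeneric("featureMeta"))

#' @export
setGeneric("suiteMember", function(x, name) standardGeneric("suiteMember"))

#' @export
setGeneric("cvMetrics", function(x) standardGeneric("cvMetrics"))

#' @export
setGeneric("predictedPositives", function(x) standardGeneric("predictedPositives"))
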