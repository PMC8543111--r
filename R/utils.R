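`%||%` <- function(a, b) if (is.null(a)) b else a

# round half away from zero (base round() rounds half to even); a relative
# epsilon guards against values like 1.235 that are stored just below the
# midpoint in binary floating point
roundHalfAway <- function(x, digits = 0L) {
  p <- 10^digits
  y <- x * p
  eps <- abs(y) * .Machine$double.eps * 4 + 1e-9
  sign(x) * floor(abs(y) + 0.5 + eps) / p
}

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)

# unify snapshot/graph edge table as a data.frame(from, to[, weight]) with
# from < to lexicographically
edgeTable <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el)) {
    swap <- el[, 1] > el[, 2]
    tmp <- el[swap, 1]
    el[swap, 1] <- el[swap, 2]
    el[swap, 2] <- tmp
  }
  out <- data.frame(from = el[, 1], to = el[, 2],
                    stringsAsFactors = FALSE)
  if ("weight" %in% igraph::edge_attr_names(g))
    out$weight <- igraph::E(g)$weight
  out
}

edgeKeys <- function(g) {
  et <- edgeTable(g)
  paste(et$from, et$to, sep = "\r")
}
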