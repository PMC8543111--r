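#' @include utils.R io.R
#' @importFrom Matrix sparseMatrix Diagonal rowSums t crossprod
NULL

#' Random-walk-with-restart parameters
#'
#' @param restart restart probability, strictly inside (0, 1). 0.15 is the
#'   conventional restart-walk default.
#' @param tolerance L1 convergence tolerance of the power iteration.
#' @param maxIterations iteration cap; exceeding it is an error.
#' @return a named list of class `walkParams`.
#' @export
walkParams <- function(restart = 0.15, tolerance = 1e-10,
                       maxIterations = 10000L) {
  stopIfNot(restart > 0 && restart < 1,
            "restart probability must be strictly inside (0, 1)")
  stopIfNot(tolerance > 0, "tolerance must be positive")
  stopIfNot(maxIterations >= 1, "maxIterations must be positive")
  structure(list(restart = restart, tolerance = tolerance,
                 maxIterations = as.integer(maxIterations)),
            class = "walkParams")
}

#' Assign positive activity values to every network node for one age
#'
#' Option 1 gives measured expression values only to the genes called
#' active at the age and a small dummy value to every other node; option 2
#' gives measured expression values to every measured gene (active or not)
#' and the dummy value only to unmeasured network nodes. Values are then
#' shifted, if necessary, so the minimum is at least `epsilon`, keeping all
#' node values strictly positive as the walk requires.
#'
#' @param expr an [ExpressionSeries].
#' @param age one of `ages(expr)`.
#' @param net the entire network (`igraph`).
#' @param option `"option2"` (default, the better-performing variant) or
#'   `"option1"`.
#' @param epsilon dummy value for nodes without usable expression; default
#'   is 0.01 times the smallest positive measured value at that age.
#' @return named numeric vector over `V(net)`, all values > 0, with
#'   attributes `option` and `epsilon`.
#' @export
assignActivities <- function(expr, age, net, option = c("option2", "option1"),
                             epsilon = NULL) {
  option <- match.arg(option)
  stopIfNot(age %in% ages(expr), paste0("age '", age, "' not in the series"))
  nodes <- igraph::V(net)$name
  ev <- exprValues(expr)[, age]
  av <- activeMatrix(expr)[, age]
  if (is.null(epsilon)) {
    pos <- ev[is.finite(ev) & ev > 0]
    epsilon <- if (length(pos)) 0.01 * min(pos) else 0.01
  }
  stopIfNot(is.finite(epsilon) && epsilon > 0, "epsilon must be positive")
  vals <- rep(epsilon, length(nodes))
  names(vals) <- nodes
  measured <- intersect(nodes, names(ev)[is.finite(ev)])
  if (option == "option1") {
    act <- intersect(nodes, names(av)[av])
    vals[act] <- ev[act]
  } else {
    vals[measured] <- ev[measured]
  }
  if (min(vals) < epsilon) vals <- vals + (epsilon - min(vals))
  attr(vals, "option") <- option
  attr(vals, "epsilon") <- epsilon
  vals
}

#' Activity-biased transition matrix
#'
#' Row-stochastic matrix with `T[i, j] = value(j) / sum(value over
#' neighbors of i)` for neighbors j of i, 0 elsewhere: the walker moves
#' preferentially toward highly active neighbors.
#'
#' @param net connected `igraph`.
#' @param activities named positive vector over all nodes (see
#'   [assignActivities()]).
#' @return sparse `dgCMatrix` with rows and columns named by node.
#' @export
transitionMatrix <- function(net, activities) {
  nodes <- igraph::V(net)$name
  stopIfNot(all(nodes %in% names(activities)),
            "every network node needs an activity value")
  vals <- activities[nodes]
  stopIfNot(all(is.finite(vals) & vals > 0),
            "activity values must be finite and strictly positive")
  stopIfNot(igraph::is_connected(net),
            "network must be connected (run largestConnectedComponent first)")
  el <- igraph::as_edgelist(g <- net, names = FALSE)
  i <- c(el[, 1], el[, 2])
  j <- c(el[, 2], el[, 1])
  w <- vals[j]
  denom <- as.numeric(tapply(w, factor(i, levels = seq_along(nodes)), sum))
  tm <- Matrix::sparseMatrix(i = i, j = j, x = w / denom[i],
                             dims = c(length(nodes), length(nodes)),
                             dimnames = list(nodes, nodes))
  tm
}

#' Stationary distribution of the restart walk
#'
#' Power iteration on `p <- (1 - r) * t(T) %*% p + r * q`, with restart
#' distribution `q` proportional to the node activities, started at `q`.
#' Converges when the L1 change drops to `tolerance`.
#'
#' @param tm row-stochastic transition matrix from [transitionMatrix()].
#' @param activities the activity vector (defines `q`).
#' @param params a [walkParams()] list.
#' @return named probability vector (sums to 1), with attribute `residual`
#'   (final L1 change) and `iterations`.
#' @export
stationaryDistribution <- function(tm, activities, params = walkParams()) {
  nodes <- rownames(tm)
  vals <- activities[nodes]
  q <- vals / sum(vals)
  r <- params$restart
  tmt <- Matrix::t(tm)
  p <- q
  for (it in seq_len(params$maxIterations)) {
    pNew <- as.numeric((1 - r) * (tmt %*% p)) + r * q
    res <- sum(abs(pNew - p))
    p <- pNew
    if (res <= params$tolerance) {
      p <- p / sum(p)
      names(p) <- nodes
      attr(p, "residual") <- res
      attr(p, "iterations") <- it
      return(p)
    }
  }
  stop(sprintf("power iteration did not converge in %d iterations (residual %.3e)",
               params$maxIterations, res), call. = FALSE)
}

#' Edge flux of the stationary walk
#'
#' The directed flux along i -> j is `p(i) * (1 - r) * T(i, j)`; the weight
#' of the undirected edge {i, j} is the sum of the two directed fluxes.
#' Restart mass is excluded, so the weights over all edges sum to `1 - r`.
#'
#' @param net the network the walk ran on.
#' @param tm its transition matrix.
#' @param p stationary distribution from [stationaryDistribution()].
#' @param params the [walkParams()] used.
#' @return `net` with edge attribute `weight` set to the flux, and graph
#'   attributes `stationary` (p) and `restart`.
#' @export
edgeFlux <- function(net, tm, p, params = walkParams()) {
  r <- params$restart
  el <- igraph::as_edgelist(net, names = FALSE)
  flux <- p[el[, 1]] * (1 - r) * tm[cbind(el[, 1], el[, 2])] +
          p[el[, 2]] * (1 - r) * tm[cbind(el[, 2], el[, 1])]
  out <- net
  igraph::E(out)$weight <- as.numeric(flux)
  out <- igraph::set_graph_attr(out, "restart", r)
  out <- igraph::set_graph_attr(out, "stationary", p)
  out
}

#' Age-specific weighted snapshot by network propagation
#'
#' Composition of [assignActivities()], [transitionMatrix()],
#' [stationaryDistribution()] and [edgeFlux()]: every edge of the entire
#' network receives an age-specific propagated weight.
#'
#' @inheritParams assignActivities
#' @param params a [walkParams()] list.
#' @return weighted `igraph` over all edges of `net`.
#' @export
netwalkWeightSnapshot <- function(net, expr, age,
                                  option = c("option2", "option1"),
                                  params = walkParams(), epsilon = NULL) {
  act <- assignActivities(expr, age, net, option = option, epsilon = epsilon)
  tm <- transitionMatrix(net, act)
  p <- stationaryDistribution(tm, act, params)
  edgeFlux(net, tm, p, params)
}
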