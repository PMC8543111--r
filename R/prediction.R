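#' @include features.R
NULL

#' Cross-validation configuration
#'
#' @param nFolds stratified folds (>= 2).
#' @param nRepeats CV repeats (>= 1).
#' @param seed integer seed; every random choice in the CV derives from it.
#' @param decisionThreshold probability cutoff for hard calls of the
#'   probabilistic classifiers.
#' @return a named list of class `cvConfig`.
#' @export
cvConfig <- function(nFolds = 5L, nRepeats = 10L, seed = 1L,
                     decisionThreshold = 0.5) {
  stopIfNot(nFolds >= 2L, "need at least two folds")
  stopIfNot(nRepeats >= 1L, "need at least one repeat")
  structure(list(nFolds = as.integer(nFolds), nRepeats = as.integer(nRepeats),
                 seed = as.integer(seed),
                 decisionThreshold = decisionThreshold),
            class = "cvConfig")
}

#' Specify a predictive model
#'
#' A model is a feature, a dimensionality-reduction choice and a
#' classifier; its name follows the `"X+Y+Z"` convention.
#'
#' @param feature name of the feature matrix the model runs on.
#' @param reduction `"None"` or `"PCA"` (components explaining >= 90\%
#'   of training-fold variance).
#' @param classifier `"LR"` (logistic regression), `"NB"` (Gaussian naive
#'   Bayes) or `"SVM_rbf"` (SVM with radial kernel).
#' @return a named list of class `predictiveModel`.
#' @export
predictiveModel <- function(feature, reduction = c("None", "PCA"),
                            classifier = c("LR", "NB", "SVM_rbf")) {
  reduction <- match.arg(reduction)
  classifier <- match.arg(classifier)
  structure(list(feature = feature, reduction = reduction,
                 classifier = classifier,
                 name = paste(feature, reduction,
                              sub("_rbf", "-rbf", classifier), sep = "+")),
            class = "predictiveModel")
}

# stratified fold assignment; error when a fold would lack positives
.stratifiedFolds <- function(truth, nFolds) {
  stopIfNot(sum(truth) >= nFolds,
            "too few positives for the requested number of folds; reduce folds")
  stopIfNot(sum(!truth) >= nFolds,
            "too few negatives for the requested number of folds; reduce folds")
  fold <- integer(length(truth))
  fold[truth] <- sample(rep_len(seq_len(nFolds), sum(truth)))
  fold[!truth] <- sample(rep_len(seq_len(nFolds), sum(!truth)))
  fold
}

# training-fold preprocessing: drop zero-variance columns, center/scale,
# optional PCA to >= 90% variance; returns transform closure
.fitPreprocess <- function(x, reduction) {
  sds <- apply(x, 2L, stats::sd)
  keep <- which(is.finite(sds) & sds > 0)
  if (!length(keep)) keep <- 1L  # degenerate: keep one constant column
  mu <- colMeans(x[, keep, drop = FALSE])
  sd1 <- pmax(sds[keep], .Machine$double.eps)
  rot <- NULL
  if (reduction == "PCA" && length(keep) > 1L) {
    xs <- scale(x[, keep, drop = FALSE], center = mu, scale = sd1)
    pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    ncomp <- which(cum >= 0.9)[1]
    rot <- pc$rotation[, seq_len(ncomp), drop = FALSE]
  }
  function(newx) {
    xs <- scale(newx[, keep, drop = FALSE], center = mu, scale = sd1)
    if (!is.null(rot)) xs %*% rot else xs
  }
}

# fit one classifier on (x, truth) and score a test matrix; returns
# list(score = numeric, call = logical); scores are probabilities for
# LR/NB (cutoff `thr`), signed margins for the SVM (cutoff 0)
.fitScore <- function(x, truth, xt, classifier, thr) {
  n <- length(truth)
  if (classifier == "LR") {
    # class-balanced case weights against the label imbalance
    wts <- ifelse(truth, n / (2 * sum(truth)), n / (2 * sum(!truth)))
    fit <- suppressWarnings(stats::glm.fit(
      x = cbind(1, x), y = as.numeric(truth), weights = wts,
      family = stats::binomial()))
    beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    score <- as.numeric(stats::plogis(cbind(1, xt) %*% beta))
    list(score = score, call = score >= thr)
  } else if (classifier == "NB") {
    y <- factor(ifelse(truth, "pos", "neg"), levels = c("neg", "pos"))
    fit <- e1071::naiveBayes(as.data.frame(x), y)
    pr <- stats::predict(fit, as.data.frame(xt), type = "raw",
                         threshold = 1e-3, eps = 1e-9)
    score <- pr[, "pos"]
    list(score = score, call = score >= thr)
  } else {
    y <- factor(ifelse(truth, "pos", "neg"), levels = c("neg", "pos"))
    cw <- c(neg = n / (2 * sum(!truth)), pos = n / (2 * sum(truth)))
    fit <- e1071::svm(x, y, kernel = "radial", scale = FALSE,
                      class.weights = cw)
    pred <- stats::predict(fit, xt, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    score <- as.numeric(dv[, 1])
    # orient the margin so that larger means more aging-related
    if (!startsWith(colnames(dv)[1], "pos")) score <- -score
    list(score = score, call = score > 0)
  }
}

#' Cross-validated evaluation of one predictive model
#'
#' Stratified k-fold cross-validation repeated `nRepeats` times. All
#' preprocessing (zero-variance filtering, standardization, PCA) is fitted
#' on training folds only. Every labeled gene is scored exactly once per
#' repeat, out of fold; per-repeat AUPR, precision, recall and F-score are
#' recorded.
#'
#' @param fm a [FeatureMatrix] covering all labeled genes.
#' @param labels a [LabelSet].
#' @param model a [predictiveModel()].
#' @param cv a [cvConfig()].
#' @return a [PredictionResult].
#' @export
runCrossValidation <- function(fm, labels, model, cv = cvConfig()) {
  genes <- c(positives(labels), negatives(labels))
  missing <- setdiff(genes, geneIds(fm))
  if (length(missing))
    stop("labeled genes missing from the feature matrix: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...", call. = FALSE)
  truth <- genes %in% positives(labels)
  x <- featureValues(fm)[match(genes, geneIds(fm)), , drop = FALSE]
  scores <- matrix(NA_real_, length(genes), cv$nRepeats)
  calls <- matrix(NA, length(genes), cv$nRepeats)
  metrics <- data.frame(aupr = numeric(cv$nRepeats),
                        precision = numeric(cv$nRepeats),
                        recall = numeric(cv$nRepeats),
                        fscore = numeric(cv$nRepeats))
  for (rep in seq_len(cv$nRepeats)) {
    set.seed(cv$seed + 7907L * (rep - 1L))
    fold <- .stratifiedFolds(truth, cv$nFolds)
    for (k in seq_len(cv$nFolds)) {
      tr <- fold != k
      prep <- .fitPreprocess(x[tr, , drop = FALSE], model$reduction)
      fs <- .fitScore(prep(x[tr, , drop = FALSE]), truth[tr],
                      prep(x[!tr, , drop = FALSE]), model$classifier,
                      cv$decisionThreshold)
      scores[!tr, rep] <- fs$score
      calls[!tr, rep] <- fs$call
    }
    metrics$aupr[rep] <- aupr(scores[, rep], truth)
    prf <- .prfFromCalls(calls[, rep], truth, warn = FALSE)
    metrics$precision[rep] <- prf[1]
    metrics$recall[rep] <- prf[2]
    metrics$fscore[rep] <- prf[3]
  }
  methods::new("PredictionResult", scores = scores, predicted = calls,
               genes = genes, truth = truth, metrics = metrics,
               model = unclass(model))
}

#' Area under the precision-recall curve
#'
#' Step-wise (interpolation-free) AUPR: ranks genes by decreasing score,
#' walks the thresholds at each distinct score (tied scores enter
#' together), and sums precision times the recall increment. With all
#' scores equal this reduces to the positive-class prevalence.
#'
#' @param scores numeric scores, larger meaning more likely positive.
#' @param truth logical labels.
#' @return AUPR in [0, 1].
#' @export
aupr <- function(scores, truth) {
  stopIfNot(length(scores) == length(truth), "scores and labels must align")
  stopIfNot(any(truth), "AUPR needs at least one positive")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- truth[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); npred <- seq_along(y)
  last <- which(!duplicated(grp, fromLast = TRUE))
  prec <- tp[last] / npred[last]
  rec <- tp[last] / sum(truth)
  sum(prec * diff(c(0, rec)))
}

.prfFromCalls <- function(calls, truth, warn = TRUE) {
  tp <- sum(calls & truth)
  fp <- sum(calls & !truth)
  fn <- sum(!calls & truth)
  if (tp + fp == 0) {
    if (warn) warning("no predicted positives; precision/recall/F set to 0")
    return(c(precision = 0, recall = 0, fscore = 0))
  }
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, fscore = f)
}

#' Precision, recall and F-score of the aggregated hard predictions
#'
#' Aggregation across repeats: a gene is predicted positive when a strict
#' majority of repeats call it positive. With no predicted positives all
#' three measures are 0, with a warning.
#'
#' @param result a [PredictionResult].
#' @return named numeric vector `precision`, `recall`, `fscore`.
#' @export
precisionRecallF <- function(result) {
  calls <- result@genes %in% predictedPositives(result)
  .prfFromCalls(calls, result@truth)
}

#' Pick the best model by mean AUPR
#'
#' Argmax of the mean AUPR over repeats; exact ties break toward the
#' higher mean F-score, then the simpler model (`None` before `PCA`,
#' `LR` before `NB` before `SVM_rbf`).
#'
#' @param results named list of [PredictionResult]s.
#' @return the name of the winning model.
#' @export
selectBestModel <- function(results) {
  stopIfNot(length(results) >= 1L, "no models to select from")
  auprs <- vapply(results, function(r) mean(r@metrics$aupr), numeric(1))
  fs <- vapply(results, function(r) mean(r@metrics$fscore), numeric(1))
  redRank <- vapply(results, function(r)
    match(r@model$reduction, c("None", "PCA")), numeric(1))
  clsRank <- vapply(results, function(r)
    match(r@model$classifier, c("LR", "NB", "SVM_rbf")), numeric(1))
  ord <- order(-auprs, -fs, redRank, clsRank)
  names(results)[ord[1]]
}

#' Permutation (random) baseline for a model
#'
#' Re-runs the cross-validation with the gene labels randomly permuted
#' (seeded), `nDraws` times, yielding the null distribution of every
#' accuracy measure under "no association between features and labels".
#'
#' @param fm,labels,model,cv as in [runCrossValidation()].
#' @param nDraws number of label permutations.
#' @param nRepeats CV repeats per draw (default 1; the draw dimension
#'   already averages over fold randomness).
#' @return data.frame with one row per draw: `aupr`, `precision`,
#'   `recall`, `fscore` (means over the draw's repeats).
#' @export
randomBaseline <- function(fm, labels, model, cv = cvConfig(), nDraws = 100L,
                           nRepeats = 1L) {
  genes <- c(positives(labels), negatives(labels))
  nPos <- length(positives(labels))
  out <- data.frame(aupr = numeric(nDraws), precision = numeric(nDraws),
                    recall = numeric(nDraws), fscore = numeric(nDraws))
  for (d in seq_len(nDraws)) {
    set.seed(cv$seed + 104729L + d)
    permPos <- sample(genes, nPos)
    permLabels <- LabelSet(permPos, setdiff(genes, permPos))
    cvd <- cvConfig(cv$nFolds, nRepeats, cv$seed + 7L * d,
                    cv$decisionThreshold)
    res <- runCrossValidation(fm, permLabels, model, cvd)
    out[d, ] <- colMeans(res@metrics)
  }
  out
}

#' Empirical one-sided p-value against a baseline distribution
#'
#' `p = (1 + #\{baseline >= observed\}) / (1 + nDraws)`.
#'
#' @param observed observed statistic (e.g. mean AUPR).
#' @param baseline numeric vector of baseline draws.
#' @return p-value in (0, 1].
#' @export
compareToBaseline <- function(observed, baseline) {
  (1 + sum(baseline >= observed)) / (1 + length(baseline))
}

#' Multiple-testing adjustment of a family of p-values
#'
#' Benjamini-Hochberg by default; any `stats::p.adjust` method is
#' accepted. Adjusted values are monotone and never below the raw ones.
#'
#' @param ps numeric p-values.
#' @param method adjustment method (default `"BH"`).
#' @return adjusted p-values.
#' @export
adjustPvalues <- function(ps, method = "BH") {
  stats::p.adjust(ps, method = method)
}

#' Jaccard index of two gene sets
#'
#' `|a intersect b| / |a union b|`; two empty sets give 0 with a warning.
#'
#' @param a,b character vectors.
#' @return the Jaccard index in [0, 1].
#' @export
jaccardIndex <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- union(a, b)
  if (!length(u)) {
    warning("both sets empty; Jaccard index set to 0")
    return(0)
  }
  length(intersect(a, b)) / length(u)
}

#' Hypergeometric overlap test
#'
#' Upper-tail probability of observing at least the realized overlap when
#' `|b|` genes are drawn without replacement from `universe` of which
#' `|a|` are marked.
#'
#' @param a,b gene sets (subsets of `universe`).
#' @param universe the background gene set.
#' @return the upper-tail p-value.
#' @export
hypergeometricOverlapTest <- function(a, b, universe) {
  a <- unique(a); b <- unique(b); universe <- unique(universe)
  stopIfNot(all(a %in% universe) && all(b %in% universe),
            "both sets must be subsets of the universe")
  k <- length(intersect(a, b))
  stats::phyper(k - 1, length(a), length(universe) - length(a), length(b),
                lower.tail = FALSE)
}

#' Novel predictions: predicted aging-related genes labeled non-aging
#'
#' @param result a [PredictionResult].
#' @param labels the [LabelSet] used for training.
#' @return character vector of novel predictions.
#' @export
novelPredictions <- function(result, labels) {
  intersect(predictedPositives(result), negatives(labels))
}

#' Cancer-related validation precision of novel predictions
#'
#' Percentage of novel predictions present in a cancer-related gene list.
#' With no novel predictions the measure is undefined and `NA` is
#' returned with a message.
#'
#' @param novel character vector of novel predictions.
#' @param cancer character vector of cancer-related genes.
#' @return percentage in [0, 100], or `NA`.
#' @export
cancerValidation <- function(novel, cancer) {
  novel <- unique(novel)
  if (!length(novel)) {
    message("no novel predictions; cancer validation not applicable")
    return(NA_real_)
  }
  100 * length(intersect(novel, cancer)) / length(novel)
}

#' Assemble classification labels shared by all suite members
#'
#' Positives are the genes of the positive ground-truth source present in
#' every one of the eight (sub)networks; negatives are the genes present
#' in every (sub)network but absent from all aging-related ground-truth
#' sources. The same labels are used for every suite member, so accuracy
#' is comparable across members.
#'
#' @param positiveSource character vector (e.g. a GenAge-style list).
#' @param allAgingSources list of character vectors covering every
#'   aging-related ground-truth source (including the positive one).
#' @param suite a [SubnetworkSuite].
#' @return a [LabelSet].
#' @export
assembleLabels <- function(positiveSource, allAgingSources, suite) {
  common <- Reduce(intersect, suiteNodeSets(suite))
  pos <- intersect(positiveSource, common)
  neg <- setdiff(common, unique(unlist(allAgingSources)))
  stopIfNot(length(pos) >= 2L && length(neg) >= 2L,
            "need at least two positives and two negatives after intersection")
  LabelSet(pos, neg)
}

#' Run a grid of predictive models and select the best by AUPR
#'
#' Crosses the supplied feature matrices with the dimensionality-reduction
#' choices and classifiers, evaluates each model by cross-validation and
#' selects the winner with [selectBestModel()].
#'
#' @param featureList named list of [FeatureMatrix] objects.
#' @param labels a [LabelSet].
#' @param cv a [cvConfig()].
#' @param reductions subset of `c("None", "PCA")`.
#' @param classifiers subset of `c("LR", "NB", "SVM_rbf")`.
#' @return list with `results` (named list of [PredictionResult]s),
#'   `best` (the winning model name) and `summary` (data.frame of mean
#'   metrics per model).
#' @export
evaluateModelGrid <- function(featureList, labels, cv = cvConfig(),
                              reductions = c("None", "PCA"),
                              classifiers = c("LR", "NB", "SVM_rbf")) {
  results <- list()
  for (fn in names(featureList)) {
    for (red in reductions) {
      for (cls in classifiers) {
        model <- predictiveModel(fn, red, cls)
        results[[model$name]] <-
          runCrossValidation(featureList[[fn]], labels, model, cv)
      }
    }
  }
  summary <- do.call(rbind, lapply(names(results), function(nm) {
    m <- colMeans(results[[nm]]@metrics)
    data.frame(model = nm, aupr = m["aupr"], precision = m["precision"],
               recall = m["recall"], fscore = m["fscore"],
               row.names = NULL)
  }))
  list(results = results, best = selectBestModel(results), summary = summary)
}
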