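makeSeparableFeature <- function(nPos = 12, nNeg = 36, gap = 6, seed = 101) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(nPos + nNeg))
  truthPos <- genes[seq_len(nPos)]
  x <- cbind(rnorm(nPos + nNeg), rnorm(nPos + nNeg))
  x[seq_len(nPos), 1] <- x[seq_len(nPos), 1] + gap
  rownames(x) <- genes
  list(fm = FeatureMatrix(genes, x, meta = list(name = "sep")),
       labels = LabelSet(truthPos, genes[-seq_len(nPos)]))
}

test_that("aupr matches hand-computed values and the brute-force oracle", {
  # scores .9 .8 .7 .6, truth T F T F -> 1*.5 + (2/3)*.5 = 5/6
  expect_equal(aupr(c(0.9, 0.8, 0.7, 0.6), c(TRUE, FALSE, TRUE, FALSE)), 5 / 6)
  # perfect ranking
  expect_equal(aupr(c(3, 2, 1), c(TRUE, TRUE, FALSE)), 1)
  # all scores equal -> prevalence
  expect_equal(aupr(rep(0.5, 10), c(rep(TRUE, 3), rep(FALSE, 7))), 0.3)
  expect_error(aupr(1:3, rep(FALSE, 3)), "at least one positive")
  set.seed(61)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    truth <- c(TRUE, runif(n - 1) < 0.3)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # force ties
    expect_equal(aupr(scores, truth), bruteAupr(scores, truth),
                 tolerance = 1e-12)
  }
})

test_that("precision/recall/F helper matches hand arithmetic", {
  # calls T T F F, truth T F T F: tp 1 fp 1 fn 1 -> P = R = F = 0.5
  expect_equal(dynAgeNet:::.prfFromCalls(c(TRUE, TRUE, FALSE, FALSE),
                                         c(TRUE, FALSE, TRUE, FALSE)),
               c(precision = 0.5, recall = 0.5, fscore = 0.5))
  expect_warning(
    out <- dynAgeNet:::.prfFromCalls(rep(FALSE, 3), c(TRUE, FALSE, FALSE)),
    "no predicted positives")
  expect_equal(unname(out), c(0, 0, 0))
})

test_that("stratified folds cover every gene with both classes per fold", {
  truth <- c(rep(TRUE, 10), rep(FALSE, 40))
  set.seed(67)
  fold <- dynAgeNet:::.stratifiedFolds(truth, 5L)
  expect_equal(sort(unique(fold)), 1:5)
  for (k in 1:5) {
    expect_equal(sum(fold == k & truth), 2L)
    expect_equal(sum(fold == k & !truth), 8L)
  }
  expect_error(dynAgeNet:::.stratifiedFolds(c(TRUE, rep(FALSE, 9)), 2L),
               "too few positives")
})

test_that("preprocessing drops zero variance, standardizes on training data only", {
  set.seed(71)
  x <- cbind(const = rep(3, 20), a = rnorm(20, 5, 2), b = rnorm(20, -1, 0.1))
  prep <- dynAgeNet:::.fitPreprocess(x, "None")
  xt <- prep(x)
  expect_equal(ncol(xt), 2L)  # constant column dropped
  expect_equal(unname(colMeans(xt)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(xt, 2, sd)), c(1, 1), tolerance = 1e-12)
  # new data transformed with the training parameters, not its own
  xNew <- x[1:3, ] + 100
  expect_equal(prep(xNew)[, 1], (xNew[, 2] - mean(x[, 2])) / sd(x[, 2]),
               ignore_attr = TRUE)
})

test_that("PCA reduction keeps components explaining >= 90% of variance", {
  set.seed(73)
  base <- rnorm(50)
  x <- cbind(base, base + rnorm(50, sd = 1e-3), rnorm(50))
  prep <- dynAgeNet:::.fitPreprocess(x, "PCA")
  xt <- prep(x)
  expect_lte(ncol(xt), 2L)  # two near-duplicate directions collapse
  expect_gte(ncol(xt), 1L)
})

test_that("all classifiers separate an easy two-cluster problem", {
  d <- makeSeparableFeature()
  for (cls in c("LR", "NB", "SVM_rbf")) {
    model <- predictiveModel("sep", "None", cls)
    res <- runCrossValidation(d$fm, d$labels, model,
                              cvConfig(nFolds = 4L, nRepeats = 2L, seed = 5L))
    expect_gte(mean(cvMetrics(res)$aupr), 0.95)
    expect_setequal(predictedPositives(res), positives(d$labels))
  }
})

test_that("model names follow the X+Y+Z convention", {
  expect_equal(predictiveModel("Diff-bin-1", "PCA", "SVM_rbf")$name,
               "Diff-bin-1+PCA+SVM-rbf")
  expect_equal(predictiveModel("f", "None", "LR")$name, "f+None+LR")
  expect_error(predictiveModel("f", "Both", "LR"))
})

test_that("cross-validation is seed-deterministic and seed-sensitive", {
  d <- makeSeparableFeature(gap = 1)
  model <- predictiveModel("sep", "None", "LR")
  r1 <- runCrossValidation(d$fm, d$labels, model, cvConfig(4L, 2L, seed = 9L))
  r2 <- runCrossValidation(d$fm, d$labels, model, cvConfig(4L, 2L, seed = 9L))
  expect_identical(r1@scores, r2@scores)
  expect_identical(cvMetrics(r1), cvMetrics(r2))
  r3 <- runCrossValidation(d$fm, d$labels, model, cvConfig(4L, 2L, seed = 10L))
  expect_false(identical(r1@scores, r3@scores))
})

test_that("labeled genes missing from the feature matrix are an error", {
  d <- makeSeparableFeature()
  labs <- LabelSet(c(positives(d$labels), "ghost"), negatives(d$labels))
  expect_error(runCrossValidation(d$fm, labs, predictiveModel("sep")),
               "missing from the feature matrix: ghost")
})

test_that("shuffled labels drive AUPR toward prevalence", {
  d <- makeSeparableFeature(nPos = 10, nNeg = 40, gap = 6, seed = 103)
  set.seed(79)
  permPos <- sample(c(positives(d$labels), negatives(d$labels)), 10)
  permLabels <- LabelSet(permPos,
                         setdiff(c(positives(d$labels), negatives(d$labels)),
                                 permPos))
  res <- runCrossValidation(d$fm, permLabels, predictiveModel("sep"),
                            cvConfig(5L, 4L, seed = 11L))
  expect_lt(mean(cvMetrics(res)$aupr), 0.6)  # prevalence is 0.2
})

test_that("selectBestModel applies the documented tie-breaking order", {
  mk <- function(auprs, fs, red, cls) {
    methods::new("PredictionResult",
                 scores = matrix(0, 1, length(auprs)),
                 predicted = matrix(FALSE, 1, length(auprs)),
                 genes = "g1", truth = TRUE,
                 metrics = data.frame(aupr = auprs, precision = 0, recall = 0,
                                      fscore = fs),
                 model = list(feature = "f", reduction = red,
                              classifier = cls))
  }
  res <- list(a = mk(c(0.5, 0.7), c(0.2, 0.2), "PCA", "SVM_rbf"),
              b = mk(c(0.4, 0.6), c(0.9, 0.9), "None", "LR"))
  expect_equal(selectBestModel(res), "a")          # higher mean AUPR wins
  res$b <- mk(c(0.5, 0.7), c(0.9, 0.9), "None", "LR")
  expect_equal(selectBestModel(res), "b")          # tie -> higher F
  res$b <- mk(c(0.5, 0.7), c(0.2, 0.2), "None", "SVM_rbf")
  expect_equal(selectBestModel(res), "b")          # tie -> simpler reduction
  res$b <- mk(c(0.5, 0.7), c(0.2, 0.2), "PCA", "LR")
  expect_equal(selectBestModel(res), "b")          # tie -> simpler classifier
})

test_that("randomBaseline is reproducible and centered near prevalence", {
  d <- makeSeparableFeature(nPos = 8, nNeg = 32, seed = 107)
  model <- predictiveModel("sep", "None", "LR")
  cv <- cvConfig(4L, 1L, seed = 13L)
  b1 <- randomBaseline(d$fm, d$labels, model, cv, nDraws = 8L)
  b2 <- randomBaseline(d$fm, d$labels, model, cv, nDraws = 8L)
  expect_identical(b1, b2)
  expect_lt(mean(b1$aupr), 0.6)  # prevalence 0.2; null stays far below signal
  obs <- mean(cvMetrics(runCrossValidation(d$fm, d$labels, model, cv))$aupr)
  expect_lt(compareToBaseline(obs, b1$aupr), 0.2)
})

test_that("compareToBaseline uses the add-one permutation rule", {
  expect_equal(compareToBaseline(10, c(1, 2, 3)), 1 / 4)
  expect_equal(compareToBaseline(2, c(1, 2, 3)), 3 / 4)   # ties count
  expect_equal(compareToBaseline(0, c(1, 2, 3)), 1)
})

test_that("adjustPvalues matches a hand-written BH step-up", {
  p <- c(0.01, 0.02, 0.04)
  expect_equal(adjustPvalues(p), c(0.03, 0.03, 0.04))
  set.seed(83)
  for (i in 1:5) {
    ps <- runif(sample(3:20, 1))
    expect_equal(adjustPvalues(ps), bruteBH(ps), tolerance = 1e-12)
    expect_true(all(adjustPvalues(ps) >= ps))
  }
  expect_equal(adjustPvalues(p, method = "bonferroni"), pmin(p * 3, 1))
})

test_that("jaccardIndex matches set arithmetic", {
  expect_equal(jaccardIndex(c("a", "b", "c"), c("b", "c", "d")), 2 / 4)
  expect_equal(jaccardIndex(c("a", "a"), "a"), 1)
  expect_equal(jaccardIndex("a", "b"), 0)
  expect_warning(out <- jaccardIndex(character(0), character(0)), "both sets empty")
  expect_equal(out, 0)
})

test_that("hypergeometric test matches closed forms and exhaustive enumeration", {
  u <- letters[1:10]
  # draw 2 of 10, 5 marked, overlap 2: C(5,2)/C(10,2) = 10/45
  expect_equal(hypergeometricOverlapTest(u[1:5], u[1:2], u), 10 / 45)
  # zero overlap has p = 1
  expect_equal(hypergeometricOverlapTest(u[1:5], u[6:7], u), 1)
  expect_error(hypergeometricOverlapTest(c("zz"), u[1:2], u), "subsets")
  set.seed(89)
  for (i in 1:5) {
    uu <- letters[1:sample(8:12, 1)]
    a <- sample(uu, sample(2:5, 1))
    b <- sample(uu, sample(2:4, 1))
    expect_equal(hypergeometricOverlapTest(a, b, uu), bruteHyper(a, b, uu),
                 tolerance = 1e-12)
  }
})

test_that("novel predictions and cancer validation follow the definitions", {
  res <- methods::new("PredictionResult",
                      scores = matrix(1, 4, 3),
                      predicted = matrix(c(TRUE, TRUE, FALSE, FALSE), 4, 3),
                      genes = c("p1", "n1", "n2", "p2"),
                      truth = c(TRUE, FALSE, FALSE, TRUE),
                      metrics = data.frame(aupr = 1, precision = 1, recall = 1,
                                           fscore = 1),
                      model = list())
  labels <- LabelSet(c("p1", "p2"), c("n1", "n2"))
  expect_setequal(predictedPositives(res), c("p1", "n1"))
  expect_equal(novelPredictions(res, labels), "n1")
  expect_equal(cancerValidation(c("n1", "n2"), c("n2", "x")), 50)
  expect_message(na <- cancerValidation(character(0), "x"), "not applicable")
  expect_true(is.na(na))
})

test_that("predicted positives require a strict majority of repeats", {
  res <- methods::new("PredictionResult",
                      scores = matrix(1, 2, 2),
                      predicted = matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2),
                      genes = c("g1", "g2"), truth = c(TRUE, FALSE),
                      metrics = data.frame(aupr = 1, precision = 1, recall = 1,
                                           fscore = 1),
                      model = list())
  # g1: 1 of 2 repeats (not strict majority); g2: 2 of 2
  expect_equal(predictedPositives(res), "g2")
})

test_that("assembleLabels intersects members and excludes all aging sources", {
  set.seed(97)
  sim <- simulateAgingStudy(syntheticConfig(nGenes = 50, nAges = 3, seed = 97,
                                            nAgingGenes = 8))
  suite <- buildSuite(sim$network, sim$expr)
  otherSource <- sample(negatives(sim$labels), 5)
  labels <- assembleLabels(positives(sim$labels),
                           list(positives(sim$labels), otherSource), suite)
  common <- Reduce(intersect, suiteNodeSets(suite))
  expect_true(all(positives(labels) %in% intersect(positives(sim$labels), common)))
  expect_setequal(positives(labels), intersect(positives(sim$labels), common))
  expect_true(all(negatives(labels) %in% common))
  expect_length(intersect(negatives(labels), otherSource), 0L)
  expect_length(intersect(positives(labels), negatives(labels)), 0L)
})

test_that("evaluateModelGrid crosses the axes and reports the winner", {
  d <- makeSeparableFeature(nPos = 10, nNeg = 30)
  noise <- d$fm
  set.seed(109)
  noise@values <- matrix(rnorm(length(noise@values)), nrow(noise@values))
  grid <- evaluateModelGrid(list(sep = d$fm, noise = noise), d$labels,
                            cvConfig(4L, 2L, seed = 15L),
                            reductions = "None",
                            classifiers = c("LR", "NB"))
  expect_length(grid$results, 4L)
  expect_equal(nrow(grid$summary), 4L)
  expect_true(grepl("^sep\\+None\\+", grid$best))
  expect_gt(mean(grid$results[[grid$best]]@metrics$aupr),
            max(vapply(grid$results[grepl("^noise", names(grid$results))],
                       function(r) mean(r@metrics$aupr), numeric(1))))
})
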