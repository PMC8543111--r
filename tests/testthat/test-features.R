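# a 5-node weighted graph used for hand-checked neighborhoods:
#   a-b, b-c, c-d, d-e, b-d   (distances from a: b=1, c=2, d=2, e=3)
nbGraph <- function(w = c(10, 20, 30, 40, 50)) {
  toyGraph(c("a","b", "b","c", "c","d", "d","e", "b","d"), weights = w)
}

test_that("neighborhoodEdges matches hand-derived T1..T4 sets", {
  g <- nbGraph()
  wOf <- function(es) sort(igraph::E(g)$weight[as.integer(es)])
  # from a: T1 = {a-b}; T2 = {} (single neighbor); T3 = {b-c, b-d}; T4 = {c-d}
  expect_equal(wOf(neighborhoodEdges(g, "a", "T1")), 10)
  expect_length(neighborhoodEdges(g, "a", "T2"), 0)
  expect_equal(wOf(neighborhoodEdges(g, "a", "T3")), c(20, 50))
  expect_equal(wOf(neighborhoodEdges(g, "a", "T4")), 30)
  # from c (neighbors b, d; two-hop a, e): T2 = {b-d}, T3 = {a-b, d-e}, T4 = {}
  expect_equal(wOf(neighborhoodEdges(g, "c", "T1")), c(20, 30))
  expect_equal(wOf(neighborhoodEdges(g, "c", "T2")), 50)
  expect_equal(wOf(neighborhoodEdges(g, "c", "T3")), c(10, 40))
  expect_length(neighborhoodEdges(g, "c", "T4"), 0)
  expect_error(neighborhoodEdges(g, "zz", "T1"), "not in snapshot")
})

test_that("neighborhood classification ignores edge weights for hop counts", {
  # heavy weight on a-b must not push b beyond one hop
  g <- nbGraph(w = c(1e6, 1, 1, 1, 1))
  expect_equal(length(neighborhoodEdges(g, "a", "T1")), 1L)
})

test_that("roundHalfAway rounds half away from zero", {
  expect_equal(dynAgeNet:::roundHalfAway(c(2.5, -2.5, 1.25, -1.25), 0),
               c(3, -3, 1, -1))
  expect_equal(dynAgeNet:::roundHalfAway(c(1.235, -1.235, 0.125), 2),
               c(1.24, -1.24, 0.13))
  expect_equal(dynAgeNet:::roundHalfAway(99.995, 2), 100)
})

test_that("buildVocabulary produces rounded distinct raw values or 200 bins", {
  d <- DynamicNetwork(list(triangleGraph(w = c(1.234, -5.678, 1.236)),
                           triangleGraph(w = c(1.234, 0, 99))),
                      c("y1", "y2"), weighted = TRUE)
  vRaw <- buildVocabulary(d, "raw", roundingDecimals = 2L)
  expect_equal(vRaw$values, c(-5.68, 0, 1.23, 1.24, 99))
  expect_equal(vRaw$W, 5L)
  vBin <- buildVocabulary(d, "binned")
  expect_equal(vBin$W, 200L)
  expect_equal(vBin$values, 0:199)
})

test_that("binIndex maps [-100, 100] onto bins 0..199", {
  expect_equal(binIndex(c(-100, -99.5, -99, -0.5, 0, 99, 99.999, 100)),
               c(0L, 0L, 1L, 99L, 100L, 199L, 199L, 199L))
  expect_error(binIndex(100.1), "\\[-100, 100\\]")
})

test_that("weightCountVector counts against the vocabulary and conserves totals", {
  vocab <- structure(list(encoding = "raw", values = c(-1, 0.5, 2), W = 3L,
                          roundingDecimals = 2L), class = "WeightVocabulary")
  expect_equal(weightCountVector(c(2, -1, 2, 0.5), vocab), c(1L, 1L, 2L))
  expect_equal(weightCountVector(numeric(0), vocab), integer(3))
  expect_error(weightCountVector(7, vocab), "not present in the vocabulary")

  vBin <- structure(list(encoding = "binned", values = 0:199, W = 200L,
                         roundingDecimals = NA_integer_),
                    class = "WeightVocabulary")
  set.seed(29)
  w <- runif(500, -100, 100)
  cv <- weightCountVector(w, vBin)
  expect_equal(sum(cv), 500L)
  expect_equal(cv[binIndex(w[1]) + 1L] >= 1L, TRUE)
})

test_that("approach 1 counts match a hand example and conserve edge counts", {
  d <- DynamicNetwork(list(nbGraph(), nbGraph(w = c(10, 10, 30, 40, 50))),
                      c("y1", "y2"), weighted = TRUE)
  vocab <- buildVocabulary(d, "raw")
  # vocabulary: 10, 20, 30, 40, 50
  f <- approach1Features(d, "T1", vocab)
  expect_equal(featureMeta(f)$length, 10L)  # W * N = 5 * 2
  # gene a, snapshot 1: T1 = {10} -> counts (1,0,0,0,0); snapshot 2 same
  expect_equal(unname(featureValues(f)["a", ]),
               c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0))
  # gene c snapshot 2: T1 weights {10, 30}
  expect_equal(unname(featureValues(f)["c", 6:10]), c(1, 0, 1, 0, 0))

  fAll <- approach1Features(d, "ALL", vocab)
  expect_equal(ncol(featureValues(fAll)), 5L * 4L * 2L)
  # snapshot-major layout: first 20 columns are snapshot 1 (T1 T2 T3 T4)
  expect_equal(unname(featureValues(fAll)["a", 1:20]),
               c(1,0,0,0,0, 0,0,0,0,0, 0,1,0,0,1, 0,0,1,0,0))
  # total count over a T-block equals the neighborhood size
  expect_equal(sum(featureValues(fAll)["c", ]),
               sum(vapply(c("T1","T2","T3","T4"), function(tt)
                 length(neighborhoodEdges(nbGraph(), "c", tt)) +
                 length(neighborhoodEdges(nbGraph(w = c(10,10,30,40,50)),
                                          "c", tt)), numeric(1))))
})

test_that("approach 2 correlations match stats::cor on hand-built counts", {
  d <- DynamicNetwork(list(nbGraph(c(10, 20, 30, 40, 50)),
                           nbGraph(c(50, 40, 30, 20, 10)),
                           nbGraph(c(10, 20, 30, 40, 50))),
                      c("y1", "y2", "y3"), weighted = TRUE)
  vocab <- buildVocabulary(d, "raw")
  f <- approach2Features(d, "T1", vocab)
  expect_equal(featureMeta(f)$length, 3L)  # N(N-1)/2 pairs
  # gene a T1 counts: s1 (1,0,0,0,0), s2 (0,0,0,0,1), s3 (1,0,0,0,0)
  c1 <- c(1,0,0,0,0); c2 <- c(0,0,0,0,1)
  expect_equal(unname(featureValues(f)["a", ]),
               c(cor(c1, c2), cor(c1, c1), cor(c2, c1)))
  # an isolated-in-type gene has zero-variance counts -> 0 by convention
  expect_equal(unname(featureValues(approach2Features(d, "T2", vocab))["a", ]),
               c(0, 0, 0))
})

test_that("upper-triangle pair ordering is row-major (i then j)", {
  set.seed(37)
  d <- randomWeightedDynamic(8, 4)
  vocab <- buildVocabulary(d, "binned")
  f <- approach2Features(d, "T1", vocab, genes = igraph::V(snapshots(d)[[1]])$name[1])
  expect_equal(ncol(featureValues(f)), 6L)  # pairs 12 13 14 23 24 34
  # recompute pair (2,3) directly: position 4 in row-major upper triangle
  g <- geneIds(f)[1]
  cnt <- vapply(1:4, function(s) as.numeric(weightCountVector(
    igraph::E(snapshots(d)[[s]])$weight[
      as.integer(neighborhoodEdges(snapshots(d)[[s]], g, "T1"))], vocab)),
    numeric(200))
  expected <- suppressWarnings(cor(cnt[, 2], cnt[, 3]))
  if (!is.finite(expected)) expected <- 0
  expect_equal(unname(featureValues(f)[1, 4]), expected)
})

test_that("cramerVonMises matches hand values and the brute-force oracle", {
  expect_equal(cramerVonMises(1, 2), 0.25)
  expect_equal(cramerVonMises(c(1, 2), c(1, 2)), 0)
  expect_equal(cramerVonMises(1, 2), cramerVonMises(2, 1))
  expect_error(cramerVonMises(numeric(0), 1), "non-empty")
  set.seed(43)
  for (i in 1:10) {
    a <- rnorm(sample(1:40, 1))
    b <- rnorm(sample(1:40, 1), mean = runif(1, -2, 2))
    expect_equal(cramerVonMises(a, b), bruteCvm(a, b), tolerance = 1e-12)
  }
  # ties across samples
  a <- c(1, 1, 2, 3); b <- c(1, 2, 2, 4)
  expect_equal(cramerVonMises(a, b), bruteCvm(a, b), tolerance = 1e-12)
})

test_that("approach 3 has length N per type, zero for empty neighborhoods", {
  d <- DynamicNetwork(list(nbGraph(), nbGraph(c(1, 2, 3, 4, 5))),
                      c("y1", "y2"), weighted = TRUE)
  f <- approach3Features(d, "T2")
  expect_equal(featureMeta(f)$length, 2L)
  expect_equal(unname(featureValues(f)["a", ]), c(0, 0))  # a has no T2 edges
  fAll <- approach3Features(d, "ALL")
  expect_equal(ncol(featureValues(fAll)), 8L)
  # recompute gene c, T1, snapshot 1 against the pooled weights
  pooled <- c(igraph::E(snapshots(d)[[1]])$weight,
              igraph::E(snapshots(d)[[2]])$weight)
  f1 <- approach3Features(d, "T1")
  expect_equal(unname(featureValues(f1)["c", 1]),
               bruteCvm(c(20, 30), pooled), tolerance = 1e-12)
  # binned encoding compares bin indices
  fb <- approach3Features(d, "T1", encoding = "binned")
  expect_equal(unname(featureValues(fb)["c", 1]),
               bruteCvm(binIndex(c(20, 30)), binIndex(pooled)),
               tolerance = 1e-12)
})

test_that("allProposedFeatures yields the full named 30-feature grid", {
  set.seed(47)
  d <- randomWeightedDynamic(10, 3)
  fl <- allProposedFeatures(d)
  expect_length(fl, 30L)
  expect_equal(sum(grepl("^Diff-nobin", names(fl))), 15L)
  expect_equal(sum(grepl("^Diff-bin", names(fl))), 15L)
  expect_true(all(c("Diff-nobin-1", "Diff-bin-all", "Diff-nobin-cor-2",
                    "Diff-bin-cvm-4", "Diff-nobin-cvm-all") %in% names(fl)))
  N <- 3L; W <- buildVocabulary(d, "raw")$W
  expect_equal(featureMeta(fl[["Diff-nobin-1"]])$length, W * N)
  expect_equal(featureMeta(fl[["Diff-bin-all"]])$length, 200L * 4L * N)
  expect_equal(featureMeta(fl[["Diff-nobin-cor-2"]])$length, N * (N - 1L) / 2L)
  expect_equal(featureMeta(fl[["Diff-bin-cvm-all"]])$length, 4L * N)
  for (f in fl) {
    expect_s4_class(f, "FeatureMatrix")
    expect_equal(nrow(featureValues(f)), length(geneIds(f)))
    expect_equal(featureMeta(f)$source, "wNetWalk-Dynamic")
  }
})

test_that("feature extraction is invariant under gene relabeling", {
  set.seed(53)
  d <- randomWeightedDynamic(9, 3)
  genes <- igraph::V(snapshots(d)[[1]])$name
  perm <- sample(genes)
  dP <- DynamicNetwork(lapply(snapshots(d), function(g) {
    igraph::V(g)$name <- perm[match(igraph::V(g)$name, genes)]
    g
  }), ages(d), weighted = TRUE)
  for (mk in list(
    function(dd, gg) approach1Features(dd, "T3", buildVocabulary(dd, "binned"), gg),
    function(dd, gg) approach2Features(dd, "ALL", buildVocabulary(dd, "raw"), gg),
    function(dd, gg) approach3Features(dd, "T1", genes = gg))) {
    f <- mk(d, genes)
    fP <- mk(dP, perm[match(genes, genes)])
    expect_equal(unname(featureValues(fP)), unname(featureValues(f)))
  }
})

test_that("static counterparts mirror the dynamic features at N = 1", {
  g <- nbGraph(w = c(0.2, 0.4, 0.6, 0.8, 1))
  f1 <- staticCounterpartFeatures(g, 1L, "T1", "raw")
  expect_equal(featureMeta(f1)$name, "Static-nobin-1")
  expect_equal(featureMeta(f1)$length, 5L)  # 5 distinct weights, N = 1
  expect_equal(sum(featureValues(f1)["c", ]), 2)  # c has two T1 edges
  f3 <- staticCounterpartFeatures(g, 3L, "T2", "binned")
  expect_equal(featureMeta(f3)$name, "Static-bin-cvm-2")
  expect_equal(featureMeta(f3)$length, 1L)
  expect_message(f2 <- staticCounterpartFeatures(g, 2L, "T1", "raw"),
                 "approach-1 counterpart")
  expect_equal(featureValues(f2), featureValues(f1))
})

test_that("Onnela clustering matches a hand-computed triangle-plus-tail", {
  # triangle a-b-c (weights 1, 2, 4) with a tail c-d (weight 8)
  g <- toyGraph(c("a","b", "a","c", "b","c", "c","d"), weights = c(1, 2, 4, 8))
  cc <- dynAgeNet:::.onnelaClustering(g)
  # normalized by max weight 8: tilde-w = (1/8, 2/8, 4/8, 1)
  expected <- ((1 / 8) * (2 / 8) * (4 / 8))^(1 / 3)
  expect_equal(unname(cc["a"]), expected, tolerance = 1e-12)
  expect_equal(unname(cc["b"]), expected, tolerance = 1e-12)
  expect_equal(unname(cc["c"]), 2 * expected / (3 * 2), tolerance = 1e-12)
  expect_equal(unname(cc["d"]), 0)
})

test_that("weighted centralities match hand values on a weighted star", {
  g <- starGraph(center = "h", leaves = c("x", "y", "z"), w = c(1, 2, 3))
  d <- DynamicNetwork(list(g), "y1", weighted = TRUE)
  fl <- weightedCentralityFeatures(d)
  expect_setequal(names(fl), c("DegC-wt", "ClusC-wt", "CloseC-wt",
                               "BetwC-wt", "EigenC-wt"))
  deg <- featureValues(fl[["DegC-wt"]])[, 1]
  expect_equal(deg[c("h", "x", "y", "z")], c(h = 6, x = 1, y = 2, z = 3))
  bet <- featureValues(fl[["BetwC-wt"]])[, 1]
  expect_equal(bet[c("h", "x")], c(h = 3, x = 0))
  expect_equal(unname(featureValues(fl[["ClusC-wt"]])[, 1]), rep(0, 4))
  eig <- featureValues(fl[["EigenC-wt"]])[, 1]
  expect_equal(unname(eig["h"]), 1)  # igraph scales the max to 1
  expect_error(weightedCentralityFeatures(
    DynamicNetwork(list(triangleGraph(w = c(1, -1, 1))), "y1",
                   weighted = TRUE)), "positive weights")
})

test_that("centrality features concatenate over snapshots", {
  set.seed(59)
  d <- randomWeightedDynamic(10, 4, range = c(0.01, 1))
  fl <- weightedCentralityFeatures(d)
  for (f in fl) {
    expect_equal(ncol(featureValues(f)), 4L)
    expect_equal(featureMeta(f)$length, 4L)
  }
})

test_that("writeFeatureMatrix emits a TSV plus metadata sidecar", {
  fm <- FeatureMatrix(c("g1", "g2"), matrix(1:4, 2),
                      meta = list(name = "demo", approach = 1L))
  f <- withr_local_tempfile()
  writeFeatureMatrix(fm, f)
  tab <- read.delim(f)
  expect_equal(tab$gene, c("g1", "g2"))
  expect_equal(ncol(tab), 3L)
  meta <- jsonlite::read_json(paste0(f, ".meta.json"))
  expect_equal(meta$name, "demo")
  expect_equal(meta$length, 2L)
  unlink(paste0(f, ".meta.json"))
})
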