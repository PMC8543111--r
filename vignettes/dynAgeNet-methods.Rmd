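---
title: "Weighted dynamic PPI subnetworks for aging-gene prediction: methods"
author: "dynAgeNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted dynamic PPI subnetworks for aging-gene prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynAgeNet)
```

# Overview

dynAgeNet starts from two inputs — an *entire*, context-unspecific
protein–protein interaction (PPI) network and a gene × age expression
table — and produces supervised predictions of aging-related genes in
four stages:

1. **Subnetwork inference** (`buildSuite()`): aging-specific
   subnetworks are carved out of the entire network, either by inducing
   on the genes called active at each age, or by activity-biased network
   propagation followed by edge-weight thresholding or differential
   weighting.
2. **Feature extraction** (`allProposedFeatures()`,
   `weightedCentralityFeatures()`): per-gene numeric features computed
   from the weighted dynamic subnetworks.
3. **Supervised evaluation** (`evaluateModelGrid()`,
   `evaluateSuite()`): a grid of classifiers is cross-validated against
   a labeled gene set, the best model selected by AUPR, and its
   predictions compared to a label-permutation baseline.
4. **Validation analyses**: overlap statistics between feature groups'
   predictions (Jaccard, hypergeometric), and the fraction of novel
   predictions appearing in a cancer-related gene list.

A seeded synthetic generator (`simulateAgingStudy()`) provides
end-to-end benchmarks with a plantable aging signal; it is a
first-class component, and every randomized quantity in the package is
reproducible from explicit integer seeds.

# Activity calls and the age series

An `ExpressionSeries` holds the expression matrix and a logical
gene × age *activity* matrix. The default rule calls a gene active at an
age when it is measured and at or above the per-age mean over measured
genes; a z-score rule and arbitrary user functions are also supported
(`ExpressionSeries(expr, activityRule = ...)`). Missing measurements
are never active.

# Network propagation

For each age, every node of the entire network receives a strictly
positive *activity value* (`assignActivities()`):

* **Option 2** (default): every measured gene keeps its measured
  expression value; unmeasured network nodes get a small dummy value
  ε (default: 0.01 × the smallest positive measured value at that age).
* **Option 1**: only the genes called active keep their expression
  value; all other nodes get ε.

Values are shifted, if necessary, so the minimum is at least ε, keeping
them strictly positive. The walk then runs on the row-stochastic
transition matrix

$$T_{ij} = \frac{v_j}{\sum_{k \in N(i)} v_k},$$

i.e. the walker moves preferentially toward highly active neighbors.
The stationary distribution of the restart walk,
$p \leftarrow (1-r)\,T^{\top}p + r\,q$ with restart vector $q \propto v$,
is found by power iteration (restart $r = 0.15$, L1 tolerance
$10^{-10}$, at most 10{,}000 iterations; non-convergence is an error,
never a silent result). The **edge flux** of an undirected edge
$\{i,j\}$ is

$$w_{ij} = p_i\,(1-r)\,T_{ij} + p_j\,(1-r)\,T_{ji},$$

so the weights over all edges sum exactly to $1-r$ — a conservation
invariant the test suite checks against an independent dense linear
solve of the same fixed point.

# The eight (sub)networks

`buildSuite()` constructs, from one entire network (reduced to its
largest connected component) and one expression series with $N$ ages:

| member | kind | construction |
|---|---|---|
| `entire` | static | the full PPI network (LCC) |
| `inducedDynamic` | dynamic, $N$ snapshots | induced subgraph on the active genes per age |
| `inducedStatic` | static | union of the induced snapshots |
| `netwalkDynamic` | dynamic, $N$ | propagation weights per age, top 25% of edges kept (ties at the cut weight included) |
| `netwalkStatic` | static | union of the thresholded snapshots |
| `netwalkStaticStar` | static | thresholding of the *weighted static* network, edge-count matched to `netwalkStatic` |
| `wNetwalkDynamicNondiff` | weighted dynamic, $N$ | propagated weights, normalized jointly to $[0.01, 1]$ |
| `wNetwalkDynamic` | weighted dynamic, $N-1$ | differential snapshots (below) |
| `wNetwalkStaticStar` | weighted static | propagation on the age-aggregated expression, normalized to $[0.01, 1]$ |

Normalization is the joint linear map
$w' = 0.01 + 0.99\,(w - \min)/(\max - \min)$ with the extremes taken
over *all* snapshots, so weights stay comparable across ages. The
**differential weight** between consecutive normalized snapshots is the
percentage change

$$d = \frac{(w_{i+1} - w_i) \cdot 100}{w_{i+1} + w_i},$$

which is antisymmetric under swapping the snapshots and bounded by 100
in magnitude for strictly positive inputs. The weighted members retain
every entire-network edge; only the thresholded unweighted members drop
edges.

# Weighted dynamic node features

Features are computed over four **edge neighborhood types** of a gene
$v$ (hop counts ignore weights): T1, edges from $v$ to its one-hop
neighbors; T2, edges among one-hop neighbors; T3, edges between one-hop
and two-hop neighbors; T4, edges among two-hop neighbors ("two-hop"
means distance exactly 2). A fifth option, ALL, concatenates the four.

Weights enter either **raw** (rounded half away from zero to 2 decimals
for distinctness; the vocabulary is the sorted distinct rounded weights
over all snapshots) or **binned** (200 half-open bins of width 1
spanning $[-100, 100]$, the last bin closed). Three feature families:

1. **Counts** (`approach1Features()`): per snapshot, the count vector
   of the neighborhood weights against the vocabulary; concatenated
   over snapshots (length $W \cdot N$; ALL is snapshot-major, length
   $W \cdot 4 \cdot N$).
2. **Correlations** (`approach2Features()`): Pearson correlation of the
   count vectors between every snapshot pair, upper triangle in
   row-major order (length $N(N-1)/2$); a zero-variance vector
   contributes 0.
3. **Distribution deviation** (`approach3Features()`): the two-sample
   Cramér–von Mises statistic between the gene's neighborhood weights
   in one snapshot and the pooled weights of all snapshots (length
   $N$); an empty neighborhood contributes 0.

The full grid {3 approaches} × {T1–T4, ALL} × {raw, binned} gives the
**30 proposed features**, named
`Diff-{nobin|bin}[-cor|-cvm]-{1|2|3|4|all}`. Static counterparts
(`Static-...`) treat the weighted static network as a one-snapshot
dynamic (an approach-2 request falls back to approach 1 with a message,
since one snapshot has no pairs). Five comparator centralities on the
non-differential dynamic — weighted degree, Onnela clustering, weighted
closeness and betweenness (edge length $1/w$), eigenvector centrality —
are concatenated over snapshots.

# Supervised evaluation

Labels are assembled (`assembleLabels()`) as: positives = the positive
ground-truth source intersected with the genes present in *all*
(sub)networks; negatives = those common genes absent from every
aging-related source. Evaluation is stratified k-fold cross-validation
(default 5 folds, 10 repeats); all preprocessing — zero-variance
filtering, standardization, optional PCA to ≥ 90% training variance —
is fitted on training folds only. Classifiers: class-weighted logistic
regression, Gaussian naive Bayes, and a class-weighted RBF-kernel SVM
scored by its signed margin. The model grid is scored by mean **AUPR**
(step-wise, tie-grouped; all-equal scores reduce to prevalence), with
exact ties broken toward higher F-score, then the simpler model. A gene
is *predicted positive* when a strict majority of CV repeats call it
positive; *novel predictions* are predicted positives currently labeled
negative.

Significance against chance uses a seeded label-permutation baseline
with the add-one rule
$p = (1 + \#\{\text{baseline} \ge \text{observed}\})/(1 + n)$,
Benjamini–Hochberg adjustment across feature groups, pairwise Jaccard
and hypergeometric overlap of predictions, and the percentage of novel
predictions found in a cancer-related list.

# The synthetic generator

`simulateAgingStudy()` draws a preferential-attachment network (heavy
tailed, reduced to its LCC), i.i.d. lognormal baseline expression, and
plants in a random subset of genes a multiplicative exponential trend
of total log-magnitude `effectSize` across the age range, plus additive
Gaussian noise everywhere. The planted genes are the positives;
negatives are sampled from the rest; a synthetic cancer list includes
positives and negatives at configurable rates.

The defaults — 300 genes, 10 ages, 30 planted genes, `effectSize = 2`,
`noiseSd = 0.5` — are this package's own desk-scale study conditions,
chosen during design so a planted signal of the stated size is clearly
above the noise floor of the propagation pipeline ("effect ≫ noise")
while a zero effect is indistinguishable from it. The signal acts on
*expression only*: any label signal in the features must survive
propagation, normalization, differential weighting and feature
extraction, which is exactly what the acceptance tests probe.

# Numerical choices

* Power iteration stops at L1 change ≤ $10^{-10}$ and errors beyond
  10,000 iterations; agreement with a dense solve is tested to
  $10^{-8}$.
* Rounding for raw vocabularies is half-away-from-zero with a relative
  epsilon guard against binary-representation artifacts.
* Bin index is $\lfloor w + 100 \rfloor$ capped at 199, so $-100$ maps
  to bin 0 and $+100$ joins the last bin.
* All derived seeds stay below $2^{31}$; every stochastic step
  (generator, folds, permutations) is seeded explicitly.

# Limitations

* The induced subnetworks depend entirely on the activity rule; the
  default per-age-mean rule is a simple, deterministic stand-in for
  study-specific significance calls.
* Raw-weight vocabularies grow with the number of distinct rounded
  weights, so approach-1 raw features can be wide on large networks;
  the binned encoding bounds the width at 200 per type and snapshot.
* The permutation baseline and cross-validation repeats trade
  statistical resolution for runtime; the defaults target desk-scale
  problems (hundreds of genes, ~10 ages), the package's own choice of
  problem size.
* Cancer-list validation is a precision proxy, not a causal claim: it
  reports the fraction of novel predictions present in the list, and is
  `NA` when there are no novel predictions.

# Worked example

```{r example, eval = FALSE}
sim <- simulateAgingStudy(syntheticConfig(seed = 1))
suite <- buildSuite(sim$network, sim$expr)
labels <- assembleLabels(positives(sim$labels),
                         list(positives(sim$labels)), suite)
report <- evaluateSuite(
  suite, labels,
  featureGroups = list(proposed = c("Diff-bin-1", "Diff-nobin-cvm-1")),
  cancer = sim$cancer,
  cv = cvConfig(nFolds = 5, nRepeats = 2, seed = 1),
  reductions = c("None", "PCA"), classifiers = "LR",
  nBaselineDraws = 20)
report$groups$proposed$grid
```

See the README for the same example with its printed output, and
`inst/cli/dynagenet.R` for the command-line pipeline
(`simulate`, `infer`, `features`, `evaluate`, `all`).
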