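---
title: "Methods: GO semantic similarity, clustering and validation in gostrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GO semantic similarity, clustering and validation in gostrat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gostrat)
```

# The problem and the model

`gostrat` stratifies a gene list into functionally coherent subgroups
using nothing but the genes' Gene Ontology annotations. The underlying
model is simple: if a disease gene list mixes several biological
aetiologies, genes belonging to the same aetiology should be annotated to
related GO terms, so a gene-by-gene functional similarity matrix should
carry block structure that dimension reduction and clustering can
recover. Each step of that chain is standard; the package's job is to
implement the chain end to end, reproducibly, with explicit validation
statistics at the end.

The pipeline has three stages:

1. **Similarity.** Parse one namespace of the ontology (a rooted DAG over
   `is_a`/`part_of` edges), propagate gene annotations to all ancestors
   (the true-path rule), estimate term information content, score every
   gene pair with a term-level semantic similarity measure and a set-level
   aggregation function.
2. **Embedding.** Reduce the similarity matrix to coordinates by PCA,
   PCoA, t-SNE or UMAP.
3. **Clustering.** Cluster (k-means, PAM, Ward, fuzzy c-means), choose k
   by silhouette sweep, report per-gene/per-cluster/overall silhouettes
   and per-cluster statistics, optionally remove negative-silhouette
   outliers and re-cluster once.

# Information content and the IC family of measures

For a propagated corpus, `p(t)` is the fraction of annotated genes
reaching term `t` (denominator: genes annotated to the namespace root,
i.e. all annotated genes), and `IC(t) = -ln p(t)`. Choices worth making
explicit:

* **Probability basis.** Distinct genes, not annotation rows — a gene
  annotated twice to a term counts once. This matches the dominant
  convention in GO similarity software.
* **Logarithm base.** Natural log. The base only rescales Resnik's raw
  score (and cancels after normalisation); Lin, Rel and Jiang are ratios
  or differences of ICs and are base-invariant.
* **Undefined IC.** Terms with zero annotated genes get `p = 0` and an
  `NA` IC; they are removed from gene term sets before similarity is
  computed and can never be a MICA.
* **MICA.** The common ancestor (each term's closure includes the term
  itself, so `MICA(t, t) = t`) with maximal defined IC; exact ties are
  broken by lexicographic term id so runs are deterministic.
* **Resnik normalisation.** Raw Resnik is an unbounded IC. To keep every
  measure on the same [0, 1] scale the score is divided by the largest
  finite IC in the namespace; the raw value stays available
  (`normalize = FALSE`). Rel, by contrast, uses the raw ICs throughout —
  its `(1 - p(MICA))` factor already damps uninformative ancestors.
* **Jiang.** `1 - min(1, d)` with `d` the IC semantic distance; the clamp
  makes the score a similarity in [0, 1] at the cost of zeroing all pairs
  with distance above 1.

# The Wang measure

Wang similarity ignores annotation statistics and uses the DAG itself.
For a term `t`, every ancestor `a` receives an S-value: `S(t) = 1` and
`S(a) = max over in-closure children c of w(c→a) · S(c)`, computed in a
topological order of the induced sub-DAG so each node is final before it
contributes. The semantic value `SV(t)` is the sum of S-values, and the
similarity of two terms is the sum of both closures' S-values over their
shared terms divided by `SV(t1) + SV(t2)`. The relation weights default
to the values of the original graph-based method — 0.8 for `is_a`, 0.6
for `part_of` — and are configurable; profiles built with different
weights refuse to be compared.

# Aggregation over gene term sets

Gene-pair scores aggregate the term-pair matrix over the two genes'
**direct** annotations (default). Aggregating over propagated closures is
available (`use_propagated = TRUE`) but inflates every aggregator with
ancestor self-matches, so direct sets are the default. `rcmax` is read as
`max(mean of row maxima, mean of column maxima)`; the best-match average
is `(Σ row maxima + Σ column maxima) / (n_rows + n_cols)`. Under `max`,
`rcmax` and `bma`, the diagonal of the gene matrix is exactly 1 for Lin,
Jiang and Wang; Rel's self-similarity is `1 - p(t)`-weighted and below 1
by construction, which is a property of the measure, not a bug.

The working namespace is a required, explicit parameter (default `"BP"`,
the usual choice for disease-gene stratification) rather than something
inferred from the data. Evidence codes are not filtered by default; an
exclusion list (e.g. `IEA`) can be supplied.

# Embedding

* **PCA** treats each gene's row of the similarity matrix as its feature
  vector (centred, unscaled). Components are sign-fixed by making the
  largest-magnitude loading positive, so runs are bit-reproducible.
* **PCoA** double-centres the squared `1 - s` distances and keeps the
  positive-eigenvalue coordinates; negative eigenvalues (the distances
  are generally non-Euclidean) are dropped with a logged count, and
  explained variance is reported relative to the positive spectrum.
* **t-SNE / UMAP** run single-threaded with a caller-supplied seed;
  identical seed, parameters and input give identical coordinates.
  Defaults: perplexity 30, 15 neighbours, `min_dist` 0.1.
* **Similarity to distance** is `d = 1 - s` with the diagonal forced to
  zero — order-preserving and simple; the square-root variant adds
  nothing for ranking-based downstream steps.
* **Component selection** offers a fixed `k` and an explicit elbow rule:
  the smallest `k` whose drop `evr[k] - evr[k+1]` falls below a fraction
  (default 0.1) of the first drop. The default formalises "the curve has
  flattened relative to its initial slope" without eyeballing.

# Clustering and validation

k-means uses k-means++ seeding with 10 restarts under a fixed seed; Ward
is `ward.D2` on Euclidean embedding coordinates; PAM consumes distances
natively; fuzzy c-means uses fuzzifier `m = 2` and returns row-normalised
memberships hardened by maximum membership (ties to the lowest index).
Coordinate methods given a distance matrix auto-embed it with PCoA
(logged). Labels are always relabelled contiguously `1..k`.

The silhouette implementation follows the textbook formula with `b` as
the *nearest-cluster* mean distance and one convention: members of
singleton clusters get silhouette 0 (neither cohesive nor separated).
The sweep default is `k = 2..min(25, n - 1)`.

**What distances validate a clustering?** The package clusters in
embedding space but scores candidate k values on the functional
distances `1 - s` (`validate_on`). The distinction matters: IC depth
gradients inside a functionally coherent group make its embedding cloud
elongated, so silhouettes measured in embedding space reward splitting
such groups indefinitely and the sweep runs to the top of its range.
Measured on the bounded functional distances — where between-group
dissimilarity saturates at 1 — the curve peaks at the genuine group
count. When no similarity matrix is in scope (clustering raw
coordinates), validation falls back to distances in the clustered space.

Per-cluster statistics are diameter, mean within-cluster distance, mean
member-to-non-member distance, separation (minimum member-to-non-member
distance) and mean silhouette. A `stable` flag marks clusters whose mean
silhouette reaches a configurable threshold (default 0.25); the
threshold is an interpretive aid, not part of any computation.

**Outlier refinement** runs the sweep, clusters at the optimum, flags
genes with negative silhouette, removes them, and repeats the sweep and
clustering once on the reduced set — exactly one pass by default
(`iterate = TRUE` repeats to a fixed point). With no outliers, round 2
equals round 1 and says so. Note that a gene assigned to its nearest
cluster by a centroid method has a non-negative silhouette up to noise;
negative silhouettes therefore diagnose genuine misassignment (e.g.
near-duplicate genes split across clusters or non-centroid linkage
artefacts), and geometries in which every point sits with its nearest
centroid can legitimately produce zero outliers.

# The synthetic generator

`synthetic_spec()` describes a corpus with planted structure: one root,
`n_branches` disjoint `is_a` chains of `depth` terms, and
`genes_per_group` genes per branch drawing `terms_per_gene` distinct
terms from their own branch, each draw replaced by a uniform
foreign-branch term with probability `leak`. Defaults — 4 branches,
depth 6, 25 genes per group, 4 terms per gene, leak 0.05 — model a
moderately noisy four-aetiology gene list of 100 genes. With `leak = 0`
cross-group similarity is exactly zero for IC measures (the only common
ancestor is the root), which gives the package a sharp end-to-end truth
to test against; `leak = 1` destroys the structure entirely.

What the generator deliberately does **not** emulate: realistic GO
topology (branching factors, multiple parenthood at scale), annotation
depth distributions, inter-group similarity gradients, or annotation
biases. Passing the planted-recovery tests therefore demonstrates that
the chain of computations is correct and that the silhouette criterion
identifies truly disjoint functional groups; it does not certify
clustering quality on real corpora, where group boundaries are soft. One
sizing caveat found while testing: if `terms_per_gene` is close to
`depth`, the per-branch term pool is so small that many genes draw
identical term sets, creating distance-zero duplicate bundles that
dominate silhouette sweeps — keep `depth` comfortably above
`terms_per_gene` when designing corpora.

# Numerical and reproducibility choices

* All randomness flows from explicit integer seeds; stochastic backends
  run single-threaded.
* Similarity and embedding TSVs serialise doubles as `%.17g` and are
  parsed with base R's correctly rounded reader, so a resumed run is
  byte-identical to the original (the faster tabular readers round the
  last ulp and silently break this contract).
* Symmetry is enforced structurally (each pair computed once), matrix
  entries are validated against [0, 1] at module boundaries, and cluster
  labels, exclusion lists and gene orders are deterministic functions of
  the input order.
* Test problem sizes: random-DAG oracle comparisons use 20 DAGs of up to
  100 terms with all term pairs; silhouette oracle checks use 50 random
  labelings up to n = 300; PCoA fidelity up to n = 200; the end-to-end
  recovery standard is the generator default (100 genes) over 5 seeds.

# Known limitations

* One namespace per run; no cross-namespace similarity.
* `regulates`-family edges are ignored (only `is_a` and `part_of`
  carry similarity semantics here).
* No consensus clustering, gap statistic, or alternative k-selection
  criteria; silhouette is the single arbiter.
* The functional-enrichment interpretation of clusters (pathway and
  phenotype annotation of each subgroup) is out of scope; the package
  stops at validated cluster assignments.
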