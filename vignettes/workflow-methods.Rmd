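---
title: "Methods: topological abstraction, delta loadings and matrix brushing"
author: "omicsbrush"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topological abstraction, delta loadings and matrix brushing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicsbrush)
```

# The problem

Exploratory analysis of a two-group omics cohort — say a clinical
biochemistry panel measured on diagnosed and healthy individuals —
usually asks three questions in sequence: *do the diagnosed samples form
a distinct region of measurement space, and which features drive the
separation?* (a data-driven view); *which of those features are already
reported as disease-associated?* (a knowledge-driven view); and *which
interactions among the features deserve a closer look?* (an integration
step on the feature correlation network). omicsbrush implements the
three steps headlessly, with deterministic outputs, so the whole chain
is scriptable and reproducible.

# Cohort container and input conventions

Cohorts are `SampleTable` objects (a `SummarizedExperiment` with a
single `values` assay; features are rows internally). Delimited files
use the opposite convention — samples as rows, features as columns —
and `readSampleMatrix()` / `writeSampleMatrix()` transpose at the
boundary. The delimiter is always explicit (default comma): no
auto-detection, so parsing is bit-reproducible. Missing values are a
configurable token (default the empty string); any other non-numeric
cell is a hard parse error naming the sample and feature, because a
silently dropped cell would bias every downstream statistic.

Two conventions come from the intended use cases:

* **Diagnosis as a feature.** `attachDiagnosis()` appends the group
  label as a 1.0/0.0 numeric column so it can enter the correlation
  network like any analyte; its correlation with a continuous feature
  is then the point-biserial correlation. The coding is fixed —
  Pearson correlation is affine-invariant, so any other coding gives
  identical edges. A cohort where every sample is positive yields a
  constant column; the correlation step refuses zero-variance features
  explicitly rather than producing `NaN` edges.
* **Healthy reference filtering.** `filterHealthyReference()` retains
  samples that have no diagnosis label and whose measurements all lie
  inside per-feature population reference intervals. A sample with any
  missing measurement is excluded: an unmeasured analyte cannot be
  certified in-range. This conservative reading costs samples but never
  admits an unverifiable "healthy" reference.

# The delta loading statistic

For a selected sample set $S$ and one feature $x$,

$$\delta(x) = \frac{\operatorname{median}_{i \in S} x_i -
  \operatorname{median}_{i \notin S} x_i}
  {\operatorname{IQR}(x_{\text{all}})}.$$

Medians and the interquartile range make $\delta$ robust to the heavy
tails and outliers routine in clinical measurements, and the IQR
denominator makes it dimensionless, so features with different units
rank on one scale. Positive $\delta$ means the feature is *higher* in
the selected group; colour conventions for display are configuration,
never computation. Quartiles use linear interpolation at index
$q\,(n-1)$ on the sorted values (R's type 7) — the most widespread
convention — and the convention is injectable (`type =`) for
cross-checks against other software. When the overall IQR is zero,
$\delta$ is flagged undefined and excluded from rankings rather than
returned infinite. `featureLoadings()` ranks features by $|\delta|$,
breaking exact ties lexicographically by feature id so the panel is a
deterministic function of the data, and returns the top 20 by default —
the size of the interactive loading-bar panel this mirrors.

Two exact symmetries are useful for testing and interpretation:
complementing the selection negates every defined $\delta$, and any
positive affine rescaling of a feature (unit change) leaves its
$\delta$ unchanged up to floating-point error.

# Topological abstraction of samples

The sample-level view is a graph whose nodes are samples and whose
edges connect similar samples (STAD-style abstraction). The operative
definition used here:

1. compute a sample distance matrix (`sampleDistanceMatrix()`;
   Euclidean on z-standardized features by default — standardization is
   on because clinical panels mix units; the choice is recorded in the
   object and configurable);
2. take the minimum spanning tree (deterministic Kruskal: candidate
   edges ordered by distance, then by the id pair, so equal-distance
   ties never depend on memory layout);
3. consider the non-tree pairs in ascending distance order, add them
   cumulatively, and at each swept edge count score the graph by the
   Pearson correlation between unit-weight shortest-path (hop)
   distances and the input distances (`graphObjective()`);
4. return the edge set with the best score, preferring fewer edges on
   ties (`stadAbstraction()`; the whole sweep is kept in `swept_sizes`
   for audit).

Hop distances are unit-weight rather than distance-weighted: the point
of the abstraction is that the *graph structure* — not re-imported edge
lengths — reproduces the metric. The result always contains the MST and
is always connected, and its objective can never fall below the MST's.
Degenerate inputs are handled explicitly: a complete graph has constant
hop distances, so the objective is undefined there and that sweep point
is skipped. The sweep evaluates every candidate count up to 2,000
candidate pairs and 100 log-spaced counts beyond — at the few hundred
samples these views are designed for (up to ~500 nodes; a warning marks
larger inputs) the sweep is exhaustive.

`layoutGraph()` provides seeded 2-D/3-D Fruchterman–Reingold
coordinates; the same graph and seed give bitwise-identical output, and
the caller's RNG state is restored. `graphFromTopology()` re-expresses
the abstraction as an `InteractionGraph` whose links carry the original
inter-sample distances, so sample topology can be explored in the same
matrix view as feature correlations.

# The correlation graph and the JSON exchange format

`matrixToGraph()` is the formatting step: one node per feature, one
link per unordered pair weighted by Pearson correlation (Spearman
selectable), and a node-node distance matrix for clustering — Canberra
distance between the feature columns by default, which emphasises
relative rather than absolute differences between profiles. Missing
values are handled pairwise-complete with a minimum overlap of three
samples per pair (fewer is an error, not a silent `NA`). An optional
`power` exponent (`sign(r)\,|r|^\beta`) is available for soft
weighting; the default $\beta = 1$ reports plain correlations.

Graphs travel as JSON with top-level `nodes` and `links` arrays and an
optional `dist` array of arrays (row-major in node order). Weights are
serialized under `value` — the common node-link convention — with
`weight` accepted as a read alias; keys are written sorted and numbers
at full precision, so write-then-read is the identity.

# The adjacency-matrix view

`clusterOrder()` reorders the matrix by average-linkage agglomerative
clustering on the graph's distance matrix (the linkage is unspecified
in the interactive tools this mirrors; average linkage is the default
and injectable). When a graph arrives without `dist` — the format
accepts any interaction data — the documented fallback distance is
$1 - w$ on the correlation scale. The dendrogram's leaf order is the
displayed permutation: cell $(i, j)$ always equals
`weightMatrix(g)[order[i], order[j]]`.

The *cut level* is a count, not a height: "cut at 5" retains exactly
five sub-trees (clamped to $n$), obtained by undoing the last four
merges. Count semantics is the only integer-valued reading; the dotted
line drawn by `renderMatrix()` is the derived height between the
relevant merges. Every resulting cluster is a contiguous run in leaf
order, which is what makes one-click sub-tree extraction equivalent to
brushing.

Three extraction operations share the threshold parameter $t$, applied
to $|w|$ by default so that strong *negative* correlations — often the
interesting ones, e.g. an analyte depressed in disease — survive
(signed comparison is available):

* `thresholdEdges(g, t)` keeps links with $|w| \ge t$ and all nodes
  (isolates are reported). Two documented presets from the worked
  diabetes analyses are 0.28 (matrix view) and 0.18 (node-link view);
  neither is privileged.
* `brushSubgraph(cm, region, t)` extracts the links whose cell falls,
  in either orientation, inside a contiguous rectangle of the
  reordered matrix, together with the spanned nodes. Brushing is
  contiguous by construction; non-contiguous selections are reached by
  re-clustering with a different distance or by thresholding instead.
* `subtreeSubgraph(cm, k, t)` is exactly the diagonal-block brush of
  cluster $k$ — the equivalence is asserted in the test suite.

`colorNodes()` tags nodes with a `colour_group` from metadata or from
the dendrogram assignment; `renderMatrix()` and `renderNetwork()` are
deterministic static exports drawing cells and edges from one shared
diverging scale over $[-1, 1]$.

# Knowledge annotation and the novelty rule

Curated knowledge enters as a flat table — `feature_id, disease,
status, source` with `status` from {`causal`, `associated`,
`unknown`} — the shape of a knowledge-graph query result reduced to
per-feature status. (Deploying a graph database or licensed pathway
content is deliberately out of scope; an exporter producing this CSV
from such a platform is a one-query job.) `annotateGraph()` is a pure
metadata join; `noveltyReport()` mechanizes the hypothesis rule: list
features whose $|w|$ to the disease node is at least $t$ and whose
status is not `causal`, strongest first. The report is a hypothesis
generator — correlation strength at the level of established causal
biomarkers, not evidence of causality.

# The synthetic cohort generator

Real cohorts of this kind are access-restricted, so validation uses a
generator with known ground truth. `simulateCohort()` draws features
from a latent-factor block model: feature $j$ in block $b$ is
$\sqrt{\rho}\, f_b + \sqrt{1-\rho}\,\varepsilon_j$ (all standard
normal, scaled by `noise_sd`), giving exactly $\rho$ within-block
correlation and zero across blocks. Group 2 means of the designated
features are shifted by `shift` population-IQR units, one unit being
$1.349 \times$ `noise_sd` (the IQR of a normal); parameterizing shifts
in IQR units ties the generator directly to the $\delta$ statistic.
For large shifts the realized $\delta$ is smaller than the nominal
shift because the pooled IQR of the two-group mixture widens — recovery
tests therefore check rank recovery, not $\delta$ magnitude.
Missingness is completely at random. Generation is seed-deterministic
and leaves the caller's RNG untouched.

The `"t2d-like"` preset fixes the study conditions used throughout the
tests: 201 samples per group, 28 features, 6 features shifted by 2.0
IQR units. `simulateMultiOmics()` column-concatenates independently
generated layers for the same samples and tags each feature with its
omics type; the validation design uses three blocks of 5 features at
$\rho = 0.7$ — a realistic within-pathway correlation for co-regulated
analytes — and 120 samples.

What the generator does *not* emulate: real marginal distributions
(features are standardized normals, not skewed positive analyte
scales), inter-block correlation, informative missingness, batch
effects. Passing recovery tests therefore demonstrates that the
statistics and the clustering recover planted structure under clean
conditions — not that they are robust to every artefact of real data.

# Numerical choices and edge cases

* Quantiles: type 7 throughout, injectable.
* Zero-variance features: an error in correlation graphs (the caller
  drops them deliberately), a warning-plus-drop in standardized sample
  distances.
* Pairwise-complete correlation requires $\ge 3$ overlapping samples.
* Undefined objectives/deltas are `NA` plus a flag, never `Inf`.
* Ties: MST edges by (distance, id pair); loading ranks by
  $(-|\delta|,$ feature id$)$; merge ties resolved by `stats::hclust`'s
  deterministic agglomeration.
* All stochastic steps (layout, simulation) take explicit seeds and
  restore the caller's RNG state.

# Problem sizes used in the shipped validation

The test-suite and the acceptance script regenerate everything from
code: 100 cohorts of 402 × 28 for loading-panel recovery, 100
three-block multi-omics cohorts of 120 × 15 for clustering recovery,
100 random metric configurations of up to 40 samples for abstraction
properties (with exhaustive spanning-tree enumeration up to 8 samples
as the MST oracle), 1,000 random inputs against a sort-and-interpolate
quantile oracle, and 500 randomized JSON round-trips. These sizes make
the whole validation run in minutes on one core while keeping every
check non-trivial.

# Known limitations

* The brush is a rectangle on the clustered order; patterns split
  across the leaf order need thresholding or a different clustering
  distance to come together.
* Matrix seriation beyond dendrogram leaf order is out of scope, as is
  any interactive front-end — this package is the headless core.
* The abstraction sweep is greedy in edge order (ascending distance);
  it does not search arbitrary edge subsets.
* Views are designed for up to ~500 nodes; beyond that the dense
  matrix and the sweep grow quadratically and a warning is issued.
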