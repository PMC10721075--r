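#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData rowData
#' @importFrom stats cor dist hclust cutree quantile median as.dist sd setNames rnorm runif
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' SampleTable: a sample-by-feature numeric matrix with metadata
#'
#' The central cohort container: `n` samples measured on `p` numeric
#' features (clinical biochemistry analytes, metabolite intensities, any
#' quantitative omics layer). Internally features are rows and samples are
#' columns, as in any [SummarizedExperiment::SummarizedExperiment-class];
#' the on-disk CSV convention (samples as rows, features as columns) is
#' handled at the IO boundary by [readSampleMatrix()] /
#' [writeSampleMatrix()]. Missing measurements are `NA`; every non-missing
#' value must be finite.
#'
#' Per-sample metadata (diagnosis labels, sex, ...) live in `colData`;
#' per-feature metadata (omics type, diagnosis-role flags, ...) in
#' `rowData`.
#'
#' @slot ... inherits all slots from `SummarizedExperiment`; the single
#'   assay is named `"values"`.
#' @seealso [SampleTable()], [featureMatrix()], [sampleIds()], [featureIds()]
#' @export
setClass("SampleTable", contains = "SummarizedExperiment")

.validSampleTable <- function(object) {
  msg <- character()
  if (!"values" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'values' is required")
  sid <- colnames(object)
  fid <- rownames(object)
  if (is.null(sid) || anyDuplicated(sid))
    msg <- c(msg, "sample identifiers must be present and unique")
  if (is.null(fid) || anyDuplicated(fid))
    msg <- c(msg, "feature identifiers must be present and unique")
  v <- SummarizedExperiment::assay(object, "values")
  if (!is.numeric(v))
    msg <- c(msg, "values must be numeric")
  bad <- !is.na(v) & !is.finite(v)
  if (any(bad))
    msg <- c(msg, "every non-missing value must be finite")
  if (length(msg)) msg else TRUE
}
setValidity("SampleTable", .validSampleTable)

#' ReferenceIntervals: per-feature normal-population bounds
#'
#' Population reference intervals (PRI): for each feature a `[low, high]`
#' range considered normal. Used by [filterHealthyReference()] to retain
#' only undiagnosed samples whose measurements all lie within range.
#'
#' @slot feature character vector of feature identifiers (unique).
#' @slot low,high numeric bounds in feature units, `low < high`.
#' @seealso [referenceIntervals()], [readReferenceIntervals()]
#' @export
setClass("ReferenceIntervals",
  representation(feature = "character", low = "numeric", high = "numeric"))

setValidity("ReferenceIntervals", function(object) {
  msg <- character()
  n <- length(object@feature)
  if (length(object@low) != n || length(object@high) != n)
    msg <- c(msg, "feature, low and high must have equal length")
  if (anyDuplicated(object@feature))
    msg <- c(msg, "feature identifiers must be unique")
  if (n && any(!is.finite(object@low) | !is.finite(object@high)))
    msg <- c(msg, "bounds must be finite")
  if (n && any(object@low >= object@high))
    msg <- c(msg, "low must be strictly below high for every feature")
  if (length(msg)) msg else TRUE
})

#' InteractionGraph: a weighted node-link graph with optional distances
#'
#' The JSON exchange object of the workflow: an ordered node table, a link
#' table with finite weights, and optionally a dense node-by-node distance
#' matrix aligned to the node order (used for hierarchical clustering of
#' the adjacency-matrix view). Self-links are not allowed; link endpoints
#' must exist; `dist`, when present, must be square, symmetric (1e-9),
#' non-negative with a zero diagonal.
#'
#' @slot nodes data.frame with at least columns `id` and `label`
#'   (characters, `id` unique); further columns are free node metadata.
#' @slot links data.frame with at least columns `source`, `target`
#'   (node ids) and `weight` (finite numeric); further columns are link
#'   metadata.
#' @slot dist a numeric matrix with side `nrow(nodes)` or `NULL`.
#' @seealso [interactionGraph()], [readGraphJSON()], [matrixToGraph()]
#' @export
setClass("InteractionGraph",
  representation(nodes = "data.frame", links = "data.frame",
                 dist = "matrixOrNULL"))

.validInteractionGraph <- function(object) {
  msg <- character()
  nd <- object@nodes
  lk <- object@links
  if (!all(c("id", "label") %in% names(nd)))
    msg <- c(msg, "nodes must have 'id' and 'label' columns")
  else {
    if (anyDuplicated(nd$id))
      msg <- c(msg, sprintf("duplicate node id(s): %s",
        paste(unique(nd$id[duplicated(nd$id)]), collapse = ", ")))
  }
  if (!all(c("source", "target", "weight") %in% names(lk)))
    msg <- c(msg, "links must have 'source', 'target' and 'weight' columns")
  else if ("id" %in% names(nd)) {
    dangling <- !(lk$source %in% nd$id) | !(lk$target %in% nd$id)
    if (any(dangling))
      msg <- c(msg, sprintf("link(s) with unknown endpoint: %s",
        paste(sprintf("%s--%s", lk$source[dangling], lk$target[dangling])[
          seq_len(min(5L, sum(dangling)))], collapse = ", ")))
    if (any(lk$source == lk$target))
      msg <- c(msg, "self-links are not allowed")
    if (nrow(lk) && any(!is.finite(lk$weight)))
      msg <- c(msg, "link weights must be finite")
  }
  d <- object@dist
  if (!is.null(d)) {
    p <- nrow(nd)
    if (!is.numeric(d) || nrow(d) != p || ncol(d) != p)
      msg <- c(msg, "dist must be a square numeric matrix with side |nodes|")
    else {
      if (any(!is.finite(d))) msg <- c(msg, "dist entries must be finite")
      else {
        if (max(abs(d - t(d))) > 1e-9)
          msg <- c(msg, "dist must be symmetric (tolerance 1e-9)")
        if (any(abs(diag(d)) > 1e-12))
          msg <- c(msg, "dist diagonal must be zero")
        if (any(d < 0))
          msg <- c(msg, "dist entries must be non-negative")
      }
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("InteractionGraph", .validInteractionGraph)

#' DistanceMatrix: sample-sample (or node-node) dissimilarities
#'
#' A labelled square matrix of non-negative dissimilarities: symmetric
#' within 1e-9, zero diagonal. The input to the topological abstraction.
#'
#' @slot ids ordered identifiers (unique).
#' @slot d square numeric matrix aligned to `ids`.
#' @seealso [sampleDistanceMatrix()], [stadAbstraction()]
#' @export
setClass("DistanceMatrix",
  representation(ids = "character", d = "matrix"))

setValidity("DistanceMatrix", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (anyDuplicated(object@ids)) msg <- c(msg, "ids must be unique")
  d <- object@d
  if (!is.numeric(d) || nrow(d) != n || ncol(d) != n)
    msg <- c(msg, "d must be a square numeric matrix with side |ids|")
  else {
    if (any(!is.finite(d))) msg <- c(msg, "distances must be finite")
    else {
      if (n && max(abs(d - t(d))) > 1e-9)
        msg <- c(msg, "d must be symmetric (tolerance 1e-9)")
      if (n && any(abs(diag(d)) > 1e-12))
        msg <- c(msg, "d diagonal must be zero")
      if (any(d < 0)) msg <- c(msg, "distances must be non-negative")
    }
  }
  if (length(msg)) msg else TRUE
})

#' StadGraph: a topological abstraction of a distance matrix
#'
#' The result of the STAD procedure: an unweighted graph on the samples,
#' grown from the minimum spanning tree by adding closest non-tree pairs
#' while it improves the Pearson correlation between unit-weight
#' shortest-path (hop) distances and the input distances. The graph is
#' always connected and contains the MST; `objective` is that correlation
#' for the returned edge set, and `swept_sizes` records the whole sweep
#' for audit.
#'
#' @slot sample_ids ordered sample identifiers.
#' @slot edges character matrix with two columns, one row per unordered
#'   edge, each row ordered (smaller id, larger id).
#' @slot objective correlation in `[-1, 1]` of hop vs input distances.
#' @slot swept_sizes data.frame with columns `edge_count`, `objective`.
#' @slot dist the source [DistanceMatrix-class] (kept so the objective is
#'   auditable).
#' @seealso [stadAbstraction()], [graphObjective()], [graphFromTopology()]
#' @export
setClass("StadGraph",
  representation(sample_ids = "character", edges = "matrix",
                 objective = "numeric", swept_sizes = "data.frame",
                 dist = "DistanceMatrix"))

setValidity("StadGraph", function(object) {
  msg <- character()
  ids <- object@sample_ids
  e <- object@edges
  if (ncol(e) != 2 && nrow(e) > 0)
    msg <- c(msg, "edges must have two columns")
  if (nrow(e) && !all(e %in% ids))
    msg <- c(msg, "edge endpoints must be sample ids")
  if (length(ids) >= 2 && nrow(e) < length(ids) - 1)
    msg <- c(msg, "too few edges to span the samples")
  if (length(ids) >= 2 && nrow(e)) {
    g <- igraph::graph_from_edgelist(e, directed = FALSE)
    g <- igraph::add_vertices(g, sum(!ids %in% igraph::V(g)$name),
                              name = ids[!ids %in% igraph::V(g)$name])
    if (!igraph::is_connected(g))
      msg <- c(msg, "graph must be connected")
  }
  if (!identical(object@dist@ids, ids))
    msg <- c(msg, "dist ids must match sample_ids")
  if (length(msg) == 0 && length(ids) >= 3) {
    obj <- graphObjective(e, object@dist)
    if (is.na(obj) != is.na(object@objective) ||
        (!is.na(obj) && abs(obj - object@objective) > 1e-9))
      msg <- c(msg, "stored objective does not match recomputation")
  }
  if (length(msg)) msg else TRUE
})

#' ClusteredMatrix: a reordered adjacency-matrix view state
#'
#' Captures everything the matrix view needs: the underlying
#' [InteractionGraph-class], the dendrogram (`stats::hclust` fit), the
#' resulting leaf order, the cut level (number of sub-trees retained) and
#' the node-to-cluster assignment. Each cluster is a contiguous run in
#' leaf order.
#'
#' @slot graph the clustered [InteractionGraph-class].
#' @slot order integer permutation of node indices (dendrogram leaf order).
#' @slot hclust the `stats::hclust` object (merges and heights).
#' @slot cut_level number of sub-trees requested (clamped to `[1, n]`).
#' @slot assignment integer cluster id per node, named by node id.
#' @seealso [clusterOrder()], [cutDendrogram()], [brushSubgraph()],
#'   [subtreeSubgraph()]
#' @export
setClass("ClusteredMatrix",
  representation(graph = "InteractionGraph", order = "integer",
                 hclust = "ANY", cut_level = "integer",
                 assignment = "integer"))

setValidity("ClusteredMatrix", function(object) {
  msg <- character()
  n <- nrow(object@graph@nodes)
  if (!identical(sort(object@order), seq_len(n)))
    msg <- c(msg, "order must be a permutation of the node indices")
  if (n >= 2) {
    h <- object@hclust
    if (!inherits(h, "hclust"))
      msg <- c(msg, "hclust slot must hold an hclust fit")
    else {
      if (nrow(h$merge) != n - 1)
        msg <- c(msg, "dendrogram must have |nodes|-1 agglomeration steps")
      if (is.unsorted(h$height))
        msg <- c(msg, "merge heights must be non-decreasing")
    }
  }
  if (object@cut_level < 1L)
    msg <- c(msg, "cut_level must be positive")
  k <- length(unique(object@assignment))
  if (length(object@assignment) != n ||
      k != min(object@cut_level, max(n, 1L)))
    msg <- c(msg, "assignment must have exactly min(cut_level, |nodes|) clusters")
  if (length(msg)) msg else TRUE
})

#' BrushRegion: a contiguous rectangle on the reordered matrix
#'
#' Inclusive 1-based index intervals on the reordered row and column axes
#' of a [ClusteredMatrix-class]. Brushing is contiguous by construction:
#' only a rectangle of adjacent cells can be selected.
#'
#' @slot row_range,col_range integer vectors `c(from, to)`, `from <= to`.
#' @seealso [brushRegion()], [brushSubgraph()]
#' @export
setClass("BrushRegion",
  representation(row_range = "integer", col_range = "integer"))

setValidity("BrushRegion", function(object) {
  msg <- character()
  for (nm in c("row_range", "col_range")) {
    r <- slot(object, nm)
    if (length(r) != 2L || any(r < 1L) || r[1] > r[2])
      msg <- c(msg, sprintf("%s must be c(from, to) with 1 <= from <= to", nm))
  }
  if (length(msg)) msg else TRUE
})

#' AnnotationTable: curated feature-disease association records
#'
#' One record per (feature, disease) pair with a status from the closed
#' vocabulary `causal`, `associated`, `unknown` plus a free-text source.
#' Stands in for a knowledge-graph query result (e.g. an export from an
#' open clinical knowledge graph): only the per-feature status is
#' modelled, not the evidence network behind it.
#'
#' @slot records data.frame with columns `feature_id`, `disease`,
#'   `status`, `source`.
#' @seealso [annotationTable()], [readAnnotations()], [annotateGraph()],
#'   [noveltyReport()]
#' @export
setClass("AnnotationTable", representation(records = "data.frame"))

setValidity("AnnotationTable", function(object) {
  msg <- character()
  r <- object@records
  need <- c("feature_id", "disease", "status", "source")
  if (!all(need %in% names(r)))
    msg <- c(msg, "records need columns feature_id, disease, status, source")
  else {
    bad <- !r$status %in% c("causal", "associated", "unknown")
    if (any(bad))
      msg <- c(msg, sprintf("unknown status token(s): %s",
        paste(unique(r$status[bad]), collapse = ", ")))
    if (anyDuplicated(r[c("feature_id", "disease")]))
      msg <- c(msg, "(feature_id, disease) pairs must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' CohortSpec: parameters of the synthetic two-group cohort generator
#'
#' Defines a two-group cohort with `p` features on a standardized scale:
#' a latent-factor block-correlation structure (features in the same
#' block share a common factor with loading `sqrt(rho)`), a set of
#' features whose group-2 mean is shifted by a stated number of
#' normal-population IQR units, completely-at-random missingness, and a
#' seed making generation deterministic.
#'
#' @slot n_per_group samples per group.
#' @slot p number of features.
#' @slot shifted_idx,shift feature indices shifted in group 2 and the
#'   shift sizes in population-IQR units (recycled).
#' @slot blocks integer block assignment of the `p` features.
#' @slot rho within-block correlation in `[0, 1)`.
#' @slot noise_sd marginal feature standard deviation.
#' @slot missing_rate fraction of cells set missing, in `[0, 1)`.
#' @slot seed integer RNG seed.
#' @seealso [cohortSpec()], [simulateCohort()], [simulateMultiOmics()]
#' @export
setClass("CohortSpec",
  representation(n_per_group = "integer", p = "integer",
                 shifted_idx = "integer", shift = "numeric",
                 blocks = "integer", rho = "numeric",
                 noise_sd = "numeric", missing_rate = "numeric",
                 seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@n_per_group < 1L) msg <- c(msg, "n_per_group must be >= 1")
  if (object@p < 1L) msg <- c(msg, "p must be >= 1")
  if (length(object@blocks) != object@p)
    msg <- c(msg, "blocks must assign every feature")
  if (length(object@shifted_idx) &&
      (any(object@shifted_idx < 1L) || any(object@shifted_idx > object@p)))
    msg <- c(msg, "shifted feature indices out of range")
  if (anyDuplicated(object@shifted_idx))
    msg <- c(msg, "shifted feature indices must be unique")
  if (object@rho < 0 || object@rho >= 1)
    msg <- c(msg, "rho must lie in [0, 1)")
  if (object@noise_sd <= 0) msg <- c(msg, "noise_sd must be positive")
  if (object@missing_rate < 0 || object@missing_rate >= 1)
    msg <- c(msg, "missing_rate must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})
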