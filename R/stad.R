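#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a DistanceMatrix
#' @param ids ordered identifiers
#' @param d square numeric matrix of dissimilarities
#' @return a validated [DistanceMatrix-class]
#' @export
distanceMatrix <- function(ids, d) {
  d <- as.matrix(d)
  ids <- as.character(ids)
  dimnames(d) <- list(ids, ids)
  new("DistanceMatrix", ids = ids, d = d)
}

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "DistanceMatrix", function(x) x@ids)

#' @rdname graphDist
#' @export
setMethod("graphDist", "DistanceMatrix", function(x) x@d)

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix: %d ids\n", length(object@ids)))
})

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "StadGraph", function(x) x@sample_ids)

#' @rdname stadEdges
#' @export
setMethod("stadEdges", "StadGraph", function(x) x@edges)

setMethod("show", "StadGraph", function(object) {
  cat(sprintf(
    "StadGraph: %d sample(s), %d edge(s), objective %.4f (MST %d edges)\n",
    length(object@sample_ids), nrow(object@edges), object@objective,
    length(object@sample_ids) - 1L))
})

#' Sample-sample distance matrix of a cohort
#'
#' Pairwise dissimilarities between samples over the feature columns.
#' Features are z-standardized by default because clinical and omics
#' features come in heterogeneous units; zero-variance features cannot
#' be standardized and are dropped with a warning. Missing values are
#' handled by [stats::dist()]'s pairwise exclusion with rescaling.
#'
#' @param table a [SampleTable-class]; no feature may be entirely missing
#' @param metric any method of [stats::dist()] (default `"euclidean"`)
#' @param standardize z-scale each feature first (default `TRUE`)
#' @return a [DistanceMatrix-class] over the samples
#' @export
sampleDistanceMatrix <- function(table, metric = "euclidean",
                                 standardize = TRUE) {
  m <- featureMatrix(table)
  allmiss <- colSums(!is.na(m)) == 0
  if (any(allmiss))
    stop("feature(s) entirely missing: ",
         paste(colnames(m)[allmiss], collapse = ", "))
  if (standardize) {
    sds <- apply(m, 2, stats::sd, na.rm = TRUE)
    flat <- is.na(sds) | sds == 0
    if (any(flat)) {
      warning("dropping zero-variance feature(s): ",
              paste(colnames(m)[flat], collapse = ", "))
      m <- m[, !flat, drop = FALSE]
    }
    m <- scale(m)
  }
  d <- as.matrix(stats::dist(m, method = metric))
  if (any(is.na(d)))
    stop("distance undefined for some sample pair (no shared features)")
  distanceMatrix(rownames(m), d)
}

# ordered (smaller, larger) id pair rows for a set of index pairs
.edge_ids <- function(ids, i, j) {
  a <- ids[i]; b <- ids[j]
  swap <- a > b
  cbind(ifelse(swap, b, a), ifelse(swap, a, b), deparse.level = 0)
}

#' Minimum spanning tree of a distance matrix
#'
#' Kruskal's algorithm with a fully deterministic tie-break: candidate
#' edges are considered in increasing (distance, smaller id, larger id)
#' order, so equal-weight ties always resolve the same way.
#'
#' @param dist a [DistanceMatrix-class] with at least 2 ids
#' @return character matrix of `n - 1` edges, each row
#'   `(smaller id, larger id)`, in insertion order
#' @export
minimumSpanningTree <- function(dist) {
  ids <- dist@ids
  n <- length(ids)
  if (n < 2) stop("need at least 2 samples")
  ut <- which(upper.tri(dist@d), arr.ind = TRUE)
  pairs <- .edge_ids(ids, ut[, 1], ut[, 2])
  o <- order(dist@d[ut], pairs[, 1], pairs[, 2], method = "radix")
  ut <- ut[o, , drop = FALSE]
  pairs <- pairs[o, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  keep <- logical(nrow(pairs))
  taken <- 0L
  for (k in seq_len(nrow(pairs))) {
    ra <- find(ut[k, 1]); rb <- find(ut[k, 2])
    if (ra != rb) {
      parent[ra] <- rb
      keep[k] <- TRUE
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  pairs[keep, , drop = FALSE]
}

.igraph_from_edges <- function(edges, ids) {
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(edges)) g <- igraph::add_edges(g, t(matrix(match(edges, ids),
                                                      ncol = 2)))
  g
}

#' Fit of a graph to its source distances
#'
#' Pearson correlation between the unit-weight shortest-path (hop)
#' distances of the graph and the input distances, over the condensed
#' upper triangle. This is the objective the topological abstraction
#' maximizes: 1 means graph hops perfectly rank-reproduce the metric
#' structure. Undefined (NA, with a warning) when hop distances have
#' zero variance, e.g. on a complete graph.
#'
#' @param edges two-column matrix (or data.frame) of id pairs connecting
#'   all samples
#' @param dist the source [DistanceMatrix-class]
#' @return correlation in `[-1, 1]`, or `NA` when undefined
#' @export
graphObjective <- function(edges, dist) {
  edges <- as.matrix(edges)
  ids <- dist@ids
  g <- .igraph_from_edges(edges, ids)
  if (!igraph::is_connected(g))
    stop("graph is disconnected: hop distances are infinite")
  hops <- igraph::distances(g, weights = NA)
  hops <- hops[ids, ids]
  uh <- hops[upper.tri(hops)]
  ud <- dist@d[upper.tri(dist@d)]
  if (stats::sd(uh) == 0 || stats::sd(ud) == 0) {
    warning("objective undefined: zero variance in hop or input distances")
    return(NA_real_)
  }
  stats::cor(uh, ud)
}

#' Topological abstraction of a distance matrix
#'
#' Builds the sample-similarity graph: starting from the minimum
#' spanning tree, non-tree pairs are considered in ascending distance
#' order and cumulatively added; at each swept edge count the hop-vs-
#' input-distance correlation ([graphObjective()]) is evaluated, and the
#' edge set with the highest objective is returned (ties favour fewer
#' edges). The sweep evaluates every candidate count when there are at
#' most `sweep_cap` candidate pairs, otherwise 100 log-spaced counts.
#' Deterministic for a given input.
#'
#' @param dist a [DistanceMatrix-class] with at least 3 ids
#' @param sweep_cap exhaustive-sweep limit on candidate pairs
#' @param grid optional explicit vector of candidate-addition counts to
#'   evaluate (0 = MST only); overrides the automatic grid
#' @return a [StadGraph-class]; its `swept_sizes` slot records the sweep
#' @export
stadAbstraction <- function(dist, sweep_cap = 2000, grid = NULL) {
  ids <- dist@ids
  n <- length(ids)
  if (n < 3) stop("need at least 3 samples")
  mst <- minimumSpanningTree(dist)
  key <- function(e) paste(e[, 1], e[, 2], sep = "\r")
  ut <- which(upper.tri(dist@d), arr.ind = TRUE)
  pairs <- .edge_ids(ids, ut[, 1], ut[, 2])
  o <- order(dist@d[ut], pairs[, 1], pairs[, 2], method = "radix")
  pairs <- pairs[o, , drop = FALSE]
  cand <- pairs[!key(pairs) %in% key(mst), , drop = FALSE]
  K <- nrow(cand)
  if (is.null(grid))
    grid <- if (K <= sweep_cap) 0:K
            else unique(c(0L, round(exp(seq(0, log(K), length.out = 100)))))
  grid <- sort(unique(pmin(as.integer(grid), K)))
  sweep <- data.frame(edge_count = integer(), objective = numeric())
  best_obj <- -Inf; best_m <- 0L
  for (m in grid) {
    edges <- rbind(mst, cand[seq_len(m), , drop = FALSE])
    obj <- withCallingHandlers(graphObjective(edges, dist),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.na(obj)) next  # zero-variance hop distances at this size
    sweep <- rbind(sweep,
                   data.frame(edge_count = nrow(edges), objective = obj))
    if (obj > best_obj + 1e-12) { best_obj <- obj; best_m <- m }
  }
  if (!is.finite(best_obj))
    stop("objective undefined at every swept size")
  edges <- rbind(mst, cand[seq_len(best_m), , drop = FALSE])
  new("StadGraph", sample_ids = ids, edges = edges, objective = best_obj,
      swept_sizes = sweep, dist = dist)
}

#' Deterministic force-directed layout
#'
#' Fruchterman–Reingold coordinates in 2 or 3 dimensions with a fixed
#' seed: the same graph and seed always give identical coordinates. The
#' caller's RNG state is left untouched.
#'
#' @param graph a [StadGraph-class] or [InteractionGraph-class]
#' @param dims 2 (default) or 3
#' @param seed integer seed
#' @return numeric matrix of coordinates, one row per node, rownames =
#'   node ids
#' @export
layoutGraph <- function(graph, dims = 2, seed = 1) {
  stopifnot(dims %in% c(2, 3))
  if (is(graph, "StadGraph")) {
    ids <- graph@sample_ids
    g <- .igraph_from_edges(graph@edges, ids)
  } else {
    ids <- graph@nodes$id
    g <- .igraph_from_edges(as.matrix(graph@links[, c("source", "target")]),
                            ids)
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  xy <- igraph::layout_with_fr(g, dim = dims, niter = 500)
  rownames(xy) <- ids
  xy
}
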