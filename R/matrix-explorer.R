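#' @include AllClasses.R AllGenerics.R graph-model.R
NULL

#' @rdname leafOrder
#' @export
setMethod("leafOrder", "ClusteredMatrix", function(x) x@order)

#' @rdname clusterAssignment
#' @export
setMethod("clusterAssignment", "ClusteredMatrix", function(x) x@assignment)

setMethod("show", "ClusteredMatrix", function(object) {
  cat(sprintf(
    "ClusteredMatrix: %d node(s), cut level %d (%d cluster(s))\n",
    nrow(object@graph@nodes), object@cut_level,
    length(unique(object@assignment))))
})

.cluster_distance_matrix <- function(graph, distance) {
  if (distance == "precomputed") {
    if (!is.null(graph@dist)) return(graph@dist)
    distance <- "one_minus_weight"  # documented fallback
  }
  if (distance == "one_minus_weight") {
    d <- 1 - weightMatrix(graph)
    diag(d) <- 0
    d[d < 0] <- 0
    return(d)
  }
  # profile distance between rows of the dense weight matrix
  as.matrix(stats::dist(weightMatrix(graph), method = distance))
}

#' Hierarchically cluster a graph's adjacency matrix
#'
#' Agglomerative clustering of the nodes on the graph's distance matrix
#' (by default the precomputed `dist` the formatting step attached, e.g.
#' Canberra between feature profiles; when absent, `1 - weight` on the
#' correlation scale is the fallback). The dendrogram leaf order becomes
#' the displayed row/column order of the adjacency matrix, and the
#' dendrogram is cut so that `cut_level` sub-trees remain, colouring
#' contiguous runs of leaves. Deterministic for fixed input.
#'
#' @param graph an [InteractionGraph-class]
#' @param distance `"precomputed"` (use `graph` dist, falling back to
#'   `1 - weight` when absent), `"one_minus_weight"`, or any
#'   [stats::dist()] method applied to the rows of the dense weight
#'   matrix (e.g. `"canberra"`)
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   `"average"`)
#' @param cut_level number of sub-trees retained (default 5, the setting
#'   used throughout the worked examples)
#' @return a [ClusteredMatrix-class]
#' @export
clusterOrder <- function(graph, distance = "precomputed",
                         linkage = "average", cut_level = 5) {
  validObject(graph)
  n <- nNodes(graph)
  if (n < 2) stop("need at least 2 nodes to cluster")
  d <- .cluster_distance_matrix(graph, distance)
  dimnames(d) <- list(graph@nodes$id, graph@nodes$id)
  h <- stats::hclust(stats::as.dist(d), method = linkage)
  cm <- new("ClusteredMatrix", graph = graph, order = h$order, hclust = h,
            cut_level = 1L,
            assignment = stats::setNames(rep(1L, n), graph@nodes$id))
  cutDendrogram(cm, cut_level)
}

#' Cut the dendrogram into a number of sub-trees
#'
#' Cuts the agglomeration sequence so that `level` sub-trees remain
#' (count semantics, clamped to `[1, n]`): the assignment drives sub-tree
#' colouring and one-click sub-tree extraction. Every cluster is a
#' contiguous run in leaf order.
#'
#' @param cm a [ClusteredMatrix-class]
#' @param level positive integer; `level > n` clamps to `n` singletons
#' @return the [ClusteredMatrix-class] with updated `cut_level` and
#'   assignment (read it with [clusterAssignment()])
#' @export
cutDendrogram <- function(cm, level) {
  stopifnot(level >= 1)
  n <- nrow(cm@graph@nodes)
  k <- as.integer(min(level, n))
  assignment <- if (n == 1) stats::setNames(1L, cm@graph@nodes$id)
                else stats::cutree(cm@hclust, k = k)
  cm@cut_level <- as.integer(level)
  cm@assignment <- stats::setNames(as.integer(assignment),
                                   cm@graph@nodes$id)
  validObject(cm)
  cm
}

#' Filter links by weight threshold
#'
#' Retains links whose absolute weight (default) or signed weight is at
#' least `t`; all nodes are kept, so thresholding can isolate nodes.
#' Absolute comparison is the default so that strong negative
#' correlations survive. Monotone: a higher threshold keeps a subset.
#'
#' @param graph an [InteractionGraph-class]
#' @param t non-negative threshold (documented presets from the worked
#'   type-2-diabetes examples: 0.28 for the matrix view caption and 0.18
#'   for the node-link view; neither is privileged)
#' @param use_absolute compare `|weight|` (default) or signed weight
#' @return the thresholded [InteractionGraph-class]
#' @export
thresholdEdges <- function(graph, t, use_absolute = TRUE) {
  w <- if (use_absolute) abs(graph@links$weight) else graph@links$weight
  links <- graph@links[w >= t, , drop = FALSE]
  rownames(links) <- NULL
  iso <- setdiff(graph@nodes$id, c(links$source, links$target))
  if (length(iso) && nrow(graph@links))
    message(length(iso), " node(s) isolated at threshold ", t)
  interactionGraph(graph@nodes, links, dist = graph@dist)
}

#' Construct a brush region
#' @param rows,cols inclusive 1-based `c(from, to)` intervals on the
#'   reordered row and column axes
#' @return a [BrushRegion-class]
#' @export
brushRegion <- function(rows, cols = rows) {
  new("BrushRegion", row_range = as.integer(rows), col_range = as.integer(cols))
}

#' Extract the subgraph under a brushed matrix region
#'
#' Brushing selects a contiguous rectangle of cells on the reordered
#' adjacency matrix. The extracted node set is the union of the nodes
#' spanned by the row and column intervals; the extracted links are the
#' links whose cell, in either orientation, falls inside the rectangle
#' — both endpoints therefore lie in the node set — subject to the edge
#' threshold `t`.
#'
#' @param cm a [ClusteredMatrix-class]
#' @param region a [BrushRegion-class] within `[1, n]`
#' @param t edge threshold applied on `|weight|` (default 0: keep all)
#' @return an [InteractionGraph-class]
#' @export
brushSubgraph <- function(cm, region, t = 0) {
  validObject(region)
  ids <- cm@graph@nodes$id
  n <- length(ids)
  if (any(c(region@row_range, region@col_range) > n))
    stop("brush region exceeds the matrix")
  ord_ids <- ids[cm@order]
  rset <- ord_ids[region@row_range[1]:region@row_range[2]]
  cset <- ord_ids[region@col_range[1]:region@col_range[2]]
  nset <- union(rset, cset)
  lk <- cm@graph@links
  inside <- (lk$source %in% rset & lk$target %in% cset) |
            (lk$target %in% rset & lk$source %in% cset)
  lk <- lk[inside & abs(lk$weight) >= t, , drop = FALSE]
  nodes <- cm@graph@nodes[cm@graph@nodes$id %in% nset, , drop = FALSE]
  interactionGraph(nodes, lk)
}

#' Extract one dendrogram sub-tree as a subgraph
#'
#' One-click equivalent of brushing the cluster's diagonal block: the
#' induced subgraph on the nodes of one cut cluster, subject to the edge
#' threshold. Exactly equal to [brushSubgraph()] on the cluster's
#' contiguous run in leaf order.
#'
#' @param cm a [ClusteredMatrix-class]
#' @param cluster_id a cluster id present in the assignment
#' @param t edge threshold on `|weight|`
#' @return an [InteractionGraph-class]
#' @export
subtreeSubgraph <- function(cm, cluster_id, t = 0) {
  if (!cluster_id %in% cm@assignment)
    stop("unknown cluster id: ", cluster_id)
  members <- names(cm@assignment)[cm@assignment == cluster_id]
  pos <- which(cm@graph@nodes$id[cm@order] %in% members)
  brushSubgraph(cm, brushRegion(range(pos)), t)
}

#' Colour nodes by metadata or dendrogram sub-tree
#'
#' Adds a `colour_group` metadata key to every node: either the value of
#' an existing node-metadata key (missing values become `"unknown"`), or
#' the dendrogram cluster id from a [ClusteredMatrix-class] so node
#' colours match the sub-tree colours of the matrix view.
#'
#' @param graph an [InteractionGraph-class]
#' @param scheme `"dendrogram"` or the name of a node metadata column
#' @param cm required [ClusteredMatrix-class] when
#'   `scheme = "dendrogram"`
#' @return the graph with a `colour_group` node column
#' @export
colorNodes <- function(graph, scheme, cm = NULL) {
  nodes <- graph@nodes
  if (identical(scheme, "dendrogram")) {
    if (is.null(cm)) stop("dendrogram colouring needs a ClusteredMatrix")
    grp <- as.character(cm@assignment[nodes$id])
    grp[is.na(grp)] <- "unknown"
  } else {
    if (!scheme %in% names(nodes)) {
      grp <- rep("unknown", nrow(nodes))
    } else {
      grp <- as.character(nodes[[scheme]])
      grp[is.na(grp)] <- "unknown"
    }
  }
  nodes$colour_group <- grp
  interactionGraph(nodes, graph@links, dist = graph@dist)
}
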