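#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an InteractionGraph
#'
#' @param nodes a data.frame with columns `id` (required) and optionally
#'   `label` plus free metadata columns, or a character vector of ids.
#' @param links a data.frame with columns `source`, `target`, `weight`
#'   (or `value`, accepted as an alias) plus free metadata columns.
#'   Omitted or `NULL` means no links.
#' @param dist optional square node-node distance matrix in node order.
#' @return a validated [InteractionGraph-class]
#' @examples
#' g <- interactionGraph(c("a", "b"),
#'   data.frame(source = "a", target = "b", weight = 0.5))
#' @export
interactionGraph <- function(nodes, links = NULL, dist = NULL) {
  if (is.character(nodes)) nodes <- data.frame(id = nodes)
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!"id" %in% names(nodes)) stop("nodes need an 'id' column")
  nodes$id <- as.character(nodes$id)
  if (!"label" %in% names(nodes)) nodes$label <- nodes$id
  nodes$label <- as.character(nodes$label)
  nodes <- nodes[, c("id", "label",
                     setdiff(names(nodes), c("id", "label"))), drop = FALSE]
  if (is.null(links) || !nrow(as.data.frame(links)))
    links <- data.frame(source = character(), target = character(),
                        weight = numeric())
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  if (!"weight" %in% names(links) && "value" %in% names(links))
    names(links)[names(links) == "value"] <- "weight"
  if (!all(c("source", "target", "weight") %in% names(links)))
    stop("links need 'source', 'target' and 'weight' (or 'value') columns")
  links$source <- as.character(links$source)
  links$target <- as.character(links$target)
  links$weight <- as.numeric(links$weight)
  links <- links[, c("source", "target", "weight",
                     setdiff(names(links), c("source", "target", "weight"))),
                 drop = FALSE]
  rownames(nodes) <- NULL
  rownames(links) <- NULL
  if (!is.null(dist)) {
    dist <- as.matrix(dist)
    dimnames(dist) <- list(nodes$id, nodes$id)
  }
  new("InteractionGraph", nodes = nodes, links = links, dist = dist)
}

#' @rdname graphNodes
#' @export
setMethod("graphNodes", "InteractionGraph", function(x) x@nodes)

#' @rdname graphLinks
#' @export
setMethod("graphLinks", "InteractionGraph", function(x) x@links)

#' @rdname graphDist
#' @export
setMethod("graphDist", "InteractionGraph", function(x) x@dist)

setMethod("show", "InteractionGraph", function(object) {
  cat(sprintf("InteractionGraph: %d node(s), %d link(s)%s\n",
              nrow(object@nodes), nrow(object@links),
              if (!is.null(object@dist)) ", with dist matrix" else ""))
  extra <- setdiff(names(object@nodes), c("id", "label"))
  if (length(extra))
    cat("  node metadata: ", paste(extra, collapse = ", "), "\n", sep = "")
})

#' Number of nodes / links
#' @param graph an [InteractionGraph-class]
#' @return integer count
#' @export
nNodes <- function(graph) nrow(graph@nodes)

#' @rdname nNodes
#' @export
nLinks <- function(graph) nrow(graph@links)

#' Symmetric weight matrix of a graph
#'
#' Dense node-by-node matrix with the link weight in both orientations,
#' zero where no link exists and on the diagonal. Cell `(i, j)` of the
#' reordered matrix view equals `weightMatrix(g)[order[i], order[j]]`.
#'
#' @param graph an [InteractionGraph-class]
#' @return numeric matrix with node ids as dimnames
#' @export
weightMatrix <- function(graph) {
  ids <- graph@nodes$id
  w <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  lk <- graph@links
  if (nrow(lk)) {
    w[cbind(lk$source, lk$target)] <- lk$weight
    w[cbind(lk$target, lk$source)] <- lk$weight
  }
  w
}

.coerce_meta <- function(v) {
  if (is.list(v)) v <- vapply(v, function(e) {
    if (is.null(e) || length(e) == 0) NA_character_
    else as.character(e[[1]])
  }, character(1))
  v
}

#' Read a node-link graph from JSON
#'
#' Expects a JSON object with top-level `nodes` and `links` arrays and an
#' optional `dist` array of arrays (row-major, node order). Link weights
#' may be under `value` (canonical) or `weight`. Unknown node/link fields
#' are preserved as metadata columns.
#'
#' @param path file path
#' @return a validated [InteractionGraph-class]
#' @export
readGraphJSON <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  if (!is.list(obj) || !all(c("nodes", "links") %in% names(obj)))
    stop("graph JSON must contain top-level 'nodes' and 'links' arrays")
  nodes <- obj$nodes
  if (length(nodes) == 0) nodes <- data.frame(id = character())
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  nodes[] <- lapply(nodes, .coerce_meta)
  links <- obj$links
  if (length(links) == 0)
    links <- data.frame(source = character(), target = character(),
                        weight = numeric())
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  dist <- NULL
  if (!is.null(obj$dist)) {
    dist <- obj$dist
    if (is.list(dist)) dist <- do.call(rbind, dist)
    dist <- as.matrix(dist)
  }
  interactionGraph(nodes, links, dist)
}

#' Write a node-link graph as canonical JSON
#'
#' Canonical form: keys sorted within each object, node and link order
#' preserved, link weight serialized under `value`, `dist` as an array of
#' arrays in node order. [readGraphJSON()] after `writeGraphJSON()` is
#' the identity.
#'
#' @param graph an [InteractionGraph-class]
#' @param path output path
#' @export
writeGraphJSON <- function(graph, path) {
  validObject(graph)
  sorted_records <- function(df) {
    df <- df[, order(names(df)), drop = FALSE]
    lapply(seq_len(nrow(df)), function(i) {
      rec <- as.list(df[i, , drop = FALSE])
      rec[!vapply(rec, function(v) is.na(v) || is.null(v), logical(1))]
    })
  }
  lk <- graph@links
  names(lk)[names(lk) == "weight"] <- "value"
  out <- list(links = sorted_records(lk), nodes = sorted_records(graph@nodes))
  if (!is.null(graph@dist))
    out$dist <- unname(lapply(seq_len(nrow(graph@dist)),
                              function(i) graph@dist[i, ]))
  out <- out[order(names(out))]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE, null = "null")
  invisible(path)
}

#' Build a feature correlation graph from a cohort matrix
#'
#' The formatting step of the workflow: one node per feature (carrying
#' the feature metadata), one link per unordered feature pair weighted by
#' their correlation across samples, and a node-node distance matrix for
#' the clustered adjacency-matrix view (default Canberra distance between
#' the feature profiles). Missing values are handled pairwise-complete
#' with a minimum overlap of 3 samples per pair.
#'
#' @param table a [SampleTable-class] with at least 3 samples and 2
#'   features
#' @param correlation `"pearson"` (default) or `"spearman"`
#' @param cluster_distance distance between feature columns for the
#'   `dist` matrix; any method of [stats::dist()], default `"canberra"`
#' @param power optional exponent applied as
#'   `sign(r) * abs(r)^power` (soft-threshold style weighting); default 1
#'   leaves plain correlations.
#' @return an [InteractionGraph-class] with `p(p-1)/2` links
#' @export
matrixToGraph <- function(table, correlation = c("pearson", "spearman"),
                          cluster_distance = "canberra", power = 1) {
  correlation <- match.arg(correlation)
  m <- featureMatrix(table)
  if (nrow(m) < 3) stop("need at least 3 samples")
  if (ncol(m) < 2) stop("need at least 2 features")
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  flat <- colnames(m)[is.na(sds) | sds == 0]
  if (length(flat))
    stop("correlation undefined for zero-variance feature(s): ",
         paste(flat, collapse = ", "))
  nobs <- crossprod(!is.na(m))
  if (any(nobs[upper.tri(nobs)] < 3))
    stop("fewer than 3 pairwise-complete samples for some feature pair")
  r <- stats::cor(m, use = "pairwise.complete.obs", method = correlation)
  if (power != 1) r <- sign(r) * abs(r)^power
  ut <- which(upper.tri(r), arr.ind = TRUE)
  links <- data.frame(source = colnames(m)[ut[, 1]],
                      target = colnames(m)[ut[, 2]],
                      weight = r[ut])
  d <- as.matrix(stats::dist(t(m), method = cluster_distance))
  fmeta <- as.data.frame(featureData(table))
  nodes <- cbind(data.frame(id = colnames(m)), fmeta)
  interactionGraph(nodes, links, dist = d)
}

#' Convert a topological sample abstraction to an interaction graph
#'
#' Nodes are the samples; links are the abstraction's edges, each
#' annotated with the original distance between the two samples it
#' connects, so the topology can be explored in the adjacency-matrix
#' view like any other interaction data.
#'
#' @param stad_graph a [StadGraph-class]
#' @return an [InteractionGraph-class]
#' @export
graphFromTopology <- function(stad_graph) {
  ids <- stad_graph@sample_ids
  e <- stad_graph@edges
  d <- stad_graph@dist@d
  dimnames(d) <- list(ids, ids)
  links <- if (nrow(e))
    data.frame(source = e[, 1], target = e[, 2], weight = d[e])
  else NULL
  interactionGraph(ids, links)
}
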