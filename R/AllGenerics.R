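#' @include AllClasses.R
NULL

#' Sample identifiers of a container
#' @param x a [SampleTable-class], [DistanceMatrix-class] or
#'   [StadGraph-class]
#' @return character vector of sample ids, in container order
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Feature identifiers of a container
#' @param x a [SampleTable-class]
#' @return character vector of feature ids
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' Numeric measurement matrix, samples as rows
#' @param x a [SampleTable-class]
#' @return numeric matrix, `n` samples by `p` features, dimnames set
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Per-sample metadata
#' @param x a [SampleTable-class]
#' @return a [S4Vectors::DataFrame-class] with one row per sample
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' Per-feature metadata
#' @param x a [SampleTable-class]
#' @return a [S4Vectors::DataFrame-class] with one row per feature
#' @export
setGeneric("featureData", function(x) standardGeneric("featureData"))

#' Node table of a graph
#' @param x an [InteractionGraph-class]
#' @return data.frame of nodes (id, label, metadata columns)
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' Link table of a graph
#' @param x an [InteractionGraph-class]
#' @return data.frame of links (source, target, weight, metadata columns)
#' @export
setGeneric("graphLinks", function(x) standardGeneric("graphLinks"))

#' Node-node distance matrix of a graph
#' @param x an [InteractionGraph-class] or [DistanceMatrix-class]
#' @return numeric matrix, or `NULL` when the graph carries no distances
#' @export
setGeneric("graphDist", function(x) standardGeneric("graphDist"))

#' Edge list of a topological abstraction
#' @param x a [StadGraph-class]
#' @return two-column character matrix of unordered edges
#' @export
setGeneric("stadEdges", function(x) standardGeneric("stadEdges"))

#' Leaf order of a clustered matrix view
#' @param x a [ClusteredMatrix-class]
#' @return integer permutation of node indices
#' @export
setGeneric("leafOrder", function(x) standardGeneric("leafOrder"))

#' Cluster assignment of a clustered matrix view
#' @param x a [ClusteredMatrix-class]
#' @return integer cluster id per node, named by node id
#' @export
setGeneric("clusterAssignment", function(x) standardGeneric("clusterAssignment"))
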