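#' @include AllClasses.R
NULL

#' Construct an AnnotationTable
#'
#' @param records data.frame with columns `feature_id`, `disease`,
#'   `status` (one of `causal`, `associated`, `unknown`), `source`
#' @return a validated [AnnotationTable-class]
#' @export
annotationTable <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("feature_id", "disease", "status", "source"))
    if (col %in% names(records)) records[[col]] <- as.character(records[[col]])
  rownames(records) <- NULL
  new("AnnotationTable", records = records)
}

#' Records of an annotation table
#' @param ann an [AnnotationTable-class]
#' @return the underlying data.frame
#' @export
annotationRecords <- function(ann) ann@records

setMethod("show", "AnnotationTable", function(object) {
  cat(sprintf("AnnotationTable: %d record(s), %d disease(s)\n",
              nrow(object@records), length(unique(object@records$disease))))
})

#' Read curated feature-disease associations from CSV
#'
#' Expected columns: `feature_id`, `disease`, `status`, `source`. This
#' flat file is the contract standing in for a knowledge-graph export: a
#' query against a clinical knowledge graph (optionally enriched from
#' licensed pathway databases) that returns, per measured feature and
#' disease, whether the association is reported causal, merely
#' associated, or unknown, plus its provenance, maps one row per
#' (feature, disease) pair onto this format. Features absent from the
#' table are implicitly `unknown` downstream.
#'
#' @param path CSV file path (a header plus zero or more records)
#' @return a validated [AnnotationTable-class]; an unknown status token
#'   is an error naming the row
#' @export
readAnnotations <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("feature_id", "disease", "status", "source")
  if (!all(need %in% names(df)))
    stop("annotation CSV needs columns: ", paste(need, collapse = ", "))
  bad <- which(!df$status %in% c("causal", "associated", "unknown"))
  if (length(bad))
    stop(sprintf("unknown status '%s' in row %d", df$status[bad[1]], bad[1]))
  annotationTable(df[need])
}

#' Annotate graph nodes with disease-association status
#'
#' Joins the annotation table onto the feature nodes: every node gains
#' an `association_status` metadata key for the given disease
#' (`"unknown"` when the feature is not in the table). Annotations for
#' features absent from the graph are ignored with a warning. Nodes and
#' links are never removed.
#'
#' @param graph an [InteractionGraph-class] whose nodes are features
#' @param ann an [AnnotationTable-class]
#' @param disease disease identifier to annotate for
#' @return the annotated graph
#' @export
annotateGraph <- function(graph, ann, disease) {
  rec <- ann@records[ann@records$disease == disease, , drop = FALSE]
  nodes <- graph@nodes
  extra <- setdiff(rec$feature_id, nodes$id)
  if (length(extra))
    warning("annotation(s) for feature(s) absent from the graph: ",
            paste(extra, collapse = ", "))
  status <- rec$status[match(nodes$id, rec$feature_id)]
  status[is.na(status)] <- "unknown"
  nodes$association_status <- status
  interactionGraph(nodes, graph@links, dist = graph@dist)
}

#' Report strongly disease-linked yet unreported features
#'
#' The hypothesis-generation rule: features whose absolute link weight
#' to the disease node is at least `t` and whose curated status is not
#' `causal`, ordered by `|weight|` descending. These are candidates
#' correlating with the disease as strongly as its established causal
#' biomarkers without being reported as one — hypotheses for follow-up,
#' not causal claims.
#'
#' @param graph an [InteractionGraph-class] containing `disease_node`
#' @param ann an [AnnotationTable-class]
#' @param disease_node id of the disease node in the graph
#' @param t minimum `|weight|` to the disease node
#' @param disease disease identifier in the annotation table; defaults
#'   to `disease_node`
#' @return data.frame with columns `feature_id`, `weight`, `status`,
#'   `rank`; antitone in `t`
#' @export
noveltyReport <- function(graph, ann, disease_node, t, disease = disease_node) {
  if (!disease_node %in% graph@nodes$id)
    stop("disease node not in graph: ", disease_node)
  lk <- graph@links
  touches <- lk$source == disease_node | lk$target == disease_node
  lk <- lk[touches & abs(lk$weight) >= t, , drop = FALSE]
  neigh <- ifelse(lk$source == disease_node, lk$target, lk$source)
  rec <- ann@records[ann@records$disease == disease, , drop = FALSE]
  status <- rec$status[match(neigh, rec$feature_id)]
  status[is.na(status)] <- "unknown"
  keep <- status != "causal"
  out <- data.frame(feature_id = neigh[keep], weight = lk$weight[keep],
                    status = status[keep])
  out <- out[order(-abs(out$weight), out$feature_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
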