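#' @include AllGenerics.R
NULL

#' Construct a SampleTable
#'
#' @param values numeric matrix, samples as rows and features as columns
#'   (the tabular file convention).
#' @param sample_ids,feature_ids identifiers; default to the dimnames of
#'   `values`.
#' @param sample_meta,feature_meta optional data.frame / DataFrame of
#'   per-sample and per-feature metadata (one row per sample / feature).
#' @return a [SampleTable-class]
#' @examples
#' st <- SampleTable(matrix(1:6, 2, 3,
#'   dimnames = list(c("s1", "s2"), c("A", "B", "C"))))
#' featureIds(st)
#' @export
SampleTable <- function(values, sample_ids = rownames(values),
                        feature_ids = colnames(values),
                        sample_meta = NULL, feature_meta = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids))
    sample_ids <- paste0("s", seq_len(nrow(values)))
  if (is.null(feature_ids))
    feature_ids <- paste0("f", seq_len(ncol(values)))
  dimnames(values) <- list(as.character(sample_ids),
                           as.character(feature_ids))
  cd <- if (is.null(sample_meta)) S4Vectors::DataFrame(row.names = sample_ids)
        else S4Vectors::DataFrame(sample_meta, row.names = sample_ids)
  rd <- if (is.null(feature_meta)) S4Vectors::DataFrame(row.names = feature_ids)
        else S4Vectors::DataFrame(feature_meta, row.names = feature_ids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = t(values)), colData = cd, rowData = rd)
  new("SampleTable", se)
}

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "SampleTable", function(x) colnames(x))

#' @rdname featureIds
#' @export
setMethod("featureIds", "SampleTable", function(x) rownames(x))

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "SampleTable",
  function(x) t(SummarizedExperiment::assay(x, "values")))

#' @rdname sampleData
#' @export
setMethod("sampleData", "SampleTable",
  function(x) SummarizedExperiment::colData(x))

#' @rdname featureData
#' @export
setMethod("featureData", "SampleTable",
  function(x) SummarizedExperiment::rowData(x))

setMethod("show", "SampleTable", function(object) {
  cat(sprintf("SampleTable: %d samples x %d features\n",
              ncol(object), nrow(object)))
  cat("  features: ",
      paste(utils::head(rownames(object), 5), collapse = ", "),
      if (nrow(object) > 5) ", ..." else "", "\n", sep = "")
  nm <- names(SummarizedExperiment::colData(object))
  if (length(nm))
    cat("  sample metadata: ", paste(nm, collapse = ", "), "\n", sep = "")
  nmiss <- sum(is.na(SummarizedExperiment::assay(object, "values")))
  if (nmiss) cat(sprintf("  missing values: %d\n", nmiss))
})

#' Read a sample-by-feature matrix from a delimited text file
#'
#' The file must have features as columns and samples as rows: the first
#' row holds the feature names (its first field names the id column and
#' is ignored), the first column holds the sample identifiers. Cells
#' equal to `missing_token` become missing; any other non-numeric cell is
#' a parse error naming the offending row and column.
#'
#' @param path file path.
#' @param delimiter field separator, default comma. No auto-detection is
#'   attempted.
#' @param missing_token string marking missing values (default empty).
#' @return a [SampleTable-class]
#' @export
readSampleMatrix <- function(path, delimiter = ",", missing_token = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = delimiter, header = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", check.names = FALSE,
                           na.strings = NULL, encoding = "UTF-8")
  if (nrow(raw) < 1 || ncol(raw) < 2)
    stop("need a header row and at least one feature column")
  feature_ids <- as.character(raw[1, -1])
  sample_ids <- as.character(raw[-1, 1])
  if (anyDuplicated(feature_ids))
    stop("duplicate feature name(s): ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifier(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  cells <- as.matrix(raw[-1, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  vals[cells == missing_token] <- NA_real_
  bad <- is.na(vals) & cells != missing_token
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("unparseable value '%s' at sample '%s', feature '%s'",
                 cells[w[1], w[2]], sample_ids[w[1]], feature_ids[w[2]]))
  }
  SampleTable(vals, sample_ids = sample_ids, feature_ids = feature_ids)
}

#' Write a SampleTable to a delimited text file
#'
#' Inverse of [readSampleMatrix()]: read after write recovers an
#' identical table (values equal within 1e-12). Metadata columns are not
#' serialized; only the numeric matrix.
#'
#' @param table a [SampleTable-class]
#' @param path output path
#' @param delimiter field separator
#' @param missing_token string written for missing values
#' @export
writeSampleMatrix <- function(table, path, delimiter = ",",
                              missing_token = "") {
  m <- featureMatrix(table)
  out <- format(m, digits = 17, trim = TRUE, scientific = FALSE)
  out[is.na(m)] <- missing_token
  header <- paste(c("id", colnames(m)), collapse = delimiter)
  rows <- paste(rownames(m),
                apply(out, 1, paste, collapse = delimiter),
                sep = delimiter)
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Append a 0/1-coded diagnosis column as a numeric feature
#'
#' The workflow treats the diagnosis numerically so it can enter the
#' correlation network like any molecular feature; its link weight with a
#' continuous feature is then the point-biserial correlation. Coding is
#' fixed at 1.0 for `positive_label` and 0.0 otherwise (Pearson
#' correlation is affine-invariant, so the coding choice is immaterial
#' downstream). If every sample is positive the column is constant and
#' downstream correlation is undefined there, flagged by
#' [matrixToGraph()].
#'
#' @param table a [SampleTable-class]
#' @param meta_key sample-metadata key holding the label (must be
#'   present; `NA` values code as 0).
#' @param positive_label label coded as 1.0.
#' @param feature_id id of the appended feature; defaults to `meta_key`.
#' @return the table with one appended feature, marked `role = "diagnosis"`
#'   in its feature metadata
#' @export
attachDiagnosis <- function(table, meta_key, positive_label,
                            feature_id = meta_key) {
  sm <- sampleData(table)
  if (!meta_key %in% names(sm))
    stop(sprintf("sample metadata key '%s' missing for samples: %s",
                 meta_key, paste(sampleIds(table), collapse = ", ")))
  if (feature_id %in% featureIds(table))
    stop("feature '", feature_id, "' already exists")
  lab <- as.character(sm[[meta_key]])
  code <- as.numeric(!is.na(lab) & lab == positive_label)
  m <- cbind(featureMatrix(table), code)
  colnames(m)[ncol(m)] <- feature_id
  fmeta <- as.data.frame(featureData(table))
  if (!nrow(fmeta)) fmeta <- data.frame(row.names = featureIds(table))
  if (!"role" %in% names(fmeta)) fmeta$role <- NA_character_
  newrow <- fmeta[0, , drop = FALSE]
  newrow[1, ] <- NA
  newrow$role <- "diagnosis"
  rownames(newrow) <- feature_id
  fmeta <- rbind(fmeta, newrow)
  SampleTable(m, sample_meta = sampleData(table), feature_meta = fmeta)
}

#' Construct reference intervals
#'
#' @param feature feature identifiers
#' @param low,high numeric normal-range bounds, `low < high`
#' @return a [ReferenceIntervals-class]
#' @export
referenceIntervals <- function(feature, low, high) {
  new("ReferenceIntervals", feature = as.character(feature),
      low = as.numeric(low), high = as.numeric(high))
}

#' Read reference intervals from a 3-column CSV (feature, low, high)
#'
#' @param path file path
#' @return a [ReferenceIntervals-class]
#' @export
readReferenceIntervals <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "numeric", "numeric"))
  if (ncol(df) < 3) stop("expected columns: feature, low, high")
  referenceIntervals(df[[1]], df[[2]], df[[3]])
}

setMethod("show", "ReferenceIntervals", function(object) {
  cat(sprintf("ReferenceIntervals for %d feature(s)\n", length(object@feature)))
})

#' Retain healthy reference samples
#'
#' Keeps exactly the samples with no diagnosis label set (the
#' `diagnosis_key` metadata value is `NA` or the empty string) and all
#' measurements of interval-covered features inside their normal
#' population reference interval `[low, high]`. A candidate sample with
#' any missing measurement is excluded: an unmeasured value cannot be
#' certified in-range. Sample order is preserved; the filter is
#' idempotent.
#'
#' @param table a [SampleTable-class]
#' @param intervals a [ReferenceIntervals-class] covering every
#'   non-diagnosis feature
#' @param diagnosis_key sample-metadata key holding diagnosis labels;
#'   samples lacking the key entirely count as undiagnosed
#' @return the filtered [SampleTable-class]
#' @export
filterHealthyReference <- function(table, intervals, diagnosis_key = "diagnosis") {
  fids <- featureIds(table)
  roles <- featureData(table)$role
  isdx <- if (is.null(roles)) rep(FALSE, length(fids)) else
    !is.na(roles) & roles == "diagnosis"
  need <- fids[!isdx]
  missing_iv <- setdiff(need, intervals@feature)
  if (length(missing_iv))
    stop("no reference interval for feature(s): ",
         paste(missing_iv, collapse = ", "))
  sm <- sampleData(table)
  undiag <- if (diagnosis_key %in% names(sm)) {
    lab <- as.character(sm[[diagnosis_key]])
    is.na(lab) | lab == ""
  } else rep(TRUE, ncol(table))
  m <- featureMatrix(table)[, need, drop = FALSE]
  idx <- match(need, intervals@feature)
  lo <- matrix(intervals@low[idx], nrow(m), length(need), byrow = TRUE)
  hi <- matrix(intervals@high[idx], nrow(m), length(need), byrow = TRUE)
  inrange <- !is.na(m) & m >= lo & m <= hi
  keep <- undiag & rowSums(inrange) == length(need)
  table[, keep]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
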