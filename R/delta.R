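#' @include AllClasses.R
NULL

#' Interquartile range under an explicit quantile convention
#'
#' Q3 minus Q1. The default convention is linear interpolation at index
#' `q * (n - 1)` on the sorted values (R's quantile type 7), the single
#' most widespread default; the convention is injectable for comparison.
#' Missing values are dropped.
#'
#' @param values numeric vector with at least 2 finite values
#' @param type quantile type passed to [stats::quantile()]
#' @return non-negative scalar; 0 for constant data (the delta statistic
#'   is then undefined and callers must flag it)
#' @examples
#' interquartileRange(c(0, 0, 0, 0, 10, 10, 10, 10))  # 10
#' interquartileRange(1:6)                            # 2.5
#' @export
interquartileRange <- function(values, type = 7) {
  values <- values[!is.na(values)]
  if (length(values) < 2 || any(!is.finite(values)))
    stop("need at least 2 finite values")
  q <- stats::quantile(values, c(0.25, 0.75), type = type, names = FALSE)
  q[2] - q[1]
}

#' Delta statistic for one feature and one sample selection
#'
#' A robust, dimensionless group-discrimination score:
#' \deqn{\delta = \frac{\mathrm{median}(selected) -
#'   \mathrm{median}(unselected)}{\mathrm{IQR}(all)}}
#' A large absolute delta marks a feature whose typical value differs
#' strongly between the selected samples and the rest. The sign is
#' positive when the feature is higher in the selected group. When the
#' overall IQR is 0 the statistic is undefined (flagged, never infinite).
#' Delta is invariant under positive affine transforms of the feature
#' and exactly negates when the selection mask is complemented.
#'
#' @param values per-sample numeric values of one feature (missing
#'   dropped)
#' @param selected logical mask, same length as `values`
#' @param type quantile convention for the IQR
#' @return list with `delta`, `defined`, `n_selected`, `n_unselected`
#' @export
deltaStatistic <- function(values, selected, type = 7) {
  stopifnot(length(values) == length(selected), is.logical(selected))
  ok <- !is.na(values) & !is.na(selected)
  values <- values[ok]; selected <- selected[ok]
  ns <- sum(selected); nu <- sum(!selected)
  if (ns == 0 || nu == 0)
    stop("both groups must be non-empty after dropping missing values")
  iqr <- interquartileRange(values, type = type)
  if (iqr == 0)
    return(list(delta = NA_real_, defined = FALSE,
                n_selected = ns, n_unselected = nu))
  list(delta = (stats::median(values[selected]) -
                stats::median(values[!selected])) / iqr,
       defined = TRUE, n_selected = ns, n_unselected = nu)
}

#' Ranked feature-loading panel for a sample selection
#'
#' Computes the delta statistic for every feature of a cohort against a
#' selection mask and returns the most discriminating features ranked by
#' absolute delta (descending; ties broken lexicographically by feature
#' id). Features with undefined delta (zero overall IQR, or a group
#' emptied by missing values) are excluded. By default the 20 most
#' discriminating features are returned, mirroring the loading-bar panel
#' of the interactive view.
#'
#' @param table a [SampleTable-class]
#' @param selected logical mask over samples (see [selectGroup()]); at
#'   least one selected and one unselected sample
#' @param panel_size maximum number of features returned (default 20)
#' @param type quantile convention for the IQR
#' @return a [S4Vectors::DataFrame-class] with columns `feature`,
#'   `delta`, `n_selected`, `n_unselected`, `rank`
#' @export
featureLoadings <- function(table, selected, panel_size = 20, type = 7) {
  stopifnot(panel_size >= 1)
  if (length(selected) != ncol(table))
    stop("selection mask length must equal the number of samples")
  if (!any(selected) || all(selected))
    stop("selection must leave both groups non-empty")
  m <- featureMatrix(table)
  rows <- lapply(colnames(m), function(f) {
    v <- m[, f]
    ok <- !is.na(v)
    if (!any(selected & ok) || !any(!selected & ok)) return(NULL)
    d <- deltaStatistic(v, selected, type = type)
    if (!d$defined) return(NULL)
    data.frame(feature = f, delta = d$delta, n_selected = d$n_selected,
               n_unselected = d$n_unselected)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(S4Vectors::DataFrame(feature = character(), delta = numeric(),
                                n_selected = integer(),
                                n_unselected = integer(), rank = integer()))
  res <- res[order(-abs(res$delta), res$feature), , drop = FALSE]
  res <- utils::head(res, panel_size)
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  S4Vectors::DataFrame(res)
}

#' Resolve a selector to a sample mask
#'
#' Selectors mirror the interactive drop-down: a condition
#' `"key=value"` (all samples whose metadata `key` — or, when no such
#' metadata exists, whose value of feature `key` — equals `value`) or a
#' single sample identifier. The feature fallback covers cohorts whose
#' diagnosis travels as a 0/1 feature column rather than as metadata.
#'
#' @param table a [SampleTable-class]
#' @param selector a string, `"key=value"` or a sample id
#' @return logical mask over samples, at least one `TRUE`
#' @export
selectGroup <- function(table, selector) {
  stopifnot(is.character(selector), length(selector) == 1)
  ids <- sampleIds(table)
  if (grepl("=", selector, fixed = TRUE)) {
    kv <- strsplit(selector, "=", fixed = TRUE)[[1]]
    key <- kv[1]; value <- paste(kv[-1], collapse = "=")
    sm <- sampleData(table)
    if (key %in% names(sm)) {
      lab <- as.character(sm[[key]])
    } else if (key %in% featureIds(table)) {
      lab <- as.character(featureMatrix(table)[, key])
    } else {
      stop("unknown sample metadata key: ", key)
    }
    mask <- !is.na(lab) & lab == value
  } else {
    mask <- ids == selector
  }
  if (!any(mask)) stop("selector matched no samples: ", selector)
  stats::setNames(mask, ids)
}
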