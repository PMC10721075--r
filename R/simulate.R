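#' @include AllClasses.R
NULL

#' Specify a synthetic two-group cohort
#'
#' Parameters of the generator in [simulateCohort()]. Features are drawn
#' on a standardized scale (mean 0, sd `noise_sd`) from a latent-factor
#' block model: features in the same block share a common factor with
#' loading `sqrt(rho)`, giving within-block correlation `rho` and zero
#' expected correlation across blocks. Listed features have their
#' group-2 mean shifted by `shift` normal-population IQR units
#' (`1.349 * noise_sd` per unit). Missingness is completely at random.
#'
#' @param n_per_group samples per group (default 201, the worked
#'   two-group design of 402 individuals)
#' @param p number of features (default 28, a clinical biochemistry
#'   panel size)
#' @param shifted_idx indices of group-shifted features
#' @param shift shift sizes in population-IQR units (recycled over
#'   `shifted_idx`)
#' @param blocks integer block assignment of length `p`; default: no
#'   blocks (each feature its own block)
#' @param rho within-block correlation in `[0, 1)`
#' @param noise_sd marginal feature sd (default 1)
#' @param missing_rate MCAR cell missingness in `[0, 1)` (default 0)
#' @param seed integer RNG seed
#' @return a validated [CohortSpec-class]
#' @export
cohortSpec <- function(n_per_group = 201, p = 28, shifted_idx = integer(),
                       shift = numeric(), blocks = seq_len(p), rho = 0,
                       noise_sd = 1, missing_rate = 0, seed = 1) {
  shifted_idx <- as.integer(shifted_idx)
  if (length(shifted_idx) && length(shift) == 0)
    stop("shift sizes required for shifted features")
  shift <- rep_len(as.numeric(shift), length(shifted_idx))
  new("CohortSpec", n_per_group = as.integer(n_per_group), p = as.integer(p),
      shifted_idx = shifted_idx, shift = shift,
      blocks = as.integer(blocks), rho = as.numeric(rho),
      noise_sd = as.numeric(noise_sd), missing_rate = as.numeric(missing_rate),
      seed = as.integer(seed))
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: 2 x %d samples, %d features, %d shifted, %d block(s), rho=%.2f, seed=%d\n",
    object@n_per_group, object@p, length(object@shifted_idx),
    length(unique(object@blocks)), object@rho, object@seed))
})

#' Named cohort presets
#'
#' `"t2d-like"` emulates the worked two-group clinical-biochemistry
#' design: 201 samples per group, 28 features, 6 features shifted by 2.0
#' population-IQR units in the diagnosed group.
#'
#' @param name preset name (currently `"t2d-like"`)
#' @param seed integer RNG seed
#' @return a [CohortSpec-class]
#' @export
cohortPreset <- function(name = "t2d-like", seed = 1) {
  name <- match.arg(name, "t2d-like")
  cohortSpec(n_per_group = 201, p = 28,
             shifted_idx = c(3L, 7L, 12L, 17L, 22L, 27L),
             shift = rep(2.0, 6), seed = seed)
}

# latent-factor draw for one group; mu is the per-feature mean vector
.draw_group <- function(n, spec, mu) {
  p <- spec@p
  f <- matrix(stats::rnorm(n * length(unique(spec@blocks))), n)
  colnames(f) <- as.character(unique(spec@blocks))
  eps <- matrix(stats::rnorm(n * p), n, p)
  x <- sqrt(spec@rho) * f[, as.character(spec@blocks), drop = FALSE] +
       sqrt(1 - spec@rho) * eps
  sweep(x * spec@noise_sd, 2, mu, `+`)
}

#' Simulate a two-group cohort with known ground truth
#'
#' Draws `2 * n_per_group` samples from the latent-factor block model of
#' the [CohortSpec-class]: group 1 ("healthy", diagnosis metadata `NA`)
#' at mean zero, group 2 (diagnosis label `positive_label`) with the
#' shifted features' means raised by `shift * 1.349 * noise_sd` (one
#' normal-population IQR per unit). Deterministic for a fixed seed; the
#' caller's RNG state is left untouched.
#'
#' @param spec a [CohortSpec-class]
#' @param positive_label diagnosis label of group 2 (default `"case"`)
#' @return a list with elements `table` (a [SampleTable-class] with a
#'   `diagnosis` sample-metadata column) and `truth` (list: `shifted_idx`,
#'   `shift`, `blocks`, `diagnosis` logical vector)
#' @export
simulateCohort <- function(spec, positive_label = "case") {
  validObject(spec)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec@seed)
  n <- spec@n_per_group
  mu1 <- rep(0, spec@p)
  mu2 <- mu1
  mu2[spec@shifted_idx] <- mu2[spec@shifted_idx] +
    spec@shift * 1.349 * spec@noise_sd
  x <- rbind(.draw_group(n, spec, mu1), .draw_group(n, spec, mu2))
  if (spec@missing_rate > 0) {
    holes <- stats::runif(length(x)) < spec@missing_rate
    x[holes] <- NA_real_
  }
  sample_ids <- sprintf("s%03d", seq_len(2 * n))
  feature_ids <- sprintf("f%02d", seq_len(spec@p))
  diagnosis <- c(rep(NA_character_, n), rep(positive_label, n))
  tab <- SampleTable(x, sample_ids = sample_ids, feature_ids = feature_ids,
                     sample_meta = data.frame(diagnosis = diagnosis),
                     feature_meta = data.frame(
                       block = spec@blocks,
                       shifted = seq_len(spec@p) %in% spec@shifted_idx))
  list(table = tab,
       truth = list(shifted_idx = spec@shifted_idx, shift = spec@shift,
                    blocks = spec@blocks,
                    diagnosis = !is.na(diagnosis)))
}

#' Concatenate simulated omics layers into one multi-omics cohort
#'
#' Emulates loading several quantitative omics types at once: each spec
#' generates one feature block for the same samples, the blocks are
#' column-concatenated, and the feature metadata records the omics type
#' per block. All specs must agree on `n_per_group`; sample metadata
#' (diagnosis) is taken from the first layer.
#'
#' @param specs list of [CohortSpec-class], one per omics layer
#' @param types character vector of omics-type tags, one per layer
#' @return a [SampleTable-class] whose feature metadata has an
#'   `omics_type` column
#' @export
simulateMultiOmics <- function(specs, types = paste0("omics", seq_along(specs))) {
  stopifnot(length(specs) >= 1, length(types) == length(specs))
  npg <- vapply(specs, function(s) s@n_per_group, integer(1))
  if (length(unique(npg)) != 1)
    stop("all layers must have the same number of samples per group")
  sims <- lapply(specs, simulateCohort)
  mats <- lapply(seq_along(sims), function(i) {
    m <- featureMatrix(sims[[i]]$table)
    colnames(m) <- sprintf("%s_%s", types[i], colnames(m))
    m
  })
  x <- do.call(cbind, mats)
  fmeta <- data.frame(
    omics_type = rep(types, vapply(mats, ncol, integer(1))),
    block = unlist(lapply(seq_along(specs), function(i)
      sprintf("%s_b%d", types[i], specs[[i]]@blocks))))
  SampleTable(x, sample_meta = sampleData(sims[[1]]$table),
              feature_meta = fmeta)
}
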