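test_that("delimited matrices parse with ids, missing tokens and errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,A,B", "s1,1,2", "s2,3,4"), f)
  st <- readSampleMatrix(f)
  expect_identical(sampleIds(st), c("s1", "s2"))
  expect_identical(featureIds(st), c("A", "B"))
  expect_equal(unname(featureMatrix(st)), matrix(c(1, 3, 2, 4), 2))

  writeLines(c("id,A,A", "s1,1,2"), f)
  expect_error(readSampleMatrix(f), "duplicate feature")
  writeLines(c("id,A,B", "s1,1,2", "s1,3,4"), f)
  expect_error(readSampleMatrix(f), "duplicate sample")

  writeLines(c("id,A,B", "s1,1,oops", "s2,3,4"), f)
  expect_error(readSampleMatrix(f), "oops.*s1.*B")

  writeLines(c("id;A;B", "s1;;2", "s2;3;4"), f)
  st <- readSampleMatrix(f, delimiter = ";")
  expect_true(is.na(featureMatrix(st)["s1", "A"]))
  writeLines(c("id,A,B", "s1,NA,2", "s2,3,4"), f)
  st <- readSampleMatrix(f, missing_token = "NA")
  expect_true(is.na(featureMatrix(st)["s1", "A"]))
})

test_that("a written synthetic cohort reads back identically", {
  sim <- simulateCohort(cohortPreset("t2d-like", seed = 11))
  sim$table <- sim$table  # 402 x 28 with default settings
  f <- withr::local_tempfile(fileext = ".csv")
  writeSampleMatrix(sim$table, f)
  back <- readSampleMatrix(f)
  expect_identical(sampleIds(back), sampleIds(sim$table))
  expect_identical(featureIds(back), featureIds(sim$table))
  expect_equal(featureMatrix(back), featureMatrix(sim$table),
               tolerance = 1e-12)
})

test_that("diagnosis attaches as a 0/1 feature in sample order", {
  st <- SampleTable(matrix(rnorm(8), 4, 2,
                           dimnames = list(paste0("s", 1:4), c("A", "B"))),
                    sample_meta = data.frame(
                      diagnosis = c("t2d", NA, "t2d", NA)))
  st2 <- attachDiagnosis(st, "diagnosis", "t2d")
  expect_equal(unname(featureMatrix(st2)[, "diagnosis"]), c(1, 0, 1, 0))
  expect_identical(featureData(st2)["diagnosis", "role"], "diagnosis")

  # degenerate all-positive coding is allowed; correlation flags it later
  st3 <- SampleTable(matrix(rnorm(8), 4, 2,
                            dimnames = list(paste0("s", 1:4), c("A", "B"))),
                     sample_meta = data.frame(diagnosis = rep("t2d", 4)))
  st3 <- attachDiagnosis(st3, "diagnosis", "t2d")
  expect_equal(unname(featureMatrix(st3)[, "diagnosis"]), rep(1, 4))
  expect_error(matrixToGraph(st3), "zero-variance.*diagnosis")

  expect_error(attachDiagnosis(st, "absent", "t2d"), "absent")
})

test_that("diagnosis coding correlates positively with a shifted feature", {
  sim <- simulateCohort(cohortSpec(n_per_group = 100, p = 4,
                                   shifted_idx = 1, shift = 2, seed = 5))
  st <- attachDiagnosis(sim$table, "diagnosis", "case")
  m <- featureMatrix(st)
  # oracle: direct correlation of the raw labels with the feature
  expect_gt(oracle_cor(as.numeric(sim$truth$diagnosis), m[, "f01"]), 0)
  expect_equal(unname(m[, "diagnosis"]), as.numeric(sim$truth$diagnosis))
})

test_that("healthy reference filtering matches a brute-force scan", {
  set.seed(7)
  n <- 60; p <- 5
  vals <- matrix(runif(n * p, 1, 9), n, p,
                 dimnames = list(sprintf("s%02d", 1:n), sprintf("f%d", 1:p)))
  # inject out-of-range values and missings
  vals[cbind(sample(n, 10), sample(p, 10, replace = TRUE))] <- 12
  vals[cbind(sample(n, 5), sample(p, 5, replace = TRUE))] <- NA
  dx <- ifelse(runif(n) < 0.3, "sick", NA)
  st <- SampleTable(vals, sample_meta = data.frame(diagnosis = dx))
  iv <- referenceIntervals(sprintf("f%d", 1:p), rep(0, p), rep(10, p))

  kept <- filterHealthyReference(st, iv)
  ok <- vapply(seq_len(n), function(i) {
    is.na(dx[i]) && !anyNA(vals[i, ]) && all(vals[i, ] >= 0 & vals[i, ] <= 10)
  }, logical(1))
  expect_identical(sampleIds(kept), rownames(vals)[ok])

  # idempotent, and the all-clean cohort passes unchanged
  again <- filterHealthyReference(kept, iv)
  expect_identical(sampleIds(again), sampleIds(kept))
  clean <- SampleTable(matrix(5, 3, 5, dimnames = list(paste0("s", 1:3),
                                                       sprintf("f%d", 1:p))))
  expect_identical(sampleIds(filterHealthyReference(clean, iv)),
                   paste0("s", 1:3))

  expect_error(
    filterHealthyReference(st, referenceIntervals("f1", 0, 10)),
    "no reference interval")
})

test_that("reference intervals validate and read from CSV", {
  expect_error(referenceIntervals("A", 5, 5), "strictly below")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature,low,high", "A,1,3", "B,0,10"), f)
  iv <- readReferenceIntervals(f)
  expect_identical(iv@feature, c("A", "B"))
  expect_equal(iv@high, c(3, 10))
})
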