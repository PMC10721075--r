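test_that("sample distances match direct metric evaluation", {
  # identical samples at distance zero
  m <- rbind(s1 = c(1, 2, 3), s2 = c(1, 2, 3), s3 = c(4, 0, 1))
  colnames(m) <- c("A", "B", "C")
  d <- sampleDistanceMatrix(SampleTable(m), standardize = FALSE)
  expect_equal(graphDist(d)["s1", "s2"], 0)

  # 1-D points at 0, 1, 2 without standardization
  m1 <- matrix(c(0, 1, 2), 3, 1, dimnames = list(c("a", "b", "c"), "x"))
  d1 <- sampleDistanceMatrix(SampleTable(m1), standardize = FALSE)
  expect_equal(graphDist(d1)["a", "c"], 2)

  # random table vs brute-force pairwise Euclidean on z-scaled features
  tab <- small_table(10, 4, seed = 21)
  d2 <- sampleDistanceMatrix(tab)
  z <- scale(featureMatrix(tab))
  for (i in 1:9) for (j in (i + 1):10)
    expect_equal(unname(graphDist(d2)[i, j]),
                 sqrt(sum((z[i, ] - z[j, ])^2)), tolerance = 1e-12)

  # zero-variance features cannot be standardized
  mc <- cbind(flat = rep(1, 5), ok = rnorm(5))
  rownames(mc) <- paste0("s", 1:5)
  expect_warning(sampleDistanceMatrix(SampleTable(mc)), "zero-variance")
})

test_that("the spanning tree is minimal and deterministically tie-broken", {
  # collinear equidistant points force the path
  d <- distanceMatrix(c("a", "b", "c"),
                      matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3))
  expect_identical(minimumSpanningTree(d),
                   rbind(c("a", "b"), c("b", "c")))

  d2 <- distanceMatrix(c("x", "y"), matrix(c(0, 3, 3, 0), 2))
  expect_identical(minimumSpanningTree(d2), rbind(c("x", "y")))

  # total weight equals the exhaustive enumeration over all labeled trees
  for (seed in 1:3) {
    dm <- random_distance_matrix(6, seed = seed)
    mst <- minimumSpanningTree(dm)
    total <- sum(graphDist(dm)[mst])
    expect_equal(total, oracle_min_tree_weight(graphDist(dm)),
                 tolerance = 1e-12)
  }

  # equal-weight ties resolve identically across permuted evaluation
  du <- distanceMatrix(c("a", "b", "c", "d"),
                       matrix(1, 4, 4) - diag(4))
  expect_identical(minimumSpanningTree(du), minimumSpanningTree(du))
  expect_identical(minimumSpanningTree(du)[, 1], c("a", "a", "a"))
})

test_that("the objective is the hop-vs-distance correlation", {
  ids <- c("a", "b", "c", "d")
  d <- distanceMatrix(ids, matrix(c(0, 1, 2, 3,
                                    1, 0, 1, 2,
                                    2, 1, 0, 1,
                                    3, 2, 1, 0), 4))
  path <- rbind(c("a", "b"), c("b", "c"), c("c", "d"))
  expect_equal(graphObjective(path, d), 1.0)

  # complete graph on non-equidistant points: hops constant, flagged NA
  dm <- random_distance_matrix(4, seed = 5)
  cmpl <- t(combn(sampleIds(dm), 2))
  expect_warning(obj <- graphObjective(cmpl, dm), "zero variance")
  expect_true(is.na(obj))

  expect_error(graphObjective(rbind(c("a", "b")), d), "disconnected")

  # random trees vs an independent all-pairs BFS + correlation oracle
  for (seed in 4:6) {
    dm <- random_distance_matrix(6, seed = seed)
    tree <- minimumSpanningTree(dm)
    hops <- oracle_hops(tree, sampleIds(dm))
    want <- cor(hops[upper.tri(hops)],
                graphDist(dm)[upper.tri(graphDist(dm))])
    expect_equal(graphObjective(tree, dm), want, tolerance = 1e-12)
  }
})

test_that("the abstraction sweeps edges and never falls below the MST", {
  # collinear equidistant points: the MST path is already perfect
  n <- 7
  pts <- matrix(seq_len(n), ncol = 1)
  d <- distanceMatrix(sprintf("p%d", 1:n), as.matrix(dist(pts)))
  sg <- stadAbstraction(d)
  expect_equal(nrow(stadEdges(sg)), n - 1)
  expect_equal(sg@objective, 1.0)

  # degenerate grid: MST only
  dm <- random_distance_matrix(8, seed = 31)
  mst_only <- stadAbstraction(dm, grid = 0)
  expect_equal(nrow(stadEdges(mst_only)), 7)
  expect_equal(mst_only@objective, graphObjective(minimumSpanningTree(dm), dm))

  # two tight, well-separated clusters: improvement over the MST
  set.seed(77)
  pts <- rbind(matrix(rnorm(20, 0, 0.1), ncol = 2),
               matrix(rnorm(20, 5, 0.1), ncol = 2))
  dcl <- distanceMatrix(sprintf("q%02d", 1:20), as.matrix(dist(pts)))
  sgc <- stadAbstraction(dcl)
  mst_obj <- graphObjective(minimumSpanningTree(dcl), dcl)
  expect_gte(sgc@objective, mst_obj - 1e-12)
  expect_gte(nrow(stadEdges(sgc)), 19)

  # MST edges always contained; graph connected; sweep recorded
  key <- function(e) paste(e[, 1], e[, 2])
  expect_true(all(key(minimumSpanningTree(dcl)) %in% key(stadEdges(sgc))))
  expect_true(nrow(sgc@swept_sizes) >= 1)
  expect_equal(sgc@objective, max(sgc@swept_sizes$objective))

  # full determinism: same input gives identical graphs
  expect_identical(stadEdges(stadAbstraction(dm)), stadEdges(stadAbstraction(dm)))
})

test_that("layouts are seed-deterministic and geometry-faithful", {
  d2 <- distanceMatrix(c("x", "y"), matrix(c(0, 3, 3, 0), 2))
  sg2 <- new("StadGraph", sample_ids = c("x", "y"),
             edges = rbind(c("x", "y")), objective = NA_real_,
             swept_sizes = data.frame(), dist = d2)
  xy <- layoutGraph(sg2, seed = 3)
  expect_equal(dim(xy), c(2, 2))
  sep <- sqrt(sum((xy[1, ] - xy[2, ])^2))
  expect_true(is.finite(sep) && sep > 0)

  # bitwise determinism, and RNG state untouched
  n <- 9
  d <- distanceMatrix(sprintf("p%d", 1:n),
                      as.matrix(dist(matrix(seq_len(n), ncol = 1))))
  sg <- stadAbstraction(d)
  set.seed(1); before <- runif(1)
  set.seed(1)
  a <- layoutGraph(sg, dims = 3, seed = 42)
  expect_identical(runif(1), before)
  b <- layoutGraph(sg, dims = 3, seed = 42)
  expect_identical(a, b)
  expect_equal(dim(a), c(n, 3))

  # a path projects monotonically onto its principal axis
  xy <- layoutGraph(sg, dims = 2, seed = 7)
  proj <- prcomp(xy)$x[, 1]
  expect_true(all(diff(proj) > 0) || all(diff(proj) < 0))
})
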