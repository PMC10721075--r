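ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# graph on planted blocks whose dist matrix separates them cleanly
planted_graph <- function(block_sizes, seed) {
  pb <- planted_block_dist(block_sizes, seed = seed)
  n <- length(pb$blocks)
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  set.seed(seed + 1)
  links <- data.frame(source = ids[pairs[, 1]], target = ids[pairs[, 2]],
                      weight = round(runif(nrow(pairs), -1, 1), 4))
  list(graph = interactionGraph(ids, links, dist = pb$d),
       blocks = pb$blocks)
}

test_that("clustering reorders the matrix deterministically", {
  g2 <- interactionGraph(c("a", "b"),
                         data.frame(source = "a", target = "b", weight = 0.4),
                         dist = matrix(c(0, 1, 1, 0), 2))
  cm2 <- clusterOrder(g2, cut_level = 1)
  expect_equal(sort(leafOrder(cm2)), 1:2)
  expect_equal(length(unique(clusterAssignment(cm2))), 1)

  # two zero-distance pairs far apart end up adjacent in leaf order
  d <- matrix(1, 4, 4); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0; d[3, 4] <- d[4, 3] <- 0
  g4 <- interactionGraph(c("a", "b", "c", "d"), dist = d)
  ord <- leafOrder(clusterOrder(g4, cut_level = 2))
  expect_true(abs(diff(match(1:2, ord))) == 1)
  expect_true(abs(diff(match(3:4, ord))) == 1)

  # planted 2-block dist: cut at 2 equals the exhaustive best 2-partition
  pg <- planted_graph(c(3, 3), seed = 8)
  cm <- clusterOrder(pg$graph, cut_level = 2)
  asg <- clusterAssignment(cm)
  best <- NULL; best_cost <- Inf
  d <- graphDist(pg$graph)
  for (code in 1:(2^5)) {  # all 2-partitions of 6 nodes (node 1 fixed)
    part <- c(1L, as.integer(intToBits(code))[1:5] + 1L)
    if (length(unique(part)) < 2) next
    cost <- sum(d[outer(part, part, "==") & upper.tri(d)])
    if (cost < best_cost) { best_cost <- cost; best <- part }
  }
  expect_equal(ari(asg, best), 1)
  expect_equal(ari(asg, pg$blocks), 1)
})

test_that("dendrogram cuts give contiguous leaf-order clusters", {
  pg <- planted_graph(c(4, 3, 2, 3, 4), seed = 13)
  cm <- clusterOrder(pg$graph, cut_level = 5)
  expect_equal(ari(clusterAssignment(cm), pg$blocks), 1)

  n <- nNodes(pg$graph)
  expect_equal(length(unique(clusterAssignment(cutDendrogram(cm, 1)))), 1)
  expect_equal(length(unique(clusterAssignment(cutDendrogram(cm, n)))), n)
  # level beyond n clamps to singletons
  expect_equal(length(unique(clusterAssignment(cutDendrogram(cm, n + 10)))), n)

  # contiguity in leaf order, for random levels on random graphs
  set.seed(99)
  for (i in 1:8) {
    g <- random_graph(sample(5:12, 1), seed = 300 + i, with_dist = TRUE)
    k <- sample(1:nNodes(g), 1)
    cmr <- clusterOrder(g, cut_level = k)
    runs <- rle(clusterAssignment(cmr)[leafOrder(cmr)])
    expect_equal(length(runs$values), length(unique(runs$values)))
    expect_equal(length(unique(clusterAssignment(cmr))), min(k, nNodes(g)))
  }
})

test_that("clustering falls back to 1 - weight when dist is absent", {
  g <- random_graph(7, seed = 55, with_dist = FALSE, p_link = 1)
  cm <- clusterOrder(g, cut_level = 3)
  expect_s4_class(cm, "ClusteredMatrix")
  d <- 1 - weightMatrix(g); diag(d) <- 0
  h <- hclust(as.dist(d), method = "average")
  expect_equal(leafOrder(cm), h$order)
})

test_that("edge thresholding is an exhaustive, monotone filter", {
  g <- random_graph(10, seed = 17, p_link = 0.8)
  lk <- graphLinks(g)

  expect_equal(graphLinks(thresholdEdges(g, 0)), lk)
  tmax <- max(abs(lk$weight))
  expect_equal(nLinks(thresholdEdges(g, tmax + 0.01)), 0)
  expect_equal(nNodes(thresholdEdges(g, tmax + 0.01)), 10)

  t028 <- suppressMessages(thresholdEdges(g, 0.28))
  expect_equal(graphLinks(t028), lk[abs(lk$weight) >= 0.28, ],
               ignore_attr = TRUE)
  signed <- suppressMessages(thresholdEdges(g, 0.28, use_absolute = FALSE))
  expect_equal(graphLinks(signed), lk[lk$weight >= 0.28, ],
               ignore_attr = TRUE)

  # monotone: higher threshold keeps a subset
  key <- function(x) paste(graphLinks(x)$source, graphLinks(x)$target)
  for (t1 in c(0, 0.2, 0.5)) {
    s1 <- suppressMessages(thresholdEdges(g, t1))
    s2 <- suppressMessages(thresholdEdges(g, t1 + 0.3))
    expect_true(all(key(s2) %in% key(s1)))
  }
})

test_that("brushing extracts exactly the rectangle's links", {
  g <- random_graph(6, seed = 23, with_dist = TRUE, p_link = 0.9)
  cm <- clusterOrder(g, cut_level = 2)

  # full-matrix brush equals thresholding
  for (t in c(0, 0.3)) {
    full <- brushSubgraph(cm, brushRegion(c(1, 6)), t = t)
    thr <- suppressMessages(thresholdEdges(g, t))
    expect_setequal(graphNodes(full)$id, graphNodes(thr)$id)
    expect_equal(graphLinks(full)[c("source", "target", "weight")],
                 graphLinks(thr)[c("source", "target", "weight")],
                 ignore_attr = TRUE)
  }

  # off-diagonal rectangle vs brute-force cell scan
  ord_ids <- graphNodes(g)$id[leafOrder(cm)]
  w <- weightMatrix(g)
  region <- brushRegion(c(1, 2), c(4, 6))
  got <- brushSubgraph(cm, region, t = 0.1)
  cells <- expand.grid(r = 1:2, c = 4:6)
  want <- unique(do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    i <- ord_ids[cells$r[k]]; j <- ord_ids[cells$c[k]]
    wij <- w[i, j]
    has <- any((graphLinks(g)$source == i & graphLinks(g)$target == j) |
               (graphLinks(g)$source == j & graphLinks(g)$target == i))
    if (has && abs(wij) >= 0.1)
      data.frame(a = min(i, j), b = max(i, j)) else NULL
  })))
  gl <- graphLinks(got)
  expect_equal(nrow(gl), if (is.null(want)) 0L else nrow(want))
  if (!is.null(want))
    expect_setequal(paste(pmin(gl$source, gl$target),
                          pmax(gl$source, gl$target)),
                    paste(want$a, want$b))
  expect_setequal(graphNodes(got)$id, union(ord_ids[1:2], ord_ids[4:6]))

  # on-diagonal square equals the induced subgraph of the run
  run <- brushSubgraph(cm, brushRegion(c(2, 4)), t = 0)
  members <- ord_ids[2:4]
  lk <- graphLinks(g)
  induced <- lk[lk$source %in% members & lk$target %in% members, ]
  expect_equal(nLinks(run), nrow(induced))

  expect_error(brushSubgraph(cm, brushRegion(c(5, 9)), t = 0), "exceeds")
  expect_error(brushRegion(c(3, 2)), "from <= to")
})

test_that("sub-tree extraction equals the diagonal-block brush", {
  pg <- planted_graph(c(3, 4, 3), seed = 29)
  cm <- clusterOrder(pg$graph, cut_level = 3)
  asg <- clusterAssignment(cm)

  for (k in unique(asg)) {
    sub <- subtreeSubgraph(cm, k, t = 0.2)
    members <- names(asg)[asg == k]
    pos <- range(match(members, graphNodes(pg$graph)$id[leafOrder(cm)]))
    brushed <- brushSubgraph(cm, brushRegion(pos), t = 0.2)
    expect_setequal(graphNodes(sub)$id, graphNodes(brushed)$id)
    expect_equal(graphLinks(sub), graphLinks(brushed))
    expect_setequal(graphNodes(sub)$id, members)
  }

  # a singleton cluster is one node with no links
  g1 <- planted_graph(c(1, 5), seed = 31)
  cm1 <- clusterOrder(g1$graph, cut_level = 2)
  a1 <- clusterAssignment(cm1)
  singleton <- as.integer(names(table(a1))[table(a1) == 1])
  sub1 <- subtreeSubgraph(cm1, singleton, t = 0)
  expect_equal(nNodes(sub1), 1)
  expect_equal(nLinks(sub1), 0)

  # the whole-tree cluster at level 1 equals plain thresholding
  cm_all <- cutDendrogram(cm, 1)
  all_sub <- subtreeSubgraph(cm_all, 1L, t = 0.2)
  thr <- suppressMessages(thresholdEdges(pg$graph, 0.2))
  expect_equal(graphLinks(all_sub)[c("source", "target", "weight")],
               graphLinks(thr)[c("source", "target", "weight")],
               ignore_attr = TRUE)

  expect_error(subtreeSubgraph(cm, 99L, t = 0), "unknown cluster")
})

test_that("the displayed matrix is a consistent permutation", {
  g <- random_graph(9, seed = 41, with_dist = TRUE, p_link = 0.7)
  cm <- clusterOrder(g, cut_level = 3)
  w <- weightMatrix(g)
  ord <- leafOrder(cm)
  disp <- w[ord, ord]
  for (i in c(1, 4, 9)) for (j in c(2, 5, 8))
    expect_identical(disp[i, j], w[ord[i], ord[j]])
})

test_that("node colouring follows metadata or the dendrogram", {
  pg <- planted_graph(c(3, 3, 2, 2, 3), seed = 47)
  cm <- clusterOrder(pg$graph, cut_level = 5)
  g5 <- colorNodes(pg$graph, "dendrogram", cm)
  expect_equal(length(unique(graphNodes(g5)$colour_group)), 5)

  gm <- interactionGraph(data.frame(id = c("a", "b", "c"),
                                    omics_type = c("rna", "protein", NA)))
  cg <- graphNodes(colorNodes(gm, "omics_type"))$colour_group
  expect_identical(cg, c("rna", "protein", "unknown"))

  none <- colorNodes(gm, "absent_key")
  expect_identical(unique(graphNodes(none)$colour_group), "unknown")

  expect_error(colorNodes(pg$graph, "dendrogram"), "ClusteredMatrix")
})
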