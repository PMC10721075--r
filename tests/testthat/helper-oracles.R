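# Independent oracles and fixture builders used across the suite.
# Oracles deliberately avoid the package's own code paths.

# quartiles by hand: sort, then linear interpolation at index q*(n-1)
oracle_iqr <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  at <- function(q) {
    h <- q * (n - 1)
    lo <- floor(h); hi <- ceiling(h)
    x[lo + 1] + (h - lo) * (x[hi + 1] - x[lo + 1])
  }
  at(0.75) - at(0.25)
}

oracle_delta <- function(values, selected) {
  (median(values[selected]) - median(values[!selected])) /
    oracle_iqr(values)
}

# plain-formula Pearson correlation on complete pairs
oracle_cor <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

# all-pairs unit-weight hop distances by repeated adjacency products
oracle_hops <- function(edges, ids) {
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (nrow(edges)) {
    adj[cbind(edges[, 1], edges[, 2])] <- TRUE
    adj[cbind(edges[, 2], edges[, 1])] <- TRUE
  }
  hops <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(hops) <- 0
  reach <- diag(TRUE, n)
  frontier <- reach
  for (k in seq_len(n)) {
    frontier <- (frontier %*% adj > 0) & !reach
    if (!any(frontier)) break
    hops[frontier] <- k
    reach <- reach | frontier
  }
  hops
}

# minimum spanning-tree weight by exhaustive Pruefer-sequence enumeration
oracle_min_tree_weight <- function(d) {
  n <- nrow(d)
  if (n == 2) return(d[1, 2])
  decode <- function(s) {
    deg <- tabulate(s, n) + 1L
    w <- 0
    for (x in s) {
      leaf <- which.max(deg == 1L)  # smallest index with degree 1
      w <- w + d[leaf, x]
      deg[leaf] <- 0L
      deg[x] <- deg[x] - 1L
    }
    uv <- which(deg == 1L)
    w + d[uv[1], uv[2]]
  }
  idx <- rep(0L, n - 2)
  best <- Inf
  repeat {
    best <- min(best, decode(idx + 1L))
    j <- 1L
    repeat {
      idx[j] <- idx[j] + 1L
      if (idx[j] < n) break
      idx[j] <- 0L
      j <- j + 1L
      if (j > n - 2) return(best)
    }
  }
}

random_distance_matrix <- function(n, seed) {
  set.seed(seed)
  pts <- matrix(rnorm(n * 3), n)
  distanceMatrix(sprintf("x%02d", seq_len(n)), as.matrix(dist(pts)))
}

# a valid random graph; with_dist adds a metric distance matrix
random_graph <- function(n, seed, with_dist = FALSE, p_link = 0.5) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p_link
  links <- if (any(keep))
    data.frame(source = ids[pairs[keep, 1]], target = ids[pairs[keep, 2]],
               weight = round(runif(sum(keep), -1, 1), 6))
  else NULL
  dist <- if (with_dist)
    as.matrix(dist(matrix(rnorm(n * 2), n))) else NULL
  interactionGraph(data.frame(id = ids, group = sample(letters[1:3], n,
                                                       replace = TRUE)),
                   links, dist = dist)
}

# structural graph equality, ignoring metadata column order
expect_graphs_equal <- function(a, b, tol = 1e-12) {
  na <- graphNodes(a); nb <- graphNodes(b)
  expect_identical(na[sort(names(na))], nb[sort(names(nb))])
  la <- graphLinks(a); lb <- graphLinks(b)
  expect_equal(la[sort(names(la))], lb[sort(names(lb))], tolerance = tol)
  da <- graphDist(a); db <- graphDist(b)
  if (is.null(da) || is.null(db)) expect_identical(is.null(da), is.null(db))
  else expect_equal(unname(da), unname(db), tolerance = tol)
}

# planted-block distance matrix: small distances within blocks
planted_block_dist <- function(block_sizes, seed, within = 0.1, between = 1) {
  set.seed(seed)
  blocks <- rep(seq_along(block_sizes), block_sizes)
  n <- length(blocks)
  d <- matrix(between, n, n) + matrix(runif(n * n, 0, 0.05), n, n)
  d[outer(blocks, blocks, "==")] <- within
  d <- (d + t(d)) / 2
  diag(d) <- 0
  list(d = d, blocks = blocks)
}

small_table <- function(n = 10, p = 4, seed = 1) {
  set.seed(seed)
  SampleTable(matrix(rnorm(n * p), n, p,
                     dimnames = list(sprintf("s%02d", 1:n),
                                     sprintf("f%02d", 1:p))))
}
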