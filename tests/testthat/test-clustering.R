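test_that("z-scoring standardises columns and rejects degenerate features", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 20, 60))
  rownames(m) <- paste0("p", 1:3)
  z <- zscoreMatrix(m)
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
  expect_equal(colMeans(z), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), c(a = 1, b = 1), tolerance = 1e-12)
  expect_error(zscoreMatrix(cbind(k = rep(2, 4))), "zero variance")
  mNA <- cbind(a = c(1, NA, 3, 5))
  expect_identical(is.na(zscoreMatrix(mNA)[, 1]), is.na(mNA[, 1]))
})

test_that("uncentered correlation matches its closed form and properties", {
  expect_equal(uncenteredCorrelation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(uncenteredCorrelation(c(1, 2), c(-1, -2)), -1)
  expect_equal(uncenteredCorrelation(c(1, 0), c(0, 1)), 0)
  expect_error(uncenteredCorrelation(c(0, 0), c(1, 2)), "zero vector")

  set.seed(2)
  for (i in 1:20) {
    x <- rnorm(5); y <- rnorm(5)
    s <- uncenteredCorrelation(x, y)
    expect_equal(s, sum(x * y) / sqrt(sum(x^2) * sum(y^2)))  # direct formula
    expect_equal(s, uncenteredCorrelation(y, x))
    expect_lte(abs(s), 1 + 1e-12)
  }
  ## distance matrix agrees with the pairwise scalar function
  z <- matrix(rnorm(15), 5, 3, dimnames = list(paste0("p", 1:5), NULL))
  d <- uncenteredDistance(z)
  expect_equal(d[2, 4], 1 - uncenteredCorrelation(z[2, ], z[4, ]))
  expect_equal(d, t(d))
})

## by-definition average linkage: recompute all pairwise cluster means each step
bruteAverageLinkage <- function(z, k) {
  d <- uncenteredDistance(z)
  groups <- as.list(seq_len(nrow(z)))
  while (length(groups) > k) {
    best <- c(Inf, 0, 0)
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (j <= i) next
      dist <- mean(d[groups[[i]], groups[[j]]])
      if (dist < best[1] - 1e-12) best <- c(dist, i, j)
    }
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  out <- integer(nrow(z))
  for (i in seq_along(groups)) out[groups[[i]]] <- i
  out
}

test_that("average linkage agrees with a brute-force implementation and hclust", {
  set.seed(3)
  for (rep in 1:8) {
    n <- sample(5:8, 1)
    z <- matrix(rnorm(n * 3), n, 3, dimnames = list(paste0("p", 1:n), letters[1:3]))
    k <- sample(2:4, 1)
    res <- averageLinkageCluster(z, k)
    mine <- unname(clusterAssignments(res))
    expect_equal(randIndex(mine, bruteAverageLinkage(z, k)), 1)
    hc <- stats::cutree(stats::hclust(stats::as.dist(uncenteredDistance(z)),
                                      method = "average"), k)
    expect_equal(randIndex(mine, unname(hc)), 1)
    expect_true(all(diff(res@height) >= -1e-12))   # no inversions
  }
})

test_that("identical-row groups split exactly and order does not matter", {
  z <- rbind(matrix(rep(c(1, 2, 3), 4), 4, 3, byrow = TRUE),
             matrix(rep(c(-1, 2, -3), 3), 3, 3, byrow = TRUE))
  rownames(z) <- paste0("p", 1:7)
  a <- clusterAssignments(averageLinkageCluster(z, 2))
  expect_identical(length(unique(a[1:4])), 1L)
  expect_identical(length(unique(a[5:7])), 1L)
  expect_false(a[1] == a[5])

  set.seed(4)
  z2 <- matrix(rnorm(24), 8, 3, dimnames = list(paste0("p", 1:8), NULL))
  a1 <- clusterAssignments(averageLinkageCluster(z2, 3))
  perm <- sample(8)
  a2 <- clusterAssignments(averageLinkageCluster(z2[perm, ], 3))
  expect_equal(randIndex(unname(a1[perm]), unname(a2)), 1)
  expect_error(averageLinkageCluster(z2, 9), "exceed")
})

test_that("3-sigma-separated planted partitions are recovered with Rand index 1", {
  set.seed(5)
  for (rep in 1:5) {
    centroidA <- c(3, -3, -3); centroidB <- c(-3, 3, 3)   # 3 within-SD gaps per axis
    z <- rbind(sweep(matrix(rnorm(30), 10, 3), 2, centroidA, "+"),
               sweep(matrix(rnorm(36), 12, 3), 2, centroidB, "+"))
    rownames(z) <- paste0("p", 1:22)
    a <- clusterAssignments(averageLinkageCluster(zscoreMatrix(z), 2))
    expect_equal(randIndex(unname(a), rep(1:2, c(10, 12))), 1)
  }
})

test_that("the favorable-cluster rule is the centroid sign conjunction", {
  keys <- clusteringKeys()
  cent <- rbind(c(1, -1, -1), c(-1, 1, 1), c(1, 1, -1), c(0.2, -0.1, -0.3))
  colnames(cent) <- keys
  res <- new("ClusterResult",
             assignments = setNames(rep(1:4, each = 2L), paste0("p", 1:8)),
             merge = matrix(0L, 0, 2), height = numeric(0),
             centroids = cent, favorable = rep(FALSE, 4), keys = keys)
  res <- selectFavorableClusters(res)
  expect_identical(favorableClusters(res), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("patients missing a clustering key are excluded, not imputed", {
  set.seed(6)
  m <- matrix(rlnorm(36), 12, 3, dimnames = list(paste0("p", 1:12), clusteringKeys()))
  m[3, 2] <- NA
  clu <- clusterCohort(m, k = 3)
  expect_identical(clu$excluded, "p3")
  expect_true(is.na(clu$ftme[["p3"]]))
  expect_identical(length(clusterAssignments(clu$result)), 11L)
})
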