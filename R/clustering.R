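#' z-score feature columns across patients
#'
#' Per feature: \code{(x - mean) / sd} over non-missing patients, with the
#' sample (n-1) standard deviation. Missing entries propagate. A feature with
#' zero variance cannot be z-scored and raises an error naming it.
#'
#' @param features a \code{\link{TMEFeatures}} or numeric matrix.
#' @param keys feature columns to keep (default all).
#' @return numeric matrix of z-scores.
#' @export
zscoreMatrix <- function(features, keys = NULL) {
  m <- if (is(features, "TMEFeatures")) featureValues(features) else features
  if (!is.null(keys)) {
    missing <- setdiff(keys, colnames(m))
    if (length(missing))
      stop(sprintf("unknown feature(s): %s", paste(missing, collapse = ", ")))
    m <- m[, keys, drop = FALSE]
  }
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    ok <- !is.na(v)
    if (sum(ok) < 2L)
      stop(sprintf("feature %s has fewer than 2 non-missing values", colnames(m)[j]))
    s <- sd(v[ok])
    if (s == 0)
      stop(sprintf("feature %s has zero variance", colnames(m)[j]))
    m[, j] <- (v - mean(v[ok])) / s
  }
  m
}

#' Uncentered correlation similarity
#'
#' The Cluster 3.0 similarity: \code{sum(x*y) / (sqrt(sum(x^2)) *
#' sqrt(sum(y^2)))} — a cosine similarity without mean-centering, bounded in
#' [-1, 1], with \code{s(x, x) = 1} for any nonzero \code{x}. The associated
#' clustering distance is \code{1 - s}.
#'
#' @param x,y numeric vectors of equal length.
#' @return similarity in [-1, 1].
#' @export
uncenteredCorrelation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1L)
    stop("x and y must have equal positive length")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop("uncentered correlation is undefined for a zero vector")
  sum(x * y) / (nx * ny)
}

#' Pairwise uncentered-correlation distance matrix
#'
#' @param z numeric observations x variables matrix (no missing values).
#' @return symmetric matrix of distances \code{1 - s}.
#' @export
uncenteredDistance <- function(z) {
  norms <- sqrt(rowSums(z^2))
  if (any(norms == 0))
    stop("uncentered correlation is undefined for a zero vector")
  s <- (z %*% t(z)) / outer(norms, norms)
  d <- 1 - s
  diag(d) <- 0
  d
}

#' Average-linkage hierarchical clustering under the uncentered-correlation distance
#'
#' Agglomerative clustering with unweighted average linkage over original
#' observations (UPGMA): the distance between two clusters is the mean of all
#' pairwise observation distances, maintained by the Lance-Williams update.
#' Merge order is deterministic: at equal heights the pair with the smallest
#' (first, then second) cluster index merges first, cluster indices following
#' creation order. The dendrogram is cut to exactly \code{k} clusters by
#' stopping the agglomeration after \code{n - k} merges (equivalent to a
#' height cut, as average-linkage heights are monotone non-decreasing);
#' cluster ids are numbered by each cluster's smallest observation index.
#'
#' @param z numeric observations x keys matrix of z-scores (rows named).
#' @param k number of clusters to cut to.
#' @return a \code{\link{ClusterResult}} (favorable flags all \code{FALSE};
#'   see \code{\link{selectFavorableClusters}}).
#' @export
averageLinkageCluster <- function(z, k) {
  if (is.null(colnames(z)))
    colnames(z) <- paste0("k", seq_len(ncol(z)))
  n <- nrow(z)
  if (k > n) stop("k must not exceed the number of observations")
  if (k < 1L) stop("k must be >= 1")
  d <- uncenteredDistance(z)

  size <- rep(1L, n)
  active <- rep(TRUE, n)
  id <- -seq_len(n)             # hclust convention: negatives = singletons
  members <- as.list(seq_len(n))
  merge <- matrix(0L, max(n - 1L, 0L), 2L)
  height <- numeric(max(n - 1L, 0L))
  assign <- seq_len(n)

  if (n > 1L) {
    for (step in seq_len(n - 1L)) {
      act <- which(active)
      sub <- d[act, act, drop = FALSE]
      sub[lower.tri(sub, diag = TRUE)] <- Inf
      best <- which(sub == min(sub), arr.ind = TRUE)
      best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
      i <- act[best[1]]; j <- act[best[2]]
      merge[step, ] <- c(id[i], id[j])
      height[step] <- d[i, j]
      ## Lance-Williams UPGMA update into slot i
      others <- act[act != i & act != j]
      if (length(others)) {
        d[i, others] <- (size[i] * d[i, others] + size[j] * d[j, others]) /
          (size[i] + size[j])
        d[others, i] <- d[i, others]
      }
      size[i] <- size[i] + size[j]
      active[j] <- FALSE
      id[i] <- step
      members[[i]] <- c(members[[i]], members[[j]])
      if (step <= n - k) {
        for (m in members[[i]]) assign[m] <- i
      }
    }
  }
  ## renumber the cut partition 1..k by smallest member index
  first <- tapply(seq_len(n), assign, min)
  relab <- setNames(rank(first), names(first))
  assign <- as.integer(relab[as.character(assign)])
  names(assign) <- rownames(z)

  cent <- do.call(rbind, lapply(seq_len(max(assign)), function(cl) {
    colMeans(z[assign == cl, , drop = FALSE])
  }))
  colnames(cent) <- colnames(z)
  new("ClusterResult", assignments = assign, merge = merge, height = height,
      centroids = cent, favorable = rep(FALSE, nrow(cent)),
      keys = colnames(z))
}

#' Default clustering keys: the three key TME features
#'
#' Functional (Ki-67+) tumor-reactive (CD39+CD103+) CD8 TIL density in the
#' tumor nest; immunosuppressive CD206+ M2-TAM density; FAP positivity in
#' stromal cells of the intratumoral stroma.
#' @return character vector of feature names.
#' @export
clusteringKeys <- function() {
  c("ki67_trm_cd8_density_tn", "cd206_tam_density_it", "fap_pos_stromal_isa")
}

#' Flag favorable-TME (fTME) clusters by the centroid-sign rule
#'
#' A cluster is favorable when its centroid shows above-average functional
#' tumor-reactive CD8 TILs without immunosuppressive M2-TAMs or CAFs:
#' z(Ki-67+ Trm-like CD8 density) > 0 AND z(CD206+ TAM density) < 0 AND
#' z(FAP positivity in stromal cells) < 0.
#'
#' @param result a \code{\link{ClusterResult}} computed on the three keys.
#' @param keys the three key feature names, in the order (tumor-reactive,
#'   M2-TAM, CAF).
#' @return the \code{ClusterResult} with its \code{favorable} flags set.
#' @export
selectFavorableClusters <- function(result, keys = clusteringKeys()) {
  cent <- clusterCentroids(result)
  missing <- setdiff(keys, colnames(cent))
  if (length(missing))
    stop(sprintf("centroids lack clustering key(s): %s",
                 paste(missing, collapse = ", ")))
  fav <- cent[, keys[1]] > 0 & cent[, keys[2]] < 0 & cent[, keys[3]] < 0
  result@favorable <- unname(fav)
  result
}

#' Cluster a cohort on the key TME features and flag fTME patients
#'
#' z-scores the clustering keys, excludes patients with any missing key
#' (missing data are not imputed), runs uncentered-correlation average-linkage
#' clustering, cuts at \code{k} and applies the favorable-cluster rule.
#'
#' @param features a \code{\link{TMEFeatures}} or numeric matrix.
#' @param keys clustering keys (default \code{\link{clusteringKeys}}).
#' @param k number of clusters (default 10).
#' @return list: \code{result} (a \code{\link{ClusterResult}}), \code{ftme}
#'   (named logical per patient; \code{NA} for excluded patients),
#'   \code{excluded} (patient ids with missing keys), \code{z} (the z matrix).
#' @export
clusterCohort <- function(features, keys = clusteringKeys(), k = 10) {
  m <- if (is(features, "TMEFeatures")) featureValues(features) else features
  missingKeys <- setdiff(keys, colnames(m))
  if (length(missingKeys))
    stop(sprintf("feature matrix lacks clustering key(s): %s",
                 paste(missingKeys, collapse = ", ")))
  sub <- m[, keys, drop = FALSE]
  complete <- rownames(sub)[complete.cases(sub)]
  excluded <- setdiff(rownames(sub), complete)
  z <- zscoreMatrix(sub[complete, , drop = FALSE])
  res <- selectFavorableClusters(averageLinkageCluster(z, k), keys)
  fav <- favorableClusters(res)[clusterAssignments(res)]
  ftme <- setNames(rep(NA, nrow(m)), rownames(m))
  ftme[complete] <- fav
  list(result = res, ftme = ftme, excluded = excluded, z = z)
}
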