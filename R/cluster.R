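#' K-means clustering with condition agreement
#'
#' Runs `stats::kmeans` with multiple restarts (best inertia kept) and, when
#' reference labels are supplied, reports how well the clusters recover
#' them: purity (fraction of rows in their cluster's majority class) and the
#' adjusted Rand index (chance-corrected pair-counting agreement).
#'
#' @param points Numeric matrix of rows to cluster (e.g. t-SNE coordinates
#'   or standardized feature rows).
#' @param k Number of clusters (default 2).
#' @param seed Integer seed.
#' @param restarts Random restarts (default 10).
#' @param labels Optional reference labels, one per row.
#' @return An object of class `cluster_result`: `cluster` (integer labels),
#'   `k`, `purity`, `adjusted_rand`, `tot_withinss`, `seed`.
#' @export
kmeans_cluster <- function(points, k = 2L, seed = 0L, restarts = 10L,
                           labels = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < k) stop("fewer rows than clusters", call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  km <- stats::kmeans(points, centers = k, nstart = restarts, iter.max = 100L)
  res <- list(cluster = unname(km$cluster), k = as.integer(k),
              purity = NA_real_, adjusted_rand = NA_real_,
              tot_withinss = km$tot.withinss, seed = as.integer(seed))
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(points))
    res$purity <- cluster_purity(km$cluster, labels)
    res$adjusted_rand <- adjusted_rand_index(km$cluster, labels)
  }
  class(res) <- "cluster_result"
  res
}

#' Cluster purity
#'
#' Sum over clusters of the majority-class count, divided by n. Invariant to
#' permutations of cluster labels; at least `1/k` for k balanced classes.
#'
#' @param cluster Cluster assignment per row.
#' @param labels Reference class labels per row.
#' @return Purity in `[0, 1]`.
#' @export
cluster_purity <- function(cluster, labels) {
  tab <- table(cluster, labels)
  sum(apply(tab, 1L, max)) / sum(tab)
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, corrected for chance:
#' 0 expected for independent partitions, 1 for identical ones.
#'
#' @param a,b Two partitions of the same rows.
#' @return Adjusted Rand index (can be slightly negative).
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(0)
  (sum_ij - expected) / (max_idx - expected)
}

#' PCA linear projection of a feature table
#'
#' Projects the complete rows of a standardized feature table onto the first
#' two principal components, with a per-feature axis vector (the feature's
#' loadings on PC1/PC2) pointing toward increasing feature values. Component
#' signs are fixed so each PC's largest-magnitude loading is positive.
#'
#' @param table A `feature_table` (standardized internally) or a numeric
#'   matrix.
#' @return An object of class `projection_result`: `scores` (n x 2),
#'   `axes` (features x 2 loading matrix), `var_explained` (length-2
#'   fractions), `rows` (embedded row indices).
#' @export
pca_projection <- function(table) {
  if (inherits(table, "feature_table")) {
    rows <- which(complete_feature_rows(table))
    x <- feature_matrix(standardize(table), complete_only = TRUE)
  } else {
    x <- as.matrix(table)
    rows <- seq_len(nrow(x))
    x <- scale(x)
    x[is.nan(x)] <- 0
  }
  if (nrow(x) < 2L) stop("PCA needs at least 2 complete rows", call. = FALSE)
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  k <- min(2L, ncol(pc$rotation))
  rot <- matrix(0, ncol(x), 2, dimnames = list(colnames(x), c("PC1", "PC2")))
  rot[, seq_len(k)] <- pc$rotation[, seq_len(k)]
  scores <- matrix(0, nrow(x), 2)
  scores[, seq_len(k)] <- pc$x[, seq_len(k)]
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, axes = rot,
                 var_explained = c(ve, 0)[1:2], rows = rows),
            class = "projection_result")
}
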