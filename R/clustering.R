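#' K-means partition of TSS occupancy profiles
#'
#' Partitions genes into `k` occupancy classes by Lloyd k-means (squared
#' Euclidean distance on the raw bin profiles, no standardization — classes
#' are meant to run from high to low modification level, which row scaling
#' would destroy). The best of `restarts` k-means++ initializations by
#' within-cluster sum of squares is kept, and labels are renumbered 1..k by
#' descending cluster mean occupancy (mean of row means), so label 1 is
#' always the most heavily marked class and label `k` the unmarked one.
#'
#' Rows are processed in gene-name-sorted order, so the result is
#' deterministic given the gene set and `seed`, regardless of input row
#' order. A cluster left empty during iteration is re-seeded from the point
#' farthest from its current centroid (with a message).
#'
#' @param matrix An [build_occupancy_matrix()] result (or any numeric matrix
#'   with gene rownames).
#' @param k Number of clusters (default 4).
#' @param restarts Independent initializations (default 10).
#' @param seed Integer RNG seed.
#' @param max_iter Lloyd iteration cap per restart (default 100).
#' @return A list of class `ClusterAssignment`: `labels` (named integer
#'   vector, 1..k), `centers` (k x bins matrix, ordered rows), `sizes`,
#'   `cluster_means` (per-label mean occupancy, non-increasing), `wcss`,
#'   `k`, `seed`.
#' @export
kmeans_occupancy <- function(matrix, k = 4, restarts = 10, seed = 1,
                             max_iter = 100) {
  stopifnot(k >= 2, restarts >= 1, nrow(matrix) >= 1)
  x <- unclass(matrix)[order(rownames(matrix)), , drop = FALSE]
  attr(x, "offsets") <- NULL
  attr(x, "edge_clipped") <- NULL
  if (nrow(unique(as.data.frame(x))) < k) {
    stop_input("kmeans_occupancy: fewer than k distinct profiles")
  }
  best <- NULL
  with_local_seed(seed, {
    for (r in seq_len(restarts)) {
      init <- .kmeanspp_init(x, k)
      fit <- .lloyd(x, init, max_iter)
      if (is.null(best) || fit$wcss < best$wcss) best <- fit
    }
  })
  # relabel by descending mean occupancy
  row_means <- rowMeans(x)
  cl_means <- vapply(seq_len(k), function(j) {
    mean(row_means[best$labels == j])
  }, numeric(1))
  ord <- order(cl_means, decreasing = TRUE)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- relabel[best$labels]
  names(labels) <- rownames(x)
  structure(
    list(
      labels = labels,
      centers = best$centers[ord, , drop = FALSE],
      sizes = as.integer(tabulate(labels, k)),
      cluster_means = cl_means[ord],
      wcss = best$wcss,
      k = as.integer(k),
      seed = seed
    ),
    class = "ClusterAssignment"
  )
}

# squared Euclidean distances, n x k
.sqdist <- function(x, centers) {
  d <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
  pmax(d, 0)
}

# k-means++ seeding (Arthur & Vassilvitskii): D^2-weighted center draws
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- .sqdist(x, centers[1L, , drop = FALSE])[, 1L]
  for (j in seq_len(k)[-1L]) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1L, prob = prob), ]
    d2 <- pmin(d2, .sqdist(x, centers[j, , drop = FALSE])[, 1L])
  }
  centers
}

# Lloyd iterations with farthest-point re-seeding of empty clusters
.lloyd <- function(x, centers, max_iter) {
  k <- nrow(centers)
  labels <- integer(nrow(x))
  for (it in seq_len(max_iter)) {
    d <- .sqdist(x, centers)
    new_labels <- max.col(-d, ties.method = "first")
    empty <- which(tabulate(new_labels, k) == 0L)
    for (j in empty) {
      far <- which.max(d[cbind(seq_len(nrow(x)), new_labels)])
      message("k-means: empty cluster ", j, " re-seeded from farthest point")
      centers[j, ] <- x[far, ]
      new_labels[far] <- j
      d <- .sqdist(x, centers)
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(x[labels == j, , drop = FALSE])
    }
  }
  d <- .sqdist(x, centers)
  wcss <- sum(d[cbind(seq_len(nrow(x)), labels)])
  list(labels = labels, centers = centers, wcss = wcss)
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat("ClusterAssignment: k =", x$k, "; sizes:",
      paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Group another matrix's rows by a fixed cluster assignment
#'
#' Applies an existing gene -> label map to a second occupancy matrix (e.g.
#' the mutant genotype) without re-clustering, so genotype metagenes are
#' compared over a common partition.
#'
#' @param assignment A [kmeans_occupancy()] result.
#' @param matrix An occupancy matrix whose gene names are all present in the
#'   assignment.
#' @return A list of length `k`; element `j` is the sub-matrix of genes with
#'   label `j` (possibly 0 rows).
#' @export
apply_assignment <- function(assignment, matrix) {
  genes <- rownames(matrix)
  missing <- setdiff(genes, names(assignment$labels))
  if (length(missing) > 0L) {
    stop_input("apply_assignment: gene(s) missing from assignment: ",
               paste(missing, collapse = ", "))
  }
  labels <- assignment$labels[genes]
  lapply(seq_len(assignment$k), function(j) {
    matrix[labels == j, , drop = FALSE]
  })
}
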