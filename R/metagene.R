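#' Metagene profile of a gene group
#'
#' Per-bin arithmetic mean and standard error of the mean across a set of
#' genes' occupancy rows — the average TSS-centered signal profile of a
#' cluster or gene set.
#'
#' @param matrix An `OccupancyMatrix` (or numeric matrix with an `offsets`
#'   attribute).
#' @param genes Optional character vector selecting rows; default all rows.
#' @param label Profile label (cluster id, gene-set name, genotype, ...).
#' @return A data.frame of class `MetageneProfile` with columns `label`,
#'   `offset`, `mean`, `sem`, `n`.
#' @export
metagene_profile <- function(matrix, genes = NULL, label = "all") {
  offs <- attr(matrix, "offsets")
  if (is.null(offs)) {
    stop_input("metagene_profile: matrix lacks an 'offsets' attribute")
  }
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(matrix))
    if (length(missing) > 0L) {
      stop_input("metagene_profile: gene(s) not in matrix: ",
                 paste(missing, collapse = ", "))
    }
    matrix <- matrix[genes, , drop = FALSE]
  }
  n <- nrow(matrix)
  if (n == 0L) stop_input("metagene_profile: empty gene selection")
  m <- unclass(matrix)
  means <- colMeans(m)
  sems <- if (n == 1L) {
    rep(0, ncol(m))
  } else {
    apply(m, 2L, stats::sd) / sqrt(n)
  }
  structure(
    data.frame(label = label, offset = offs, mean = unname(means),
               sem = unname(sems), n = n, stringsAsFactors = FALSE),
    class = c("MetageneProfile", "data.frame")
  )
}

#' Genotype difference of two metagene profiles
#'
#' Per-bin `mutant - wild-type` difference with SEM propagated as
#' `sqrt(sem_wt^2 + sem_mut^2)`. Descriptive only — no per-bin testing.
#'
#' @param profile_wt,profile_mut [metagene_profile()] results on identical
#'   bin grids.
#' @return Data.frame with columns `offset`, `diff` (mut - wt), `sem`,
#'   `label`.
#' @export
genotype_difference <- function(profile_wt, profile_mut) {
  if (nrow(profile_wt) != nrow(profile_mut) ||
      !isTRUE(all.equal(profile_wt$offset, profile_mut$offset))) {
    stop_input("genotype_difference: mismatched bin grids")
  }
  data.frame(
    offset = profile_wt$offset,
    diff = profile_mut$mean - profile_wt$mean,
    sem = sqrt(profile_wt$sem^2 + profile_mut$sem^2),
    label = paste0(profile_mut$label[1L], "-", profile_wt$label[1L]),
    stringsAsFactors = FALSE
  )
}

#' Per-cluster metagene profiles for one genotype
#'
#' Convenience wrapper: applies a fixed cluster assignment to a matrix and
#' computes one metagene per cluster.
#'
#' @param matrix An `OccupancyMatrix`.
#' @param assignment A [kmeans_occupancy()] result covering the matrix genes.
#' @param genotype Label prefix for the profiles.
#' @return A list of `MetageneProfile`, one per cluster label 1..k; empty
#'   clusters yield `NULL`.
#' @export
cluster_metagenes <- function(matrix, assignment, genotype = "WT") {
  groups <- apply_assignment(assignment, matrix)
  lapply(seq_along(groups), function(j) {
    if (nrow(groups[[j]]) == 0L) return(NULL)
    metagene_profile(groups[[j]],
                     label = paste0(genotype, ".cluster", j))
  })
}
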