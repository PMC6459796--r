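#' Read a gene -> term annotation table
#'
#' Three-column TSV: `gene`, `term`, `branch`, where branch is one of
#' `biological_process`, `cellular_component`, `molecular_function`.
#'
#' @param file Path or connection.
#' @return Data.frame with columns `gene`, `term`, `branch`.
#' @export
read_term_table <- function(file) {
  df <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("gene", "term", "branch"))
  bad <- setdiff(unique(df$branch),
                 c("biological_process", "cellular_component",
                   "molecular_function"))
  if (length(bad) > 0L) {
    stop_input("annotation format error: unknown branch ",
               paste(bad, collapse = ", "))
  }
  df
}

#' Read a GMT gene-set file
#'
#' One term per line: `term <tab> description <tab> gene1 <tab> gene2 ...`.
#' GMT carries no ontology branch, so terms are assigned branch
#' `biological_process`.
#'
#' @param file Path or connection.
#' @return Data.frame with columns `gene`, `term`, `branch` (long format,
#'   compatible with [classify_neuronal()] and [ease_enrichment()]).
#' @export
read_gmt <- function(file) {
  lines <- readLines(if (is.character(file)) gzfile(file) else file)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  do.call(rbind, lapply(fields, function(f) {
    if (length(f) < 3L) {
      stop_input("GMT format error: line with fewer than 3 fields")
    }
    data.frame(gene = f[-(1:2)], term = f[1L],
               branch = "biological_process", stringsAsFactors = FALSE)
  }))
}

#' Classify neuronal genes from annotation terms
#'
#' A gene is neuronal if it carries any term (any branch) whose name
#' contains "synapse" or "synaptic" (case-insensitive substring), or a
#' cellular-component term whose name contains "neuron". This reproduces the
#' rule, not any particular annotation release's list.
#'
#' @param annotations Data.frame with `gene`, `term`, `branch` (see
#'   [read_term_table()]).
#' @param genes Optional universe; the result is intersected with it.
#' @return Character vector of neuronal gene names (possibly empty).
#' @export
classify_neuronal <- function(annotations, genes = NULL) {
  hit <- grepl("synapse|synaptic", annotations$term, ignore.case = TRUE) |
    (annotations$branch == "cellular_component" &
       grepl("neuron", annotations$term, ignore.case = TRUE))
  out <- unique(annotations$gene[hit])
  if (!is.null(genes)) out <- intersect(out, genes)
  out
}

#' Distribution of a gene set across occupancy clusters
#'
#' Percentage of the gene set falling in each cluster label 1..k. Genes
#' absent from the assignment are dropped (with a message reporting the
#' count); percentages are over the retained genes and sum to 100.
#'
#' @param assignment A [kmeans_occupancy()] result.
#' @param geneset Character vector of gene names.
#' @return Named numeric vector of percentages (`cluster1` ... `clusterk`).
#' @export
cluster_distribution <- function(assignment, geneset) {
  geneset <- unique(geneset)
  present <- geneset %in% names(assignment$labels)
  if (any(!present)) {
    message(sum(!present), " gene(s) absent from the assignment dropped")
  }
  kept <- geneset[present]
  if (length(kept) == 0L) {
    stop_input("cluster_distribution: no gene of the set is in the ",
               "assignment")
  }
  counts <- tabulate(assignment$labels[kept], assignment$k)
  stats::setNames(100 * counts / length(kept),
                  paste0("cluster", seq_len(assignment$k)))
}

#' EASE p-value of a 2x2 enrichment table
#'
#' The EASE score is DAVID's conservatively modified one-sided Fisher's
#' exact p-value: the overlap count `a` is replaced by `max(a - 1, 0)`
#' before computing the hypergeometric upper tail, penalizing single-gene
#' overlaps.
#'
#' @param a Genes in list and term.
#' @param b Genes in list but not term.
#' @param c Genes in term but not list.
#' @param d Background genes in neither.
#' @return Upper-tail probability in `[0, 1]` (vectorized).
#' @export
ease_pvalue <- function(a, b, c, d) {
  a1 <- pmax(a - 1, 0)
  # P(X >= a1) with X ~ Hypergeom over the decremented table
  stats::phyper(a1 - 1, m = a1 + c, n = b + d, k = a1 + b,
                lower.tail = FALSE)
}

#' EASE-score term enrichment with Benjamini-Hochberg correction
#'
#' For each term, counts the 2x2 overlap of `gene_list` with the term's
#' genes inside `background`, computes the EASE p-value (one-sided,
#' enrichment only) and adjusts across all tested terms by BH step-up.
#'
#' @param gene_list Character vector, a subset of `background`.
#' @param background Character vector of universe genes.
#' @param terms Either a named list of gene vectors (term -> genes) or a
#'   long annotation data.frame with `gene` and `term` columns.
#' @param alpha Significance cutoff on the adjusted p (default 0.05).
#' @return Data.frame sorted by `ease_p`: `term`, `a`, `b`, `c`, `d`,
#'   `ease_p`, `bh_q`, `significant`.
#' @export
ease_enrichment <- function(gene_list, background, terms, alpha = 0.05) {
  background <- unique(background)
  gene_list <- unique(gene_list)
  if (length(background) == 0L) {
    stop_input("ease_enrichment: empty background")
  }
  stray <- setdiff(gene_list, background)
  if (length(stray) > 0L) {
    stop_input("ease_enrichment: gene_list not contained in background: ",
               paste(utils::head(stray, 5L), collapse = ", "))
  }
  if (is.data.frame(terms)) {
    terms <- split(terms$gene, terms$term)
  }
  n_bg <- length(background)
  n_list <- length(gene_list)
  counts <- t(vapply(terms, function(g) {
    g <- intersect(unique(g), background)
    a <- length(intersect(g, gene_list))
    c(a = a, b = n_list - a, c = length(g) - a,
      d = n_bg - n_list - (length(g) - a))
  }, numeric(4)))
  p <- ease_pvalue(counts[, "a"], counts[, "b"], counts[, "c"],
                   counts[, "d"])
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(
    term = names(terms),
    a = as.integer(counts[, "a"]), b = as.integer(counts[, "b"]),
    c = as.integer(counts[, "c"]), d = as.integer(counts[, "d"]),
    ease_p = p, bh_q = q, significant = q < alpha,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$ease_p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
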