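#' Read a long-format Ct table
#'
#' TSV with header: `sample_id`, `gene`, `ct`, `arm` and optionally
#' `pair_id`. One row per well; technical replicates (repeated sample x
#' gene) are allowed and averaged on the Ct scale downstream.
#'
#' @param file Path or connection.
#' @return Data.frame of Ct records.
#' @export
read_ct_table <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "ct", "arm")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop_input("Ct table format error: missing column(s) ",
               paste(missing, collapse = ", "))
  }
  if (any(!is.finite(df$ct))) {
    stop_input("Ct table format error: non-finite Ct value")
  }
  df
}

#' Delta-Ct of target versus reference
#'
#' @param ct_target,ct_reference Finite threshold-cycle values.
#' @return `ct_target - ct_reference` (vectorized).
#' @export
delta_ct <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference))) {
    stop_input("delta_ct: non-finite Ct value")
  }
  ct_target - ct_reference
}

# Average technical replicates on the Ct scale and compute per-sample
# delta-Ct of every target gene against the reference gene.
.sample_dct <- function(table, reference) {
  agg <- stats::aggregate(ct ~ sample_id + gene + arm, data = table,
                          FUN = mean)
  ref <- agg[agg$gene == reference, c("sample_id", "ct")]
  names(ref)[2L] <- "ct_ref"
  tgt <- agg[agg$gene != reference, , drop = FALSE]
  no_ref <- setdiff(unique(tgt$sample_id), ref$sample_id)
  if (length(no_ref) > 0L) {
    stop_input("qPCR: sample(s) lacking a ", reference, " reference record: ",
               paste(no_ref, collapse = ", "))
  }
  tgt <- merge(tgt, ref, by = "sample_id")
  tgt$dct <- delta_ct(tgt$ct, tgt$ct_ref)
  tgt
}

# classical equal-variance two-sample t; degenerate zero variance -> t=0,p=1
.student_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  df <- nx + ny - 2
  if (sp2 == 0) {
    warning("zero-variance fold values; t = 0, p = 1 by convention",
            call. = FALSE)
    return(list(t = 0, df = df, p = 1))
  }
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Relative expression for the unpaired wild-type vs mutant design
#'
#' Per gene, the mean wild-type delta-Ct (`dct_mean`) is the normalizer:
#' every sample's fold is `2^-(dct - dct_mean)`, so wild-type folds are
#' centered at geometric mean 1. Genotypes are compared per gene with the
#' classical (equal-variance) two-sided Student's t test on the fold values.
#'
#' @param table Long Ct data.frame ([read_ct_table()]) with arms `WT` and
#'   `Mut`.
#' @param reference Reference (housekeeping) gene name, default `"Hprt"`.
#' @return List of class `ExpressionResult`: `folds` (per sample x gene:
#'   `sample_id`, `gene`, `arm`, `dct`, `fold`) and `tests` (per gene:
#'   group mean folds, `t`, `df`, `p`).
#' @export
unpaired_expression <- function(table, reference = "Hprt") {
  tgt <- .sample_dct(table, reference)
  arms <- unique(tgt$arm)
  if (!setequal(arms, c("WT", "Mut"))) {
    stop_input("unpaired_expression: arms must be WT and Mut (got ",
               paste(arms, collapse = ", "), ")")
  }
  folds <- NULL
  tests <- NULL
  for (g in unique(tgt$gene)) {
    sub <- tgt[tgt$gene == g, , drop = FALSE]
    n_arm <- table(sub$arm)
    if (any(n_arm < 2L) || length(n_arm) < 2L) {
      stop_input("unpaired_expression: gene ", g,
                 " has an arm with fewer than 2 samples")
    }
    dct_mean <- mean(sub$dct[sub$arm == "WT"])
    sub$fold <- 2^(-(sub$dct - dct_mean))
    folds <- rbind(folds, sub[, c("sample_id", "gene", "arm", "dct", "fold")])
    wt <- sub$fold[sub$arm == "WT"]
    mut <- sub$fold[sub$arm == "Mut"]
    tt <- .student_t(wt, mut)
    tests <- rbind(tests, data.frame(
      gene = g, dct_mean = dct_mean, mean_fold_wt = mean(wt),
      mean_fold_mut = mean(mut), t = tt$t, df = tt$df, p = tt$p,
      stringsAsFactors = FALSE
    ))
  }
  rownames(folds) <- rownames(tests) <- NULL
  structure(list(folds = folds, tests = tests, design = "unpaired"),
            class = "ExpressionResult")
}

#' Relative expression for the paired vehicle vs drug design
#'
#' Each pair (one embryo's culture split onto two wells) contributes one
#' fold `2^-(dct_drug - dct_vehicle)`; the vehicle side is 1 by
#' construction. Per gene, folds are tested against 1 with a two-sided
#' paired t test (equivalently a one-sample t on `fold - 1`).
#'
#' @param table Long Ct data.frame with arms `vehicle` and `drug` and a
#'   `pair_id` column; every pair must have exactly one record per arm and
#'   gene.
#' @param reference Reference gene name, default `"Hprt"`.
#' @param scale Test scale: `"fold"` (default, matches the plotted
#'   quantity) or `"ddct"` (one-sample t on the per-pair delta-delta-Ct
#'   against 0).
#' @return List of class `ExpressionResult`: `folds` (per pair x gene) and
#'   `tests` (per gene: `mean_fold`, `t`, `df`, `p`).
#' @export
paired_expression <- function(table, reference = "Hprt",
                              scale = c("fold", "ddct")) {
  scale <- match.arg(scale)
  if (!"pair_id" %in% names(table)) {
    stop_input("paired_expression: table lacks a pair_id column")
  }
  tgt <- .sample_dct(table, reference)
  pair_map <- unique(table[, c("sample_id", "pair_id")])
  tgt <- merge(tgt, pair_map, by = "sample_id")
  arms <- unique(tgt$arm)
  if (!setequal(arms, c("vehicle", "drug"))) {
    stop_input("paired_expression: arms must be vehicle and drug (got ",
               paste(arms, collapse = ", "), ")")
  }
  folds <- NULL
  tests <- NULL
  for (g in unique(tgt$gene)) {
    sub <- tgt[tgt$gene == g, , drop = FALSE]
    v <- sub[sub$arm == "vehicle", c("pair_id", "dct")]
    d <- sub[sub$arm == "drug", c("pair_id", "dct")]
    bad <- c(setdiff(v$pair_id, d$pair_id), setdiff(d$pair_id, v$pair_id),
             v$pair_id[duplicated(v$pair_id)],
             d$pair_id[duplicated(d$pair_id)])
    if (length(bad) > 0L) {
      stop_input("paired_expression: unmatched pair(s) for gene ", g, ": ",
                 paste(unique(bad), collapse = ", "))
    }
    m <- merge(v, d, by = "pair_id", suffixes = c("_v", "_d"))
    ddct <- m$dct_d - m$dct_v
    fold <- 2^(-ddct)
    folds <- rbind(folds, data.frame(
      pair_id = m$pair_id, gene = g, ddct = ddct, fold = fold,
      stringsAsFactors = FALSE
    ))
    x <- if (scale == "fold") fold - 1 else ddct
    n <- length(x)
    s <- stats::sd(x)
    df <- n - 1
    if (s == 0) {
      if (any(x != 0)) {
        warning("zero-variance paired values for gene ", g,
                "; t = 0, p = 1 by convention", call. = FALSE)
      }
      tt <- list(t = 0, df = df, p = 1)
    } else {
      t <- mean(x) / (s / sqrt(n))
      tt <- list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
    }
    tests <- rbind(tests, data.frame(
      gene = g, mean_fold = mean(fold), t = tt$t, df = tt$df, p = tt$p,
      stringsAsFactors = FALSE
    ))
  }
  rownames(folds) <- rownames(tests) <- NULL
  structure(list(folds = folds, tests = tests, design = "paired",
                 scale = scale),
            class = "ExpressionResult")
}

#' @export
print.ExpressionResult <- function(x, ...) {
  cat("ExpressionResult (", x$design, " design)\n", sep = "")
  print(x$tests)
  invisible(x)
}
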