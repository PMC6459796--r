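# Independent brute-force oracles and small fixture builders.

# per-base mean over [start, end) straight from the interval list; bases
# outside every interval (including negative positions) count as 0
brute_mean <- function(iv, chrom, start, end) {
  pos <- seq(start, end - 1)
  vals <- numeric(length(pos))
  for (i in seq_len(nrow(iv))) {
    if (iv$chrom[i] != chrom) next
    sel <- pos >= iv$start[i] & pos < iv$end[i]
    vals[sel] <- iv$value[i]
  }
  mean(vals)
}

# per-base binning oracle for one gene row (0-based tss), strand-oriented
brute_matrix_row <- function(iv, chrom, tss, strand, window = 5000,
                             bin = 100) {
  nbin <- 2 * window / bin
  vapply(seq_len(nbin), function(i) {
    s <- if (strand == "+") tss - window + (i - 1) * bin
         else tss + window - i * bin
    brute_mean(iv, chrom, s, s + bin)
  }, numeric(1))
}

# random sorted non-overlapping toy intervals on one chromosome
random_track_df <- function(n_iv = 10, chrom = "chrT", max_pos = 10000) {
  bounds <- sort(sample(0:max_pos, 2 * n_iv))
  data.frame(
    chrom = chrom,
    start = bounds[seq(1, 2 * n_iv, 2)],
    end = bounds[seq(2, 2 * n_iv, 2)],
    value = round(stats::runif(n_iv, 0, 10), 3)
  )
}

# minimal gene-model data.frame
gene_models <- function(gene_name, chrom, strand, tss) {
  data.frame(
    gene_name = gene_name, chrom = chrom, strand = strand,
    tx_start = ifelse(strand == "+", tss, tss - 999),
    tx_end = ifelse(strand == "+", tss + 1000, tss + 1),
    tss = tss, stringsAsFactors = FALSE
  )
}

# deterministic sample that leaves the global RNG stream untouched
with_seed_sample <- function(x, size, seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample(x, size)
}

# a refGene line with given fields, padded to 16 columns
refgene_line <- function(name, chrom, strand, start, end, gene) {
  paste(c("0", name, chrom, strand, start, end, start, end, "1",
          paste0(start, ","), paste0(end, ","), "0", gene, "cmpl",
          "cmpl", "0,"), collapse = "\t")
}
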