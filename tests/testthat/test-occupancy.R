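test_that("uniform signal gives a constant matrix on both strands", {
  tr <- coverage_track(data.frame(chrom = "chr1", start = 0, end = 40000,
                                  value = 3))
  genes <- gene_models(c("P", "M"), "chr1", c("+", "-"), c(12000L, 25000L))
  m <- build_occupancy_matrix(genes, tr)
  expect_equal(dim(m), c(2L, 100L))  # B = 100 for the default config
  expect_true(all(m == 3))
  expect_equal(attr(m, "offsets")[1], -4950)
  expect_equal(attr(m, "offsets")[100], 4950)
  expect_false(any(attr(m, "edge_clipped")))
})

test_that("a single upstream interval lands in the expected bin", {
  tss <- 20000L
  tr <- coverage_track(data.frame(chrom = "chr1", start = tss - 200,
                                  end = tss - 100, value = 10))
  # plus strand: offsets [-200,-100) are bin 49 (1-based)
  mp <- build_occupancy_matrix(gene_models("P", "chr1", "+", tss), tr)
  expect_equal(unname(mp[1, 49]), 10)
  expect_equal(sum(mp), 10)
  # minus strand: same genomic signal mirrors to bin 52
  mm <- build_occupancy_matrix(gene_models("M", "chr1", "-", tss), tr)
  expect_equal(unname(mm[1, 52]), 10)
  expect_equal(sum(mm), 10)
})

test_that("matrix equals the per-base brute-force oracle on toy data", {
  set.seed(21)
  cfg <- occupancy_config(window_bp = 2000, bin_bp = 100)
  for (rep in 1:3) {
    df <- random_track_df(10, max_pos = 9000)
    tr <- coverage_track(df)
    genes <- gene_models(sprintf("G%d", 1:4), "chrT",
                         c("+", "-", "+", "-"),
                         as.integer(sample(2000:7000, 4)))
    m <- build_occupancy_matrix(genes, tr, cfg)
    for (i in 1:4) {
      oracle <- brute_matrix_row(df, "chrT", genes$tss[i], genes$strand[i],
                                 window = 2000, bin = 100)
      expect_equal(unname(m[i, ]), oracle, tolerance = 1e-9)
    }
  }
})

test_that("reflecting the track and flipping strand leaves a row unchanged", {
  set.seed(33)
  tss <- 20000L
  df <- random_track_df(8, max_pos = 4800)
  df$start <- df$start + tss - 4900  # place inside the window
  df$end <- df$end + tss - 4900
  tr <- coverage_track(df)
  m_plus <- build_occupancy_matrix(gene_models("G", "chrT", "+", tss), tr)
  # reflect each interval around the TSS: [s, e) -> [2*tss - e, 2*tss - s)
  refl <- data.frame(chrom = df$chrom, start = 2 * tss - df$end,
                     end = 2 * tss - df$start, value = df$value)
  m_minus <- build_occupancy_matrix(gene_models("G", "chrT", "-", tss),
                                    coverage_track(refl))
  expect_equal(unname(m_plus[1, ]), unname(m_minus[1, ]), tolerance = 1e-12)
})

test_that("chromosome-start overhang is zero-filled and flagged", {
  tr <- coverage_track(data.frame(chrom = "chr1", start = 0, end = 30000,
                                  value = 2))
  genes <- gene_models(c("Edge", "Mid"), "chr1", c("+", "+"),
                       c(1000L, 20000L))
  m <- build_occupancy_matrix(genes, tr)
  expect_equal(attr(m, "edge_clipped"),
               c(Edge = TRUE, Mid = FALSE))
  # first 40 bins of Edge lie before position 0 -> zero
  expect_true(all(m["Edge", 1:40] == 0))
  expect_true(all(m["Edge", 41:100] == 2))
  expect_true(all(m["Mid", ] == 2))
})

test_that("genes on chromosomes absent from the track get zero rows", {
  tr <- coverage_track(data.frame(chrom = "chr1", start = 0, end = 30000,
                                  value = 2))
  genes <- gene_models(c("A", "B"), c("chr1", "chrUn"), c("+", "+"),
                       c(15000L, 15000L))
  expect_warning(m <- build_occupancy_matrix(genes, tr), "chrUn")
  expect_true(all(m["B", ] == 0))
  expect_true(all(m["A", ] == 2))
})

test_that("matrix TSV io round-trips losslessly with the stated header", {
  set.seed(2)
  tr <- coverage_track(random_track_df(10, max_pos = 30000))
  genes <- gene_models(c("A", "B"), "chrT", c("+", "-"),
                       c(11000L, 19000L))
  m <- build_occupancy_matrix(genes, tr)
  f <- tempfile()
  write_occupancy_matrix(m, f)
  lines <- readLines(f)
  expect_equal(length(lines), 3L)  # header + 2 genes
  expect_match(lines[1], "^gene\t-4950\t-4850\t")
  back <- read_occupancy_matrix(f)
  expect_equal(unclass(back), unclass(m))
  expect_equal(attr(back, "offsets"), attr(m, "offsets"))
  expect_equal(attr(back, "edge_clipped"), attr(m, "edge_clipped"))
  writeLines(c(lines, "short\t1\t2"), f)
  expect_error(read_occupancy_matrix(f), "ragged")
})

test_that("strand flipping can be disabled by configuration", {
  tss <- 20000L
  tr <- coverage_track(data.frame(chrom = "chr1", start = tss - 200,
                                  end = tss - 100, value = 10))
  cfg <- occupancy_config(orient_strand = FALSE)
  mm <- build_occupancy_matrix(gene_models("M", "chr1", "-", tss), tr, cfg)
  expect_equal(unname(mm[1, 49]), 10)  # genomic order kept
})
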