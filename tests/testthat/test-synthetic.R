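test_that("annotation layout is deterministic, parseable and well spaced", {
  ann1 <- simulate_annotation(10, seed = 5)
  ann2 <- simulate_annotation(10, seed = 5)
  f1 <- tempfile(); f2 <- tempfile()
  write_refgene(ann1$transcripts, f1)
  write_refgene(ann2$transcripts, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical re-run
  models <- select_longest_transcripts(parse_refgene(f1))
  expect_equal(nrow(models), 10L)
  expect_true(all(diff(sort(ann1$models$tss)) >= 11000))  # default window
  expect_true(all(ann1$models$tss %% 100 == 0))
  expect_error(simulate_annotation(10, chrom_length = 1000), "too short")
})

test_that("variance-zero tracks reproduce archetype shapes exactly", {
  params <- archetype_params()
  ann <- simulate_annotation(20, seed = 2)
  truth <- assign_archetypes(ann$models, params, seed = 3)
  sim_wt <- simulate_track(ann$models, truth, params, "WT", noise = "none",
                           chrom_length = ann$chrom_length)
  sim_mut <- simulate_track(ann$models, truth, params, "Mut",
                            noise = "none", chrom_length = ann$chrom_length)
  wt <- scale_to_million(sim_wt$track, sim_wt$mappable_reads)
  mut <- scale_to_million(sim_mut$track, sim_mut$mappable_reads)
  m_wt <- build_occupancy_matrix(ann$models, wt)
  m_mut <- build_occupancy_matrix(ann$models, mut)
  bare <- function(m) matrix(as.numeric(unclass(m)), nrow(m), ncol(m))
  cls <- setNames(truth$class, truth$gene_name)
  un <- names(cls)[cls == "unmarked"]
  expect_true(length(un) > 0)
  expect_equal(bare(m_wt[un, , drop = FALSE]),
               matrix(params$baseline, length(un), 100))
  br <- names(cls)[cls == "broad"]
  if (length(br) > 0) {
    expect_equal(bare(m_mut[br, , drop = FALSE]),
                 bare(m_wt[br, , drop = FALSE]) * (1 + params$delta_broad),
                 tolerance = 1e-12)
    expect_equal(unname(m_wt[br[1], ]), rep(params$h_broad, 100))
  }
  st <- names(cls)[cls == "tss_strong"]
  if (length(st) > 0) {
    offs <- attr(m_wt, "offsets")
    expected <- params$baseline +
      params$h_strong * exp(-offs^2 / (2 * params$sigma_strong^2))
    expect_equal(unname(m_wt[st[1], ]), expected, tolerance = 1e-12)
  }
})

test_that("declared read counts make scaling recover expectation scale", {
  params <- archetype_params()
  ann <- simulate_annotation(60, seed = 9)
  truth <- data.frame(gene_name = ann$models$gene_name, class = "broad")
  sim <- simulate_track(ann$models, truth, params, "WT",
                        depth_reads = 8e6, seed = 13,
                        chrom_length = ann$chrom_length)
  expect_equal(sim$mappable_reads, 8e6)
  sc <- scale_to_million(sim$track, sim$mappable_reads)
  m <- build_occupancy_matrix(ann$models, sc)
  # Poisson mean h * 8 per segment, averaged over 60 genes x 100 bins
  expect_equal(mean(m), params$h_broad, tolerance = 0.02)
  expect_error(simulate_track(ann$models, truth[-1, ], params), "lacks")
})

test_that("track simulation is reproducible under a fixed seed", {
  ann <- simulate_annotation(15, seed = 1)
  truth <- assign_archetypes(ann$models, seed = 2)
  s1 <- simulate_track(ann$models, truth, seed = 7,
                       chrom_length = ann$chrom_length)
  s2 <- simulate_track(ann$models, truth, seed = 7,
                       chrom_length = ann$chrom_length)
  expect_identical(s1$track$intervals, s2$track$intervals)
})

test_that("noise-free Ct tables force exact folds", {
  tab <- simulate_ct(3, 3, effect = 1, sd = 0)
  res <- suppressWarnings(unpaired_expression(tab))
  expect_equal(res$folds$fold[res$folds$arm == "Mut"], rep(0.5, 3))
  expect_equal(res$folds$fold[res$folds$arm == "WT"], rep(1, 3))
  tab0 <- simulate_ct(3, 3, effect = 0, sd = 0)
  res0 <- suppressWarnings(unpaired_expression(tab0))
  expect_equal(res0$folds$fold, rep(1, 6))
  expect_equal(res0$tests$t, 0)
  pt_ <- simulate_ct_paired(4, effect = -1, sd = 0)
  resp <- suppressWarnings(paired_expression(pt_))
  expect_equal(resp$folds$fold, rep(2, 4))
})

test_that("planted term tables are deterministic and rank first", {
  truth <- data.frame(
    gene_name = sprintf("G%03d", 1:300),
    class = rep(c("tss_strong", "tss_weak", "unmarked"), each = 100),
    stringsAsFactors = FALSE
  )
  t1 <- simulate_term_table(truth, n_null = 20, odds = 8, seed = 11)
  t2 <- simulate_term_table(truth, n_null = 20, odds = 8, seed = 11)
  expect_identical(t1, t2)
  lst <- truth$gene_name[truth$class != "unmarked"]
  res <- ease_enrichment(lst, truth$gene_name, t1)
  expect_match(res$term[1], "planted")
  # classification picks up exactly the planted neuronal-style terms
  neur <- classify_neuronal(t1)
  expect_true(all(neur %in% unique(t1$gene[grepl("planted", t1$term)])))
})
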