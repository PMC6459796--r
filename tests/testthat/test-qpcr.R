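make_ct <- function(dct_wt, dct_mut, ref = "Hprt", gene = "Tgt") {
  n <- length(dct_wt) + length(dct_mut)
  arm <- rep(c("WT", "Mut"), c(length(dct_wt), length(dct_mut)))
  id <- sprintf("s%02d", seq_len(n))
  rbind(
    data.frame(sample_id = id, gene = ref, ct = 20, arm = arm),
    data.frame(sample_id = id, gene = gene, ct = 20 + c(dct_wt, dct_mut),
               arm = arm)
  )
}

test_that("delta-Ct is the plain target-minus-reference difference", {
  expect_equal(delta_ct(25, 23), 2)
  expect_equal(delta_ct(23, 23), 0)
  expect_equal(delta_ct(20, 22), -2)
  expect_error(delta_ct(NA_real_, 20), "finite")
})

test_that("a sample without a reference record is an error", {
  tab <- make_ct(c(2, 2), c(3, 3))
  tab <- tab[!(tab$sample_id == "s01" & tab$gene == "Hprt"), ]
  expect_error(unpaired_expression(tab), "s01")
})

test_that("technical replicates are averaged on the Ct scale", {
  tab <- make_ct(c(2, 2), c(3, 3))
  dup <- tab[tab$sample_id == "s03" & tab$gene == "Tgt", ]
  dup$ct <- dup$ct + 2   # replicate well: mean dct becomes 4
  res <- suppressWarnings(unpaired_expression(rbind(tab, dup)))
  expect_equal(res$folds$dct[res$folds$sample_id == "s03"], 4)
})

test_that("wild-type folds are centered at 1 and mutant folds forced by 2^-x", {
  res <- suppressWarnings(unpaired_expression(make_ct(c(2, 2, 2), c(3, 3))))
  wt <- res$folds$fold[res$folds$arm == "WT"]
  expect_equal(wt, c(1, 1, 1))      # dct_mean = 2
  expect_equal(res$folds$fold[res$folds$arm == "Mut"], c(0.5, 0.5))
  expect_error(unpaired_expression(make_ct(c(2, 2), 3)), "fewer than 2")
})

test_that("the WT log2-fold mean is exactly zero by construction", {
  set.seed(6)
  tab <- make_ct(rnorm(7, 2, 0.5), rnorm(5, 3, 0.5))
  res <- unpaired_expression(tab)
  wt <- res$folds$fold[res$folds$arm == "WT"]
  expect_equal(mean(log2(wt)), 0, tolerance = 1e-12)
  # symmetric dct perturbations around dct_mean multiply to fold 1
  dct_mean <- res$tests$dct_mean
  expect_equal(2^(-(dct_mean + 0.7 - dct_mean)) *
                 2^(-(dct_mean - 0.7 - dct_mean)), 1)
})

test_that("the genotype test matches the pooled-variance closed form", {
  tab <- make_ct(c(1.8, 2.0, 2.3), c(2.9, 3.1, 3.6))
  res <- unpaired_expression(tab)
  wt_f <- res$folds$fold[res$folds$arm == "WT"]
  mut_f <- res$folds$fold[res$folds$arm == "Mut"]
  sp2 <- (2 * var(wt_f) + 2 * var(mut_f)) / 4
  t_hand <- (mean(wt_f) - mean(mut_f)) / sqrt(sp2 * (2 / 3))
  expect_equal(res$tests$t, t_hand, tolerance = 1e-12)
  expect_equal(res$tests$df, 4)
  expect_equal(res$tests$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  # and the standard library route agrees
  ref <- t.test(wt_f, mut_f, var.equal = TRUE)
  expect_equal(res$tests$t, unname(ref$statistic))
  expect_equal(res$tests$p, ref$p.value)
})

make_paired <- function(ddct, ref = "Hprt", gene = "Tgt") {
  n <- length(ddct)
  pid <- sprintf("e%02d", seq_len(n))
  mk <- function(arm, dct) rbind(
    data.frame(sample_id = paste0(pid, arm), gene = ref, ct = 20,
               arm = arm, pair_id = pid),
    data.frame(sample_id = paste0(pid, arm), gene = gene, ct = 20 + dct,
               arm = arm, pair_id = pid)
  )
  rbind(mk("vehicle", rep(2, n)), mk("drug", 2 + ddct))
}

test_that("paired folds are per-pair 2^-ddct with vehicle fixed at 1", {
  res <- suppressWarnings(paired_expression(make_paired(c(-1, -1, -1))))
  expect_equal(res$folds$fold, c(2, 2, 2))
  res0 <- suppressWarnings(paired_expression(make_paired(c(0, 0, 0))))
  expect_equal(res0$folds$fold, c(1, 1, 1))
  expect_equal(res0$tests$t, 0)
  expect_equal(res0$tests$p, 1)
})

test_that("unmatched pairs are rejected by name", {
  tab <- make_paired(c(0.5, 0.5, 0.5))
  tab <- tab[!(tab$pair_id == "e02" & tab$arm == "drug"), ]
  expect_error(paired_expression(tab), "e02")
})

test_that("the paired test equals the one-sample closed form on folds", {
  folds <- c(1.2, 1.3, 1.4, 1.5)
  res <- paired_expression(make_paired(-log2(folds)))
  expect_equal(res$folds$fold, folds, tolerance = 1e-12)
  x <- folds - 1
  t_hand <- mean(x) / (sd(x) / sqrt(4))
  expect_equal(res$tests$t, t_hand, tolerance = 1e-12)
  expect_equal(res$tests$p, 2 * pt(-abs(t_hand), 3), tolerance = 1e-12)
  ref <- t.test(folds, mu = 1)
  expect_equal(res$tests$t, unname(ref$statistic))
  # the documented alternative scale tests ddct against zero
  res_d <- paired_expression(make_paired(-log2(folds)), scale = "ddct")
  ref_d <- t.test(-log2(folds), mu = 0)
  expect_equal(res_d$tests$t, unname(ref_d$statistic), tolerance = 1e-12)
})

test_that("zero-variance degenerate input warns and returns t=0, p=1", {
  expect_warning(res <- unpaired_expression(make_ct(c(2, 2), c(2, 2))),
                 "zero-variance")
  expect_equal(res$tests$t, 0)
  expect_equal(res$tests$p, 1)
  expect_warning(resp <- paired_expression(make_paired(c(-1, -1))),
                 "zero-variance")
  expect_equal(resp$tests$t, 0)
})
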