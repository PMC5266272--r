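test_that("A-site offsets follow the stated length rules", {
  expect_equal(asite_offset(28, "footprint"), 15L)
  expect_equal(vapply(26:30, asite_offset, integer(1), read_class = "footprint"),
               13:17)
  expect_true(is.na(asite_offset(31, "footprint")))
  expect_true(is.na(asite_offset(25, "footprint")))
  expect_equal(asite_offset(40, "mrna_fragment"), 15L)
  expect_equal(asite_offset(22, "mrna_fragment"), 15L)
  expect_true(is.na(asite_offset(21, "mrna_fragment")))
  expect_true(is.na(asite_offset(52, "mrna_fragment")))
  # explicit table overrides the linear footprint map
  tab <- data.frame(length = 28, offset = 12)
  expect_equal(asite_offset(28, "footprint", tab), 12L)
  expect_true(is.na(asite_offset(29, "footprint", tab)))
})

test_that("counting window excludes the first 15 and last 5 codons", {
  cds <- data.frame(transcript_id = "t1", cds_start = 100L, cds_end = 400L)
  win <- countable_window(cds)
  expect_equal(win$start, 145L)
  expect_equal(win$end, 385L)
  expect_equal(win$effective_length, 240L)

  read_at <- function(fp) data.frame(transcript_id = "t1", five_prime = fp,
                                     length = 28L, read_class = "footprint")
  expect_equal(count_gene(read_at(100L + 30L), cds), 1L)  # A-site 145: in
  expect_equal(count_gene(read_at(100L + 29L), cds), 1L - 1L)  # 144: out
  expect_equal(count_gene(read_at(384L - 15L), cds), 1L)  # 384: last in
  expect_equal(count_gene(read_at(385L - 15L), cds), 0L)  # 385: out
  # rejected lengths contribute nothing
  bad <- data.frame(transcript_id = "t1", five_prime = 200L, length = 31L,
                    read_class = "footprint")
  expect_equal(count_gene(bad, cds), 0L)

  expect_error(countable_window(
    data.frame(transcript_id = "t", cds_start = 0L, cds_end = 100L)),
    "multiple of 3")
  expect_error(countable_window(
    data.frame(transcript_id = "t", cds_start = 0L, cds_end = 60L)),
    "too short")
})

test_that("counts are additive over a partition of the countable window", {
  cds <- data.frame(transcript_id = "t1", cds_start = 0L, cds_end = 600L)
  win <- countable_window(cds)
  withr::with_seed(31, {
    reads <- data.frame(
      transcript_id = "t1",
      five_prime = sample(0:560, 400, replace = TRUE),
      length = sample(24:32, 400, replace = TRUE),
      read_class = "footprint")
  })
  total <- count_gene(reads, cds)
  # count each read's A-site against the two halves of the window directly
  off <- asite_offset(reads$length, "footprint")
  asite <- reads$five_prime + off
  mid <- (win$start + win$end) %/% 2
  lower <- sum(!is.na(asite) & asite >= win$start & asite < mid)
  upper <- sum(!is.na(asite) & asite >= mid & asite < win$end)
  expect_equal(lower + upper, total)
})

test_that("read-level and matrix-level generation share one truth", {
  r <- gen_ribo(n_genes = 4, n_replicates = 1, base_mean = 60,
                read_level = TRUE, seed = 7)
  mats <- count_matrix(r$reads, r$cds)
  expect_equal(mats$footprint, r$counts$footprint[, colnames(mats$footprint)])
  expect_equal(mats$mrna_fragment,
               r$counts$mrna_fragment[, colnames(mats$mrna_fragment)])
})

test_that("median-of-ratios size factors recover library scale", {
  m <- cbind(s1 = c(10, 20, 30), s2 = c(10, 20, 30))
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(unname(size_factors(m2[, 1, drop = FALSE])), 1)
  expect_error(size_factors(cbind(c(0, 5), c(3, 0))), "no gene")

  r <- gen_ribo(n_genes = 200, n_replicates = 1, base_mean = 2000,
                library_sizes = c(0.5, 1), dispersion = 1e-4, seed = 3)
  sf <- size_factors(r$counts$mrna_fragment)
  expect_lt(abs(unname(sf[2] / sf[1]) - 2), 0.1)
})

test_that("size factors agree with the DESeq median-of-ratios reference", {
  skip_if_not_installed("DESeq2")
  r <- gen_ribo(n_genes = 50, n_replicates = 2, base_mean = 300,
                library_sizes = c(0.8, 1.2, 1, 1.5), seed = 5)
  mine <- size_factors(r$counts$mrna_fragment)
  ref <- DESeq2::estimateSizeFactorsForMatrix(r$counts$mrna_fragment)
  expect_equal(unname(mine), unname(ref), tolerance = 1e-8)
})

test_that("TE folds cancel depth, lengths, and unchanged translation", {
  genes <- paste0("g", 1:3)
  design <- data.frame(sample = c("single_r1", "multi_r1"),
                       condition = c("single", "multi"), replicate = 1L)
  base <- matrix(c(100, 200, 300, 100, 200, 300), ncol = 2,
                 dimnames = list(genes, design$sample))
  same <- te_fold_change(base, base, design)
  expect_equal(same$mrna_fold, rep(1, 3))
  expect_equal(same$te_fold, rep(1, 3))

  # one gene's footprints and mRNA both doubled: transcription signal
  # survives, the TE ratio cancels
  doubled <- base; doubled["g1", "multi_r1"] <- 2 * base["g1", "multi_r1"]
  out <- te_fold_change(doubled, doubled, design)
  expect_equal(out$mrna_fold[out$gene == "g1"], 2)
  expect_equal(out$te_fold, rep(1, 3))

  # effective lengths cancel in the fold ratio
  r <- gen_ribo(n_genes = 10, seed = 2)
  a <- te_fold_change(r$counts$footprint, r$counts$mrna_fragment, r$design)
  lens <- setNames(seq(300, 300 + 10 * 60, length.out = 11),
                   rownames(r$counts$footprint))
  b <- te_fold_change(r$counts$footprint, r$counts$mrna_fragment, r$design,
                      effective_lengths = lens)
  expect_equal(a$te_fold, b$te_fold, tolerance = 1e-12)

  # per-sample integer rescaling of raw counts is absorbed by size factors
  fp <- r$counts$footprint; rna <- r$counts$mrna_fragment
  fp2 <- sweep(fp, 2, c(2L, 3L, 1L, 4L), "*")
  rna2 <- sweep(rna, 2, c(3L, 1L, 2L, 2L), "*")
  c1 <- te_fold_change(fp, rna, r$design)
  c2 <- te_fold_change(fp2, rna2, r$design)
  expect_equal(c1$te_fold, c2$te_fold, tolerance = 1e-9)
})

test_that("zero Single-condition counts are flagged, not dropped", {
  genes <- paste0("g", 1:3)
  design <- data.frame(sample = c("single_r1", "multi_r1"),
                       condition = c("single", "multi"), replicate = 1L)
  fp <- matrix(c(0, 200, 300, 50, 200, 300), ncol = 2,
               dimnames = list(genes, design$sample))
  rna <- matrix(c(100, 200, 300, 100, 200, 300), ncol = 2,
                dimnames = list(genes, design$sample))
  out <- te_fold_change(fp, rna, design)
  expect_true(out$flagged[1])
  expect_true(is.na(out$te_fold[1]))
  expect_equal(nrow(out), 3)
  expect_false(any(out$flagged[-1]))
})

test_that("null data shows no spurious TE signal", {
  r <- gen_ribo(n_genes = 60, target_mrna_fold = 1, target_te_fold = 1,
                n_replicates = 2, dispersion = 0.01, seed = 13)
  out <- te_fold_change(r$counts$footprint, r$counts$mrna_fragment, r$design)
  # dispersion 0.01 at mean 500 gives per-count CV ~ sqrt(1/500 + 0.01);
  # a TE fold averages 4 such counts over 2 replicate pairs
  cv <- sqrt(1 / 500 + 0.01)
  bound <- 2 * cv * sqrt(4 / 2) / log(2)
  expect_lte(median(abs(log2(out$te_fold))), bound)
})
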