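gr <- function(chrom, start, end) { # 0-based half-open shorthand
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1L,
                                                 end = end))
}

test_that("cluster partitioning follows the minimum-overlap rule exactly", {
  a <- gr("chr1", 100, 200)
  empty <- GenomicRanges::GRanges()
  p <- cluster_peaks(a, empty, min_overlap_bp = 50)
  expect_length(p$clusterI, 1L)
  expect_length(p$clusterII_A, 0L)
  expect_length(p$clusterIII, 0L)

  b50 <- gr("chr1", 150, 250) # overlap exactly 50
  p2 <- cluster_peaks(a, b50, min_overlap_bp = 50)
  expect_length(p2$clusterII_A, 1L)
  expect_length(p2$clusterI, 0L)

  b49 <- gr("chr1", 151, 250) # overlap 49 < 50
  p3 <- cluster_peaks(a, b49, min_overlap_bp = 50)
  expect_length(p3$clusterI, 1L)
  expect_length(p3$clusterIII, 1L)
  expect_error(cluster_peaks(a, b49, min_overlap_bp = 0), "min_overlap")
})

test_that("partition completeness holds over random interval sets", {
  withr::with_seed(1001, {
    genome <- c(chr1 = 1e5, chr2 = 5e4)
    for (i in 1:50) {
      A <- frame_to_granges(random_peak_frame(sample.int(40, 1), genome))
      B <- frame_to_granges(random_peak_frame(sample.int(40, 1), genome))
      p <- cluster_peaks(A, B, min_overlap_bp = 50)
      expect_equal(length(p$clusterI) + length(p$clusterII_A), length(A))
      expect_equal(length(p$clusterIII) + length(p$clusterII_B), length(B))
    }
  })
})

test_that("cluster_peaks matches the brute-force all-pairs scanner", {
  withr::with_seed(2002, {
    genome <- c(chr1 = 2e5, chr2 = 1e5)
    for (i in 1:25) {
      fa <- random_peak_frame(sample.int(60, 1), genome)
      fb <- random_peak_frame(sample.int(60, 1), genome)
      min_bp <- sample(c(1, 25, 50, 100), 1)
      p <- cluster_peaks(frame_to_granges(fa), frame_to_granges(fb),
                         min_overlap_bp = min_bp)
      expect_equal(length(p$clusterII_A), sum(bf_shared(fa, fb, min_bp)))
      expect_equal(length(p$clusterII_B), sum(bf_shared(fb, fa, min_bp)))
    }
  })
})

test_that("overlap_fraction reports the percentage of A peaks shared", {
  a <- c(gr("chr1", 0, 100), gr("chr1", 200, 300), gr("chr1", 400, 500),
         gr("chr1", 600, 700))
  b <- c(gr("chr1", 0, 100), gr("chr1", 250, 260), gr("chr1", 450, 500))
  expect_equal(overlap_fraction(a, b), 75)
  expect_equal(overlap_fraction(a, a), 100)
  expect_equal(suppressWarnings(overlap_fraction(a, gr("chr2", 0, 100))), 0)
  expect_error(overlap_fraction(GenomicRanges::GRanges(), a), "empty")
})

test_that("width statistics summarize peak widths", {
  s <- width_stats(gr("chr1", 100, 200))
  expect_equal(s$count, 1L)
  expect_equal(s$total_bp, 100)
  expect_equal(unname(s$fivenum["median"]), 100)
  s3 <- width_stats(c(gr("chr1", 0, 10), gr("chr1", 20, 40),
                      gr("chr1", 100, 130)))
  expect_equal(unname(s3$fivenum["median"]), 20)
  expect_equal(width_stats(GenomicRanges::GRanges())$count, 0L)
})

test_that("TSS distances are signed and strand-aware", {
  genes_plus <- genes_frame_to_granges(data.frame(
    gene_id = "g1", chrom = "chr1", strand = "+", tss = 10000, tes = 20000))
  genes_minus <- genes_frame_to_granges(data.frame(
    gene_id = "g2", chrom = "chr1", strand = "-", tss = 11000, tes = 1000))
  on_tss <- gr("chr1", 9950, 10050) # center 10000
  expect_equal(tss_distance_distribution(on_tss, genes_plus)$distance, 0)
  downstream <- gr("chr1", 10950, 11050) # center 11000
  expect_equal(tss_distance_distribution(downstream, genes_plus)$distance,
               1000)
  # same position relative to a minus-strand TSS at 11000 -> upstream is +
  at_10k <- gr("chr1", 9950, 10050)
  expect_equal(tss_distance_distribution(at_10k, genes_minus)$distance,
               1000) # 1 kb downstream in transcription direction
  at_12k <- gr("chr1", 11950, 12050)
  expect_equal(tss_distance_distribution(at_12k, genes_minus)$distance,
               -1000)
})

test_that("gene association uses the TSS-TES +/- flank window", {
  genes <- genes_frame_to_granges(data.frame(
    gene_id = "g1", chrom = "chr1", strand = "+", tss = 10000, tes = 20000))
  inside_window <- gr("chr1", 7600, 7700)   # window starts at 7500
  outside <- gr("chr1", 7400, 7499)
  in_body <- gr("chr1", 15000, 15100)
  a1 <- assign_peaks_to_genes(inside_window, genes, flank_bp = 2500)
  expect_equal(a1$associated_genes, "g1")
  a2 <- assign_peaks_to_genes(outside, genes, flank_bp = 2500)
  expect_length(a2$associated_genes, 0L)
  a3 <- assign_peaks_to_genes(in_body, genes, flank_bp = 2500)
  expect_equal(a3$associated_genes, "g1")
  expect_equal(a3$peak_annotation$feature, "gene_body")
})

test_that("gene association matches the brute-force scanner on random sets", {
  withr::with_seed(3003, {
    genome <- c(chr1 = 2e5, chr2 = 1e5)
    for (i in 1:25) {
      peaks_f <- random_peak_frame(sample.int(50, 1), genome)
      genes_f <- random_peak_frame(sample.int(30, 1), genome,
                                   min_w = 1000, max_w = 10000)
      genes_f$gene_id <- sprintf("g%03d", seq_len(nrow(genes_f)))
      genes_f$strand <- sample(c("+", "-"), nrow(genes_f), replace = TRUE)
      genes_f$tss <- ifelse(genes_f$strand == "+", genes_f$start, genes_f$end)
      genes_f$tes <- ifelse(genes_f$strand == "+", genes_f$end, genes_f$start)
      genes <- genes_frame_to_granges(genes_f)
      res <- assign_peaks_to_genes(frame_to_granges(peaks_f), genes,
                                   flank_bp = 2500)
      want <- sort(genes_f$gene_id[bf_gene_associated(genes_f, peaks_f, 2500)])
      expect_equal(sort(res$associated_genes), want)
    }
  })
})

test_that("nearest-gene ties break by distance then lexicographic id", {
  genes <- genes_frame_to_granges(data.frame(
    gene_id = c("gB", "gA"), chrom = "chr1", strand = "+",
    tss = c(9000, 11000), tes = c(9500, 11500)))
  peak <- gr("chr1", 9950, 10050) # center 10000: equidistant to both TSS
  res <- assign_peaks_to_genes(peak, genes)
  expect_equal(res$peak_annotation$nearest_gene, "gA")
})

test_that("strong-gene classification applies the pseudocounted fold threshold", {
  sig <- data.frame(gene_id = c("up", "notquite", "flat", "dead"),
                    mean_A = c(1, 1, 1, 0), mean_B = c(2, 1.9, 1, 0))
  expect_equal(classify_strong_genes(sig, 2, pseudocount = 0),
               "up")
  # the pseudocount shrinks ratios toward 1: exactly-2-fold genes with a
  # nonzero baseline drop out, and all-zero genes never qualify
  expect_equal(classify_strong_genes(sig, 2, pseudocount = 0.01),
               character(0))
  rescued <- data.frame(gene_id = "newdom", mean_A = 0, mean_B = 1)
  expect_equal(classify_strong_genes(rescued, 2, pseudocount = 0.01),
               "newdom")
  # raising the threshold never enlarges the set
  for (thr in c(1, 1.5, 2, 3, 10)) {
    lo <- classify_strong_genes(sig, thr, pseudocount = 0.01)
    hi <- classify_strong_genes(sig, thr + 0.5, pseudocount = 0.01)
    expect_true(all(hi %in% lo))
  }
  sig$mean_B[2] <- NA
  expect_warning(out <- classify_strong_genes(sig, 2, pseudocount = 0),
                 "missing")
  expect_equal(out, "up")
})

test_that("venn partitions count exclusive regions exactly", {
  v <- gene_set_venn(list(X = c("a", "b", "c"), Y = c("b", "c", "d")))
  expect_equal(unname(v[c("X_only", "Y_only", "X_and_Y")]), c(1L, 1L, 2L))
  same <- gene_set_venn(list(X = letters[1:5], Y = letters[1:5]))
  expect_equal(unname(same["X_and_Y"]), 5L)
  expect_equal(unname(same["X_only"]), 0L)
  disj <- gene_set_venn(list(X = c("a"), Y = c("b")))
  expect_equal(unname(disj["X_and_Y"]), 0L)
  v3 <- gene_set_venn(list(X = c("a", "b"), Y = c("b", "c"), Z = c("b", "d")))
  expect_equal(unname(v3["X_and_Y_and_Z"]), 1L)
  expect_error(gene_set_venn(list(c("a"))), "named list")
})

test_that("two-group tests give Welch or paired t results", {
  x <- c(1, 2, 3, 4, 5)
  same <- two_group_test(x, x, paired = TRUE)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  withr::with_seed(55, {
    a <- stats::rnorm(200)
    b <- stats::rnorm(200, mean = 2)
    shift <- two_group_test(a, b)
    expect_lt(shift$p_value, 1e-10)
    # on equal-variance data Welch agrees with Student within tolerance
    student <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(shift$statistic, unname(student$statistic), tolerance = 1e-3)
    expect_equal(shift$p_value, student$p.value, tolerance = 1e-6)
  })
  expect_error(two_group_test(1, c(1, 2)), "at least 2")
  expect_error(two_group_test(c(1, 2, 3), c(1, 2), paired = TRUE), "equal-length")
})

test_that("simulated domain gains are recovered as cluster III peaks and strong genes", {
  truth <- toy_chiprx_truth(seed = 61, k_new = 3)
  res <- run_chiprx_arm(truth = truth, noise = "none",
                        out_dir = withr::local_tempdir())
  expect_length(res$partition$clusterIII, 3L)
  expect_length(res$partition$clusterI, 0L)
  new_genes <- res$gene_table$gene_id[grepl("domgene", res$gene_table$gene_id)]
  truth_new <- setdiff(
    sprintf("domgene_%s_%d", truth$domains$B$chrom,
            as.integer(truth$domains$B$start)),
    sprintf("domgene_%s_%d", truth$domains$A$chrom,
            as.integer(truth$domains$A$start)))
  expect_setequal(res$strong_genes, truth_new)
})
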