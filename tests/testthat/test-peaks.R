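test_that("aggregate_profile geometry and constant/impulse behavior", {
  refs <- data.frame(chrom = "chr1", start = c(20000, 60000),
                     end = c(20200, 60200))
  const <- data.frame(chrom = "chr1", start = 0, end = 1e5, value = 3)
  pm <- aggregate_profile(const, refs, flank = 5000, step = 50)
  expect_equal(dim(pm$matrix), c(2L, 200L))
  expect_true(all(abs(pm$matrix - 3) < 1e-9))

  # unit impulses at the midpoints peak at the center columns
  mids <- floor((refs$start + refs$end) / 2)
  imp <- data.frame(chrom = "chr1", start = mids - 25, end = mids + 25,
                    value = 10)
  pm2 <- aggregate_profile(imp, refs, flank = 5000, step = 50)
  expect_equal(which.max(pm2$curve) %in% c(100L, 101L), TRUE)
  expect_true(all(pm2$curve[c(1, 200)] == 0))

  # windows hanging off the chromosome start read zero and are flagged
  edge <- data.frame(chrom = "chr1", start = 100, end = 300)
  pm3 <- aggregate_profile(const, edge, flank = 5000, step = 50,
                           layout = genome_layout(c(chr1 = 1e5)))
  expect_true(pm3$clipped[1])
  expect_equal(pm3$matrix[1, 1], 0)
})

test_that("colocalization heatmaps share the first track's row order", {
  set.seed(9)
  refs <- random_intervals(50, chroms = "chr1", max_pos = 80000)
  t1 <- data.frame(chrom = "chr1", start = seq(0, 79000, 1000),
                   end = seq(500, 79500, 1000),
                   value = runif(80, 0, 5))
  out <- colocalization_heatmap(list(a = t1, b = t1), refs, flank = 2000,
                                step = 50)
  expect_identical(out$a$order, out$b$order)
  expect_equal(out$a$matrix, out$b$matrix)

  # independent impulse tracks: row sums essentially uncorrelated
  t2 <- t1
  t2$value <- sample(t2$value)
  out2 <- colocalization_heatmap(list(a = t1, b = t2), refs, flank = 2000,
                                 step = 50)
  expect_identical(out2$a$order, out2$b$order)
})

test_that("peak_overlap_test matches enumeration and handles edge cases", {
  # N = 10 bins, K = 5, n = 4, k = 4 -> 5/210
  layout <- genome_layout(c(chr1 = 10000), bin_size = 1000)
  a <- data.frame(chrom = "chr1", start = (0:4) * 1000 + 10,
                  end = (0:4) * 1000 + 50)
  b <- data.frame(chrom = "chr1", start = (0:3) * 1000 + 100,
                  end = (0:3) * 1000 + 150)
  res <- peak_overlap_test(a, b, layout, universe_bin = 1000)
  expect_equal(res$N, 10)
  expect_equal(res$K, 5)
  expect_equal(res$n, 4)
  expect_equal(res$k, 4)
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)
  expect_equal(res$p, enum_hyper_upper(10, 5, 4, 4), tolerance = 1e-12)
  expect_equal(unname(res$venn$peaks["a_overlapping_b"]), 0L)

  # k = 0 with empty margins -> p = 1
  empty <- a[0, ]
  res0 <- peak_overlap_test(empty, b, layout)
  expect_equal(res0$p, 1)
  # a == b: maximal overlap for the margins
  res1 <- peak_overlap_test(a, a, layout)
  expect_equal(res1$k, res1$K)
  expect_error(peak_overlap_test(a, b, genome_layout(c(chr1 = 1))[-1] |>
                                   (\(x) structure(c(x, list(chroms =
                                     data.frame(name = "chr1", length = 0))),
                                     class = "genome_layout"))()),
               "zero-length")
})

test_that("a peak spanning a bin boundary hits both bins", {
  layout <- genome_layout(c(chr1 = 3000), bin_size = 1000)
  pk <- data.frame(chrom = "chr1", start = 900, end = 1100)
  res <- peak_overlap_test(pk, pk, layout)
  expect_equal(res$K, 2)
})

test_that("pwm_scan reports consensus hits on both strands and matches the brute-force oracle", {
  cols <- list(A = c(0.91, 0.03, 0.03, 0.03), C = c(0.03, 0.91, 0.03, 0.03),
               G = c(0.03, 0.03, 0.91, 0.03))
  pw <- pwm("toy", do.call(cbind, cols[c("A", "A", "A", "C", "G")]),
            threshold_frac = 0.9)
  cons <- pwm_consensus(pw)
  expect_equal(cons, "AAACG")
  seqs <- c(chrZ = paste0("CCCCC", cons, "CCCCC"))
  hits <- pwm_scan(seqs, pw)
  expect_equal(hits$start, 5)
  expect_equal(hits$strand, "+")

  # reverse complement of the consensus is found on the minus strand
  hits2 <- pwm_scan(c(chrZ = paste0("CCCCC", "CGTTT", "CCCCC")), pw)
  expect_equal(hits2$strand, "-")
  expect_equal(hits2$start, 5)

  # windows containing N are skipped
  hitsN <- pwm_scan(c(chrZ = "CCNCCAAACN"), pw)
  expect_equal(nrow(hitsN), 0L)

  # random sequence: exact agreement with the naive rescoring oracle
  set.seed(19)
  rnd <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
               collapse = "")
  pw2 <- pwm("toy2", pw$mat, threshold_frac = 0.75)
  got <- pwm_scan(c(chr1 = rnd), pw2)
  want <- brute_pwm_scan(rnd, pw2)
  expect_equal(got$start, want$start)
  expect_equal(got$strand, want$strand)
  expect_equal(got$score, want$score, tolerance = 1e-12)
})

test_that("motif_enrichment ranks a planted motif first and handles degenerate classes", {
  set.seed(4)
  bg <- data.frame(chrom = "chr1", start = (0:49) * 1000,
                   end = (0:49) * 1000 + 500)
  cls <- bg[1:10, ]
  occ_planted <- data.frame(chrom = "chr1",
                            start = c(cls$start + 10, bg$start[45:49] + 10))
  occ_planted$end <- occ_planted$start + 8
  occ_rare <- data.frame(chrom = "chr1", start = bg$start[30:34] + 10)
  occ_rare$end <- occ_rare$start + 8
  res <- motif_enrichment(list(planted = cls),
                          list(m_planted = occ_planted, m_other = occ_rare),
                          bg)
  res_p <- res[order(res$p), ]
  expect_equal(res_p$motif[1], "m_planted")
  expect_lt(res_p$p[1], 0.01)
  # class == background -> p = 1 for every motif
  res2 <- motif_enrichment(list(all = bg),
                           list(m = occ_planted), bg)
  expect_equal(res2$p, 1)
  # zero-occurrence motif -> k = 0, p = 1
  res3 <- motif_enrichment(list(planted = cls),
                           list(none = occ_planted[0, ]), bg)
  expect_equal(res3$k, 0)
  expect_equal(res3$p, 1)
  expect_error(motif_enrichment(list(x = data.frame(chrom = "chr9",
                                                    start = 1, end = 2)),
                                list(m = occ_planted), bg), "subset")
})

ep_fixture <- function(seed, n = 120, elevate = NULL, fold = 3) {
  # one-chromosome matrix plus peak classes mapped to distinct bins
  set.seed(seed)
  layout <- genome_layout(c(chr1 = n * 5000), bin_size = 5000)
  D <- abs(outer(1:n, 1:n, "-"))
  lam <- (1 + D)^-1
  bins_p <- seq(5, 40, by = 5)
  bins_e <- seq(52, 100, by = 4)
  if (!is.null(elevate)) {
    for (bp in bins_p) for (be in bins_e)
      if (abs(bp - be) >= 4 && abs(bp - be) <= 80)
        lam[bp, be] <- lam[be, bp] <- lam[bp, be] * fold
  }
  ut <- upper.tri(lam, diag = TRUE)
  cnt <- matrix(0, n, n)
  cnt[ut] <- rmultinom(1, 3e5, lam[ut] / sum(lam[ut]))
  cnt <- cnt + t(cnt); diag(cnt) <- diag(cnt) / 2
  m <- ice_normalize(contact_matrix(cnt, "chr1", 5000))
  mk <- function(bins) data.frame(chrom = "chr1", start = (bins - 1) * 5000 + 100,
                                  end = (bins - 1) * 5000 + 300)
  others <- setdiff(seq(3, n - 2), c(bins_p, bins_e))[1:40]
  univ <- rbind(mk(bins_p), mk(bins_e), mk(others))
  list(mats = list(chr1 = m), prom = mk(bins_p), enh = mk(bins_e),
       univ = univ, layout = layout)
}

test_that("ep_interaction_test detects planted promoter-enhancer elevation", {
  fx <- ep_fixture(1, elevate = TRUE, fold = 3)
  res <- ep_interaction_test(fx$mats, fx$prom, fx$enh, fx$univ, fx$layout,
                             n_perm = 199, max_dist_bins = 80, seed = 7)
  expect_lte(res$p, 0.05)
  expect_equal(res$n_perm, 199)
  expect_true(all(c("PP", "PE", "EE") %in% res$class_pairs$pair))
})

test_that("ep_interaction_test is reproducible under a fixed seed and validates inputs", {
  fx <- ep_fixture(2)
  r1 <- ep_interaction_test(fx$mats, fx$prom, fx$enh, fx$univ, fx$layout,
                            n_perm = 99, max_dist_bins = 80, seed = 5)
  r2 <- ep_interaction_test(fx$mats, fx$prom, fx$enh, fx$univ, fx$layout,
                            n_perm = 99, max_dist_bins = 80, seed = 5)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$null_mean, r2$null_mean)
  expect_error(ep_interaction_test(fx$mats, fx$prom, fx$enh, fx$univ,
                                   fx$layout, n_perm = 0, seed = 1),
               "n_perm")
  stranger <- data.frame(chrom = "chr1", start = 1, end = 5)
  expect_error(ep_interaction_test(fx$mats, stranger, fx$enh, fx$univ,
                                   fx$layout, n_perm = 9, seed = 1),
               "subsets")
  expect_error(ep_interaction_test(fx$mats, fx$prom, fx$enh, fx$univ,
                                   fx$layout, n_perm = 9,
                                   min_dist_bins = 110, max_dist_bins = 119,
                                   seed = 1),
               "no testable pairs")
})
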