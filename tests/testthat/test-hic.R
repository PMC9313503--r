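make_pair <- function(chrom1, pos1, strand1, chrom2, pos2, strand2,
                      id = "r1") {
  data.frame(read_id = id, chrom1 = chrom1, pos1 = pos1, chrom2 = chrom2,
             pos2 = pos2, strand1 = strand1, strand2 = strand2)
}

test_that("filter_pairs applies the strand-aware 500 bp cut-site rule", {
  layout <- genome_layout(c(chr1 = 10000),
                          cut_sites = list(chr1 = c(1300, 1700, 5000)),
                          bin_size = 5000)
  ok_end <- list(chrom2 = "chr1", pos2 = 4800, strand2 = "+")  # site 5000, 200 bp
  # + read at 1000 with next site at 1300 -> kept
  p1 <- make_pair("chr1", 1000, "+", ok_end$chrom2, ok_end$pos2, "+")
  expect_equal(filter_pairs(p1, layout)$report$kept, 1L)
  # + read at 1000 with next site at 1700 only -> 700 bp, removed
  layout2 <- genome_layout(c(chr1 = 10000),
                           cut_sites = list(chr1 = c(1700, 5000)))
  expect_equal(filter_pairs(p1, layout2)$report$site_filtered, 1L)
  # - read looks upstream: pos 1500 with site 1300 -> 200 bp, kept
  p2 <- make_pair("chr1", 1500, "-", "chr1", 4800, "+")
  expect_equal(filter_pairs(p2, layout2)$report$kept, 0L)  # 1300 absent here
  expect_equal(filter_pairs(p2, layout)$report$kept, 1L)
  # read exactly on a site: distance 0
  p3 <- make_pair("chr1", 1700, "+", "chr1", 4800, "+")
  expect_equal(filter_pairs(p3, layout2)$report$kept, 1L)
})

test_that("filter_pairs collapses duplicates and conserves counts", {
  layout <- genome_layout(c(chr1 = 10000),
                          cut_sites = list(chr1 = c(1000, 5000)))
  base <- make_pair("chr1", 900, "+", "chr1", 4900, "+")
  dup <- rbind(base, base, make_pair("chr1", 4900, "+", "chr1", 900, "+", "r2"),
               make_pair("chrUn", 1, "+", "chr1", 4900, "+", "r3"),
               make_pair("chr1", 3000, "+", "chr1", 4900, "+", "r4"))
  out <- filter_pairs(dup, layout)
  r <- out$report
  # swapped-order record is the same pair after genome-order normalization
  expect_equal(r$duplicate, 2L)
  expect_equal(r$unknown_chrom, 1L)
  expect_equal(r$site_filtered, 1L)
  expect_equal(r$kept, 1L)
  expect_equal(r$unknown_chrom + r$duplicate + r$site_filtered + r$kept,
               r$input)
})

test_that("bin_pairs conserves mass and fills the diagonal once", {
  layout <- genome_layout(c(chr1 = 15000), bin_size = 5000)
  pairs <- data.frame(read_id = c("a", "b", "c"),
                      chrom1 = "chr1", pos1 = c(2000, 1000, 12000),
                      chrom2 = "chr1", pos2 = c(7000, 2000, 14000),
                      strand1 = "+", strand2 = "+")
  out <- bin_pairs(pairs, layout)
  m <- out$matrices$chr1$counts
  expect_equal(m[1, 2], 1)
  expect_equal(m[2, 1], 1)
  expect_equal(m[1, 1], 1)
  expect_equal(m[3, 3], 1)
  expect_equal(sum(m[upper.tri(m, diag = TRUE)]), out$n_cis)
  expect_true(isSymmetric(m))
})

test_that("trans pairs are counted but not matrixed", {
  layout <- tiny_layout()
  pairs <- data.frame(read_id = "t", chrom1 = "chr1", pos1 = 100,
                      chrom2 = "chr2", pos2 = 100, strand1 = "+",
                      strand2 = "+")
  out <- bin_pairs(pairs, layout)
  expect_equal(out$n_trans, 1L)
  expect_equal(out$n_cis, 0L)
  expect_equal(sum(out$matrices$chr1$counts), 0)
})

test_that("ice_normalize: fixed point, 2x2 closed form, factorization", {
  # equal-marginal matrix is a fixed point up to global scale
  m0 <- contact_matrix(matrix(c(2, 1, 1, 2), 2), "c", 10)
  n0 <- ice_normalize(m0)
  expect_equal(n0$counts / n0$counts[1, 1], m0$counts / m0$counts[1, 1],
               tolerance = 1e-6)
  expect_equal(n0$bias[1], n0$bias[2], tolerance = 1e-4)

  # 2x2 [[0,4],[4,0]]: marginals already equal; bias = sqrt(2), norm = 2
  m1 <- ice_normalize(contact_matrix(matrix(c(0, 4, 4, 0), 2), "c", 10))
  s <- rowSums(m1$counts)
  expect_equal(s[1], s[2], tolerance = 1e-4)
  b <- m1$bias
  expect_equal(b[1] * b[2] * m1$counts[1, 2], 4, tolerance = 1e-6)

  expect_error(ice_normalize(contact_matrix(matrix(0, 3, 3), "c", 10)),
               "empty matrix")
})

test_that("ice_normalize contract holds on random matrices", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    raw <- matrix(rpois(n * n, 5), n)
    raw <- raw + t(raw)
    raw[, 1] <- raw[1, ] <- 0          # force a masked bin
    m <- contact_matrix(raw, "c", 10)
    nm <- ice_normalize(m)
    ok <- !is.na(nm$bias)
    # equal marginals on unmasked rows
    s <- rowSums(nm$counts)[ok]
    expect_lt(max(abs(s / mean(s) - 1)), 1e-4)
    # factorization identity raw = b_i b_j norm
    B <- outer(nm$bias[ok], nm$bias[ok])
    rel <- abs(raw[ok, ok] - B * nm$counts[ok, ok]) /
      pmax(raw[ok, ok], 1e-12)
    expect_lt(max(rel[raw[ok, ok] > 0]), 1e-6)
  }
})

test_that("expected_by_distance is exact on uniform input and tracks decay", {
  u <- contact_matrix(matrix(3, 30, 30), "c", 10)
  e <- expected_by_distance(u)
  expect_equal(length(e), 30L)
  expect_true(all(e == 3))

  set.seed(5)
  m <- decay_matrix(n = 150, n_pairs = 5e5)
  e <- expected_by_distance(m)
  d <- 1:60
  truth <- (1 + d)^-1
  est <- e[d + 1]
  ratio <- est / truth
  ratio <- ratio / mean(ratio)
  expect_lt(max(abs(ratio - 1)), 0.10)
})

test_that("compartment calling separates a two-block checkerboard", {
  set.seed(3)
  n <- 80
  lab <- rep(c("A", "B"), each = 40)
  D <- abs(outer(1:n, 1:n, "-"))
  lam <- (1 + D)^-1 * ifelse(outer(lab, lab, "=="), 2, 0.5)
  ut <- upper.tri(lam, diag = TRUE)
  cnt <- matrix(0, n, n)
  cnt[ut] <- rmultinom(1, 4e5, lam[ut] / sum(lam[ut]))
  cnt <- cnt + t(cnt); diag(cnt) <- diag(cnt) / 2
  m <- ice_normalize(contact_matrix(cnt, "c", 5000))
  track <- as.numeric(lab == "A")
  cp <- call_compartments(m, track)
  expect_gte(mean(cp$labels == lab), 0.95)
  # flipping the orientation track flips every assigned label
  cp2 <- call_compartments(m, -track)
  assigned <- cp$labels != "unassigned"
  expect_true(all(cp$labels[assigned] != cp2$labels[assigned]))
})

test_that("compartment degenerate and error cases", {
  u <- contact_matrix(matrix(1, 30, 30), "c", 10)
  u$normalized <- TRUE; u$bias <- rep(1, 30)
  cp <- call_compartments(u, rnorm(30))
  expect_true(all(cp$labels == "unassigned"))
  small <- contact_matrix(matrix(1, 5, 5), "c", 10)
  expect_error(call_compartments(small, 1:5), "too short")
})

test_that("insulation TADs find the junction of two blocks and stay quiet on uniform input", {
  m <- block_matrix(n = 40, split = 20)
  m$normalized <- TRUE; m$bias <- rep(1, 40)
  td <- call_tads(m, window_bins = 5, delta_bins = 3)
  expect_equal(length(td$boundaries), 1L)
  expect_lte(abs(td$boundaries - 20), 1)
  # domains tile, ordered, non-overlapping
  d <- td$domains
  expect_true(all(d$start < d$end))
  expect_true(all(utils::head(d$end, -1) == utils::tail(d$start, -1)))

  u <- contact_matrix(matrix(2, 40, 40), "c", 5000)
  u$normalized <- TRUE; u$bias <- rep(1, 40)
  expect_equal(length(call_tads(u, window_bins = 5)$boundaries), 0L)
  expect_error(call_tads(u, window_bins = 30), "window")
})

test_that("loop caller finds a strong planted pixel and nothing on pure decay", {
  set.seed(21)
  px <- cbind(c(30, 80), c(60, 120))
  m <- decay_matrix(n = 200, n_pairs = 3e5, loop_pixels = px, loop_fold = 10)
  nm <- ice_normalize(m)
  loops <- call_loops(nm, max_dist_bins = 100)
  expect_gte(nrow(loops), 2)
  for (r in 1:2)
    expect_true(any(abs(loops$bin1 - px[r, 1]) <= 1 &
                      abs(loops$bin2 - px[r, 2]) <= 1))
  # Poisson-tail oracle at the planted pixel: p below the reported q
  expect_true(all(loops$q <= 0.10))
  expect_true(all(loops$enrichment > 1))

  # null: pure decay emits no loops in most seeds
  calls <- vapply(1:10, function(s) {
    set.seed(100 + s)
    m0 <- decay_matrix(n = 150, n_pairs = 2e5)
    nrow(call_loops(ice_normalize(m0), max_dist_bins = 100))
  }, numeric(1))
  expect_gte(mean(calls == 0), 0.9)
})

test_that("adjacent significant pixels merge into one loop", {
  set.seed(33)
  # plant a 2-pixel blob
  px <- cbind(c(50, 50), c(90, 91))
  m <- decay_matrix(n = 150, n_pairs = 4e5, loop_pixels = px, loop_fold = 12)
  loops <- call_loops(ice_normalize(m), max_dist_bins = 100)
  near <- loops[abs(loops$bin1 - 50) <= 1 & abs(loops$bin2 - 90) <= 2, ]
  expect_equal(nrow(near), 1L)
})

test_that("loop caller recovers planted loops at the documented operating point", {
  # 20 planted loops at 5x, 5e5 cis pairs on one chromosome
  stats <- vapply(1:3, function(s) {
    set.seed(200 + s)
    n <- 400
    i <- sample(5:330, 20)
    j <- i + sample(6:60, 20, replace = TRUE)
    keep <- !duplicated(cbind(i, j)) & j <= n
    px <- cbind(i, j)[keep, , drop = FALSE]
    m <- decay_matrix(n = n, n_pairs = 5e5, loop_pixels = px, loop_fold = 5)
    loops <- call_loops(ice_normalize(m), max_dist_bins = 120,
                        donut_radius = 7)
    hit <- vapply(seq_len(nrow(px)), function(r)
      any(abs(loops$bin1 - px[r, 1]) <= 1 &
            abs(loops$bin2 - px[r, 2]) <= 1), logical(1))
    fp <- vapply(seq_len(nrow(loops)), function(r)
      !any(abs(px[, 1] - loops$bin1[r]) <= 1 &
             abs(px[, 2] - loops$bin2[r]) <= 1), logical(1))
    c(recall = mean(hit), precision = 1 - mean(fp))
  }, numeric(2))
  expect_gte(median(stats["recall", ]), 0.8)
  expect_gte(median(stats["precision", ]), 0.8)
})

test_that("classify_loops applies the gained/lost/static rules", {
  n <- 60
  mk <- function(extra = NULL, fold = 8) {
    set.seed(77)
    m <- decay_matrix(n = n, n_pairs = 1e5, loop_pixels = extra,
                      loop_fold = fold)
    ice_normalize(m)
  }
  shared <- data.frame(chrom = "chrS", bin1 = 10L, bin2 = 30L,
                       start1 = 45000, end1 = 50000, start2 = 145000,
                       end2 = 150000, observed = 50, expected = 5,
                       enrichment = 8, p = 1e-9, q = 1e-7,
                       class = "unclassified")
  only_post <- transform(shared, bin1 = 20L, bin2 = 45L)
  mats_pre <- list(chrS = mk())
  mats_post <- list(chrS = mk(extra = cbind(20, 45), fold = 8))
  cl <- classify_loops(shared, rbind(shared, only_post), mats_pre, mats_post)
  expect_equal(cl$post$class[1], "static")
  expect_equal(cl$pre$class[1], "static")
  expect_equal(cl$post$class[2], "gained")   # strong post-only pixel
  # identical lists -> all static
  cl2 <- classify_loops(shared, shared, mats_pre, mats_pre)
  expect_true(all(cl2$combined$class == "static"))
  # post-only loop with ratio ~1 -> unclassified
  cl3 <- classify_loops(shared[0, ], shared, mats_pre, mats_pre)
  expect_equal(cl3$post$class, "unclassified")
  # bin-size mismatch errors
  bad <- mk(); bad$bin_size <- 999
  expect_error(classify_loops(shared, shared, mats_pre, list(chrS = bad)),
               "bin-size mismatch")
})
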