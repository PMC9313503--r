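toy_expr <- function(seed = 1, n_genes = 500, n_true = 25, fold = 4,
                     cv = 0.2, reps = 3) {
  set.seed(seed)
  base <- rlnorm(n_genes, log(100), 1)
  trt <- base
  up <- paste0("g", seq_len(n_true))
  names(base) <- names(trt) <- paste0("g", seq_len(n_genes))
  if (n_true > 0) trt[up] <- trt[up] * fold
  sdlog <- sqrt(log(1 + cv^2))
  mat <- cbind(matrix(rep(base, reps) * rlnorm(n_genes * reps, 0, sdlog),
                      n_genes),
               matrix(rep(trt, reps) * rlnorm(n_genes * reps, 0, sdlog),
                      n_genes))
  rownames(mat) <- names(base)
  colnames(mat) <- c(paste0("ref", 1:reps), paste0("trt", 1:reps))
  list(x = expression_table(mat, rep(c("ref", "trt"), each = reps),
                            "ref", "trt"),
       up = up)
}

test_that("differential expression: null gene, antisymmetry, replicate guard", {
  fx <- toy_expr()
  x <- fx$x
  # a gene with identical values in both conditions is never called
  x$mat[10, ] <- 50
  de <- differential_expression(x)
  expect_equal(de$table$lfc[10], 0)
  expect_equal(de$table$call[10], "none")

  # swapping condition labels negates every fold change
  x2 <- x
  x2$reference <- "trt"; x2$treatment <- "ref"
  de2 <- differential_expression(x2)
  expect_equal(de2$table$lfc, -de$table$lfc, tolerance = 1e-12)

  bad <- expression_table(x$mat[, c(1, 4, 5, 6)],
                          c("ref", "trt", "trt", "trt"), "ref", "trt")
  expect_error(differential_expression(bad), "replicates")
  expect_error(expression_table(x$mat * -1, rep("a", 6), "a", "a"),
               "nonnegative")
})

test_that("differential expression recovers planted 4x genes with controlled FDR", {
  stats <- vapply(1:5, function(s) {
    fx <- toy_expr(seed = s, n_genes = 2000, n_true = 50)
    de <- differential_expression(fx$x)
    called <- c(de$up, de$down)
    c(recall = mean(fx$up %in% de$up),
      fdr = if (length(called)) mean(!called %in% fx$up) else 0)
  }, numeric(2))
  expect_gte(median(stats["recall", ]), 0.9)
  expect_lte(median(stats["fdr", ]), 0.1)
})

test_that("differential expression controls false calls under a global null", {
  false_calls <- vapply(1:20, function(s) {
    fx <- toy_expr(seed = 100 + s, n_genes = 400, n_true = 0)
    de <- differential_expression(fx$x)
    length(de$up) + length(de$down)
  }, numeric(1))
  # with no planted effects, essentially nothing should pass q < 0.05
  expect_lte(mean(false_calls > 0), 1.5 * 0.05 * 400 / 400 + 0.1)
  expect_lte(sum(false_calls), 20 * 400 * 0.05 * 1.5)
})

test_that("gene_set_enrichment matches enumeration and sorts by q", {
  universe <- paste0("g", 1:20)
  query <- paste0("g", 1:5)
  sets <- list(hit = paste0("g", c(1:4, 11, 12)),
               miss = paste0("g", 15:18),
               same = query)
  res <- gene_set_enrichment(query, sets, universe)
  expect_equal(res$set[1], "same")
  hit <- res[res$set == "hit", ]
  expect_equal(hit$p, enum_hyper_upper(20, 6, 5, 4), tolerance = 1e-12)
  expect_equal(res$p[res$set == "miss"], 1)
  expect_true(all(diff(res$q) >= 0))
  expect_error(gene_set_enrichment(query, sets, character(0)), "universe")
  expect_error(gene_set_enrichment("absent", sets, universe), "subset")
})

test_that("anchor_gene_enrichment counts TSS-in-anchor genes and is monotone in padding", {
  genes <- data.frame(chrom = "chr1",
                      start = seq(0, 95000, by = 5000) + 100,
                      end = seq(0, 95000, by = 5000) + 1100,
                      strand = "+",
                      name = paste0("g", 1:20))
  loops <- data.frame(chrom = "chr1", bin1 = 1L, bin2 = 5L,
                      start1 = 0, end1 = 5000, start2 = 20000, end2 = 25000,
                      class = "static")
  up <- c("g1", "g5", "g9")     # TSS at 100, 20100, 40100
  res <- anchor_gene_enrichment(up, loops, genes)
  expect_equal(unname(res$in_anchor), c(TRUE, TRUE, FALSE))
  expect_equal(res$fraction, 2 / 3)
  expect_equal(res$test$p,
               enum_hyper_upper(20, res$test$K, 3, 2), tolerance = 1e-12)
  # fraction is monotone non-decreasing in anchor_pad
  fr <- vapply(c(0, 5000, 15000, 40000), function(pad)
    anchor_gene_enrichment(up, loops, genes, anchor_pad = pad)$fraction,
    numeric(1))
  expect_true(all(diff(fr) >= 0))
  # no loops -> fraction 0 with warning; saturated anchors -> fraction 1, p = 1
  expect_warning(r0 <- anchor_gene_enrichment(up, loops[0, ], genes),
                 "no loops")
  expect_equal(r0$fraction, 0)
  expect_equal(r0$test$p, 1)
  sat <- transform(loops, start1 = 0, end1 = 100000)
  rs <- anchor_gene_enrichment(up, sat, genes)
  expect_equal(rs$fraction, 1)
  expect_equal(rs$test$p, 1)
  expect_error(anchor_gene_enrichment("nope", loops, genes), "present")
})

test_that("signature_score is a scale-invariant enrichment ratio with the expected contrast sign", {
  layout <- genome_layout(c(chr1 = 100000))
  sig <- data.frame(chrom = "chr1", start = c(10000, 30000),
                    end = c(12000, 32000))
  flat <- data.frame(chrom = "chr1", start = 0, end = 100000, value = 2)
  res <- signature_score(list(s1 = flat), sig, layout)
  expect_equal(unname(res$scores["s1"]), 1, tolerance = 1e-9)
  # doubling the signal leaves the ratio unchanged
  flat2 <- transform(flat, value = value * 2)
  res2 <- signature_score(list(s1 = flat2), sig, layout)
  expect_equal(res$scores, res2$scores, tolerance = 1e-12)

  # damped signature signal in treatment -> negative contrast in all seeds
  contrasts <- vapply(1:10, function(s) {
    set.seed(s)
    mk <- function(damp) {
      v <- runif(100, 0.5, 1.5)
      tr <- data.frame(chrom = "chr1", start = seq(0, 99000, 1000),
                       end = seq(1000, 100000, 1000), value = v)
      in_sig <- tr$start >= 10000 & tr$end <= 12000 |
        tr$start >= 30000 & tr$end <= 32000
      tr$value[in_sig] <- tr$value[in_sig] * damp
      tr
    }
    tracks <- list(pre1 = mk(2), pre2 = mk(2), post1 = mk(1), post2 = mk(1))
    cond <- c(pre1 = "pre", pre2 = "pre", post1 = "post", post2 = "post")
    signature_score(tracks, sig, layout, cond, "pre", "post")$contrast
  }, numeric(1))
  expect_true(all(contrasts < 0))
  expect_error(signature_score(list(z = flat[0, ]), sig, layout),
               "zero genome-wide")
})

test_that("build_tf_network filters, ranks and is order-invariant", {
  rel <- data.frame(tf = c("A", "A", "B", "C"),
                    target = c("g1", "g2", "g1", "g9"))
  net <- build_tf_network(rel, up_genes = c("g1", "g2"),
                          enriched_tfs = c("A", "B"))
  expect_equal(nrow(net$edges), 3L)
  expect_equal(net$top_tf, "A")
  expect_equal(net$out_degree$degree, c(2L, 1L))
  # every edge is present verbatim in the relation table
  expect_true(all(paste(net$edges$tf, net$edges$target) %in%
                    paste(rel$tf, rel$target)))
  # record order does not matter
  net2 <- build_tf_network(rel[c(4, 2, 3, 1), ], c("g1", "g2"), c("A", "B"))
  expect_identical(net, net2)
  empty <- build_tf_network(rel, c("g1"), character(0))
  expect_equal(nrow(empty$edges), 0L)
  expect_true(is.na(empty$top_tf))
})

test_that("ddct fold change follows 2^-ddCT", {
  expect_equal(ddct_fold_change(20, 15, 22, 17), 1)
  expect_equal(ddct_fold_change(19, 15, 22, 17), 2)
  expect_equal(ddct_fold_change(25, 15, 28, 15), 8)
  expect_equal(ddct_fold_change(c(25, 20), c(15, 15), 28, 15),
               c(2^3, 2^8))
  expect_error(ddct_fold_change(Inf, 1, 1, 1), "finite")
})
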