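#' Expression table with condition design
#'
#' @param mat nonnegative genes x samples matrix with unique rownames.
#' @param conditions character vector (one per sample) or named vector keyed
#'   by sample.
#' @param reference,treatment the two condition labels to contrast.
#' @return object of class `expression_table`.
#' @export
expression_table <- function(mat, conditions, reference, treatment) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (anyDuplicated(rownames(mat))) stop("gene names must be unique")
  if (any(mat < 0)) stop("expression values must be nonnegative")
  if (!is.null(names(conditions)))
    conditions <- conditions[colnames(mat)]
  stopifnot(length(conditions) == ncol(mat))
  structure(list(mat = mat, conditions = as.character(conditions),
                 reference = reference, treatment = treatment),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("expression_table:", nrow(x$mat), "genes x", ncol(x$mat), "samples (",
      x$reference, "vs", x$treatment, ")\n")
  invisible(x)
}

#' Differential expression between two conditions
#'
#' Per gene: log2 fold change of pseudocounted condition means (treatment
#' over reference) and a moderated two-group test on log2-transformed
#' values (limma's empirical-Bayes variance moderation with a mean-variance
#' trend, the standard remedy for per-gene variance estimates at 2-3
#' replicates), Benjamini-Hochberg corrected. Up = `q < alpha` and
#' `lfc >= lfc_thresh`; down mirrors with `<= -lfc_thresh`.
#'
#' @param x an [expression_table()].
#' @param lfc_thresh absolute log2-fold-change threshold (default 1).
#' @param alpha BH q-value threshold (default 0.05).
#' @param pseudocount added before log transform (default 1).
#' @return list of class `de_result`: `table` (per-gene lfc/p/q/call), `up`,
#'   `down` gene vectors.
#' @export
differential_expression <- function(x, lfc_thresh = 1.0, alpha = 0.05,
                                    pseudocount = 1.0) {
  ref <- x$conditions == x$reference
  trt <- x$conditions == x$treatment
  if (sum(ref) < 2 || sum(trt) < 2)
    stop("each condition needs >= 2 replicates")
  lmat <- log2(x$mat + pseudocount)
  design <- cbind(intercept = 1, trt = as.numeric(trt))
  fit <- limma::eBayes(limma::lmFit(lmat[, ref | trt, drop = FALSE],
                                    design[ref | trt, , drop = FALSE]),
                       trend = TRUE)
  p <- fit$p.value[, "trt"]
  lfc <- log2((rowMeans(x$mat[, trt, drop = FALSE]) + pseudocount) /
                (rowMeans(x$mat[, ref, drop = FALSE]) + pseudocount))
  q <- stats::p.adjust(p, method = "BH")
  call <- rep("none", nrow(x$mat))
  call[q < alpha & lfc >= lfc_thresh] <- "up"
  call[q < alpha & lfc <= -lfc_thresh] <- "down"
  tab <- data.frame(gene = rownames(x$mat), lfc = lfc, p = p, q = q,
                    call = call, row.names = NULL)
  structure(list(table = tab,
                 up = tab$gene[tab$call == "up"],
                 down = tab$gene[tab$call == "down"],
                 lfc_thresh = lfc_thresh, alpha = alpha),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat("de_result:", nrow(x$table), "genes;", length(x$up), "up,",
      length(x$down), "down (q <", x$alpha, ", |lfc| >=", x$lfc_thresh, ")\n")
  invisible(x)
}

#' Gene-set hypergeometric enrichment
#'
#' Upper-tail hypergeometric over-representation of a query gene list in
#' each named set (sets are intersected with the universe first), BH
#' corrected across sets and sorted by q then p.
#'
#' @param query character vector of genes (subset of `universe`).
#' @param sets named list of gene vectors (e.g. from [read_gmt()]).
#' @param universe character vector of all testable genes.
#' @return data.frame with per-set counts, p and q.
#' @export
gene_set_enrichment <- function(query, sets, universe) {
  if (length(universe) == 0) stop("empty universe")
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  query <- unique(query)
  universe <- unique(universe)
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(sn) {
    s <- intersect(sets[[sn]], universe)
    k <- length(intersect(query, s))
    data.frame(set = sn, N = N, K = length(s), n = n, k = k,
               p = hyper_upper(N, length(s), n, k))
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$q, out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Loop-anchor gene enrichment
#'
#' A gene is "in anchors" iff its TSS falls inside any loop anchor interval
#' (each widened by `anchor_pad` bp). Reports the fraction of the up-gene
#' list in anchors (the ">53% of upregulated genes sit in loop anchors"
#' statistic) plus an upper-tail hypergeometric test against the full gene
#' collection.
#'
#' @param up_genes character vector of gene names (subset of `genes$name`).
#' @param loops loop data.frame (see [call_loops()]).
#' @param genes gene data.frame with `name`, `chrom`, `start`, `end`, `strand`.
#' @param anchor_pad bp added to each anchor side (default 0: anchors are
#'   single bins).
#' @return list: `fraction`, `in_anchor` (per-up-gene flags), and `test`
#'   (an [enrichment_result()]).
#' @export
anchor_gene_enrichment <- function(up_genes, loops, genes, anchor_pad = 0) {
  if (!all(up_genes %in% genes$name))
    stop("up_genes must all be present in the gene collection")
  if (nrow(loops) == 0) {
    warning("no loops: anchor fraction is 0")
    return(list(fraction = 0, in_anchor = stats::setNames(
      rep(FALSE, length(up_genes)), up_genes),
      test = enrichment_result("hypergeometric", statistic = 0, p = 1,
                               N = nrow(genes), K = 0L,
                               n = length(up_genes), k = 0L)))
  }
  anchors <- loop_anchors(loops, pad = anchor_pad)
  tss <- gene_tss(genes)
  tss_iv <- data.frame(chrom = genes$chrom, start = tss, end = tss + 1)
  hit <- overlaps(tss_iv, anchors)
  gene_in <- seq_len(nrow(genes)) %in% hit$i
  in_anchor <- gene_in[match(up_genes, genes$name)]
  k <- sum(in_anchor); n <- length(up_genes)
  K <- sum(gene_in); N <- nrow(genes)
  frac <- if (n > 0) k / n else 0
  list(fraction = frac,
       in_anchor = stats::setNames(in_anchor, up_genes),
       test = enrichment_result("hypergeometric", statistic = frac,
                                p = hyper_upper(N, K, n, k),
                                N = N, K = K, n = n, k = k))
}

#' Accessibility signature score per sample
#'
#' Per sample, the score is the mean signal over the signature intervals
#' divided by the genome-wide mean signal (an enrichment ratio, invariant to
#' global scaling). The contrast is mean(treatment) - mean(reference);
#' a hyporesponsive treatment with damped activation-signature
#' accessibility yields a negative contrast.
#'
#' @param tracks named list of per-sample signal data.frames.
#' @param signature interval data.frame of signature regions (nonempty).
#' @param layout a [genome_layout()] (for chromosome lengths).
#' @param conditions named character vector mapping sample to condition.
#' @param reference,treatment condition labels for the contrast (optional).
#' @return list: `scores` (per sample), `contrast` (or `NA` without a design).
#' @export
signature_score <- function(tracks, signature, layout, conditions = NULL,
                            reference = NULL, treatment = NULL) {
  stopifnot(nrow(signature) > 0, !is.null(names(tracks)))
  glen <- sum(layout$chroms$length)
  scores <- vapply(tracks, function(tr) {
    tot <- 0; sig_sum <- 0; sig_len <- 0
    for (ch in unique(signature$chrom)) {
      I <- track_integral(tr[tr$chrom == ch, , drop = FALSE])
      s <- signature[signature$chrom == ch, , drop = FALSE]
      sig_sum <- sig_sum + sum(I(s$end) - I(s$start))
      sig_len <- sig_len + sum(s$end - s$start)
    }
    for (ch in unique(tr$chrom)) {
      I <- track_integral(tr[tr$chrom == ch, , drop = FALSE])
      tot <- tot + I(chrom_length(layout, ch))
    }
    if (tot == 0) stop("zero genome-wide signal")
    (sig_sum / sig_len) / (tot / glen)
  }, numeric(1))
  contrast <- NA_real_
  if (!is.null(conditions) && !is.null(reference) && !is.null(treatment)) {
    cond <- conditions[names(tracks)]
    contrast <- mean(scores[cond == treatment]) -
      mean(scores[cond == reference])
  }
  list(scores = scores, contrast = contrast)
}

#' Build a TF-target regulatory network
#'
#' Filters a TF-target relation table down to edges whose TF is in the
#' enriched-TF list and whose target is in the up-gene list, and ranks TFs
#' by out-degree (the construction behind "which TF most strongly regulates
#' the upregulated genes"). Output is invariant to input record order.
#'
#' @param relations data.frame with `tf`, `target` (see [read_tf_table()]).
#' @param up_genes character vector of target genes to keep.
#' @param enriched_tfs character vector of TFs to keep.
#' @return list: `edges` (data.frame `tf`, `target`), `out_degree` (sorted
#'   data.frame), `top_tf` (name or `NA`).
#' @export
build_tf_network <- function(relations, up_genes, enriched_tfs) {
  relations <- relations[!duplicated(relations[, c("tf", "target")]), ,
                         drop = FALSE]
  keep <- relations$tf %in% enriched_tfs & relations$target %in% up_genes
  edges <- relations[keep, c("tf", "target"), drop = FALSE]
  edges <- edges[order(edges$tf, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  if (nrow(edges) == 0)
    return(list(edges = edges,
                out_degree = data.frame(tf = character(), degree = integer()),
                top_tf = NA_character_))
  deg <- table(edges$tf)
  out_degree <- data.frame(tf = names(deg), degree = as.integer(deg))
  out_degree <- out_degree[order(-out_degree$degree, out_degree$tf), ,
                           drop = FALSE]
  rownames(out_degree) <- NULL
  list(edges = edges, out_degree = out_degree, top_tf = out_degree$tf[1])
}

#' Relative qPCR quantification (2^-ddCT)
#'
#' `fold = 2^-((ct_target_s - ct_ref_s) - (ct_target_c - ct_ref_c))`:
#' the target gene cycle number is normalized to a housekeeping gene in the
#' sample and in the calibrator.
#'
#' @param ct_target_s,ct_ref_s target and housekeeping CT in the sample.
#' @param ct_target_c,ct_ref_c target and housekeeping CT in the calibrator.
#' @return fold change (vectorized).
#' @export
ddct_fold_change <- function(ct_target_s, ct_ref_s, ct_target_c, ct_ref_c) {
  stopifnot(all(is.finite(c(ct_target_s, ct_ref_s, ct_target_c, ct_ref_c))))
  2^-((ct_target_s - ct_ref_s) - (ct_target_c - ct_ref_c))
}
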