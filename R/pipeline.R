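#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()]: the synthetic
#' experiment ([sim_config()] defaults), the Hi-C stage parameters, the peak
#' statistics parameters, and the integration-stage parameters. Any field
#' can be overridden before validation. A YAML file with the same structure
#' can be loaded with [read_pipeline_config()].
#'
#' @param seed master RNG seed; stage seeds derive from it.
#' @param outdir output directory (`NULL`: keep results in memory only).
#' @return nested configuration list.
#' @export
default_config <- function(seed, outdir = NULL) {
  list(
    seed = seed,
    outdir = outdir,
    conditions = c(reference = "preG", treatment = "postG"),
    stages = list(simulate = TRUE, hic = TRUE, peaks = TRUE,
                  integrate = TRUE),
    sim = unclass(sim_config(seed = seed)),
    hic = list(max_site_dist = 500, ice_tol = 1e-5, ice_max_iter = 200,
               loop_min_dist_bins = 4, loop_max_dist_bins = 120,
               loop_fdr = 0.10, donut_radius = 7, inner_radius = 2,
               tad_window_bins = 10, tad_delta_bins = 3,
               match_tol_bins = 1, fc_thresh = 1.5),
    peaks = list(promoter_window = 1000, universe_bin = 1000, top_k = 5000,
                 flank = 5000, step = 50),
    integrate = list(lfc_thresh = 1.0, alpha = 0.05, pseudocount = 1.0,
                     n_perm = 1000, ep_min_dist_bins = 4,
                     ep_max_dist_bins = 200, anchor_pad = 0,
                     motif_q_thresh = 0.05)
  )
}

#' Load a pipeline configuration from YAML
#' @param path YAML file mirroring [default_config()]'s structure; missing
#'   fields fall back to the defaults.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user$seed)) stop("config must set a seed")
  base <- default_config(seed = user$seed, outdir = user$outdir)
  modifyList(base, user)
}

#' Validate a pipeline configuration
#'
#' @param cfg configuration list (see [default_config()]).
#' @return character vector of violations, empty iff the config is runnable.
#' @export
validate_config <- function(cfg) {
  v <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  need(!is.null(cfg$seed) && is.finite(cfg$seed), "seed: must be a finite integer")
  need(!is.null(cfg$sim$bin_size) && cfg$sim$bin_size > 0, "sim.bin_size > 0")
  need(is.null(cfg$sim$n_pairs) || cfg$sim$n_pairs >= 0, "sim.n_pairs >= 0")
  fr <- c(cfg$sim$colocalization_fraction, cfg$sim$promoter_fraction,
          cfg$sim$ep_loop_fraction, cfg$sim$anchor_up_fraction,
          cfg$sim$filter_violation_rate)
  need(all(fr >= 0 & fr <= 1), "sim fractions must be in [0, 1]")
  need(cfg$hic$max_site_dist > 0, "hic.max_site_dist > 0")
  need(cfg$hic$loop_fdr > 0 && cfg$hic$loop_fdr < 1, "hic.loop_fdr in (0, 1)")
  if (isTRUE(cfg$stages$integrate)) {
    need(isTRUE(cfg$stages$hic), "integrate stage: missing dependency (hic stage off)")
    need(isTRUE(cfg$stages$peaks), "integrate stage: missing dependency (peaks stage off)")
    need(cfg$integrate$n_perm >= 1, "integrate.n_perm >= 1")
  }
  if (isTRUE(cfg$stages$hic))
    need(isTRUE(cfg$stages$simulate), "hic stage: missing dependency (simulate stage off)")
  if (isTRUE(cfg$stages$peaks))
    need(isTRUE(cfg$stages$hic), "peaks stage: missing dependency (hic stage off)")
  need(cfg$peaks$promoter_window > 0, "peaks.promoter_window > 0")
  need(cfg$peaks$universe_bin > 0, "peaks.universe_bin > 0")
  v
}

finish_report <- function(report, out, t0) {
  report$elapsed <- proc.time()[["elapsed"]] - t0
  rep <- structure(report, class = "pipeline_report")
  if (!is.null(out)) {
    clean <- unclass(rep)
    clean$elapsed <- NULL
    jsonlite::write_json(clean, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  rep
}

match_loops <- function(called, truth, tol = 1) {
  if (nrow(truth) == 0 || nrow(called) == 0)
    return(list(recall = NA_real_, precision = NA_real_, hits = 0L))
  truth_hit <- vapply(seq_len(nrow(truth)), function(r) {
    any(called$chrom == truth$chrom[r] &
          abs(called$bin1 - truth$bin1[r]) <= tol &
          abs(called$bin2 - truth$bin2[r]) <= tol)
  }, logical(1))
  called_hit <- vapply(seq_len(nrow(called)), function(r) {
    any(truth$chrom == called$chrom[r] &
          abs(truth$bin1 - called$bin1[r]) <= tol &
          abs(truth$bin2 - called$bin2[r]) <= tol)
  }, logical(1))
  list(recall = mean(truth_hit), precision = mean(called_hit),
       hits = sum(truth_hit))
}

peak_signal_track <- function(peaks, layout) {
  # rectangular score bumps over peak intervals -> bedGraph-style track
  pk <- peaks[order(match(peaks$chrom, layout$chroms$name), peaks$start), ]
  # merge overlapping peaks by keeping the max score (step track must not overlap)
  out <- list()
  for (ch in unique(pk$chrom)) {
    x <- pk[pk$chrom == ch, , drop = FALSE]
    ir <- as_iranges(x)
    cov <- IRanges::coverage(ir, weight = x$score)
    rl <- S4Vectors::runLength(cov); rv <- S4Vectors::runValue(cov)
    ends <- cumsum(rl)
    starts <- c(0, utils::head(ends, -1))
    keep <- rv != 0
    out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                            end = ends[keep], value = rv[keep])
  }
  do.call(rbind, out)
}

#' Run the full analysis pipeline on the synthetic experiment
#'
#' Stages execute in dependency order: simulate -> hic (filter, bin, ICE,
#' compartments, TADs, loops per condition, differential loops) -> peaks
#' (promoter/intergenic classification, overlap test, colocalization
#' profiles, motif scan + per-loop-class enrichment) -> integrate
#' (differential expression, loop-anchor gene enrichment, enhancer-promoter
#' permutation test, gene-set enrichment, TF network). Headline statistics,
#' per-stage parameters and truth-recovery summaries are returned in a
#' `pipeline_report`; when `cfg$outdir` is set every stage also writes its
#' standard-format files there. Reruns with the same config are bitwise
#' reproducible (the report's `elapsed` field aside).
#'
#' @param cfg configuration list from [default_config()] (validated first).
#' @return object of class `pipeline_report`.
#' @export
run_pipeline <- function(cfg) {
  t0 <- proc.time()[["elapsed"]]
  viol <- validate_config(cfg)
  if (length(viol))
    stop("invalid config:\n  ", paste(viol, collapse = "\n  "))
  out <- if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    cfg$outdir
  } else NULL
  report <- list(seed = cfg$seed, stages = list(), headline = list())

  ## --- simulate ------------------------------------------------------
  scfg <- do.call(sim_config, cfg$sim[names(cfg$sim) != "gene_length_range"])
  scfg$gene_length_range <- cfg$sim$gene_length_range
  sim <- simulate_experiment(scfg)
  if (!is.null(out)) write_sim(sim, file.path(out, "sim"))
  report$stages$simulate <- list(
    seed = scfg$seed, n_genes = nrow(sim$genes),
    n_peaks = c(tf_a = nrow(sim$tf_a), tf_b = nrow(sim$tf_b)),
    n_planted_loops = nrow(sim$loops_truth),
    n_pairs = c(pre = nrow(sim$pairs$pre), post = nrow(sim$pairs$post)))
  if (!isTRUE(cfg$stages$hic)) return(finish_report(report, out, t0))

  ## --- hic -----------------------------------------------------------
  layout <- sim$layout
  hcfg <- cfg$hic
  conds <- c("pre", "post")
  hic <- list()
  gene_density <- function(ch) {
    tabulate(local_bin(layout, gene_tss(sim$genes[sim$genes$chrom == ch, ])),
             nbins = n_bins(layout)[[ch]])
  }
  comp <- NULL
  for (cd in conds) {
    f <- filter_pairs(sim$pairs[[cd]], layout, hcfg$max_site_dist)
    b <- bin_pairs(f$pairs, layout)
    mats <- lapply(b$matrices, ice_normalize, tol = hcfg$ice_tol,
                   max_iter = hcfg$ice_max_iter)
    # compartments first: their (smoothed) labels stratify the expected
    # model the loop caller tests against
    cp <- lapply(names(mats), function(ch)
      call_compartments(mats[[ch]], gene_density(ch)))
    names(cp) <- names(mats)
    labels <- lapply(cp, function(x) smooth_labels(x$labels))
    loops <- call_loops_all(mats,
                            min_dist_bins = hcfg$loop_min_dist_bins,
                            max_dist_bins = hcfg$loop_max_dist_bins,
                            donut_radius = hcfg$donut_radius,
                            inner_radius = hcfg$inner_radius,
                            fdr = hcfg$loop_fdr,
                            groups = labels)
    hic[[cd]] <- list(filter = f$report, n_cis = b$n_cis,
                      n_trans = b$n_trans, mats = mats, loops = loops,
                      compartments = cp)
  }
  # report compartments for the treatment condition
  comp <- hic$post$compartments
  tads <- lapply(hic$post$mats, call_tads,
                 window_bins = hcfg$tad_window_bins,
                 delta_bins = hcfg$tad_delta_bins)
  cls <- classify_loops(hic$pre$loops, hic$post$loops,
                        hic$pre$mats, hic$post$mats,
                        match_tol_bins = hcfg$match_tol_bins,
                        fc_thresh = hcfg$fc_thresh)

  comp_truth <- sim$compartments
  comp_called <- unlist(lapply(names(comp), function(ch) comp[[ch]]$labels))
  comp_acc <- mean(comp_called == comp_truth$label)
  truth_post <- sim$loops_truth[sim$loops_truth$class %in%
                                  c("static", "gained"), ]
  lr <- match_loops(hic$post$loops, truth_post, tol = hcfg$match_tol_bins)
  report$stages$hic <- list(
    params = hcfg,
    filter = lapply(hic, function(x) x$filter),
    cis_pairs = vapply(hic, function(x) x$n_cis, numeric(1)),
    loops = c(pre = nrow(hic$pre$loops), post = nrow(hic$post$loops)),
    loop_classes = table(cls$combined$class),
    tad_boundaries = sum(vapply(tads, function(t) length(t$boundaries),
                                integer(1))),
    truth_recovery = list(loop_recall = lr$recall,
                          loop_precision = lr$precision,
                          compartment_accuracy = comp_acc))
  if (!is.null(out)) {
    dir.create(file.path(out, "hic"), showWarnings = FALSE)
    write_loops_bedpe(cls$combined, file.path(out, "hic", "loops_classified.bedpe"))
    for (ch in names(comp)) {
      bins <- make_bins(layout)
      bn <- bins[bins$chrom == ch, ]
      write_bedgraph(data.frame(chrom = ch, start = bn$start, end = bn$end,
                                value = ifelse(is.na(comp[[ch]]$values), 0,
                                               comp[[ch]]$values)),
                     file.path(out, "hic", paste0("compartments_", ch,
                                                  ".bedgraph")))
      write_bed(tads[[ch]]$domains, file.path(out, "hic",
                                              paste0("tads_", ch, ".bed")))
    }
  }

  report$headline <- list(
    loop_classes = as.list(table(cls$combined$class)),
    loop_recall = lr$recall, loop_precision = lr$precision,
    compartment_accuracy = comp_acc)
  if (!isTRUE(cfg$stages$peaks)) return(finish_report(report, out, t0))

  ## --- peaks ---------------------------------------------------------
  pcfg <- cfg$peaks
  tfb <- classify_peaks(sim$tf_b, sim$genes, window = pcfg$promoter_window)
  ov <- peak_overlap_test(sim$tf_a, sim$tf_b, layout,
                          universe_bin = pcfg$universe_bin)
  refs <- top_k_peaks(sim$tf_a, pcfg$top_k)
  tracks <- list(tf_a = peak_signal_track(sim$tf_a, layout),
                 tf_b = peak_signal_track(sim$tf_b, layout))
  coloc <- colocalization_heatmap(tracks, refs, flank = pcfg$flank,
                                  step = pcfg$step)
  occ <- lapply(sim$pwms, function(p) pwm_scan(sim$sequences, p))
  anchors <- loop_anchors(cls$combined)
  anchor_classes <- split(anchors[, c("chrom", "start", "end")],
                          anchors$class)
  anchor_classes <- anchor_classes[intersect(c("gained", "lost", "static"),
                                             names(anchor_classes))]
  me <- motif_enrichment(anchor_classes, occ,
                         anchors[, c("chrom", "start", "end")])
  top_motif <- function(cl) {
    x <- me[me$class == cl, ]
    if (!nrow(x)) return(NA_character_)
    x$motif[order(x$p, -x$k)][1]
  }
  report$stages$peaks <- list(
    params = pcfg,
    tfb_classes = table(tfb$class),
    overlap = list(p = ov$p, k = ov$k, K = ov$K, n = ov$n, N = ov$N),
    coloc_center_signal = vapply(coloc, function(x)
      x$curve[length(x$curve) / 2], numeric(1)),
    motif_top = c(gained = top_motif("gained"), static = top_motif("static")),
    motif_table = me)
  if (!is.null(out)) {
    dir.create(file.path(out, "peaks"), showWarnings = FALSE)
    write_bed(tfb, file.path(out, "peaks", "tf_b_classified.bed"))
    write.table(me, file.path(out, "peaks", "motif_enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  report$headline <- c(report$headline, list(
    peak_overlap_p = ov$p,
    motif_top_gained = top_motif("gained"),
    motif_top_static = top_motif("static")))
  if (!isTRUE(cfg$stages$integrate)) return(finish_report(report, out, t0))

  ## --- integrate -----------------------------------------------------
  icfg <- cfg$integrate
  de <- differential_expression(sim$expr, lfc_thresh = icfg$lfc_thresh,
                                alpha = icfg$alpha,
                                pseudocount = icfg$pseudocount)
  ag <- anchor_gene_enrichment(de$up, cls$combined, sim$genes,
                               anchor_pad = icfg$anchor_pad)
  prom <- tfb[tfb$class == "promoter", ]
  enh <- tfb[tfb$class == "intergenic", ]
  ep <- ep_interaction_test(hic$post$mats, prom, enh, tfb, layout,
                            n_perm = icfg$n_perm,
                            min_dist_bins = icfg$ep_min_dist_bins,
                            max_dist_bins = icfg$ep_max_dist_bins,
                            seed = cfg$seed + 10)
  sets <- list(planted_up = sim$expr_truth$gene[sim$expr_truth$direction == "up"],
               planted_down = sim$expr_truth$gene[sim$expr_truth$direction == "down"])
  gsea <- gene_set_enrichment(de$up, sets, sim$genes$name)
  enriched <- unique(me$motif[me$class == "gained" & me$q < icfg$motif_q_thresh])
  net <- build_tf_network(sim$relations, de$up, enriched)

  truth_up <- sim$expr_truth$gene[sim$expr_truth$direction == "up"]
  truth_dn <- sim$expr_truth$gene[sim$expr_truth$direction == "down"]
  de_recall <- mean(c(truth_up %in% de$up, truth_dn %in% de$down))
  de_fdr <- {
    called <- c(de$up, de$down)
    if (length(called)) mean(!called %in% sim$expr_truth$gene) else 0
  }
  report$stages$integrate <- list(
    params = icfg, seed_ep = cfg$seed + 10,
    de = c(up = length(de$up), down = length(de$down)),
    truth_recovery = list(de_recall = de_recall, de_empirical_fdr = de_fdr))
  report$headline <- c(report$headline, list(
    de_up = length(de$up), de_down = length(de$down),
    anchor_gene_fraction = ag$fraction, anchor_gene_p = ag$test$p,
    ep_interaction_p = ep$p, ep_statistic = ep$statistic,
    de_recall = de_recall, de_empirical_fdr = de_fdr,
    top_tf = net$top_tf,
    top_tf_degree = if (nrow(net$out_degree)) net$out_degree$degree[1] else 0,
    top_gsea_set = gsea$set[1]))
  if (!is.null(out)) {
    dir.create(file.path(out, "integrate"), showWarnings = FALSE)
    write.table(de$table, file.path(out, "integrate", "de_table.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(net$edges, file.path(out, "integrate", "network_edges.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(gsea, file.path(out, "integrate", "gene_set_enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  finish_report(report, out, t0)
}

#' @export
print.pipeline_report <- function(x, ...) {
  h <- x$headline
  cat("pipeline_report (seed ", x$seed, ")\n", sep = "")
  if (!is.null(h$de_up))
    cat(sprintf("  DE: %d up / %d down (recall %.2f, empirical FDR %.3f)\n",
                h$de_up, h$de_down, h$de_recall, h$de_empirical_fdr))
  if (!is.null(h$anchor_gene_fraction))
    cat(sprintf("  up-genes in loop anchors: %.1f%% (p = %.3g)\n",
                100 * h$anchor_gene_fraction, h$anchor_gene_p))
  if (!is.null(h$peak_overlap_p))
    cat(sprintf("  peak overlap p = %.3g\n", h$peak_overlap_p))
  if (!is.null(h$ep_interaction_p))
    cat(sprintf("  E-P interaction p = %.3g\n", h$ep_interaction_p))
  if (!is.null(h$loop_recall)) {
    cat(sprintf("  loops: recall %.2f, precision %.2f; compartments %.1f%%\n",
                h$loop_recall, h$loop_precision,
                100 * h$compartment_accuracy))
    cat("  loop classes:",
        paste(names(h$loop_classes), unlist(h$loop_classes),
              sep = "=", collapse = " "), "\n")
  }
  if (!is.null(h$motif_top_gained))
    cat(sprintf("  top motif gained=%s static=%s\n",
                h$motif_top_gained, h$motif_top_static))
  if (!is.null(h$top_tf))
    cat(sprintf("  top TF=%s (degree %d)\n", h$top_tf, h$top_tf_degree))
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed))
  invisible(x)
}
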