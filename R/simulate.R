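#' Configuration of the synthetic multiomics experiment
#'
#' Defaults describe the reference toy experiment: a 2 x 2 Mb genome at 5 kb
#' bins, GATC cut sites every ~400 bp, 2000 genes biased toward A
#' compartments, two TF peak sets (a CTCF-like and a STAT3-like factor) with
#' controlled colocalization and promoter placement, planted
#' gained/lost/static loops at 5-fold enrichment (gained loops connect
#' intergenic enhancer peaks to promoters), two conditions x 3 replicates of
#' expression with 4-fold planted effects, 53% of planted up-genes placed in
#' loop anchors, and 5e5 Hi-C read pairs per condition with a 1% planted
#' cut-site filter-violation spike.
#'
#' @param seed mandatory integer RNG seed.
#' @param n_chroms,chrom_length,bin_size genome geometry.
#' @param cut_site_spacing mean restriction-site spacing in bp.
#' @param n_genes,gene_length_range gene count and length range (bp).
#' @param gene_island_fraction fraction of a compartment block occupied by
#'   its gene island (genes cluster; the rest is gene desert).
#' @param gene_compartment_bias fraction of genes placed in A blocks.
#' @param n_compartment_blocks alternating A/B blocks per chromosome.
#' @param compartment_strength within-block contact multiplier (between-block
#'   contacts are divided by it... see details in the methods vignette).
#' @param n_up,n_down,effect_size,n_replicates,noise_cv expression design.
#' @param anchor_up_fraction fraction of planted up-genes whose TSS lies in a
#'   planted (treatment-condition) loop anchor bin.
#' @param n_peaks,peak_width,colocalization_fraction,promoter_fraction TF
#'   peak design (per factor).
#' @param n_loops named vector: planted `gained`, `lost`, `static` counts.
#' @param loop_enrichment fold enrichment at planted loop pixels.
#' @param ep_loop_fraction fraction of gained loops anchored at an
#'   (intergenic enhancer peak bin, promoter bin) pair.
#' @param loop_min_dist_bins,loop_max_dist_bins planted loop distance band.
#' @param n_pairs Hi-C read pairs per condition.
#' @param decay power-law distance-decay exponent.
#' @param filter_violation_rate fraction of pairs deliberately placed > 500 bp
#'   from any cut site (exercises the pair filter).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_chroms = 2, chrom_length = 2e6, bin_size = 5000,
                       cut_site_spacing = 400,
                       n_genes = 2000, gene_length_range = c(300, 600),
                       gene_island_fraction = 0.35,
                       gene_compartment_bias = 0.75,
                       n_compartment_blocks = 4, compartment_strength = 2,
                       n_up = 100, n_down = 100, effect_size = 4,
                       n_replicates = 3, noise_cv = 0.2,
                       anchor_up_fraction = 0.53,
                       n_peaks = 300, peak_width = 200,
                       colocalization_fraction = 0.4,
                       promoter_fraction = 0.35,
                       n_loops = c(gained = 20, lost = 15, static = 25),
                       loop_enrichment = 5, ep_loop_fraction = 1.0,
                       loop_min_dist_bins = 6, loop_max_dist_bins = 60,
                       n_pairs = 5e5, decay = 1.0,
                       filter_violation_rate = 0.01) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  fracs <- c(cfg$gene_compartment_bias, cfg$colocalization_fraction,
             cfg$promoter_fraction, cfg$ep_loop_fraction,
             cfg$anchor_up_fraction, cfg$filter_violation_rate)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must be in [0, 1]")
  stopifnot(n_chroms >= 1, chrom_length > 0, bin_size > 0,
            cut_site_spacing > 8, n_genes >= 0, n_up + n_down <= n_genes,
            effect_size >= 1, n_replicates >= 2, noise_cv >= 0,
            all(n_loops >= 0), loop_enrichment >= 1, n_pairs >= 0,
            all(c("gained", "lost", "static") %in% names(n_loops)))
  nb <- floor(chrom_length / bin_size)
  if (loop_max_dist_bins >= nb)
    stop("loop pixels outside the distance band: loop_max_dist_bins must be < bins per chromosome")
  stopifnot(loop_min_dist_bins >= 1, loop_min_dist_bins <= loop_max_dist_bins)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_chroms, "x", format(x$chrom_length, big.mark = ","),
      "bp @", x$bin_size, "bp bins; seed", x$seed, "\n")
  invisible(x)
}

#' Simulate the genome: layout, cut sites, compartment blocks, genes, FASTA
#'
#' Cut-site spacings are exponential with the configured mean (minimum 4 bp
#' so the literal GATC motifs do not collide); every recorded site has GATC
#' written into the emitted sequence. Each chromosome is split into
#' `n_compartment_blocks` alternating A/B blocks; genes are placed without
#' overlap, with `gene_compartment_bias` of them in A blocks (so per-bin gene
#' density can orient the compartment eigenvector).
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return list: `layout` ([genome_layout()]), `genes`, `seq_chars` (list of
#'   per-chromosome character vectors), `compartments` (truth labels per bin).
#' @export
simulate_genome <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  chrom_names <- paste0("chr", seq_len(cfg$n_chroms))
  sizes <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms), chrom_names)

  sites <- lapply(chrom_names, function(ch) {
    n_est <- ceiling(cfg$chrom_length / cfg$cut_site_spacing * 1.5) + 10
    gaps <- 4 + stats::rexp(n_est, rate = 1 / (cfg$cut_site_spacing - 4))
    pos <- floor(cumsum(gaps))
    pos[pos < cfg$chrom_length - 4]
  })
  names(sites) <- chrom_names

  layout <- genome_layout(sizes, cut_sites = sites, bin_size = cfg$bin_size)
  nb <- n_bins(layout)

  # alternating A/B blocks, equal size in bins
  compartments <- do.call(rbind, lapply(chrom_names, function(ch) {
    n <- nb[[ch]]
    block <- ceiling(seq_len(n) / (n / cfg$n_compartment_blocks))
    data.frame(chrom = ch, bin = seq_len(n), block = block,
               label = ifelse(block %% 2 == 1, "A", "B"))
  }))

  # genes: pick a block (A blocks weighted by the bias), then place without
  # overlap inside the block by distributing the free space as random gaps
  blocks <- do.call(rbind, lapply(chrom_names, function(ch) {
    n <- nb[[ch]]
    bsz <- cfg$bin_size
    k <- cfg$n_compartment_blocks
    edges <- round(seq(0, n, length.out = k + 1)) * bsz
    data.frame(chrom = ch, start = utils::head(edges, -1),
               end = pmin(utils::tail(edges, -1), cfg$chrom_length),
               label = ifelse(seq_len(k) %% 2 == 1, "A", "B"))
  }))
  wA <- cfg$gene_compartment_bias
  blen <- blocks$end - blocks$start
  wt <- ifelse(blocks$label == "A", wA, 1 - wA) * blen
  assign_block <- sample(nrow(blocks), cfg$n_genes, replace = TRUE,
                         prob = wt / sum(wt))
  glen <- round(stats::runif(cfg$n_genes, cfg$gene_length_range[1],
                             cfg$gene_length_range[2]))
  genes <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(b) {
    idx <- which(assign_block == b)
    if (!length(idx)) return(NULL)
    L <- glen[idx]
    # genes pack into a compact island inside the block (gene clusters and
    # gene deserts), so +/-1 kb promoter windows do not tile whole blocks
    island_len <- max(round(cfg$gene_island_fraction * blen[b]),
                      sum(L) + length(L))
    if (island_len > blen[b])
      stop("genes cannot fit: block needs >= ", island_len, " bp, has ",
           blen[b])
    island_start <- blocks$start[b] +
      floor(stats::runif(1, 0, blen[b] - island_len + 1))
    free <- island_len - sum(L)
    cuts <- sort(stats::runif(length(idx), 0, free))
    gaps <- diff(c(0, cuts))
    starts <- island_start + cumsum(gaps) +
      c(0, cumsum(utils::head(L, -1)))
    data.frame(chrom = blocks$chrom[b], start = floor(starts),
               end = floor(starts) + L,
               strand = sample(c("+", "-"), length(idx), replace = TRUE))
  }))
  genes <- genes[order(match(genes$chrom, chrom_names), genes$start), ]
  genes$name <- sprintf("gene%04d", seq_len(nrow(genes)))
  genes$score <- 0
  genes$tss <- gene_tss(genes)
  rownames(genes) <- NULL

  seq_chars <- lapply(chrom_names, function(ch) {
    x <- sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE)
    for (k in 0:3) x[sites[[ch]] + 1 + k] <- c("G", "A", "T", "C")[k + 1]
    x
  })
  names(seq_chars) <- chrom_names

  list(layout = layout, genes = genes, seq_chars = seq_chars,
       compartments = compartments)
}

#' Collapse simulated per-chromosome character vectors to sequences
#' @param genome output of [simulate_genome()] (after optional motif planting).
#' @return named character vector of chromosome sequences.
#' @export
sim_sequences <- function(genome) {
  vapply(genome$seq_chars, paste, character(1), collapse = "")
}

sim_pwms <- function() {
  make <- function(name, consensus) {
    L <- nchar(consensus)
    m <- matrix(0.05, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
    idx <- match(strsplit(consensus, "")[[1]], rownames(m))
    m[cbind(idx, seq_len(L))] <- 0.85
    pwm(name, m)
  }
  list(CTCF_like = make("CTCF_like", "CCACCAGGTGGC"),
       STAT3_like = make("STAT3_like", "TTCCCGGAA"))
}

# find a clash-free start for a motif of length L near `center`: avoids
# recorded cut sites (sorted vector) and previously planted intervals
motif_slot <- function(sites, occ_start, occ_end, center, L, chrom_len) {
  start <- center - floor(L / 2)
  for (try in 0:10) {
    s <- start + 6 * try
    if (s < 0 || s + L > chrom_len) return(NA_integer_)
    clash_site <- (findInterval(s + L - 1, sites) - findInterval(s - 4, sites)) > 0
    clash_occ <- length(occ_start) > 0 && any(occ_start < s + L & occ_end > s)
    if (!clash_site && !clash_occ) return(as.integer(s))
  }
  NA_integer_
}

#' Simulate TF peak sets with controlled colocalization
#'
#' TF-A (CTCF-like) peaks are uniform; a `colocalization_fraction` of TF-B
#' (STAT3-like) peaks are centered within 100 bp of a TF-A peak, a
#' `promoter_fraction` of the remainder in promoter windows, and the rest
#' uniform. Each peak's motif consensus is written into the genome sequence
#' at its center (shifted a few bp when it would clash with a recorded cut
#' site or another motif).
#'
#' @param cfg a [sim_config()].
#' @param genome output of [simulate_genome()].
#' @param seed RNG seed.
#' @return list: `tf_a`, `tf_b` peak data.frames, `pwms`, `motif_truth`
#'   occurrence table, and `genome` with motifs planted in `seq_chars`.
#' @export
simulate_peaks <- function(cfg, genome, seed = cfg$seed + 1) {
  set.seed(seed)
  layout <- genome$layout
  chrom_names <- layout$chroms$name
  w <- cfg$peak_width
  n <- cfg$n_peaks
  total_len <- sum(layout$chroms$length)
  if (n * w > 0.5 * total_len) stop("peak demand exceeds genome capacity")

  rand_centers <- function(k) {
    ch <- sample(chrom_names, k, replace = TRUE,
                 prob = layout$chroms$length / total_len)
    pos <- floor(stats::runif(k, w, chrom_length(layout, ch) - w))
    data.frame(chrom = ch, center = pos)
  }
  # A-compartment-biased placement (enhancer-type binding concentrates in
  # active chromatin)
  biased_centers <- function(k) {
    comp <- genome$compartments
    wA <- cfg$gene_compartment_bias
    wt <- ifelse(comp$label == "A", wA, 1 - wA)
    pick <- sample(nrow(comp), k, replace = TRUE, prob = wt / sum(wt))
    bs <- layout$bin_size
    pos <- floor((comp$bin[pick] - 1) * bs + stats::runif(k, w, bs - w))
    data.frame(chrom = comp$chrom[pick], center = pos)
  }
  a_cent <- rand_centers(n)
  n_co <- round(cfg$colocalization_fraction * n)
  n_prom <- round(cfg$promoter_fraction * n)
  n_prom <- min(n_prom, n - n_co)
  co_src <- if (n_co > 0) sample(n, n_co, replace = TRUE) else integer()
  b_co <- data.frame(chrom = a_cent$chrom[co_src],
                     center = a_cent$center[co_src] +
                       round(stats::runif(n_co, -100, 100)))
  gsel <- if (n_prom > 0) sample(nrow(genome$genes), n_prom, replace = TRUE)
          else integer()
  b_prom <- data.frame(chrom = genome$genes$chrom[gsel],
                       center = genome$genes$tss[gsel] +
                         round(stats::runif(n_prom, -500, 500)))
  b_rest <- biased_centers(n - n_co - n_prom)
  b_cent <- rbind(b_co, b_prom, b_rest)
  b_cent$center <- pmax(w, pmin(b_cent$center,
                                chrom_length(layout, b_cent$chrom) - w))

  mk_peaks <- function(cent, prefix) {
    out <- data.frame(chrom = cent$chrom, start = cent$center - w %/% 2,
                      end = cent$center + w %/% 2,
                      name = sprintf("%s_%04d", prefix, seq_len(nrow(cent))),
                      score = round(stats::rlnorm(nrow(cent), log(10), 0.8), 3),
                      strand = ".")
    out[order(match(out$chrom, chrom_names), out$start), ] |>
      (\(x) { rownames(x) <- NULL; x })()
  }
  tf_a <- mk_peaks(a_cent, "TFA")
  tf_b <- mk_peaks(b_cent, "TFB")

  pwms <- sim_pwms()
  occ_start <- occ_end <- stats::setNames(
    rep(list(integer()), length(chrom_names)), chrom_names)
  truth <- list()
  for (set in list(list(p = tf_a, motif = "CTCF_like"),
                   list(p = tf_b, motif = "STAT3_like"))) {
    cons <- pwm_consensus(pwms[[set$motif]])
    L <- nchar(cons)
    pk <- set$p
    starts <- rep(NA_integer_, nrow(pk))
    for (r in seq_len(nrow(pk))) {
      ch <- pk$chrom[r]
      st <- motif_slot(layout$sites[[ch]], occ_start[[ch]], occ_end[[ch]],
                       floor((pk$start[r] + pk$end[r]) / 2), L,
                       chrom_length(layout, ch))
      if (!is.na(st)) {
        occ_start[[ch]] <- c(occ_start[[ch]], st)
        occ_end[[ch]] <- c(occ_end[[ch]], st + L)
        starts[r] <- st
      }
    }
    ok <- !is.na(starts)
    if (any(ok))
      truth[[set$motif]] <- data.frame(chrom = pk$chrom[ok],
                                       start = starts[ok],
                                       end = starts[ok] + L,
                                       motif = set$motif, strand = "+",
                                       peak = pk$name[ok])
    # write all consensus copies into the sequence in one pass per chromosome
    cons_chars <- strsplit(cons, "")[[1]]
    for (ch in unique(pk$chrom[ok])) {
      st <- starts[ok & pk$chrom == ch]
      idx <- rep(st, each = L) + seq_len(L)
      genome$seq_chars[[ch]][idx] <- rep(cons_chars, length(st))
    }
  }
  list(tf_a = tf_a, tf_b = tf_b, pwms = pwms,
       motif_truth = do.call(rbind, truth), genome = genome)
}

# place read ends inside given bins, 0-300 bp upstream of a cut site
place_ends <- function(layout, ch, bins) {
  s <- layout$sites[[ch]]
  bs <- layout$bin_size
  len <- chrom_length(layout, ch)
  bin_start <- (bins - 1) * bs
  bin_end <- pmin(bins * bs, len)
  use_minus <- stats::runif(length(bins)) < 0.5
  pos <- numeric(length(bins))
  strand <- ifelse(use_minus, "-", "+")
  # '+' reads: site in [bin_start, bin_end + 300), pos = site - u
  idx <- which(!use_minus)
  if (length(idx)) {
    lo <- findInterval(bin_start[idx] - 0.5, s) + 1
    hi <- findInterval(bin_end[idx] + 299, s)
    cnt <- hi - lo + 1
    bad <- cnt < 1
    pick <- lo + floor(stats::runif(length(idx)) * pmax(cnt, 1))
    site <- s[pmin(pmax(pick, 1), length(s))]
    lo_u <- pmax(0, site - (bin_end[idx] - 1))
    hi_u <- pmin(300, site - bin_start[idx])
    bad <- bad | lo_u > hi_u
    u <- lo_u + floor(stats::runif(length(idx)) * (hi_u - lo_u + 1))
    pos[idx] <- ifelse(bad, bin_start[idx], site - u)
    strand[idx][bad] <- "+"
  }
  # '-' reads: site in (bin_start - 300, bin_end), pos = site + u
  idx <- which(use_minus)
  if (length(idx)) {
    lo <- findInterval(bin_start[idx] - 300, s) + 1
    hi <- findInterval(bin_end[idx] - 0.5, s)
    cnt <- hi - lo + 1
    bad <- cnt < 1
    pick <- lo + floor(stats::runif(length(idx)) * pmax(cnt, 1))
    site <- s[pmin(pmax(pick, 1), length(s))]
    lo_u <- pmax(0, bin_start[idx] - site)
    hi_u <- pmin(300, bin_end[idx] - 1 - site)
    bad <- bad | lo_u > hi_u
    u <- lo_u + floor(stats::runif(length(idx)) * (hi_u - lo_u + 1))
    pos[idx] <- ifelse(bad, bin_start[idx], site + u)
    strand[idx][bad] <- "+"
  }
  data.frame(pos = pos, strand = strand)
}

# uniform draw from positions > 500 bp upstream of every '+'-strand site
dead_zone_positions <- function(sites, k) {
  gap_ok <- which(diff(sites) > 504)
  if (!length(gap_ok)) return(NULL)
  lo <- sites[gap_ok] + 1
  hi <- sites[gap_ok + 1] - 501
  wlen <- hi - lo + 1
  pick <- sample.int(length(lo), k, replace = TRUE, prob = wlen / sum(wlen))
  floor(lo[pick] + stats::runif(k) * wlen[pick])
}

#' Simulate Hi-C read pairs with planted compartments and loops
#'
#' Pixel intensities follow a power-law distance decay times a compartment
#' checkerboard factor (x`compartment_strength` within blocks, /
#' `compartment_strength` between) times the loop factor
#' (`loop_enrichment` at planted pixels; static loops in both conditions,
#' gained in treatment only, lost in reference only). `n_pairs` pairs are
#' drawn per condition from the normalized pixel distribution; each read end
#' is placed 0-300 bp upstream of a cut site inside its bin so the 500 bp
#' filter keeps it, except for a `filter_violation_rate` fraction placed in
#' dead zones to exercise the filter. Static loops anchor at CTCF-like peak
#' bins; gained loops (an `ep_loop_fraction` of them) connect an intergenic
#' STAT3-like enhancer peak bin to a promoter bin.
#'
#' @param cfg a [sim_config()].
#' @param genome output of [simulate_genome()].
#' @param peaks output of [simulate_peaks()].
#' @param seed RNG seed.
#' @return list: `pairs` (list `pre`/`post` of pair data.frames),
#'   `loops_truth`, `violations` (planted per condition).
#' @export
simulate_hic <- function(cfg, genome, peaks, seed = cfg$seed + 2) {
  set.seed(seed)
  layout <- genome$layout
  chrom_names <- layout$chroms$name
  nb <- n_bins(layout)
  bs <- layout$bin_size
  comp <- genome$compartments

  tfb_cls <- classify_peaks(peaks$tf_b, genome$genes, window = 1000)
  enh <- tfb_cls[tfb_cls$class == "intergenic", , drop = FALSE]
  prom_pk <- tfb_cls[tfb_cls$class == "promoter", , drop = FALSE]
  enh_bins <- unique(data.frame(chrom = enh$chrom,
                                bin = local_bin(layout,
                                                floor((enh$start + enh$end) / 2))))
  prom_pk_bins <- unique(data.frame(chrom = prom_pk$chrom,
                                    bin = local_bin(layout,
                                                    floor((prom_pk$start +
                                                             prom_pk$end) / 2))))
  tfa_bins <- unique(data.frame(chrom = peaks$tf_a$chrom,
                                bin = local_bin(layout,
                                                floor((peaks$tf_a$start +
                                                         peaks$tf_a$end) / 2))))
  gene_bins <- data.frame(chrom = genome$genes$chrom,
                          bin = local_bin(layout, genome$genes$tss),
                          gene = genome$genes$name)

  in_band <- function(d) d >= cfg$loop_min_dist_bins & d <= cfg$loop_max_dist_bins
  # planted loops are intra-domain: both anchors in the same compartment block
  pair_pool <- function(b1set, b2set) {
    do.call(rbind, lapply(chrom_names, function(ch) {
      blk <- comp$block[comp$chrom == ch]
      x <- b1set$bin[b1set$chrom == ch]
      y <- b2set$bin[b2set$chrom == ch]
      if (!length(x) || !length(y)) return(NULL)
      g <- expand.grid(a = unique(x), b = unique(y))
      d <- abs(g$a - g$b)
      g <- g[in_band(d) & blk[g$a] == blk[g$b], , drop = FALSE]
      if (!nrow(g)) return(NULL)
      data.frame(chrom = ch, bin1 = pmin(g$a, g$b), bin2 = pmax(g$a, g$b))
    }))
  }
  # planted pixels keep >= 8 bins Chebyshev separation so each loop's local
  # background is uncontaminated by the others
  min_sep <- 8
  sample_pool <- function(pool, k, used) {
    key <- with(pool, paste(chrom, bin1, bin2))
    pool <- pool[!duplicated(key), , drop = FALSE]
    pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
    picked <- integer()
    for (r in seq_len(nrow(pool))) {
      u <- used[used$chrom == pool$chrom[r], , drop = FALSE]
      if (nrow(u) == 0 ||
          all(pmax(abs(u$bin1 - pool$bin1[r]),
                   abs(u$bin2 - pool$bin2[r])) >= min_sep)) {
        picked <- c(picked, r)
        used <- rbind(used, pool[r, c("chrom", "bin1", "bin2")])
        if (length(picked) == k) break
      }
    }
    if (length(picked) < k) stop("not enough candidate loop pixels")
    pool[picked, , drop = FALSE]
  }

  used <- data.frame(chrom = character(), bin1 = integer(), bin2 = integer())
  n_g <- cfg$n_loops[["gained"]]
  n_ep <- round(cfg$ep_loop_fraction * n_g)
  ep_pool <- pair_pool(enh_bins, prom_pk_bins)
  gained_ep <- if (n_ep > 0) sample_pool(ep_pool, n_ep, used) else NULL
  if (!is.null(gained_ep)) {
    used <- rbind(used, gained_ep[, c("chrom", "bin1", "bin2")])
    # record one target gene per E-P loop (a gene whose TSS bin is an anchor)
    gained_ep$target_gene <- vapply(seq_len(nrow(gained_ep)), function(r) {
      hit <- gene_bins$gene[gene_bins$chrom == gained_ep$chrom[r] &
                              (gene_bins$bin == gained_ep$bin1[r] |
                                 gene_bins$bin == gained_ep$bin2[r])]
      if (length(hit)) hit[[1]] else NA_character_
    }, character(1))
    gained_ep$ep <- TRUE
  }
  rand_bins <- do.call(rbind, lapply(chrom_names, function(ch)
    data.frame(chrom = ch, bin = seq_len(nb[[ch]]))))
  mk_rand <- function(k) {
    if (k <= 0) return(NULL)
    pool <- pair_pool(rand_bins, rand_bins)
    out <- sample_pool(pool, k, used)
    used <<- rbind(used, out[, c("chrom", "bin1", "bin2")])
    out$target_gene <- NA_character_
    out$ep <- FALSE
    out
  }
  gained_rest <- mk_rand(n_g - n_ep)
  static_pool <- pair_pool(tfa_bins, tfa_bins)
  static <- sample_pool(static_pool, cfg$n_loops[["static"]], used)
  static$target_gene <- NA_character_
  static$ep <- FALSE
  used <- rbind(used, static[, c("chrom", "bin1", "bin2")])
  lost <- mk_rand(cfg$n_loops[["lost"]])

  loops_truth <- rbind(
    if (!is.null(gained_ep)) cbind(gained_ep, class = "gained"),
    if (!is.null(gained_rest)) cbind(gained_rest, class = "gained"),
    cbind(static, class = "static"),
    if (!is.null(lost)) cbind(lost, class = "lost"))
  loops_truth$start1 <- (loops_truth$bin1 - 1) * bs
  loops_truth$end1 <- loops_truth$bin1 * bs
  loops_truth$start2 <- (loops_truth$bin2 - 1) * bs
  loops_truth$end2 <- loops_truth$bin2 * bs
  rownames(loops_truth) <- NULL

  sample_condition <- function(which_cond) {
    keep_cls <- if (which_cond == "pre") c("static", "lost")
                else c("static", "gained")
    per_chrom <- lapply(chrom_names, function(ch) {
      n <- nb[[ch]]
      lab <- comp$label[comp$chrom == ch]
      D <- abs(outer(seq_len(n), seq_len(n), "-"))
      lam <- (1 + D)^(-cfg$decay)
      same <- outer(lab, lab, "==")
      lam <- lam * ifelse(same, cfg$compartment_strength,
                          1 / cfg$compartment_strength)
      lt <- loops_truth[loops_truth$chrom == ch &
                          loops_truth$class %in% keep_cls, , drop = FALSE]
      if (nrow(lt)) {
        lam[cbind(lt$bin1, lt$bin2)] <- lam[cbind(lt$bin1, lt$bin2)] *
          cfg$loop_enrichment
        lam[cbind(lt$bin2, lt$bin1)] <- lam[cbind(lt$bin1, lt$bin2)]
      }
      ut <- upper.tri(lam, diag = TRUE)
      list(i = row(lam)[ut], j = col(lam)[ut], w = lam[ut])
    })
    tot <- vapply(per_chrom, function(x) sum(x$w), numeric(1))
    n_ch <- as.vector(stats::rmultinom(1, cfg$n_pairs, tot / sum(tot)))
    pieces <- lapply(seq_along(chrom_names), function(ci) {
      x <- per_chrom[[ci]]
      cnt <- as.vector(stats::rmultinom(1, n_ch[ci], x$w / sum(x$w)))
      sel <- cnt > 0
      b1 <- rep(x$i[sel], cnt[sel])
      b2 <- rep(x$j[sel], cnt[sel])
      e1 <- place_ends(layout, chrom_names[ci], b1)
      e2 <- place_ends(layout, chrom_names[ci], b2)
      data.frame(chrom1 = chrom_names[ci], pos1 = e1$pos, strand1 = e1$strand,
                 chrom2 = chrom_names[ci], pos2 = e2$pos, strand2 = e2$strand)
    })
    pr <- do.call(rbind, pieces)
    # planted filter violations: move one end into a cut-site dead zone
    viol <- which(stats::runif(nrow(pr)) < cfg$filter_violation_rate)
    for (ch in unique(pr$chrom1[viol])) {
      sel <- viol[pr$chrom1[viol] == ch]
      dz <- dead_zone_positions(layout$sites[[ch]], length(sel))
      if (!is.null(dz)) {
        pr$pos1[sel] <- dz
        pr$strand1[sel] <- "+"
      }
    }
    swap <- pr$pos1 > pr$pos2
    tmp <- pr[swap, ]
    pr[swap, c("pos1", "strand1")] <- tmp[, c("pos2", "strand2")]
    pr[swap, c("pos2", "strand2")] <- tmp[, c("pos1", "strand1")]
    pr <- pr[sample.int(nrow(pr)), , drop = FALSE]
    pr <- data.frame(read_id = sprintf("%s_%07d", which_cond,
                                       seq_len(nrow(pr))), pr)
    pr <- pr[, c("read_id", "chrom1", "pos1", "chrom2", "pos2",
                 "strand1", "strand2")]
    rownames(pr) <- NULL
    list(pairs = pr, n_violations = length(viol))
  }
  pre <- sample_condition("pre")
  post <- sample_condition("post")
  list(pairs = list(pre = pre$pairs, post = post$pairs),
       loops_truth = loops_truth,
       violations = c(pre = pre$n_violations, post = post$n_violations))
}

#' Simulate the expression experiment with planted DE genes
#'
#' Baseline means are log-normal; planted up/down genes are multiplied or
#' divided by `effect_size` in the treatment; replicates get multiplicative
#' log-normal noise at the configured CV. An `anchor_up_fraction` of planted
#' up-genes is drawn from genes whose TSS lies in a planted
#' treatment-condition loop anchor bin (E-P loop target genes first); the
#' rest, and all down-genes, come from non-anchor genes.
#'
#' @param cfg a [sim_config()].
#' @param genome output of [simulate_genome()].
#' @param loops_truth truth table from [simulate_hic()].
#' @param seed RNG seed.
#' @return list: `expr` (an [expression_table()]), `truth` (per planted gene:
#'   direction and anchor flag).
#' @export
simulate_expression <- function(cfg, genome, loops_truth,
                                seed = cfg$seed + 3) {
  set.seed(seed)
  layout <- genome$layout
  genes <- genome$genes
  post_loops <- loops_truth[loops_truth$class %in% c("static", "gained"), ,
                            drop = FALSE]
  anchor_key <- unique(c(with(post_loops, paste(chrom, bin1)),
                         with(post_loops, paste(chrom, bin2))))
  tss_key <- paste(genes$chrom, local_bin(layout, genes$tss))
  in_anchor <- tss_key %in% anchor_key

  n_anchor_up <- round(cfg$anchor_up_fraction * cfg$n_up)
  ep_targets <- unique(stats::na.omit(post_loops$target_gene))
  pool_anchor <- genes$name[in_anchor]
  if (length(pool_anchor) < n_anchor_up)
    stop("not enough genes in planted anchors (",
         length(pool_anchor), " < ", n_anchor_up, ")")
  first <- intersect(ep_targets, pool_anchor)
  first <- first[seq_len(min(length(first), n_anchor_up))]
  # fill the remaining slots cycling over distinct anchor bins, so the
  # planted fraction is not hostage to a few gene-dense anchor bins
  rest <- setdiff(pool_anchor, first)
  rest_bin <- tss_key[match(rest, genes$name)]
  by_bin <- lapply(split(rest, rest_bin), sample)
  fill <- character(0)
  while (length(fill) < n_anchor_up - length(first) && length(by_bin)) {
    take <- vapply(by_bin, `[`, character(1), 1)
    fill <- c(fill, unname(take))
    by_bin <- Filter(length, lapply(by_bin, `[`, -1))
  }
  up_anchor <- c(first, fill[seq_len(n_anchor_up - length(first))])
  pool_out <- setdiff(genes$name[!in_anchor], up_anchor)
  up_rest <- sample(pool_out, cfg$n_up - n_anchor_up)
  up <- c(up_anchor, up_rest)
  down <- sample(setdiff(pool_out, up_rest), cfg$n_down)

  n_genes <- nrow(genes)
  base <- stats::rlnorm(n_genes, log(100), 1)
  names(base) <- genes$name
  trt_mean <- base
  trt_mean[up] <- trt_mean[up] * cfg$effect_size
  trt_mean[down] <- trt_mean[down] / cfg$effect_size
  sdlog <- sqrt(log(1 + cfg$noise_cv^2))
  nr <- cfg$n_replicates
  noise <- function(mu) mu * stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog)
  mat <- cbind(matrix(noise(rep(base, nr)), n_genes, nr),
               matrix(noise(rep(trt_mean, nr)), n_genes, nr))
  rownames(mat) <- genes$name
  colnames(mat) <- c(paste0("preG_", seq_len(nr)),
                     paste0("postG_", seq_len(nr)))
  conditions <- rep(c("preG", "postG"), each = nr)
  truth <- data.frame(gene = c(up, down),
                      direction = rep(c("up", "down"),
                                      c(length(up), length(down))),
                      in_anchor = c(rep(c(TRUE, FALSE),
                                        c(length(up_anchor), length(up_rest))),
                                    rep(FALSE, length(down))))
  list(expr = expression_table(mat, conditions, "preG", "postG"),
       truth = truth)
}

sim_relations <- function(cfg, truth, genes, seed) {
  set.seed(seed)
  up <- truth$gene[truth$direction == "up"]
  other <- setdiff(genes$name, truth$gene)
  rel <- rbind(
    data.frame(tf = "STAT3_like",
               target = c(sample(up, round(0.7 * length(up))),
                          sample(other, 50))),
    data.frame(tf = "CTCF_like",
               target = c(sample(up, round(0.15 * length(up))),
                          sample(other, 100))))
  rel <- rel[!duplicated(rel), , drop = FALSE]
  rel$weight <- 1
  rownames(rel) <- NULL
  rel
}

#' Simulate the complete toy multiomics experiment
#'
#' Runs [simulate_genome()], [simulate_peaks()], [simulate_hic()] and
#' [simulate_expression()] with seeds derived from `cfg$seed`, and adds a
#' TF-target relation table in which the STAT3-like factor preferentially
#' targets the planted up-genes. All outputs are deterministic given the
#' seed.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_experiment`.
#' @export
simulate_experiment <- function(cfg) {
  genome <- simulate_genome(cfg)
  pk <- simulate_peaks(cfg, genome)
  genome <- pk$genome
  hic <- simulate_hic(cfg, genome, pk)
  expr <- simulate_expression(cfg, genome, hic$loops_truth)
  relations <- sim_relations(cfg, expr$truth, genome$genes, cfg$seed + 4)
  structure(list(cfg = cfg, layout = genome$layout, genes = genome$genes,
                 sequences = sim_sequences(genome),
                 compartments = genome$compartments,
                 tf_a = pk$tf_a, tf_b = pk$tf_b, pwms = pk$pwms,
                 motif_truth = pk$motif_truth,
                 pairs = hic$pairs, loops_truth = hic$loops_truth,
                 violations = hic$violations,
                 expr = expr$expr, expr_truth = expr$truth,
                 relations = relations),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("sim_experiment (seed", x$cfg$seed, "):",
      nrow(x$layout$chroms), "chroms,", nrow(x$genes), "genes,",
      nrow(x$tf_a), "+", nrow(x$tf_b), "TF peaks,",
      nrow(x$loops_truth), "planted loops,",
      nrow(x$pairs$pre), "/", nrow(x$pairs$post), "pairs\n")
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Emits FASTA, chrom.sizes, cut sites, peak BEDs, gene BED, expression TSV,
#' condition map, per-condition .pairs files, the TF relation table, truth
#' tables (JSON) and the configuration echo (JSON).
#'
#' @param sim a `sim_experiment`.
#' @param dir output directory (created).
#' @return invisibly, the named list of written paths.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  dna <- Biostrings::DNAStringSet(sim$sequences)
  Biostrings::writeXStringSet(dna, p("genome.fa"))
  write.table(sim$layout$chroms, p("chrom.sizes"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_cut_sites(sim$layout$sites, p("cut_sites.tsv"))
  write_bed(sim$tf_a, p("tf_a_peaks.bed"))
  write_bed(sim$tf_b, p("tf_b_peaks.bed"))
  write_bed(sim$genes, p("genes.bed"))
  write_expression(sim$expr$mat, p("expression.tsv"))
  write.table(data.frame(sample = colnames(sim$expr$mat),
                         condition = sim$expr$conditions),
              p("condition_map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_pairs(sim$pairs$pre, p("pre.pairs"))
  write_pairs(sim$pairs$post, p("post.pairs"))
  write.table(sim$relations, p("tf_relations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(loops = sim$loops_truth,
                            expression = sim$expr_truth,
                            compartments = sim$compartments,
                            violations = as.list(sim$violations)),
                       p("truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(sim$cfg), p("sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = dir))
}
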