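#' Unified enrichment-test record
#'
#' Carries either hypergeometric counts (N, K, n, k) or a permutation null
#' summary (mean, sd, n_perm, seed), plus the statistic and p/q values.
#' @param method `"hypergeometric"` or `"permutation"`.
#' @param statistic test statistic.
#' @param p p-value; `q` optional BH-adjusted value.
#' @param ... extra fields (counts, null summary, seed, annex tables).
#' @return object of class `enrichment_result`.
#' @export
enrichment_result <- function(method, statistic, p, q = NA_real_, ...) {
  stopifnot(p >= 0, p <= 1)
  structure(c(list(method = method, statistic = statistic, p = p, q = q),
              list(...)), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment_result [", x$method, "]\n", sep = "")
  if (!is.null(x$N))
    cat(sprintf("  counts: N=%d K=%d n=%d k=%d\n", x$N, x$K, x$n, x$k))
  if (!is.null(x$null_mean))
    cat(sprintf("  null: mean=%.4g sd=%.4g (n_perm=%d)\n",
                x$null_mean, x$null_sd, x$n_perm))
  cat(sprintf("  statistic=%.4g  p=%.3g\n", x$statistic, x$p))
  invisible(x)
}

# upper-tail hypergeometric P(X >= k) drawing n from N with K successes
hyper_upper <- function(N, K, n, k) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# piecewise-constant track integral: returns function I(x) = integral 0..x
track_integral <- function(track_ch) {
  t <- track_ch[order(track_ch$start), , drop = FALSE]
  breaks <- c(0, as.numeric(rbind(t$start, t$end)))
  segvals <- c(0, as.numeric(rbind(t$value, rep(0, nrow(t)))))
  if (anyDuplicated(breaks)) {
    keep <- !duplicated(breaks)
    # duplicated break (interval starting at 0 or abutting): keep later segment value
    for (d in which(duplicated(breaks)))
      segvals[max(which(breaks == breaks[d])) - 1] <- segvals[d]
    breaks <- breaks[keep]; segvals <- segvals[keep]
  }
  cumI <- cumsum(c(0, diff(breaks) * utils::head(segvals, -1)))
  lastI <- cumI[length(cumI)]
  function(x) {
    j <- findInterval(x, breaks)
    ifelse(j < 1, 0,
           ifelse(j >= length(breaks), lastI,
                  cumI[pmax(j, 1)] + (x - breaks[pmax(j, 1)]) *
                    segvals[pmax(j, 1)]))
  }
}

#' Signal profile matrix around reference peaks
#'
#' Builds a rows-by-position matrix of mean signal in `step`-bp cells across
#' `+/- flank` bp windows centered on the reference-peak midpoints (the
#' matrix behind aggregate plots such as "signal at +/- 5.0 kb from the
#' reference peaks"). Cells outside the chromosome read as 0 and the row is
#' flagged. Rows are ordered by descending row sum.
#'
#' @param track signal data.frame (`chrom`, `start`, `end`, `value`).
#' @param refs reference peaks (`chrom`, `start`, `end`).
#' @param flank window half-width in bp (default 5000).
#' @param step cell width in bp (default 50, must divide flank).
#' @return list of class `profile_matrix`: `matrix`, `curve` (column means),
#'   `positions` (cell centers relative to the midpoint), `order` (row
#'   indices into `refs`), `clipped` (per-row flag).
#' @export
aggregate_profile <- function(track, refs, flank = 5000, step = 50,
                              layout = NULL) {
  stopifnot(nrow(refs) > 0, flank %% step == 0)
  ncol <- 2 * flank / step
  mid <- floor((refs$start + refs$end) / 2)
  mat <- matrix(0, nrow(refs), ncol)
  clipped <- logical(nrow(refs))
  for (ch in unique(refs$chrom)) {
    sel <- which(refs$chrom == ch)
    tr <- track[track$chrom == ch, , drop = FALSE]
    I <- if (nrow(tr)) track_integral(tr) else function(x) rep(0, length(x))
    edges <- outer(mid[sel] - flank, seq(0, 2 * flank, by = step), "+")
    right_lim <- if (!is.null(layout)) chrom_length(layout, ch) else Inf
    clipped[sel] <- edges[, 1] < 0 | edges[, ncol + 1] > right_lim
    vals <- matrix(I(pmax(edges, 0)), nrow = length(sel))
    mat[sel, ] <- (vals[, -1, drop = FALSE] -
                     vals[, -(ncol + 1), drop = FALSE]) / step
  }
  ord <- order(-rowSums(mat), refs$chrom, refs$start)
  structure(list(matrix = mat[ord, , drop = FALSE],
                 curve = colMeans(mat),
                 positions = seq(-flank + step / 2, flank - step / 2, by = step),
                 order = ord, clipped = clipped[ord]),
            class = "profile_matrix")
}

#' Colocalization heatmap matrices over a shared row order
#'
#' Computes one profile matrix per named track around the same reference
#' peaks, with the row order fixed by the FIRST track's row sums and reused
#' for every other track, so colocalization is directly comparable.
#'
#' @param tracks named list of signal data.frames.
#' @param refs reference peaks (typically from [top_k_peaks()]).
#' @param flank,step window geometry, see [aggregate_profile()].
#' @return named list of `profile_matrix` objects sharing `order`.
#' @export
colocalization_heatmap <- function(tracks, refs, flank = 5000, step = 50) {
  stopifnot(length(tracks) >= 1, !is.null(names(tracks)))
  out <- vector("list", length(tracks))
  names(out) <- names(tracks)
  for (tn in names(tracks)) {
    if (nrow(tracks[[tn]]) == 0)
      warning("empty track: ", tn)
    pm <- aggregate_profile(tracks[[tn]], refs, flank, step)
    if (tn == names(tracks)[1]) {
      ref_order <- pm$order
    } else {
      # restate rows in the first track's order
      inv <- order(pm$order)
      pm$matrix <- pm$matrix[inv, , drop = FALSE][ref_order, , drop = FALSE]
      pm$clipped <- pm$clipped[inv][ref_order]
      pm$order <- ref_order
    }
    out[[tn]] <- pm
  }
  out
}

peak_bins_1d <- function(peaks, layout, universe_bin) {
  off <- bin_offsets_at(layout, universe_bin)
  ids <- mapply(function(ch, s, e) {
    off[ch] + (s %/% universe_bin):((e - 1) %/% universe_bin) + 1
  }, peaks$chrom, peaks$start, peaks$end, SIMPLIFY = FALSE)
  unique(unlist(ids, use.names = FALSE))
}

bin_offsets_at <- function(layout, universe_bin) {
  nb <- ceiling(layout$chroms$length / universe_bin)
  stats::setNames(c(0, cumsum(nb))[seq_along(nb)], layout$chroms$name)
}

#' Hypergeometric peak-overlap test with Venn counts
#'
#' The genome is tiled at `universe_bin` bp; a bin is hit when >= 1 bp of a
#' peak covers it. With N total bins, K hit by `a`, n hit by `b` and k hit by
#' both, the p-value is the upper-tail hypergeometric P(X >= k) (the test
#' behind peak-overlap Venn diagrams). Venn counts are reported both in bin
#' units and in peak units (peaks of one set overlapping >= 1 peak of the
#' other).
#'
#' @param a,b peak data.frames.
#' @param layout a [genome_layout()].
#' @param universe_bin tiling width in bp (default 1000).
#' @return an [enrichment_result()] with `venn` annex.
#' @export
peak_overlap_test <- function(a, b, layout, universe_bin = 1000) {
  if (sum(layout$chroms$length) <= 0) stop("zero-length genome")
  N <- sum(ceiling(layout$chroms$length / universe_bin))
  ba <- peak_bins_1d(a, layout, universe_bin)
  bb <- peak_bins_1d(b, layout, universe_bin)
  K <- length(ba); n <- length(bb); k <- length(intersect(ba, bb))
  p <- hyper_upper(N, K, n, k)
  ov <- overlaps(a, b, layout)
  venn <- list(bins = c(a_only = K - k, b_only = n - k, both = k, universe = N),
               peaks = c(a_overlapping_b = length(unique(ov$i)),
                         b_overlapping_a = length(unique(ov$j)),
                         a_total = nrow(a), b_total = nrow(b)))
  enrichment_result("hypergeometric", statistic = k, p = p,
                    N = N, K = K, n = n, k = k, venn = venn)
}

#' Position weight matrix
#'
#' @param name motif name.
#' @param mat 4 x L column-stochastic probability matrix, rows A, C, G, T.
#' @param background base frequencies (A, C, G, T).
#' @param threshold absolute log2-odds score threshold; when `NULL`, set to
#'   `threshold_frac` of the maximum attainable score.
#' @param threshold_frac fraction of the maximum score (default 0.8).
#' @return object of class `pwm`.
#' @export
pwm <- function(name, mat, background = rep(0.25, 4), threshold = NULL,
                threshold_frac = 0.8) {
  stopifnot(nrow(mat) == 4, ncol(mat) >= 4,
            max(abs(colSums(mat) - 1)) < 1e-6)
  rownames(mat) <- c("A", "C", "G", "T")
  lut <- log2(pmax(mat, 1e-9) / background)
  if (is.null(threshold)) threshold <- threshold_frac * sum(apply(lut, 2, max))
  structure(list(name = name, mat = mat, background = background,
                 lut = lut, threshold = threshold, length = ncol(mat)),
            class = "pwm")
}

#' Consensus sequence of a PWM
#' @param x a [pwm()].
#' @return character scalar.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$mat)[apply(x$mat, 2, which.max)], collapse = "")
}

scan_one_strand <- function(code, lut) {
  L <- ncol(lut)
  np <- length(code) - L + 1
  if (np < 1) return(numeric(0))
  sc <- numeric(np)
  for (l in seq_len(L)) {
    sc <- sc + lut[, l][code[l:(np + l - 1)]]
  }
  sc
}

#' Scan sequences for PWM occurrences
#'
#' Scores every window on both strands with the log2-odds score against the
#' PWM background; windows at or above the threshold are reported. Windows
#' containing `N` are skipped. Overlapping same-strand occurrences are all
#' kept.
#'
#' @param sequences named character vector (or `Biostrings::DNAStringSet`)
#'   of chromosome sequences.
#' @param pwm a [pwm()].
#' @return data.frame of occurrences: `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `score`.
#' @export
pwm_scan <- function(sequences, pwm) {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  L <- pwm$length
  lut_rc <- pwm$lut[4:1, L:1, drop = FALSE]   # reverse complement
  rownames(lut_rc) <- c("A", "C", "G", "T")
  out <- lapply(names(sequences), function(ch) {
    code <- match(strsplit(toupper(sequences[[ch]]), "")[[1]],
                  c("A", "C", "G", "T"))
    res <- list()
    for (st in c("+", "-")) {
      sc <- scan_one_strand(code, if (st == "+") pwm$lut else lut_rc)
      hit <- which(!is.na(sc) & sc >= pwm$threshold)
      if (length(hit))
        res[[st]] <- data.frame(chrom = ch, start = hit - 1,
                                end = hit - 1 + L, strand = st,
                                score = sc[hit])
    }
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      score = numeric()))
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Motif enrichment across region classes
#'
#' For each region class and each motif: N = background regions, K =
#' background regions containing >= 1 occurrence, n = class regions, k =
#' class regions with >= 1 occurrence; upper-tail hypergeometric p,
#' Benjamini-Hochberg q across motifs within a class. This is the
#' known-motif enrichment used to ask which TF dominates each loop class
#' (e.g. CTCF in static loop anchors).
#'
#' @param classes named list of interval data.frames (e.g. loop-anchor sets
#'   split by class).
#' @param occurrences named list of per-motif occurrence data.frames from
#'   [pwm_scan()].
#' @param background interval data.frame containing every class region.
#' @return data.frame with one row per (class, motif).
#' @export
motif_enrichment <- function(classes, occurrences, background) {
  stopifnot(!is.null(names(classes)), !is.null(names(occurrences)))
  bg_key <- with(background, paste(chrom, start, end))
  for (cl in names(classes)) {
    key <- with(classes[[cl]], paste(chrom, start, end))
    if (!all(key %in% bg_key))
      stop("class '", cl, "' is not a subset of the background")
  }
  has_occ <- function(regions, occ) {
    hit <- overlaps(regions, occ)
    seq_len(nrow(regions)) %in% hit$i
  }
  N <- nrow(background)
  rows <- list()
  for (cl in names(classes)) {
    cls <- classes[[cl]]
    n <- nrow(cls)
    ps <- ks <- Ks <- numeric(0)
    for (mo in names(occurrences)) {
      K <- sum(has_occ(background, occurrences[[mo]]))
      k <- sum(has_occ(cls, occurrences[[mo]]))
      Ks[mo] <- K; ks[mo] <- k
      ps[mo] <- hyper_upper(N, K, n, k)
    }
    qs <- stats::p.adjust(ps, method = "BH")
    rows[[cl]] <- data.frame(class = cl, motif = names(occurrences),
                             N = N, K = unname(Ks), n = n, k = unname(ks),
                             p = unname(ps), q = unname(qs))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

peaks_to_bins <- function(peaks, layout) {
  # midpoint bin per peak: (chrom, local bin index)
  mid <- floor((peaks$start + peaks$end) / 2)
  data.frame(chrom = peaks$chrom, bin = local_bin(layout, mid))
}

band_pairs <- function(pb, eb, min_dist, max_dist) {
  # all (promoter x enhancer) same-chromosome bin pairs in the distance band
  res <- lapply(intersect(unique(pb$chrom), unique(eb$chrom)), function(ch) {
    p <- pb$bin[pb$chrom == ch]
    e <- eb$bin[eb$chrom == ch]
    if (!length(p) || !length(e)) return(NULL)
    g <- expand.grid(p = p, e = e)
    d <- abs(g$p - g$e)
    keep <- d >= min_dist & d <= max_dist
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, b1 = pmin(g$p, g$e)[keep],
               b2 = pmax(g$p, g$e)[keep], d = d[keep])
  })
  do.call(rbind, res)
}

pair_values <- function(pairs, mats, expected = NULL) {
  # per-pair contact, distance-normalized (O/E) when expected profiles given
  v <- numeric(nrow(pairs))
  for (ch in unique(pairs$chrom)) {
    sel <- pairs$chrom == ch
    v[sel] <- mats[[ch]]$counts[cbind(pairs$b1[sel], pairs$b2[sel])]
    if (!is.null(expected)) {
      e <- expected[[ch]][abs(pairs$b1[sel] - pairs$b2[sel]) + 1]
      v[sel] <- ifelse(is.finite(e) & e > 0, v[sel] / e, NA_real_)
    }
  }
  v
}

#' Enhancer-promoter spatial-interaction permutation test
#'
#' The statistic is the mean distance-normalized (observed/expected) Hi-C
#' contact over all promoter-peak-bin x enhancer-peak-bin pairs within the
#' distance band. The null redraws `|promoters|` and `|enhancers|` peaks
#' from the universe without replacement `n_perm` times; to remove the
#' distance-decay confounder, pair values are divided by the
#' per-chromosome expected-at-distance profile and both the observed and
#' null statistics are additionally computed as distance-stratum means
#' weighted by the observed stratum frequencies (strata = quantile groups
#' of the observed pair distances). p uses the add-one estimator, so a
#' random selection of the same numbers of enhancer and promoter peaks
#' yields a non-significant, calibrated p.
#'
#' @param mats named list of normalized [contact_matrix()] per chromosome.
#' @param promoters,enhancers peak data.frames (subsets of `universe`).
#' @param universe peak data.frame the null redraws from.
#' @param layout a [genome_layout()].
#' @param n_perm number of permutations (>= 1).
#' @param min_dist_bins,max_dist_bins distance band in bins.
#' @param n_strata number of distance strata.
#' @param seed RNG seed (recorded in the result).
#' @return an [enrichment_result()]; annex `class_pairs` holds the P-P, P-E,
#'   E-E mean-contact summary.
#' @export
ep_interaction_test <- function(mats, promoters, enhancers, universe, layout,
                                n_perm = 1000, min_dist_bins = 4,
                                max_dist_bins = 200, n_strata = 8,
                                seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  ukey <- with(universe, paste(chrom, start, end))
  if (!all(with(promoters, paste(chrom, start, end)) %in% ukey) ||
      !all(with(enhancers, paste(chrom, start, end)) %in% ukey))
    stop("promoters and enhancers must be subsets of the universe")
  pb <- peaks_to_bins(promoters, layout)
  eb <- peaks_to_bins(enhancers, layout)
  ub <- peaks_to_bins(universe, layout)
  obs_pairs <- band_pairs(pb, eb, min_dist_bins, max_dist_bins)
  if (is.null(obs_pairs) || nrow(obs_pairs) == 0) stop("no testable pairs")
  breaks <- unique(stats::quantile(obs_pairs$d, probs = seq(0, 1, length.out =
                                                              n_strata + 1)))
  stratum <- function(d) findInterval(d, breaks, rightmost.closed = TRUE,
                                      all.inside = TRUE)
  obs_pairs$s <- stratum(obs_pairs$d)
  w <- table(factor(obs_pairs$s, levels = seq_len(length(breaks) - 1)))
  w <- as.numeric(w) / sum(w)
  strat_stat <- function(pairs, vals) {
    mu <- tapply(vals, factor(pairs$s, levels = seq_along(w)), mean,
                 na.rm = TRUE)
    ok <- !is.na(mu) & w > 0
    if (!any(ok)) return(NA_real_)
    sum(w[ok] * mu[ok]) / sum(w[ok])
  }
  expected <- lapply(mats, expected_by_distance)
  observed <- strat_stat(obs_pairs, pair_values(obs_pairs, mats, expected))

  nP <- nrow(promoters); nE <- nrow(enhancers); nU <- nrow(universe)
  if (nP + nE > nU) stop("universe smaller than |promoters| + |enhancers|")
  set.seed(seed)
  null_stats <- rep(NA_real_, n_perm)
  for (r in seq_len(n_perm)) {
    pick <- sample.int(nU, nP + nE)
    p0 <- ub[pick[seq_len(nP)], , drop = FALSE]
    e0 <- ub[pick[nP + seq_len(nE)], , drop = FALSE]
    np <- band_pairs(p0, e0, min_dist_bins, max_dist_bins)
    if (is.null(np) || nrow(np) == 0) next
    np$s <- stratum(np$d)
    null_stats[r] <- strat_stat(np, pair_values(np, mats, expected))
  }
  valid <- !is.na(null_stats)
  p <- (1 + sum(null_stats[valid] >= observed)) / (sum(valid) + 1)

  cls <- list(PP = band_pairs(pb, pb, min_dist_bins, max_dist_bins),
              PE = obs_pairs,
              EE = band_pairs(eb, eb, min_dist_bins, max_dist_bins))
  class_pairs <- data.frame(
    pair = names(cls),
    n_pairs = vapply(cls, function(x) if (is.null(x)) 0L else nrow(x),
                     integer(1)),
    mean_contact = vapply(cls, function(x) {
      if (is.null(x) || nrow(x) == 0) return(NA_real_)
      mean(pair_values(x, mats))
    }, numeric(1)))
  rownames(class_pairs) <- NULL
  enrichment_result("permutation", statistic = observed, p = p,
                    null_mean = mean(null_stats[valid]),
                    null_sd = stats::sd(null_stats[valid]),
                    n_perm = sum(valid), seed = seed,
                    class_pairs = class_pairs)
}
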