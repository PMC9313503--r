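# shared fixtures and independent oracles

tiny_layout <- function(lengths = c(chr1 = 10000, chr2 = 10000),
                        bin_size = 5000, sites = NULL) {
  genome_layout(lengths, cut_sites = sites, bin_size = bin_size)
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                             max_len = 500) {
  start <- sample.int(max_pos - max_len, n, replace = TRUE) - 1
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE))
}

# O(n*m) brute-force overlap oracle (half-open)
brute_overlaps <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] &&
        a$start[i] < b$end[j] && b$start[j] < a$end[i])
      out[[length(out) + 1]] <- c(i = i, j = j)
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer()))
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$i, df$j), ]
}

# exhaustive hypergeometric oracle: P(X >= k) by enumeration of all
# n-subsets of a universe of size N with K marked elements
enum_hyper_upper <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(subsets, 2, function(s) sum(s %in% marked))
  mean(hits >= k)
}

# naive per-window PWM rescoring oracle (both strands)
brute_pwm_scan <- function(seq_str, pw) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(toupper(seq_str), "")[[1]]
  L <- pw$length
  out <- list()
  for (p in seq_len(length(chars) - L + 1)) {
    win <- chars[p:(p + L - 1)]
    if (any(!win %in% names(comp))) next
    fwd <- sum(vapply(seq_len(L), function(l) pw$lut[win[l], l], numeric(1)))
    rcwin <- rev(unname(comp[win]))
    rev_sc <- sum(vapply(seq_len(L), function(l) pw$lut[rcwin[l], l],
                         numeric(1)))
    if (fwd >= pw$threshold)
      out[[length(out) + 1]] <- data.frame(start = p - 1, strand = "+",
                                           score = fwd)
    if (rev_sc >= pw$threshold)
      out[[length(out) + 1]] <- data.frame(start = p - 1, strand = "-",
                                           score = rev_sc)
  }
  if (!length(out)) return(data.frame(start = numeric(), strand = character(),
                                      score = numeric()))
  df <- do.call(rbind, out)
  df[order(df$start, df$strand), ]
}

# small deterministic contact matrix with two dense blocks
block_matrix <- function(n = 40, split = 20, hi = 10, lo = 1) {
  m <- matrix(lo, n, n)
  m[1:split, 1:split] <- hi
  m[(split + 1):n, (split + 1):n] <- hi
  diag(m) <- hi * 2
  contact_matrix(m, "chrT", 5000)
}

# decay-only synthetic matrix sampled like Hi-C counts
decay_matrix <- function(n = 200, n_pairs = 2e5, decay = 1,
                         loop_pixels = NULL, loop_fold = 5,
                         chrom = "chrS", bin_size = 5000) {
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  lam <- (1 + D)^(-decay)
  if (!is.null(loop_pixels)) {
    lam[loop_pixels] <- lam[loop_pixels] * loop_fold
    lam[loop_pixels[, c(2, 1), drop = FALSE]] <- lam[loop_pixels]
  }
  ut <- upper.tri(lam, diag = TRUE)
  w <- lam[ut]
  cnt <- stats::rmultinom(1, n_pairs, w / sum(w))
  m <- matrix(0, n, n)
  m[ut] <- cnt
  m <- m + t(m)
  diag(m) <- diag(m) / 2
  contact_matrix(m, chrom, bin_size)
}

small_sim_cfg <- function(seed, ...) {
  args <- list(seed = seed, n_chroms = 2, chrom_length = 5e5,
               n_genes = 400, n_up = 30, n_down = 30, n_peaks = 80,
               n_loops = c(gained = 5, lost = 4, static = 6),
               loop_max_dist_bins = 40, n_pairs = 6e4)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}
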