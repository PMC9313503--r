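#' Per-chromosome binned Hi-C contact matrix
#'
#' @param counts symmetric nonnegative square matrix of binned contacts.
#' @param chrom chromosome name.
#' @param bin_size bin width in bp.
#' @param normalized logical; `TRUE` after [ice_normalize()].
#' @param bias per-bin positive bias vector (`NA` for masked bins) such that
#'   `raw[i,j] = bias[i] * bias[j] * counts[i,j]` when normalized.
#' @return object of class `contact_matrix`.
#' @export
contact_matrix <- function(counts, chrom, bin_size, normalized = FALSE,
                           bias = NULL) {
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts))
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  if (max(abs(counts - t(counts))) > 1e-8 * max(1, max(abs(counts))))
    stop("counts must be symmetric")
  structure(list(counts = counts, chrom = chrom, bin_size = bin_size,
                 normalized = normalized, bias = bias),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", x$chrom, "-", nrow(x$counts), "bins @", x$bin_size,
      "bp,", if (x$normalized) "normalized" else "raw",
      sprintf("(mass %.4g)\n", sum(x$counts)))
  invisible(x)
}

masked_bins <- function(m) {
  if (!is.null(m$bias)) is.na(m$bias) else rowSums(m$counts) == 0
}

raw_counts <- function(m) {
  if (!m$normalized || is.null(m$bias)) return(m$counts)
  b <- m$bias
  b[is.na(b)] <- 1
  m$counts * outer(b, b)
}

# strand-aware distance to the cut site a read points toward:
# '+' reads look downstream (site >= pos), '-' reads upstream (site <= pos).
dist_to_site <- function(sites, pos, strand) {
  if (is.null(sites) || length(sites) == 0L) return(rep(Inf, length(pos)))
  j <- findInterval(pos, sites)               # largest j with sites[j] <= pos
  up <- ifelse(j >= 1, pos - sites[pmax(j, 1)], Inf)
  nxt <- ifelse(j < length(sites),
                sites[pmin(j, length(sites) - 1L) + 1L] - pos, Inf)
  dplus <- ifelse(up == 0, 0, nxt)            # a read starting on a site: distance 0
  ifelse(strand == "-", up, dplus)
}

#' Filter Hi-C read pairs by duplicates and restriction-site proximity
#'
#' Collapses exact duplicate pairs, then keeps a pair only if BOTH reads lie
#' within `max_site_dist` bp upstream of an enzyme cut site, where upstream
#' is relative to the read strand (a `+` read points toward the next site
#' downstream of it, a `-` read toward the previous one). Records on unknown
#' chromosomes are skipped and counted.
#'
#' @param pairs data.frame of pair records (see [read_pairs()]).
#' @param layout a [genome_layout()] carrying cut sites.
#' @param max_site_dist maximum read-to-site distance in bp (default 500).
#' @return list with `pairs` (the kept records, genome-order normalized) and
#'   `report` (input / unknown_chrom / duplicate / site_filtered / kept counts).
#' @export
filter_pairs <- function(pairs, layout, max_site_dist = 500) {
  if (is.null(layout$sites)) stop("layout has no cut sites")
  n_in <- nrow(pairs)
  known <- pairs$chrom1 %in% layout$chroms$name &
    pairs$chrom2 %in% layout$chroms$name
  n_unknown <- sum(!known)
  pairs <- pairs[known, , drop = FALSE]

  # normalize so (chrom1, pos1) <= (chrom2, pos2) in genome order
  ord1 <- match(pairs$chrom1, layout$chroms$name)
  ord2 <- match(pairs$chrom2, layout$chroms$name)
  swap <- ord1 > ord2 | (ord1 == ord2 & pairs$pos1 > pairs$pos2)
  if (any(swap)) {
    for (cols in list(c("chrom1", "chrom2"), c("pos1", "pos2"),
                      c("strand1", "strand2"))) {
      tmp <- pairs[[cols[1]]][swap]
      pairs[[cols[1]]][swap] <- pairs[[cols[2]]][swap]
      pairs[[cols[2]]][swap] <- tmp
    }
  }
  key <- paste(pairs$chrom1, pairs$pos1, pairs$strand1,
               pairs$chrom2, pairs$pos2, pairs$strand2)
  dup <- duplicated(key)
  n_dup <- sum(dup)
  pairs <- pairs[!dup, , drop = FALSE]

  d1 <- d2 <- rep(Inf, nrow(pairs))
  for (ch in unique(c(pairs$chrom1, pairs$chrom2))) {
    s <- layout$sites[[ch]]
    i1 <- pairs$chrom1 == ch
    d1[i1] <- dist_to_site(s, pairs$pos1[i1], pairs$strand1[i1])
    i2 <- pairs$chrom2 == ch
    d2[i2] <- dist_to_site(s, pairs$pos2[i2], pairs$strand2[i2])
  }
  keep <- d1 <= max_site_dist & d2 <= max_site_dist
  report <- list(input = n_in, unknown_chrom = n_unknown, duplicate = n_dup,
                 site_filtered = sum(!keep), kept = sum(keep))
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(pairs = out, report = report)
}

#' Bin read pairs into per-chromosome cis contact matrices
#'
#' Each cis pair increments `counts[i, j]` and `counts[j, i]` (the diagonal
#' once); trans pairs are only counted in the report. The total upper-triangle
#' plus diagonal mass of all matrices equals the number of cis pairs.
#'
#' @param pairs filtered pair records.
#' @param layout a [genome_layout()].
#' @return list with `matrices` (named list of [contact_matrix()]), `n_cis`,
#'   `n_trans`.
#' @export
bin_pairs <- function(pairs, layout) {
  cis <- pairs$chrom1 == pairs$chrom2
  n_trans <- sum(!cis)
  pairs <- pairs[cis, , drop = FALSE]
  nb <- n_bins(layout)
  mats <- lapply(layout$chroms$name, function(ch) {
    n <- nb[[ch]]
    sel <- pairs$chrom1 == ch
    i <- local_bin(layout, pairs$pos1[sel])
    j <- local_bin(layout, pairs$pos2[sel])
    lo <- pmin(i, j); hi <- pmax(i, j)
    tab <- matrix(0, n, n)
    if (length(lo)) {
      cnt <- table((lo - 1) * n + hi)
      idx <- as.integer(names(cnt))
      tab[cbind((idx - 1) %/% n + 1, (idx - 1) %% n + 1)] <- as.numeric(cnt)
    }
    m <- tab + t(tab)
    diag(m) <- diag(tab)
    contact_matrix(m, ch, layout$bin_size)
  })
  names(mats) <- layout$chroms$name
  list(matrices = mats, n_cis = nrow(pairs), n_trans = n_trans)
}

#' Iterative correction (ICE) normalization
#'
#' Iteratively divides the matrix by the outer product of its row marginals
#' (renormalized to mean one over non-masked rows) until the maximum relative
#' marginal deviation drops below `tol`. Bins with zero raw marginal are
#' masked: excluded from the convergence test, `NA` in the bias vector. The
#' factorization identity `raw[i,j] = bias[i] * bias[j] * norm[i,j]` holds on
#' every unmasked pixel.
#'
#' @param m a raw [contact_matrix()].
#' @param tol convergence tolerance on relative marginal deviation.
#' @param max_iter iteration cap.
#' @return a normalized [contact_matrix()] with `bias`.
#' @export
ice_normalize <- function(m, tol = 1e-5, max_iter = 200) {
  cnt <- m$counts
  mask <- rowSums(cnt) == 0
  if (all(mask)) stop("empty matrix")
  n <- nrow(cnt)
  bias <- rep(1, n)
  for (it in seq_len(max_iter)) {
    s <- rowSums(cnt)
    mu <- mean(s[!mask])
    dev <- max(abs(s[!mask] / mu - 1))
    if (dev < tol) break
    b <- s / mu
    b[mask] <- 1
    cnt <- cnt / outer(b, b)
    bias <- bias * b
  }
  bias[mask] <- NA
  contact_matrix(cnt, m$chrom, m$bin_size, normalized = TRUE, bias = bias)
}

#' Mean contact by bin distance
#'
#' `expected[d + 1]` is the raw mean over all pixels at bin distance `d`
#' whose two bins are both unmasked (no smoothing). Length equals the matrix
#' dimension; distances with no valid pixel are `NA`.
#'
#' @param m a [contact_matrix()].
#' @return numeric vector of per-distance means.
#' @export
expected_by_distance <- function(m) {
  cnt <- m$counts
  ok <- !masked_bins(m)
  n <- nrow(cnt)
  vapply(0:(n - 1), function(d) {
    i <- seq_len(n - d)
    v <- cnt[cbind(i, i + d)]
    keep <- ok[i] & ok[i + d]
    if (!any(keep)) return(NA_real_)
    mean(v[keep])
  }, numeric(1))
}

expected_matrix <- function(expected, n) {
  matrix(expected[abs(outer(seq_len(n), seq_len(n), "-")) + 1], n, n)
}

# expected-by-distance stratified into same-label vs cross-label pixel
# classes (e.g. A/A and B/B vs A/B compartment pairs); returns the full
# expected matrix, falling back to the pooled profile where a class is empty
expected_matrix_grouped <- function(m, group) {
  cnt <- m$counts
  ok <- !masked_bins(m)
  n <- nrow(cnt)
  pooled <- expected_by_distance(m)
  same <- outer(group, group, "==")
  E <- matrix(NA_real_, n, n)
  for (cls in c(TRUE, FALSE)) {
    prof <- vapply(0:(n - 1), function(d) {
      i <- seq_len(n - d)
      sel <- ok[i] & ok[i + d] & (same[cbind(i, i + d)] == cls)
      if (!any(sel)) return(pooled[d + 1])
      mean(cnt[cbind(i, i + d)][sel])
    }, numeric(1))
    D <- abs(outer(seq_len(n), seq_len(n), "-"))
    sel <- same == cls
    E[sel] <- prof[D[sel] + 1]
  }
  E
}

#' Call A/B compartments from a normalized contact matrix
#'
#' Computes the observed/expected matrix, its Pearson correlation matrix, and
#' the leading eigenvector; the sign is oriented so that correlation with
#' `orientation_track` (typically per-bin gene or active-peak density) is
#' positive. Positive entries are labeled `A`, negative `B`; masked or
#' degenerate bins are `unassigned`.
#'
#' @param m a normalized [contact_matrix()].
#' @param orientation_track per-bin numeric density used to orient the sign.
#' @return list of class `compartment_track` with `values` (eigenvector,
#'   `NA` where unassigned) and `labels` (`"A"`, `"B"`, `"unassigned"`).
#' @export
call_compartments <- function(m, orientation_track) {
  n <- nrow(m$counts)
  stopifnot(length(orientation_track) == n)
  ok <- !masked_bins(m)
  if (sum(ok) < 10) stop("chromosome too short")
  expected <- expected_by_distance(m)
  E <- expected_matrix(expected, n)
  oe <- m$counts / E
  # the first diagonals carry decay noise, not compartment signal: drop them
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  oe[D <= 2] <- NA
  sub <- oe[ok, ok, drop = FALSE]
  sds <- apply(sub, 2, stats::sd, na.rm = TRUE)
  good <- is.finite(sds) & sds > 0
  values <- rep(NA_real_, n)
  if (sum(good) >= 2) {
    C <- suppressWarnings(stats::cor(sub[good, good, drop = FALSE],
                                     use = "pairwise.complete.obs"))
    C[!is.finite(C)] <- 0
    ev <- eigen(C, symmetric = TRUE)$vectors[, 1]
    track <- orientation_track[ok][good]
    s <- suppressWarnings(stats::cor(ev, track))
    if (!is.na(s) && s < 0) ev <- -ev
    values[which(ok)[good]] <- ev
  }
  labels <- rep("unassigned", n)
  labels[!is.na(values) & values > 0] <- "A"
  labels[!is.na(values) & values < 0] <- "B"
  structure(list(values = values, labels = labels),
            class = "compartment_track")
}

#' Majority-smooth a per-bin label track
#'
#' Compartment labels are megabase-scale by construction; isolated single-bin
#' flips in the eigenvector sign are noise and, fed into a label-stratified
#' expected model, would masquerade as enriched stripes. This replaces each
#' label by the majority over a centered window.
#'
#' @param labels character vector of `"A"`/`"B"`/`"unassigned"` labels.
#' @param k odd window width in bins (default 5).
#' @return smoothed label vector (unassigned bins are left untouched).
#' @export
smooth_labels <- function(labels, k = 5) {
  stopifnot(k %% 2 == 1)
  sgn <- ifelse(labels == "A", 1, ifelse(labels == "B", -1, 0))
  n <- length(sgn)
  h <- (k - 1) / 2
  cs <- cumsum(c(0, sgn))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  winsum <- cs[hi + 1] - cs[lo]
  out <- labels
  assigned <- labels %in% c("A", "B")
  out[assigned & winsum > 0] <- "A"
  out[assigned & winsum < 0] <- "B"
  out
}

#' Call TADs by insulation score
#'
#' The insulation of bin `i` is the mean contact in the square window of
#' `window_bins` upstream x `window_bins` downstream bins across `i`,
#' expressed as log2 relative to the chromosome mean. Boundaries are local
#' minima whose prominence over `+/- delta_bins` exceeds `threshold`; domains
#' are the intervals between consecutive boundaries.
#'
#' @param m a normalized [contact_matrix()].
#' @param window_bins insulation window half-size in bins.
#' @param delta_bins neighborhood for the prominence test.
#' @param threshold minimum prominence (log2 units) for a boundary.
#' @return list of class `tad_set` with `boundaries` (bin indices),
#'   `domains` (data.frame of intervals) and `insulation` (per-bin log2 score).
#' @export
call_tads <- function(m, window_bins = 10, delta_bins = 3, threshold = 0.1) {
  cnt <- m$counts
  n <- nrow(cnt)
  w <- window_bins
  if (2 * w + 1 > n) stop("insulation window larger than chromosome")
  ok <- !masked_bins(m)
  ins <- rep(NA_real_, n)
  for (i in (w + 1):(n - w)) {
    rows <- (i - w):(i - 1)
    cols <- (i + 1):(i + w)
    block <- cnt[rows, cols, drop = FALSE]
    valid <- outer(ok[rows], ok[cols], "&")
    if (any(valid)) ins[i] <- mean(block[valid])
  }
  mu <- mean(ins[is.finite(ins) & ins > 0])
  li <- ifelse(is.finite(ins) & ins > 0, log2(ins / mu), NA_real_)
  boundaries <- integer()
  for (i in seq(w + 1 + delta_bins, n - w - delta_bins)) {
    v <- li[i]
    if (is.na(v)) next
    left <- li[(i - delta_bins):(i - 1)]
    right <- li[(i + 1):(i + delta_bins)]
    if (all(is.na(left)) || all(is.na(right))) next
    if (!is.na(li[i - 1]) && !is.na(li[i + 1]) &&
        v < li[i - 1] && v <= li[i + 1]) {
      prom <- mean(c(max(left, na.rm = TRUE), max(right, na.rm = TRUE))) - v
      if (prom > threshold) boundaries <- c(boundaries, i)
    }
  }
  # suppress runs of adjacent boundary calls: keep the deepest per run
  if (length(boundaries) > 1) {
    runs <- cumsum(c(1, diff(boundaries) > 1))
    boundaries <- vapply(split(boundaries, runs),
                         function(b) b[which.min(li[b])], integer(1))
    boundaries <- unname(sort(boundaries))
  }
  edges <- c(1L, boundaries, n + 1L)
  edges <- unique(edges)
  domains <- data.frame(
    chrom = m$chrom,
    start = (utils::head(edges, -1) - 1) * m$bin_size,
    end = pmin((utils::tail(edges, -1) - 1) * m$bin_size,
               n * m$bin_size))
  structure(list(boundaries = boundaries, domains = domains,
                 insulation = li), class = "tad_set")
}

# summed-area table helper: S[i,j] = sum(x[1:i, 1:j])
sat <- function(x) {
  apply(apply(x, 2, cumsum), 1, cumsum) |> t()
}

sat_query <- function(S, r1, r2, c1, c2) {
  # sum over x[r1:r2, c1:c2], vectorized over equal-length index vectors
  n <- nrow(S)
  g <- function(r, c) {
    v <- S[cbind(pmin(pmax(r, 1), n), pmin(pmax(c, 1), ncol(S)))]
    ifelse(r < 1 | c < 1, 0, v)
  }
  g(r2, c2) - g(r1 - 1, c2) - g(r2, c1 - 1) + g(r1 - 1, c1 - 1)
}

#' Call chromatin loops with a donut local background
#'
#' Tests every pixel in the distance band for focal enrichment over its local
#' background: the expected value is the distance-decay expectation scaled by
#' the local observed/expected level around the pixel, taken as the maximum
#' over a square donut ring (outer half-width `donut_radius`, inner exclusion
#' `inner_radius`) and horizontal/vertical stripe estimators, which keeps the
#' caller robust where the background changes sharply (e.g. at compartment
#' boundaries).
#' Significance is a Poisson upper tail on the raw counts, corrected across
#' all tested pixels by Benjamini-Hochberg; significant pixels are clustered
#' by 8-connectivity and each cluster is reported as one loop at its
#' maximum-enrichment pixel.
#'
#' @param m a normalized [contact_matrix()] carrying a bias vector.
#' @param expected per-distance expected profile from [expected_by_distance()]
#'   of `m` (computed when `NULL`).
#' @param min_dist_bins,max_dist_bins tested distance band (bins).
#' @param donut_radius,inner_radius donut geometry (bins).
#' @param fdr BH threshold on q-values.
#' @param min_donut_pixels minimum valid donut pixels for a testable pixel.
#' @param group optional per-bin labels (e.g. A/B compartment calls); when
#'   given, the expected model is stratified into same-label and
#'   cross-label pixel classes, which removes the compartment checkerboard
#'   from the O/E residual before local-background estimation.
#' @return data.frame of loops: anchors (`chrom`, `bin1`, `bin2`, bp
#'   intervals), `observed` raw count, `expected` local Poisson mean,
#'   `enrichment`, `p`, `q`, `class`.
#' @export
call_loops <- function(m, expected = NULL, min_dist_bins = 4,
                       max_dist_bins = 400, donut_radius = 5,
                       inner_radius = 2, fdr = 0.10, min_donut_pixels = 20,
                       group = NULL) {
  stopifnot(m$normalized, !is.null(m$bias))
  n <- nrow(m$counts)
  if (is.null(expected)) expected <- expected_by_distance(m)
  empty <- data.frame(chrom = character(), bin1 = integer(), bin2 = integer(),
                      start1 = numeric(), end1 = numeric(), start2 = numeric(),
                      end2 = numeric(), observed = numeric(),
                      expected = numeric(), enrichment = numeric(),
                      p = numeric(), q = numeric(), class = character())
  if (min_dist_bins > n - 1 || min_dist_bins > max_dist_bins) return(empty)
  ok <- !masked_bins(m)
  raw <- raw_counts(m)
  E <- if (is.null(group)) expected_matrix(expected, n)
       else expected_matrix_grouped(m, group)
  oe <- m$counts / E
  valid <- outer(ok, ok, "&") & is.finite(oe)
  oe0 <- ifelse(valid, oe, 0)
  S <- sat(oe0)
  V <- sat(valid * 1)

  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  band <- which(D >= min_dist_bins & D <= max_dist_bins & valid &
                  row(D) < col(D))
  if (!length(band)) return(empty)
  i <- (band - 1) %% n + 1
  j <- (band - 1) %/% n + 1
  box <- function(M, r1, r2, c1, c2) {
    sat_query(M, r1, r2, c1, c2) -
      sat_query(M, pmax(r1, i - inner_radius), pmin(r2, i + inner_radius),
                pmax(c1, j - inner_radius), pmin(c2, j + inner_radius))
  }
  # three local background estimators (the pixel sits inside the excluded
  # inner square of each); the final expected is their maximum, which keeps
  # the caller robust at sharp compartment transitions
  ring_sum <- box(S, i - donut_radius, i + donut_radius,
                  j - donut_radius, j + donut_radius)
  ring_n <- box(V, i - donut_radius, i + donut_radius,
                j - donut_radius, j + donut_radius)
  h_sum <- box(S, i - 1, i + 1, j - donut_radius, j + donut_radius)
  h_n <- box(V, i - 1, i + 1, j - donut_radius, j + donut_radius)
  v_sum <- box(S, i - donut_radius, i + donut_radius, j - 1, j + 1)
  v_n <- box(V, i - donut_radius, i + donut_radius, j - 1, j + 1)
  testable <- ring_n >= min_donut_pixels
  i <- i[testable]; j <- j[testable]
  # with a grouped expected model the O/E residual is locally homogeneous
  # and the ring mean suffices (pass majority-smoothed labels, see
  # [smooth_labels()]); otherwise the conservative maximum of the three
  # estimators guards against sharp compartment transitions
  donut_oe <- if (is.null(group)) {
    pmax(ring_sum / ring_n,
         ifelse(h_n > 0, h_sum / h_n, 0),
         ifelse(v_n > 0, v_sum / v_n, 0))[testable]
  } else {
    (ring_sum / ring_n)[testable]
  }
  b <- m$bias
  lambda <- E[cbind(i, j)] * pmax(donut_oe, 0) * b[i] * b[j]
  obs <- raw[cbind(i, j)]
  p <- stats::ppois(obs - 1, lambda, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  enr <- m$counts[cbind(i, j)] / (E[cbind(i, j)] * pmax(donut_oe, 1e-12))
  sig <- which(q <= fdr & obs > 0 & enr > 1)
  if (!length(sig)) return(empty)

  # cluster significant pixels by 8-connectivity
  si <- i[sig]; sj <- j[sig]
  key <- paste(si, sj)
  comp <- rep(NA_integer_, length(sig))
  lookup <- stats::setNames(seq_along(sig), key)
  cid <- 0L
  for (k in seq_along(sig)) {
    if (!is.na(comp[k])) next
    cid <- cid + 1L
    queue <- k
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[cur])) next
      comp[cur] <- cid
      nbkey <- paste(rep(si[cur] + (-1:1), 3), rep(sj[cur] + (-1:1), each = 3))
      hit <- lookup[nbkey]
      queue <- c(queue, unname(hit[!is.na(hit) & is.na(comp[hit])]))
    }
  }
  picks <- vapply(split(seq_along(sig), comp), function(idx) {
    idx[which.max(enr[sig][idx])]
  }, integer(1))
  sel <- sig[picks]
  bs <- m$bin_size
  out <- data.frame(chrom = m$chrom, bin1 = i[sel], bin2 = j[sel],
                    start1 = (i[sel] - 1) * bs, end1 = i[sel] * bs,
                    start2 = (j[sel] - 1) * bs, end2 = j[sel] * bs,
                    observed = obs[sel], expected = lambda[sel],
                    enrichment = enr[sel], p = p[sel], q = q[sel],
                    class = "unclassified")
  out <- out[order(out$bin1, out$bin2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call loops across all chromosomes
#' @param mats named list of normalized [contact_matrix()] objects.
#' @param ... passed to [call_loops()].
#' @param groups optional named list of per-bin label vectors per chromosome.
#' @return combined loop data.frame.
#' @export
call_loops_all <- function(mats, ..., groups = NULL) {
  out <- do.call(rbind, lapply(names(mats), function(ch) {
    call_loops(mats[[ch]], ..., group = groups[[ch]])
  }))
  rownames(out) <- NULL
  out
}

loop_pixel_ratio <- function(loops, mats_num, mats_den, scale_num, scale_den) {
  vapply(seq_len(nrow(loops)), function(r) {
    ch <- loops$chrom[r]
    a <- raw_counts(mats_num[[ch]])[loops$bin1[r], loops$bin2[r]]
    b <- raw_counts(mats_den[[ch]])[loops$bin1[r], loops$bin2[r]]
    ((a + 0.5) * scale_num) / ((b + 0.5) * scale_den)
  }, numeric(1))
}

#' Classify loops as gained, lost or static between two conditions
#'
#' Loops are matched across conditions when both anchors agree within
#' `match_tol_bins`. Matched loops are `static`. A post-only loop whose
#' post/pre contact ratio at the loop pixel (raw counts scaled to equal total
#' cis mass, half-count pseudocount) reaches `fc_thresh` is `gained`; the
#' mirror case is `lost`; remaining unmatched loops are `unclassified`.
#'
#' @param loops_pre,loops_post loop data.frames from [call_loops_all()].
#' @param mats_pre,mats_post named lists of the condition matrices.
#' @param match_tol_bins anchor match tolerance (bins).
#' @param fc_thresh fold-change threshold for gained/lost.
#' @return list with `pre`, `post` (inputs with `class` and `ratio` set) and
#'   `combined` (one record per loop; matched pairs reported once, from post).
#' @export
classify_loops <- function(loops_pre, loops_post, mats_pre, mats_post,
                           match_tol_bins = 1, fc_thresh = 1.5) {
  bs_pre <- unique(vapply(mats_pre, function(m) m$bin_size, numeric(1)))
  bs_post <- unique(vapply(mats_post, function(m) m$bin_size, numeric(1)))
  if (!identical(bs_pre, bs_post)) stop("bin-size mismatch between conditions")
  mass <- function(mats) sum(vapply(mats, function(m) {
    r <- raw_counts(m)
    sum(r[upper.tri(r, diag = TRUE)])
  }, numeric(1)))
  tot_pre <- mass(mats_pre); tot_post <- mass(mats_post)

  match_of <- function(a, b) {
    # for each loop in a, first loop in b with both anchors within tolerance
    vapply(seq_len(nrow(a)), function(r) {
      hit <- which(b$chrom == a$chrom[r] &
                     abs(b$bin1 - a$bin1[r]) <= match_tol_bins &
                     abs(b$bin2 - a$bin2[r]) <= match_tol_bins)
      if (length(hit)) hit[[1]] else NA_integer_
    }, integer(1))
  }
  m_pre <- match_of(loops_pre, loops_post)
  m_post <- match_of(loops_post, loops_pre)

  loops_pre$class <- ifelse(!is.na(m_pre), "static", "unclassified")
  loops_post$class <- ifelse(!is.na(m_post), "static", "unclassified")
  loops_post$ratio <- loop_pixel_ratio(loops_post, mats_post, mats_pre,
                                       1 / tot_post, 1 / tot_pre)
  loops_pre$ratio <- loop_pixel_ratio(loops_pre, mats_pre, mats_post,
                                      1 / tot_pre, 1 / tot_post)
  gain <- is.na(m_post) & loops_post$ratio >= fc_thresh
  loops_post$class[gain] <- "gained"
  lost <- is.na(m_pre) & loops_pre$ratio >= fc_thresh
  loops_pre$class[lost] <- "lost"

  combined <- rbind(loops_post,
                    loops_pre[is.na(m_pre), , drop = FALSE])
  rownames(combined) <- NULL
  list(pre = loops_pre, post = loops_post, combined = combined)
}

#' Anchor intervals of a loop set
#' @param loops loop data.frame.
#' @param pad bp added on each side of every anchor.
#' @return data.frame of anchor intervals with the source loop index and class.
#' @export
loop_anchors <- function(loops, pad = 0) {
  if (nrow(loops) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      loop = integer(), class = character()))
  out <- data.frame(
    chrom = rep(loops$chrom, 2),
    start = pmax(0, c(loops$start1, loops$start2) - pad),
    end = c(loops$end1, loops$end2) + pad,
    loop = rep(seq_len(nrow(loops)), 2),
    class = rep(if (is.null(loops$class)) "unclassified" else loops$class, 2))
  rownames(out) <- NULL
  out
}
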