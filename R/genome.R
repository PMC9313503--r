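#' Genome coordinate frame
#'
#' A `genome_layout` bundles the chromosome table, the restriction cut-site
#' positions and the working bin size. It is the coordinate frame every other
#' stage (binning, normalization, peak statistics, simulation) refers to.
#' All coordinates in the package are 0-based, half-open (BED convention).
#'
#' @param chrom_sizes data.frame with columns `name`, `length` (bp), or a
#'   named numeric vector of chromosome lengths. Order is preserved and
#'   defines the global bin index.
#' @param cut_sites named list (per chromosome) of sorted cut-site positions
#'   in bp, or `NULL` when no restriction-site filtering is needed.
#' @param bin_size bin width in bp (default 5000, the resolution used for
#'   high-resolution loop maps).
#' @return an object of class `genome_layout`.
#' @export
genome_layout <- function(chrom_sizes, cut_sites = NULL, bin_size = 5000L) {
  if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes))) {
    chrom_sizes <- data.frame(name = names(chrom_sizes),
                              length = as.numeric(chrom_sizes))
  }
  stopifnot(is.data.frame(chrom_sizes),
            all(c("name", "length") %in% names(chrom_sizes)))
  chrom_sizes$name <- as.character(chrom_sizes$name)
  if (anyDuplicated(chrom_sizes$name))
    stop("duplicated chromosome names")
  if (any(chrom_sizes$length <= 0))
    stop("chromosome lengths must be > 0")
  if (length(bin_size) != 1L || bin_size <= 0)
    stop("bin_size must be > 0")
  if (!is.null(cut_sites)) {
    if (is.null(names(cut_sites)) || !all(names(cut_sites) %in% chrom_sizes$name))
      stop("cut_sites must be a named list keyed by chromosome name")
    for (ch in names(cut_sites)) {
      s <- cut_sites[[ch]]
      len <- chrom_sizes$length[chrom_sizes$name == ch]
      if (length(s) && (is.unsorted(s, strictly = TRUE) || any(s < 0) || any(s >= len)))
        stop("cut sites for ", ch, " must be strictly increasing and within [0, length)")
    }
  }
  structure(list(chroms = chrom_sizes[, c("name", "length")],
                 sites = cut_sites,
                 bin_size = as.numeric(bin_size)),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", nrow(x$chroms), "chromosome(s),",
      format(sum(x$chroms$length), big.mark = ","), "bp, bin size",
      x$bin_size, "bp\n")
  invisible(x)
}

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chroms$name)
  if (anyNA(i)) stop("unknown chromosome: ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  layout$chroms$length[i]
}

#' Number of bins per chromosome
#' @param layout a [genome_layout()].
#' @return named integer vector, `ceil(length / bin_size)` per chromosome.
#' @export
n_bins <- function(layout) {
  stats::setNames(as.integer(ceiling(layout$chroms$length / layout$bin_size)),
                  layout$chroms$name)
}

#' Tile the genome into bins
#'
#' Bins tile each chromosome left to right in chromosome-table order; the
#' last bin of a chromosome may be short. The global `index` column is
#' 1-based and stable: chromosome order then genomic position.
#'
#' @param layout a [genome_layout()].
#' @return data.frame with columns `chrom`, `start`, `end`, `index`.
#' @export
make_bins <- function(layout) {
  nb <- n_bins(layout)
  out <- do.call(rbind, lapply(seq_len(nrow(layout$chroms)), function(i) {
    len <- layout$chroms$length[i]
    k <- nb[i]
    start <- (seq_len(k) - 1) * layout$bin_size
    data.frame(chrom = layout$chroms$name[i], start = start,
               end = pmin(start + layout$bin_size, len))
  }))
  out$index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

bin_offsets <- function(layout) {
  nb <- n_bins(layout)
  stats::setNames(c(0L, cumsum(nb))[seq_along(nb)], names(nb))
}

#' Map positions to global bin indices
#' @param layout a [genome_layout()].
#' @param chrom,pos vectors of chromosome names and 0-based positions.
#' @return 1-based global bin indices (see [make_bins()]).
#' @export
bin_index <- function(layout, chrom, pos) {
  chrom_length(layout, chrom)                 # validates names
  off <- bin_offsets(layout)
  as.integer(off[chrom] + pos %/% layout$bin_size + 1)
}

local_bin <- function(layout, pos) as.integer(pos %/% layout$bin_size + 1)

# internal: data.frame intervals -> IRanges (0-based half-open -> 1-based closed)
as_iranges <- function(x) IRanges::IRanges(start = x$start + 1L, end = x$end)

#' All overlapping interval pairs between two collections
#'
#' Reports every index pair `(i, j)` such that `a[i, ]` and `b[j, ]` share at
#' least one base (half-open semantics: `[0,100)` and `[100,200)` do not
#' overlap). Output is sorted by `i` then `j`.
#'
#' @param a,b data.frames with columns `chrom`, `start`, `end`.
#' @param layout optional [genome_layout()]; when given, unknown chromosome
#'   names raise an error naming the chromosome.
#' @return data.frame with columns `i`, `j` (row indices into `a` and `b`).
#' @export
overlaps <- function(a, b, layout = NULL) {
  if (!is.null(layout)) {
    bad <- setdiff(unique(c(a$chrom, b$chrom)), layout$chroms$name)
    if (length(bad)) stop("unknown chromosome: ", paste(bad, collapse = ", "))
  }
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(i = integer(), j = integer()))
  res <- lapply(intersect(unique(a$chrom), unique(b$chrom)), function(ch) {
    ia <- which(a$chrom == ch); ib <- which(b$chrom == ch)
    hits <- IRanges::findOverlaps(as_iranges(a[ia, ]), as_iranges(b[ib, ]))
    data.frame(i = ia[S4Vectors::queryHits(hits)],
               j = ib[S4Vectors::subjectHits(hits)])
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(data.frame(i = integer(), j = integer()))
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strand-aware transcription start sites
#' @param genes data.frame with `start`, `end`, `strand` (TSS = `start` on
#'   `+`/`.`, `end - 1` on `-`).
#' @return numeric vector of 0-based TSS positions.
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "-", genes$end - 1, genes$start)
}

#' Classify peaks as promoter or intergenic
#'
#' A peak is tagged `promoter` iff it overlaps the promoter window
#' `[tss - window, tss + window)` of any gene (the two clusters used to split
#' TF binding sites into promoter-bound and intergenic/enhancer-bound);
#' otherwise `intergenic`. The tag is binary: a peak spanning several
#' promoters is still one promoter peak.
#'
#' @param peaks data.frame of peaks (`chrom`, `start`, `end`, ...).
#' @param genes data.frame of genes (`chrom`, `start`, `end`, `strand`, ...).
#' @param window half-width of the promoter window in bp (default 1000,
#'   i.e. +/- 1 kb around the TSS).
#' @return `peaks` with a `class` column set to `"promoter"`/`"intergenic"`.
#' @export
classify_peaks <- function(peaks, genes, window = 1000) {
  stopifnot(window > 0)
  peaks$class <- rep("intergenic", nrow(peaks))
  if (nrow(genes) == 0L) {
    warning("empty gene collection: all peaks tagged intergenic")
    return(peaks)
  }
  tss <- gene_tss(genes)
  prom <- data.frame(chrom = genes$chrom,
                     start = pmax(0, tss - window), end = tss + window)
  hit <- overlaps(peaks, prom)
  peaks$class[unique(hit$i)] <- "promoter"
  peaks
}

#' Top-scoring peaks
#'
#' Returns the `k` highest-score peaks (e.g. "top 5000" reference peaks for
#' colocalization heatmaps). Ties are broken by chromosome name then start so
#' the result is deterministic; if `k` exceeds the set, all peaks return.
#'
#' @param peaks data.frame with a `score` column.
#' @param k number of peaks to keep (>= 1).
#' @return the selected rows of `peaks`.
#' @export
top_k_peaks <- function(peaks, k) {
  stopifnot(k >= 1)
  ord <- order(-peaks$score, peaks$chrom, peaks$start, peaks$end)
  out <- peaks[ord[seq_len(min(k, nrow(peaks)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}
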