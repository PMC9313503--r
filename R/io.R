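#' @importFrom rtracklayer import
#' @importFrom utils read.table write.table
NULL

# GRanges -> 0-based half-open data.frame
granges_to_df <- function(gr, score = FALSE) {
  out <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                    start = BiocGenerics::start(gr) - 1L,
                    end = BiocGenerics::end(gr))
  md <- S4Vectors::mcols(gr)
  if ("name" %in% names(md)) out$name <- as.character(md$name)
  if ("score" %in% names(md)) out$score <- as.numeric(md$score)
  st <- as.character(BiocGenerics::strand(gr))
  st[st == "*"] <- "."
  out$strand <- st
  out
}

#' Read a BED3/BED6 file of peaks or intervals
#'
#' Coordinates stay in the native BED convention (0-based half-open).
#' @param path file path.
#' @return data.frame with `chrom`, `start`, `end` and, when present in the
#'   file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  granges_to_df(gr)
}

#' Write intervals/peaks as BED
#' @param x data.frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  cols <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                     name = if (!is.null(x$name)) x$name else ".",
                     score = if (!is.null(x$score)) x$score else 0,
                     strand = if (!is.null(x$strand)) x$strand else ".")
  write.table(cols, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene table (BED6: chrom, start, end, name, score, strand)
#' @param path file path.
#' @return data.frame with a strand-aware `tss` column added.
#' @export
read_genes <- function(path) {
  g <- read_bed(path)
  if (is.null(g$name) || is.null(g$strand))
    stop("gene table must be BED6 with name and strand")
  g$tss <- gene_tss(g)
  g
}

#' Read a two-column chromosome sizes file
#' @param path TSV with columns name, length (no header).
#' @return data.frame with `name`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  x <- read.table(path, sep = "\t", col.names = c("name", "length"),
                  colClasses = c("character", "numeric"))
  x
}

#' Read restriction cut sites (TSV: chrom, position)
#' @param path file path.
#' @return named list of sorted positions per chromosome.
#' @export
read_cut_sites <- function(path) {
  x <- read.table(path, sep = "\t", col.names = c("chrom", "pos"),
                  colClasses = c("character", "numeric"))
  lapply(split(x$pos, x$chrom), sort)
}

#' Write cut sites as a two-column TSV
#' @param sites named list of positions per chromosome.
#' @param path output path.
#' @export
write_cut_sites <- function(sites, path) {
  df <- data.frame(chrom = rep(names(sites), lengths(sites)),
                   pos = unlist(sites, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

pairs_cols <- c("read_id", "chrom1", "pos1", "chrom2", "pos2",
                "strand1", "strand2")

#' Read Hi-C read pairs (.pairs-like TSV)
#'
#' Columns: readID, chrom1, pos1, chrom2, pos2, strand1, strand2.
#' Lines starting with `#` are header/comment lines and are skipped.
#' @param path file path.
#' @return data.frame with columns `read_id`, `chrom1`, `pos1`, `chrom2`,
#'   `pos2`, `strand1`, `strand2`.
#' @export
read_pairs <- function(path) {
  read.table(path, sep = "\t", comment.char = "#", col.names = pairs_cols,
             colClasses = c("character", "character", "numeric", "character",
                            "numeric", "character", "character"))
}

#' Write Hi-C read pairs
#' @param pairs data.frame as returned by [read_pairs()].
#' @param path output path.
#' @export
write_pairs <- function(pairs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("## pairs format v1.0", con)
  writeLines(paste0("#columns: readID chrom1 pos1 chrom2 pos2 strand1 strand2"), con)
  write.table(pairs[, pairs_cols], con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#' @param path file path.
#' @return data.frame with `chrom`, `start`, `end`, `value` (0-based half-open).
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             value = as.numeric(S4Vectors::mcols(gr)$score))
}

#' Write a bedGraph signal track
#' @param track data.frame with `chrom`, `start`, `end`, `value`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  write.table(track[, c("chrom", "start", "end", "value")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

loop_cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
               "name", "enrichment", "p", "q", "class")

#' Write loops as BEDPE with enrichment/p/q/class extra columns
#' @param loops loop data.frame (see [call_loops()]).
#' @param path output path.
#' @export
write_loops_bedpe <- function(loops, path) {
  df <- data.frame(chrom1 = loops$chrom, start1 = loops$start1,
                   end1 = loops$end1, chrom2 = loops$chrom,
                   start2 = loops$start2, end2 = loops$end2,
                   name = if (is.null(loops$name))
                     sprintf("loop_%d", seq_len(nrow(loops))) else loops$name,
                   enrichment = loops$enrichment, p = loops$p, q = loops$q,
                   class = if (is.null(loops$class)) "unclassified" else loops$class)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read loops from BEDPE (with enrichment/p/q/class extra columns)
#' @param path file path.
#' @return loop data.frame with anchor intervals and statistics.
#' @export
read_loops_bedpe <- function(path) {
  x <- read.table(path, sep = "\t", col.names = loop_cols,
                  colClasses = c("character", "numeric", "numeric", "character",
                                 "numeric", "numeric", "character", "numeric",
                                 "numeric", "numeric", "character"))
  if (!all(x$chrom1 == x$chrom2)) stop("trans loops are not supported")
  data.frame(chrom = x$chrom1, start1 = x$start1, end1 = x$end1,
             start2 = x$start2, end2 = x$end2, name = x$name,
             enrichment = x$enrichment, p = x$p, q = x$q, class = x$class)
}

#' Read an expression matrix (TSV, first column gene names, header = samples)
#' @param path file path.
#' @return numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                  check.names = FALSE)
  as.matrix(x)
}

#' Write an expression matrix
#' @param mat genes x samples matrix.
#' @param path output path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-condition map (TSV: sample, condition)
#' @param path file path.
#' @return named character vector, condition keyed by sample.
#' @export
read_condition_map <- function(path) {
  x <- read.table(path, sep = "\t", col.names = c("sample", "condition"),
                  colClasses = "character")
  stats::setNames(x$condition, x$sample)
}

#' Read gene sets in GMT format
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Read a TF-target relation table (TSV: tf, target[, weight])
#'
#' Duplicate (tf, target) pairs are collapsed to one record.
#' @param path file path.
#' @return data.frame with `tf`, `target` and optional `weight`.
#' @export
read_tf_table <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, fill = TRUE,
                  colClasses = "character")
  names(x) <- c("tf", "target", "weight")[seq_len(ncol(x))]
  if (!is.null(x$weight)) {
    x$weight <- suppressWarnings(as.numeric(x$weight))
  }
  x[!duplicated(x[, c("tf", "target")]), , drop = FALSE]
}

#' Read position weight matrices in JASPAR text format
#'
#' Parses records of the form `>ID NAME` followed by four lines
#' `A [ counts... ]` etc. Counts are converted to column probabilities.
#' @param path file path.
#' @param background base frequencies (A, C, G, T), default uniform.
#' @param threshold_frac log-odds threshold as a fraction of the maximum
#'   attainable score (default 0.8).
#' @return named list of `pwm` objects (see [pwm()]).
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), threshold_frac = 0.8) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  out <- list()
  for (h in seq_along(heads)) {
    name <- sub("^>\\S*\\s*", "", lines[heads[h]])
    if (!nzchar(name)) name <- sub("^>", "", lines[heads[h]])
    block <- lines[(heads[h] + 1):(heads[h] + 4)]
    rows <- lapply(block, function(l) {
      v <- strsplit(gsub("^[ACGT]\\s*\\[?|\\]", "", l), "\\s+")[[1]]
      as.numeric(v[nzchar(v)])
    })
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    probs <- sweep(m, 2, colSums(m), "/")
    out[[name]] <- pwm(name, probs, background = background,
                       threshold_frac = threshold_frac)
  }
  out
}
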