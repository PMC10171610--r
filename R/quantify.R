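#' Construct an insert-locus table
#'
#' Insert loci are the genomic footprints of the cloned plasmid inserts,
#' one per gene. Coordinates are 0-based half-open throughout the package
#' (BED convention).
#'
#' @param gene_id Unique gene identifiers.
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open interval bounds (`end > start`).
#' @return A data.frame with columns gene_id, chrom, start, end, length.
#' @export
insert_loci <- function(gene_id, chrom, start, end) {
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("locus set must not be empty", call. = FALSE)
  if (anyDuplicated(df$gene_id)) {
    stop("`gene_id` must be unique within a locus set", call. = FALSE)
  }
  if (any(df$end <= df$start)) {
    stop("locus intervals require end > start", call. = FALSE)
  }
  df$length <- df$end - df$start
  df
}

#' Construct a read-interval table
#'
#' @param read_id Read identifiers.
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open aligned interval bounds.
#' @return A data.frame with columns read_id, chrom, start, end.
#' @export
read_intervals <- function(read_id, chrom, start, end) {
  df <- data.frame(read_id = as.character(read_id),
                   chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (any(df$end <= df$start)) {
    stop("read intervals require end > start", call. = FALSE)
  }
  df
}

#' Count reads on insert loci by minimum-locus-fraction overlap
#'
#' A read is assigned to a locus when they share a chromosome and the overlap
#' covers at least `min_locus_fraction` of the LOCUS length (inclusive at the
#' threshold), mirroring interval intersection with a minimum fraction of the
#' B feature. Strand is ignored. A read overlapping several qualifying loci is
#' counted once for each of them.
#'
#' @param reads A data.frame from [read_intervals()] (may have zero rows).
#' @param loci A data.frame from [insert_loci()].
#' @param min_locus_fraction Minimum overlap as a fraction of the locus
#'   length, in (0, 1]; default 0.5.
#' @return Named integer vector of read counts, one per locus, in locus order.
#' @export
#' @examples
#' loci <- insert_loci("YFG1", "chrI", 100, 200)
#' reads <- read_intervals(c("r1", "r2"), "chrI", c(90, 100), c(210, 140))
#' assign_reads_to_loci(reads, loci)  # r1 covers the locus, r2 only 40%
assign_reads_to_loci <- function(reads, loci, min_locus_fraction = 0.5) {
  if (is.null(loci) || nrow(loci) == 0L) {
    stop("locus set must not be empty", call. = FALSE)
  }
  if (!is.numeric(min_locus_fraction) || length(min_locus_fraction) != 1L ||
      is.na(min_locus_fraction) || min_locus_fraction <= 0 ||
      min_locus_fraction > 1) {
    stop("`min_locus_fraction` must be in (0, 1]", call. = FALSE)
  }
  counts <- stats::setNames(integer(nrow(loci)), loci$gene_id)
  if (is.null(reads) || nrow(reads) == 0L) return(counts)

  # 0-based half-open -> 1-based closed for IRanges; shared seqlevels so
  # pairwise operations need no seqinfo merging
  chroms <- union(unique(reads$chrom), unique(loci$chrom))
  gr_reads <- GenomicRanges::GRanges(
    factor(reads$chrom, levels = chroms),
    IRanges::IRanges(reads$start + 1, reads$end))
  gr_loci <- GenomicRanges::GRanges(
    factor(loci$chrom, levels = chroms),
    IRanges::IRanges(loci$start + 1, loci$end))
  hits <- GenomicRanges::findOverlaps(gr_reads, gr_loci,
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) return(counts)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(gr_reads[q],
                                                       gr_loci[s]))
  keep <- ov >= min_locus_fraction * GenomicRanges::width(gr_loci)[s]
  tallied <- tabulate(s[keep], nbins = nrow(loci))
  stats::setNames(as.integer(tallied), loci$gene_id)
}

#' Convert read counts to reads per million (RPM)
#'
#' Occupancy of each insert in a sample: `rpm_i = 1e6 * count_i / sum(counts)`.
#' The denominator is the reads assigned to any locus in that sample, so each
#' column sums to one million.
#'
#' @param counts Non-negative numeric vector, or a genes x samples matrix.
#' @return Object of the same shape as `counts` with RPM values.
#' @export
rpm_normalize <- function(counts) {
  if (is.matrix(counts)) {
    if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
    totals <- colSums(counts)
    zero <- totals == 0
    if (any(zero)) {
      labs <- colnames(counts)[zero]
      if (is.null(labs)) labs <- which(zero)
      stop("sample(s) with zero assigned reads: ",
           paste(labs, collapse = ", "), call. = FALSE)
    }
    return(sweep(counts, 2, totals / 1e6, "/"))
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total == 0) {
    stop("sample with zero assigned reads: ",
         if (is.null(names(counts))) "(unnamed)" else "(all genes zero)",
         call. = FALSE)
  }
  1e6 * counts / total
}

#' Library coverage at RPM thresholds
#'
#' Fraction of genes detected at or above each RPM threshold, per sample; the
#' standard coverage summary for a pooled library (filled bars at RPM >= 10,
#' open bars at RPM >= 1 in the usual display).
#'
#' @param rpm Genes x samples RPM matrix (or vector for one sample).
#' @param thresholds RPM thresholds; default `c(1, 10)`.
#' @return Data.frame with columns sample, threshold, fraction.
#' @export
coverage_stats <- function(rpm, thresholds = c(1, 10)) {
  if (!is.matrix(rpm)) rpm <- matrix(rpm, ncol = 1,
                                     dimnames = list(names(rpm), "sample1"))
  if (any(rpm < 0)) stop("RPM values must be non-negative", call. = FALSE)
  samples <- colnames(rpm)
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(rpm)))
  out <- expand.grid(sample = samples, threshold = sort(thresholds),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$fraction <- mapply(function(s, thr) {
    mean(rpm[, match(s, samples)] >= thr)
  }, out$sample, out$threshold)
  rownames(out) <- NULL
  out
}

#' Insert-length read-detection bias diagnostic
#'
#' Pearson correlation between insert length and per-gene read count, per
#' sample. Long inserts of a multicopy plasmid tend to yield fewer reads, so a
#' clearly negative correlation flags a detection bias that the fold-change
#' normalisation (same insert in numerator and denominator) absorbs.
#'
#' @param counts Genes x samples count (or RPM) matrix, or a vector;
#'   rownames/names must match `loci$gene_id`.
#' @param loci Locus table from [insert_loci()] providing `length`.
#' @return Data.frame per sample: `r` (Pearson), `p_negative` (one-sided
#'   p-value for r < 0), `n` genes used, and `undefined` flag set when the
#'   correlation is degenerate (constant lengths or counts, or n < 3).
#' @export
length_bias_diagnostic <- function(counts, loci) {
  if (!is.matrix(counts)) {
    counts <- matrix(counts, ncol = 1,
                     dimnames = list(names(counts), "sample1"))
  }
  if (is.null(rownames(counts))) {
    if (nrow(counts) != nrow(loci)) {
      stop("unnamed counts must align row-for-row with `loci`", call. = FALSE)
    }
    rownames(counts) <- loci$gene_id
  }
  common <- intersect(rownames(counts), loci$gene_id)
  if (length(common) < 3L) {
    stop("need at least 3 genes shared between counts and loci",
         call. = FALSE)
  }
  len <- loci$length[match(common, loci$gene_id)]
  samples <- colnames(counts)
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(counts)))
  res <- lapply(seq_along(samples), function(j) {
    x <- counts[common, j]
    if (sum(x > 0) < 3L || stats::sd(len) == 0 || stats::sd(x) == 0) {
      return(data.frame(sample = samples[j], r = NA_real_,
                        p_negative = NA_real_, n = length(common),
                        undefined = TRUE, stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(len, x, alternative = "less", method = "pearson")
    data.frame(sample = samples[j], r = unname(ct$estimate),
               p_negative = ct$p.value, n = length(common),
               undefined = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "genes") <- common
  out
}
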