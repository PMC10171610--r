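# Independent oracles used to cross-check the implementation.

# All-pairs interval assignment: count a read for a locus iff same chrom and
# overlap >= frac * locus length.
brute_force_assign <- function(reads, loci, frac = 0.5) {
  counts <- stats::setNames(integer(nrow(loci)), loci$gene_id)
  if (is.null(reads) || nrow(reads) == 0L) return(counts)
  for (j in seq_len(nrow(loci))) {
    llen <- loci$end[j] - loci$start[j]
    ov <- pmin(reads$end, loci$end[j]) - pmax(reads$start, loci$start[j])
    counts[j] <- sum(reads$chrom == loci$chrom[j] & ov >= frac * llen)
  }
  counts
}

# Direct step-up Benjamini-Hochberg evaluation.
bh_step_up <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Textbook Pearson chi-square on a 2x2 table via sum((O - E)^2 / E).
pearson_2x2 <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  e <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  sum((obs - e)^2 / e)
}

random_intervals_case <- function(n_reads, n_loci, n_chrom = 3) {
  loci_start <- sample.int(1000, n_loci, replace = TRUE)
  loci <- insert_loci(
    gene_id = sprintf("L%03d", seq_len(n_loci)),
    chrom = sample(paste0("chr", seq_len(n_chrom)), n_loci, replace = TRUE),
    start = loci_start,
    end = loci_start + sample.int(200, n_loci, replace = TRUE)
  )
  rs <- sample.int(1200, n_reads, replace = TRUE)
  reads <- read_intervals(
    read_id = sprintf("r%04d", seq_len(n_reads)),
    chrom = sample(paste0("chr", seq_len(n_chrom)), n_reads, replace = TRUE),
    start = rs,
    end = rs + sample.int(250, n_reads, replace = TRUE)
  )
  list(reads = reads, loci = loci)
}
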