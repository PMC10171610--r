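#' Hit-calling thresholds
#'
#' Hits are genes whose insert occupancy rose at least 2^5 = 32-fold over the
#' competitive culture with a Benjamini-Hochberg FDR of at most 0.05, both
#' inclusive.
#'
#' @param log2fc_threshold Minimum log2 fold change (default 5).
#' @param fdr_threshold Maximum FDR (default 0.05), in (0, 1).
#' @return Object of class `hit_call_config`.
#' @export
hit_call_config <- function(log2fc_threshold = 5, fdr_threshold = 0.05) {
  if (!is.numeric(log2fc_threshold) || length(log2fc_threshold) != 1L ||
      !is.finite(log2fc_threshold)) {
    stop("`log2fc_threshold` must be a single finite number", call. = FALSE)
  }
  if (!is.numeric(fdr_threshold) || length(fdr_threshold) != 1L ||
      !is.finite(fdr_threshold) || fdr_threshold <= 0 || fdr_threshold >= 1) {
    stop("`fdr_threshold` must be in (0, 1)", call. = FALSE)
  }
  structure(list(log2fc_threshold = log2fc_threshold,
                 fdr_threshold = fdr_threshold),
            class = "hit_call_config")
}

#' Occupancy fold change between initial and cultured pools
#'
#' `FC_i = RPM_after_i / RPM_before_i`. Genes absent from the initial pool
#' (zero baseline RPM) have no defined fold change and are marked
#' `excluded_zero_baseline`; genes that drop to zero get `fc = 0` and
#' `log2fc = -Inf`.
#'
#' @param rpm0 Baseline (initial pool) RPM, vector.
#' @param rpmn Post-culture RPM, vector of the same length.
#' @return Data.frame with columns rpm0, rpmn, fc, log2fc, status.
#' @export
fold_change <- function(rpm0, rpmn) {
  if (length(rpm0) != length(rpmn)) {
    stop("`rpm0` and `rpmn` must have equal length", call. = FALSE)
  }
  if (any(rpm0 < 0) || any(rpmn < 0)) {
    stop("RPM values must be non-negative", call. = FALSE)
  }
  excluded <- rpm0 == 0
  fc <- ifelse(excluded, NA_real_, rpmn / rpm0)
  log2fc <- ifelse(excluded, NA_real_,
                   ifelse(rpmn == 0, -Inf, log2(rpmn / rpm0)))
  out <- data.frame(rpm0 = rpm0, rpmn = rpmn, fc = fc, log2fc = log2fc,
                    status = ifelse(excluded, "excluded_zero_baseline", "ok"),
                    stringsAsFactors = FALSE)
  if (!is.null(names(rpm0))) rownames(out) <- names(rpm0)
  out
}

#' Chi-square test of a gene's share before vs after culture
#'
#' Pearson chi-square (1 df) on the 2x2 table of read counts
#' `[[gene_before, other_before], [gene_after, other_after]]`: did the focal
#' gene's share of the pool change over the competitive culture? No
#' continuity correction by default (counts are large); `correct = TRUE`
#' applies Yates' correction. All four arguments are vectorised over genes.
#'
#' @param count_gene_0,count_other_0 Reads on the focal gene and on all other
#'   loci in the baseline sample.
#' @param count_gene_n,count_other_n Same for the post-culture sample.
#' @param correct Apply Yates' continuity correction (default `FALSE`).
#' @return Data.frame with columns statistic, p, degenerate. A zero row or
#'   column total gives `p = 1` with `degenerate = TRUE`.
#' @export
chisq_before_after <- function(count_gene_0, count_other_0,
                               count_gene_n, count_other_n,
                               correct = FALSE) {
  a <- as.numeric(count_gene_0); b <- as.numeric(count_other_0)
  cc <- as.numeric(count_gene_n); d <- as.numeric(count_other_n)
  if (any(c(a, b, cc, d) < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  n <- a + b + cc + d
  r1 <- a + b; r2 <- cc + d
  c1 <- a + cc; c2 <- b + d
  degenerate <- r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0
  num <- abs(a * d - b * cc)
  if (correct) num <- pmax(num - n / 2, 0)
  stat <- ifelse(degenerate, NA_real_, n * num^2 / (r1 * r2 * c1 * c2))
  # keep p strictly positive: the chi-square tail underflows to 0 for the
  # extreme statistics a selective sweep produces
  p <- ifelse(degenerate, 1,
              pmax(stats::pchisq(stat, df = 1, lower.tail = FALSE),
                   .Machine$double.xmin))
  data.frame(statistic = stat, p = p, degenerate = degenerate)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up BH adjustment of a p-value vector (wrapper around
#' [stats::p.adjust()]), kept as the single FDR entry point so every stage of
#' the pipeline adjusts identically.
#'
#' @param p Vector of p-values in (0, 1]; may be empty.
#' @return Adjusted values of the same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-replicate fold-change and test table
#'
#' Combines [fold_change()], [chisq_before_after()] and [bh_adjust()] for one
#' replicate: RPM-normalises the two count vectors, computes fold changes,
#' tests each non-excluded gene's share before vs after, and adjusts p-values
#' across the tested genes of this replicate.
#'
#' @param counts0,countsn Named integer count vectors (baseline and
#'   post-culture) on the same genes.
#' @param correct Passed to [chisq_before_after()].
#' @return Data.frame (one row per gene) with rpm0, rpmn, fc, log2fc, status,
#'   statistic, p, fdr. Excluded genes carry NA test fields.
#' @export
fold_change_table <- function(counts0, countsn, correct = FALSE) {
  if (length(counts0) != length(countsn)) {
    stop("count vectors must have equal length", call. = FALSE)
  }
  if (!is.null(names(counts0)) && !is.null(names(countsn))) {
    if (!identical(names(counts0), names(countsn))) {
      countsn <- countsn[names(counts0)]
      if (any(is.na(countsn))) {
        stop("count vectors must cover the same genes", call. = FALSE)
      }
    }
  }
  rpm0 <- rpm_normalize(counts0)
  rpmn <- rpm_normalize(countsn)
  out <- fold_change(rpm0, rpmn)
  out$count0 <- as.numeric(counts0)
  out$countn <- as.numeric(countsn)
  tot0 <- sum(counts0); totn <- sum(countsn)
  test <- chisq_before_after(out$count0, tot0 - out$count0,
                             out$countn, totn - out$countn,
                             correct = correct)
  out$statistic <- test$statistic
  out$p <- test$p
  out$fdr <- NA_real_
  tested <- out$status == "ok"
  out$fdr[tested] <- bh_adjust(out$p[tested])
  out
}

#' Call hits from a fold-change table
#'
#' A gene is a hit when `log2fc >= log2fc_threshold` and
#' `fdr <= fdr_threshold`, both inclusive. Genes excluded for a zero baseline
#' are never hits.
#'
#' @param fold_changes Data.frame from [fold_change_table()] (needs columns
#'   log2fc, fdr, status).
#' @param config A [hit_call_config()].
#' @return The input with a logical `hit` column; the hit gene ids are in
#'   `attr(, "hits")`.
#' @export
call_hits <- function(fold_changes, config = hit_call_config()) {
  stopifnot(inherits(config, "hit_call_config"))
  need <- c("log2fc", "fdr", "status")
  if (!all(need %in% names(fold_changes))) {
    stop("`fold_changes` must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  hit <- fold_changes$status == "ok" &
    !is.na(fold_changes$log2fc) & !is.na(fold_changes$fdr) &
    fold_changes$log2fc >= config$log2fc_threshold &
    fold_changes$fdr <= config$fdr_threshold
  fold_changes$hit <- hit
  attr(fold_changes, "hits") <- rownames(fold_changes)[hit]
  fold_changes
}
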