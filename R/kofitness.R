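#' Knockout relative-fitness Z-scores for one replicate
#'
#' Relative fitness is the standard-normalised fold change of barcode
#' abundance across the competitive culture: for each gene,
#' `x_i = log2(RPM_after_i / RPM_before_i)` and
#' `z_i = (x_i - mean(x)) / sd(x)`, with mean and sample (n-1) standard
#' deviation taken over the genes tested in that replicate. Genes with zero
#' counts in either sample have no defined log fold change and are dropped
#' from the replicate. A raw-ratio standardisation (`log_ratio = FALSE`) is
#' available but heavy-tailed and not recommended.
#'
#' @param counts_before,counts_after Named count vectors for the replicate.
#' @param log_ratio Standardise the log2 ratio (default) or the raw ratio.
#' @return Data.frame with columns gene, x (the standardised quantity) and z;
#'   `attr(, "degenerate")` is `TRUE` when all fold changes are equal (then
#'   all z are 0).
#' @export
#' @examples
#' z <- fitness_z(c(a = 100, b = 100, c = 100), c(a = 50, b = 100, c = 200))
fitness_z <- function(counts_before, counts_after, log_ratio = TRUE) {
  if (is.null(names(counts_before)) || is.null(names(counts_after))) {
    stop("count vectors must be named by gene", call. = FALSE)
  }
  common <- intersect(names(counts_before), names(counts_after))
  cb <- counts_before[common]
  ca <- counts_after[common]
  if (sum(cb) <= 0 || sum(ca) <= 0) {
    stop("both samples must contain reads", call. = FALSE)
  }
  keep <- cb > 0 & ca > 0
  if (sum(keep) < 2L) {
    stop("fewer than 2 genes detected in both samples", call. = FALSE)
  }
  rpm_b <- rpm_normalize(cb)[keep]
  rpm_a <- rpm_normalize(ca)[keep]
  ratio <- rpm_a / rpm_b
  x <- if (log_ratio) log2(ratio) else ratio
  s <- stats::sd(x)
  degenerate <- !is.finite(s) || s == 0
  z <- if (degenerate) rep(0, length(x)) else (x - mean(x)) / s
  out <- data.frame(gene = common[keep], x = x, z = z,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "degenerate") <- degenerate
  out
}

#' Welch's two-sample t-test (vectorised closed form)
#'
#' Mean difference over the pooled standard error with Welch-Satterthwaite
#' degrees of freedom, two-sided. Implemented in closed form so it vectorises
#' over the thousands of genes of a screen; identical samples give t = 0,
#' p = 1.
#'
#' @param x,y Numeric matrices (genes x replicates) or vectors.
#' @return Data.frame with columns t, df, p (one row per gene).
#' @export
welch_t <- function(x, y) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (!is.matrix(y)) y <- matrix(y, nrow = 1)
  if (nrow(x) != nrow(y)) {
    stop("`x` and `y` must cover the same genes", call. = FALSE)
  }
  nx <- ncol(x); ny <- ncol(y)
  if (nx < 2L || ny < 2L) {
    stop("Welch's t-test needs at least 2 replicates per group",
         call. = FALSE)
  }
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- apply(x, 1L, stats::var); vy <- apply(y, 1L, stats::var)
  se2 <- vx / nx + vy / ny
  t <- ifelse(se2 == 0, 0, (mx - my) / sqrt(se2))
  df <- ifelse(se2 == 0, nx + ny - 2,
               se2^2 / (vx^2 / (nx^2 * (nx - 1)) + vy^2 / (ny^2 * (ny - 1))))
  p <- ifelse(se2 == 0, 1, 2 * stats::pt(-abs(t), df))
  data.frame(t = t, df = df, p = p)
}

align_z_matrix <- function(z_tables) {
  genes <- Reduce(intersect, lapply(z_tables, `[[`, "gene"))
  if (length(genes) == 0L) {
    stop("replicates share no tested genes", call. = FALSE)
  }
  m <- vapply(z_tables, function(tb) tb$z[match(genes, tb$gene)],
              numeric(length(genes)))
  rownames(m) <- genes
  m
}

#' Between-condition fitness screen on Z-scores
#'
#' Screens for genes whose relative fitness differs between two conditions:
#' per gene, Welch's t-test compares the replicate Z-scores of condition A
#' against condition B; p-values are BH-adjusted across genes; a gene passes
#' when `fdr <= fdr_threshold` and `delta_z = mean_z_A - mean_z_B` is at most
#' `delta_z_threshold` (both inclusive). The defaults (-1, 0.05) select genes
#' whose knockout is at least one standard score less fit in A than in B.
#'
#' @param z_a,z_b Lists of per-replicate Z tables (from [fitness_z()]) or
#'   genes x replicates Z matrices, for conditions A and B; genes are aligned
#'   on the intersection across all replicates.
#' @param delta_z_threshold Screen threshold on `mean_z_A - mean_z_B`
#'   (default -1).
#' @param fdr_threshold FDR cut-off (default 0.05).
#' @return Data.frame per gene: mean_z_a, mean_z_b, delta_z, t, df, p, fdr,
#'   pass.
#' @export
delta_z_screen <- function(z_a, z_b, delta_z_threshold = -1,
                           fdr_threshold = 0.05) {
  as_matrix <- function(z) {
    if (is.matrix(z)) return(z)
    if (is.list(z) && all(vapply(z, is.data.frame, logical(1)))) {
      return(align_z_matrix(z))
    }
    stop("z inputs must be matrices or lists of fitness_z tables",
         call. = FALSE)
  }
  ma <- as_matrix(z_a)
  mb <- as_matrix(z_b)
  if (ncol(ma) < 2L || ncol(mb) < 2L) {
    stop("need at least 2 replicates in each condition", call. = FALSE)
  }
  genes <- intersect(rownames(ma), rownames(mb))
  if (length(genes) == 0L) stop("no shared genes", call. = FALSE)
  ma <- ma[genes, , drop = FALSE]
  mb <- mb[genes, , drop = FALSE]
  wt <- welch_t(ma, mb)
  out <- data.frame(
    gene = genes,
    mean_z_a = rowMeans(ma),
    mean_z_b = rowMeans(mb),
    t = wt$t, df = wt$df, p = wt$p,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$delta_z <- out$mean_z_a - out$mean_z_b
  out$fdr <- bh_adjust(pmin(pmax(out$p, .Machine$double.xmin), 1))
  out$pass <- out$fdr <= fdr_threshold & out$delta_z <= delta_z_threshold
  out
}

#' Classify genes by their salt-vs-rich fitness contrast
#'
#' Group I genes are knockouts whose relative fitness is at least one
#' standard score better under salt than in rich medium
#' (`Z_Na - Z_YPD >= 1`, typically because the knockout is slow in rich
#' medium already); Group II are at least one score worse
#' (`Z_Na - Z_YPD <= -1`); everything else is "other". Thresholds are
#' inclusive, and the classification can be restricted to a gene subset
#' (e.g. mitochondrial genes).
#'
#' @param mean_z_na,mean_z_ypd Named vectors of per-gene mean Z-scores under
#'   the two conditions.
#' @param gene_subset Optional gene ids to classify; others are dropped.
#' @param threshold Contrast magnitude defining the groups (default 1).
#' @return Data.frame per gene: z_na, z_ypd, contrast, group (factor with
#'   levels GroupI, GroupII, other).
#' @export
classify_groups <- function(mean_z_na, mean_z_ypd, gene_subset = NULL,
                            threshold = 1) {
  if (is.null(names(mean_z_na)) || is.null(names(mean_z_ypd))) {
    stop("mean Z vectors must be named by gene", call. = FALSE)
  }
  genes <- intersect(names(mean_z_na), names(mean_z_ypd))
  if (!is.null(gene_subset)) genes <- intersect(genes, gene_subset)
  if (length(genes) == 0L) {
    stop("no genes with Z-scores in both conditions", call. = FALSE)
  }
  contrast <- mean_z_na[genes] - mean_z_ypd[genes]
  group <- ifelse(contrast >= threshold, "GroupI",
                  ifelse(contrast <= -threshold, "GroupII", "other"))
  data.frame(
    gene = genes,
    z_na = unname(mean_z_na[genes]),
    z_ypd = unname(mean_z_ypd[genes]),
    contrast = unname(contrast),
    group = factor(group, levels = c("GroupI", "GroupII", "other")),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
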