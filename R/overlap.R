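#' Permutation test for replicate overlap of hit genes
#'
#' Are hits shared by several replicates more often than chance would allow?
#' The null redraws each replicate's hit set uniformly without replacement
#' from the gene universe, preserving that replicate's hit count, and tallies
#' how many genes are hit in exactly k of the R replicates. The one-sided
#' p-value for each category k is the proportion of permutations whose
#' exactly-k count is at least the observed count. When no permutation
#' reaches the observed count the p-value is reported as an upper bound
#' `< 1/n_permutations` (no pseudo-count by default; `plus_one = TRUE`
#' switches to the (b+1)/(m+1) estimator).
#'
#' The universe should be the genes testable in the experiment (those with a
#' defined fold change), since hits can only arise there; pass the full gene
#' set explicitly to override.
#'
#' @param hit_sets List of R (>= 2) character or integer vectors, the hit
#'   genes of each replicate.
#' @param universe Either the universe size (single integer) or the vector of
#'   all testable gene ids; every hit set must be contained in it.
#' @param n_permutations Number of permutations (default 10000).
#' @param seed Seed for reproducibility.
#' @param category `"exact"` (default) counts genes hit in exactly k
#'   replicates, matching the 1/4, 2/4, ... 4/4 presentation; `"at_least"`
#'   counts genes hit in k or more, as a sensitivity variant.
#' @param plus_one Use the add-one permutation p estimator (default `FALSE`).
#' @return Object of class `overlap_perm`: a list with `table` (data.frame
#'   k, observed, p, p_upper_bound), `null_counts` (n_permutations x R
#'   matrix), `n_replicates`, `n_permutations`, `universe_size`, `category`,
#'   `seed`.
#' @export
#' @examples
#' sets <- list(c("A", "B"), c("A", "C"), c("A", "D"))
#' overlap_permutation_test(sets, universe = 50, n_permutations = 1000,
#'                          seed = 1)
overlap_permutation_test <- function(hit_sets, universe,
                                     n_permutations = 10000L, seed = NULL,
                                     category = c("exact", "at_least"),
                                     plus_one = FALSE) {
  category <- match.arg(category)
  R <- length(hit_sets)
  if (R < 2L) stop("need at least 2 replicate hit sets", call. = FALSE)
  assert_scalar_number(n_permutations, "n_permutations", lower = 1)
  n_permutations <- as.integer(n_permutations)

  if (length(universe) == 1L && is.numeric(universe)) {
    N <- as.integer(universe)
    ids <- NULL
  } else {
    ids <- unique(as.character(universe))
    N <- length(ids)
  }
  hit_sets <- lapply(hit_sets, function(s) unique(as.character(s)))
  sizes <- lengths(hit_sets)
  if (any(sizes > N)) {
    stop("a hit set is larger than the universe", call. = FALSE)
  }
  if (!is.null(ids) && !all(unlist(hit_sets) %in% ids)) {
    stop("all hit genes must belong to the universe", call. = FALSE)
  }

  # observed genes-per-overlap-category
  tab <- table(unlist(hit_sets))
  observed_exact <- tabulate(as.integer(tab), nbins = R)

  null_counts <- with_seed(seed, {
    m <- matrix(0L, nrow = n_permutations, ncol = R)
    for (b in seq_len(n_permutations)) {
      draws <- unlist(lapply(sizes, function(sz) sample.int(N, sz)))
      occ <- tabulate(draws, nbins = N)
      m[b, ] <- tabulate(occ[occ > 0L], nbins = R)
    }
    m
  })

  to_cat <- function(x) {
    if (category == "exact") x else rev(cumsum(rev(x)))
  }
  obs <- to_cat(observed_exact)
  null_cat <- t(apply(null_counts, 1L, to_cat))
  if (R == 1L) null_cat <- matrix(null_cat, ncol = 1L)

  exceed <- vapply(seq_len(R), function(k) sum(null_cat[, k] >= obs[k]),
                   integer(1))
  if (plus_one) {
    p <- (exceed + 1) / (n_permutations + 1)
    upper <- rep(FALSE, R)
  } else {
    upper <- exceed == 0L
    p <- ifelse(upper, 1 / n_permutations, exceed / n_permutations)
  }

  structure(
    list(
      table = data.frame(k = seq_len(R), observed = obs, p = p,
                         p_upper_bound = upper),
      null_counts = null_cat,
      n_replicates = R,
      n_permutations = n_permutations,
      universe_size = N,
      category = category,
      seed = seed
    ),
    class = "overlap_perm"
  )
}

#' @export
print.overlap_perm <- function(x, ...) {
  cat(sprintf(
    "Replicate-overlap permutation test (%d replicates, universe %d, %d permutations)\n",
    x$n_replicates, x$universe_size, x$n_permutations))
  lab <- if (x$category == "exact") "exactly" else "at least"
  for (i in seq_len(nrow(x$table))) {
    row <- x$table[i, ]
    pstr <- if (row$p_upper_bound) {
      sprintf("p < %g", 1 / x$n_permutations)
    } else {
      sprintf("p = %.4g", row$p)
    }
    cat(sprintf("  hit in %s %d/%d: observed %d, %s\n",
                lab, row$k, x$n_replicates, row$observed, pstr))
  }
  invisible(x)
}

#' Gini-Simpson diversity index
#'
#' `D = 1 - sum(p_i^2)`: the probability that two reads drawn at random come
#' from different strains. 0 for a single-strain pool; at most `1 - 1/N` for
#' N strains (attained by the uniform pool). Counts are normalised to
#' frequencies automatically.
#'
#' @param x Non-negative frequencies (summing to 1) or raw counts, vector or
#'   genes x samples matrix (per-column result).
#' @return A single diversity value, or one per column for a matrix.
#' @export
#' @examples
#' gini_simpson(rep(1, 4))            # 0.75 = 1 - 1/4
#' gini_simpson(c(0.5, 0.25, 0.25))   # 0.625
gini_simpson <- function(x) {
  if (is.matrix(x)) {
    return(apply(x, 2L, gini_simpson))
  }
  if (any(x < 0) || any(!is.finite(x))) {
    stop("frequencies/counts must be finite and non-negative", call. = FALSE)
  }
  s <- sum(x)
  if (s <= 0) stop("all-zero input has no defined diversity", call. = FALSE)
  p <- x / s
  1 - sum(p^2)
}
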