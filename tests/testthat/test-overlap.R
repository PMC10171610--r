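test_that("gini-simpson matches its closed forms", {
  expect_equal(gini_simpson(rep(1, 4)), 0.75)            # 1 - 1/N
  expect_equal(gini_simpson(c(5, 0, 0)), 0)              # single strain
  expect_equal(gini_simpson(c(0.5, 0.25, 0.25)), 0.625)
  expect_equal(gini_simpson(c(10, 30, 60)),
               1 - (0.1^2 + 0.3^2 + 0.6^2), tolerance = 1e-12)
  for (N in c(2, 7, 100)) {
    expect_equal(gini_simpson(rep(3, N)), 1 - 1 / N, tolerance = 1e-12)
  }
  # agreement with the ecology reference implementation
  set.seed(29)
  x <- as.numeric(stats::rmultinom(1, 5000, stats::runif(30)))
  expect_equal(gini_simpson(x), unname(vegan::diversity(x, "simpson")),
               tolerance = 1e-12)
  expect_error(gini_simpson(c(0, 0)), "all-zero")
  expect_error(gini_simpson(c(-1, 2)), "non-negative")
  # columnwise over a matrix
  m <- cbind(a = c(1, 1, 1, 1), b = c(4, 0, 0, 0))
  expect_equal(unname(gini_simpson(m)), c(0.75, 0))
})

test_that("diversity is maximal at uniformity and drops as mass concentrates", {
  set.seed(31)
  for (i in 1:20) {
    N <- sample(3:50, 1)
    p <- as.numeric(stats::rmultinom(1, 1000, rep(1 / N, N))) / 1000
    expect_lte(gini_simpson(p), 1 - 1 / N + 1e-12)
    # move mass from a lighter to the heaviest class: diversity decreases
    q <- p
    hi <- which.max(q)
    lo <- which(q == min(q[q > 0]))[1]
    if (hi != lo && q[lo] > 0) {
      shift <- q[lo] / 2
      q[hi] <- q[hi] + shift; q[lo] <- q[lo] - shift
      expect_lt(gini_simpson(q), gini_simpson(p))
    }
  }
})

test_that("diversity declines through a simulated selective sweep", {
  n <- 300
  w <- rep(1, n); w[1] <- 1.5
  cfg <- simulation_config(n_genes = n, fitness = w, initial_cells = 1e6,
                           n_passages = 4, read_depth = 1e5)
  mean_div <- Reduce(`+`, lapply(1:5, function(s) {
    states <- simulate_competition(cfg, seed = 600 + s)
    vapply(states, function(st) {
      gini_simpson(simulate_reads(st, cfg, seed = 700 + s)$counts)
    }, numeric(1))
  })) / 5
  expect_true(all(diff(mean_div) <= 1e-3))
  expect_lt(mean_div[5], mean_div[1] - 0.1)
})

test_that("permutation test validates inputs and is seed-reproducible", {
  sets <- list(c("A", "B"), c("B", "C"))
  expect_error(overlap_permutation_test(sets[1], universe = 10),
               "at least 2")
  expect_error(overlap_permutation_test(sets, universe = 1), "larger than")
  expect_error(overlap_permutation_test(sets, universe = c("A", "B")),
               "belong to the universe")
  a <- overlap_permutation_test(sets, universe = 20, n_permutations = 500,
                                seed = 1)
  b <- overlap_permutation_test(sets, universe = 20, n_permutations = 500,
                                seed = 1)
  expect_identical(a$table, b$table)
  expect_identical(sum(a$table$observed), 3L)  # distinct genes hit
})

test_that("two-replicate permutation p matches the hypergeometric closed form", {
  N <- 60
  set.seed(41)
  ids <- sprintf("g%02d", 1:N)
  s1 <- ids[1:10]
  s2 <- ids[c(1:4, 30:40)]  # overlap of 4, |s2| = 15
  res <- overlap_permutation_test(list(s1, s2), universe = ids,
                                  n_permutations = 5000, seed = 2)
  obs2 <- res$table$observed[2]
  expect_identical(obs2, 4L)
  p_exact <- stats::phyper(obs2 - 1, 10, N - 10, 15, lower.tail = FALSE)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 5000)
  expect_lt(abs(res$table$p[2] - p_exact), 3 * mc_se + 1e-12)

  # disjoint sets: the exactly-1 category sits at its null ceiling, so its
  # p-value equals the null probability of drawing no collision at all --
  # essentially 1 when the universe dwarfs the hit sets
  big <- sprintf("G%04d", 1:5000)
  d <- overlap_permutation_test(list(big[1:2], big[3:4]), universe = big,
                                n_permutations = 1000, seed = 3)
  expect_identical(d$table$observed[1], 4L)
  expect_gte(d$table$p[1], 0.99)
})

test_that("three replicates sharing one gene give the analytic 1e-4 p-value", {
  res <- overlap_permutation_test(list("G1", "G1", "G1"), universe = 100,
                                  n_permutations = 20000, seed = 4)
  expect_identical(res$table$observed[3], 1L)
  # analytic p = (1/100)^2; permutation estimate within 3 MC SE
  p_exact <- 1e-4
  mc_se <- sqrt(p_exact * (1 - p_exact) / 20000)
  expect_lt(abs(res$table$p[3] - p_exact), 3 * mc_se + 1e-12)
})

test_that("at-least-k sensitivity variant accumulates the exact categories", {
  sets <- list(c("A", "B", "C"), c("A", "B"), c("A", "D"))
  ex <- overlap_permutation_test(sets, universe = 30, n_permutations = 100,
                                 seed = 5)
  al <- overlap_permutation_test(sets, universe = 30, n_permutations = 100,
                                 seed = 5, category = "at_least")
  expect_identical(al$table$observed, rev(cumsum(rev(ex$table$observed))))
  expect_identical(al$table$observed[1], 4L)  # every distinct hit gene
})

test_that("null-drawn hit sets give super-uniform permutation p-values", {
  n_datasets <- 150
  R <- 3; N <- 150; sizes <- c(10, 15, 20)
  set.seed(51)
  ids <- sprintf("g%03d", 1:N)
  frac_sig <- matrix(NA, n_datasets, R)
  for (d in seq_len(n_datasets)) {
    sets <- lapply(sizes, function(sz) sample(ids, sz))
    res <- overlap_permutation_test(sets, universe = ids,
                                    n_permutations = 200)
    frac_sig[d, ] <- res$table$p <= 0.05
  }
  bound <- 0.05 + 2 * sqrt(0.05 * 0.95 / n_datasets)
  for (k in 1:R) {
    expect_lte(mean(frac_sig[, k]), bound)
  }
})
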