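test_that("overlap-fraction read assignment handles the boundary cases", {
  loci <- insert_loci("YFG1", "chrI", 100, 200)
  count_of <- function(rs, re) {
    reads <- read_intervals("r1", "chrI", rs, re)
    assign_reads_to_loci(reads, loci)[["YFG1"]]
  }
  expect_identical(count_of(90, 210), 1L)   # full cover: overlap 100/100
  expect_identical(count_of(100, 140), 0L)  # 40/100 < 0.5
  expect_identical(count_of(100, 150), 1L)  # exactly 50%: inclusive
  # same coordinates on another chromosome never match
  reads <- read_intervals("r1", "chrII", 90, 210)
  expect_identical(assign_reads_to_loci(reads, loci)[["YFG1"]], 0L)
  # a read covering two adjacent loci at >= 50% counts for both
  loci2 <- insert_loci(c("A", "B"), "chrI", c(0, 100), c(100, 200))
  reads2 <- read_intervals("r1", "chrI", 40, 160)
  expect_identical(unname(assign_reads_to_loci(reads2, loci2)), c(1L, 1L))

  expect_error(assign_reads_to_loci(reads, loci[0, ]), "empty")
  expect_identical(unname(assign_reads_to_loci(reads[0, ], loci)), 0L)
  expect_error(assign_reads_to_loci(reads, loci, min_locus_fraction = 0),
               "min_locus_fraction")
})

test_that("read assignment agrees with the all-pairs brute-force oracle", {
  set.seed(101)
  for (case in 1:200) {
    inst <- random_intervals_case(n_reads = sample(0:80, 1),
                                  n_loci = sample(1:25, 1))
    frac <- sample(c(0.25, 0.5, 0.75, 1), 1)
    expect_identical(
      assign_reads_to_loci(inst$reads, inst$loci, frac),
      brute_force_assign(inst$reads, inst$loci, frac)
    )
  }
})

test_that("RPM normalisation is exact, scale-invariant, and guards zeros", {
  expect_equal(unname(rpm_normalize(c(10, 30, 60))),
               c(100000, 300000, 600000))
  expect_equal(unname(rpm_normalize(5)), 1e6)
  expect_error(rpm_normalize(c(0, 0, 0)), "zero assigned reads")
  m <- matrix(c(1, 2, 3, 0, 0, 0), ncol = 2,
              dimnames = list(NULL, c("ok", "bad")))
  expect_error(rpm_normalize(m), "bad")

  set.seed(2)
  counts <- rpois(50, 40) + 1
  expect_equal(rpm_normalize(counts), rpm_normalize(counts * 17))
  expect_equal(sum(rpm_normalize(counts)), 1e6)
  mm <- matrix(rpois(200, 30) + 1, ncol = 4,
               dimnames = list(NULL, paste0("s", 1:4)))
  expect_equal(unname(colSums(rpm_normalize(mm))), rep(1e6, 4))
})

test_that("coverage fractions are correct and monotone in the threshold", {
  # uniform pool: everything at RPM 1e6/N >= 1 for N <= 1e6
  rpm <- rpm_normalize(rep(1, 100))
  cs <- coverage_stats(matrix(rpm, dimnames = list(NULL, list("u"))))
  expect_equal(cs$fraction, c(1, 1))
  # one strain at 100%, 99 at zero
  rpm2 <- c(1e6, rep(0, 99))
  cs2 <- coverage_stats(matrix(rpm2, dimnames = list(NULL, list("mono"))))
  expect_equal(cs2$fraction, c(0.01, 0.01))
  # monotone non-increasing over random samples
  set.seed(3)
  rpm3 <- rpm_normalize(matrix(rpois(500, 5), ncol = 5,
                               dimnames = list(NULL, paste0("s", 1:5))))
  cs3 <- coverage_stats(rpm3, thresholds = c(1, 10, 100))
  for (s in unique(cs3$sample)) {
    fr <- cs3$fraction[cs3$sample == s][order(cs3$threshold[cs3$sample == s])]
    expect_true(all(diff(fr) <= 0))
  }
})

test_that("length-bias diagnostic separates biased from unbiased sampling", {
  n <- 120
  set.seed(7)
  lens <- stats::runif(n, 300, 8000)
  loci <- insert_loci(sprintf("g%03d", 1:n), "chrI",
                      start = seq(0, by = 10000, length.out = n),
                      end = seq(0, by = 10000, length.out = n) + lens)
  cfg0 <- simulation_config(n_genes = n, gene_ids = loci$gene_id,
                            initial_cells = 1e6, n_passages = 0,
                            read_depth = 1e5, insert_lengths = lens)
  st <- simulate_competition(cfg0)[[1]]

  # unbiased sampling: the one-sided negative-correlation test should stay
  # non-significant in almost all seeds
  sig <- vapply(1:40, function(s) {
    cts <- simulate_reads(st, cfg0, seed = 300 + s)$counts
    length_bias_diagnostic(cts, loci)$p_negative < 0.05
  }, logical(1))
  expect_lte(mean(sig), 0.10)

  # biased sampling: r < 0
  cfgL <- cfg0
  cfgL$length_bias_rate <- 2e-4
  ctsL <- simulate_reads(st, cfgL, seed = 12)$counts
  diagL <- length_bias_diagnostic(ctsL, loci)
  expect_lt(diagL$r, 0)
  expect_false(diagL$undefined)

  # constant lengths: undefined, not an error
  lociC <- insert_loci(sprintf("g%03d", 1:n), "chrI",
                       start = loci$start, end = loci$start + 1000)
  diagC <- length_bias_diagnostic(ctsL, lociC)
  expect_true(diagC$undefined)
  expect_true(is.na(diagC$r))

  expect_error(length_bias_diagnostic(ctsL[1:2], loci[1:2, ]), "at least 3")
})

test_that("quantified reads recover the simulated pool composition", {
  n <- 80
  w <- rep(1, n); w[5] <- 1.25
  cfg <- simulation_config(n_genes = n, fitness = w, initial_cells = 1e6,
                           n_passages = 2, read_depth = 2e5)
  states <- simulate_competition(cfg, seed = 21)
  final <- states[[3]]
  smp <- simulate_reads(final, cfg, seed = 22)
  truth <- final$abundances / sum(final$abundances)
  gof <- suppressWarnings(stats::chisq.test(smp$counts, p = truth))
  expect_gt(gof$p.value, 0.001)
  rpm <- rpm_normalize(smp$counts)
  expect_equal(unname(rpm / 1e6), unname(truth), tolerance = 0.05)
})
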