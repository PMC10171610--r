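test_that("config validation rejects degenerate or unsafe settings", {
  expect_error(simulation_config(fitness = c(-0.1, rep(1, 5750))),
               "non-negative")
  expect_error(simulation_config(n_genes = 3, fitness = c(1, NA, 1)),
               "finite")
  expect_error(simulation_config(dilution = 1.2), "dilution")
  expect_error(simulation_config(initial_cells = Inf, mutation_rate = 1e-6),
               "expectation mode")
  expect_error(simulation_config(n_genes = 2, gene_ids = c("a", "a")),
               "unique")
  # default passage design: dilution * 2^g == 1 (regrowth to saturation)
  cfg <- simulation_config(n_genes = 10)
  expect_equal(cfg$dilution * 2^cfg$generations_per_passage, 1,
               tolerance = 1e-12)
})

test_that("expected post-growth shares match the closed form on toy pools", {
  # two genes, w = (1.5, 1.0), g = 8, one passage, expectation mode:
  # share_1 = 2^(8*0.5) / (2^(8*0.5) + 1) = 16/17
  cfg <- simulation_config(n_genes = 2, initial_cells = Inf,
                           dilution = 1 / 256, n_passages = 1,
                           fitness = c(1.5, 1.0))
  st <- simulate_competition(cfg)
  expect_length(st, 2L)
  expect_equal(unname(st[[2]]$abundances), c(16 / 17, 1 / 17),
               tolerance = 1e-12)

  # 4-gene pool, unequal start, heterogeneous fitness, 3 passages: compare
  # against the closed form n_i * 2^(P * g * w_i) evaluated directly
  w <- c(1.2, 1.0, 0.8, 1.05)
  n0 <- c(10, 20, 30, 40)
  cfg4 <- simulation_config(n_genes = 4, initial_cells = Inf,
                            dilution = 1 / 256, n_passages = 3, fitness = w)
  st4 <- simulate_competition(cfg4, initial_abundances = n0 / sum(n0))
  expected <- n0 * 2^(3 * 8 * w)
  expected <- expected / sum(expected)
  expect_equal(unname(st4[[4]]$abundances), expected, tolerance = 1e-9)
})

test_that("neutral competition conserves strain frequencies", {
  k <- 200
  cfg <- simulation_config(n_genes = k, initial_cells = 1e7,
                           n_passages = 2, read_depth = 1e5)
  # chi-square goodness of fit against the uniform start, many seeds
  n_seeds <- 60
  rejected <- 0L
  for (s in seq_len(n_seeds)) {
    states <- simulate_competition(cfg, seed = 1000 + s)
    smp <- simulate_reads(states[[3]], cfg, seed = 2000 + s)
    p <- suppressWarnings(
      stats::chisq.test(smp$counts, p = rep(1 / k, k))$p.value)
    if (p < 0.01) rejected <- rejected + 1L
  }
  expect_lte(rejected / n_seeds, 0.05)

  # per-gene frequencies stay within drift + sampling error of 1/k
  states <- simulate_competition(cfg, seed = 99)
  freq <- states[[3]]$abundances / sum(states[[3]]$abundances)
  drift_sd <- sqrt(2 * (1 / k) * (1 - 1 / k) / 1e7)
  expect_lt(max(abs(freq - 1 / k)), 6 * drift_sd)
})

test_that("runs are reproducible from their seed", {
  cfg <- simulation_config(n_genes = 50, initial_cells = 1e4,
                           n_passages = 3, read_depth = 1e4,
                           mutation_rate = 1e-4, mutation_bonus = 0.5)
  a <- simulate_competition(cfg, seed = 42)
  b <- simulate_competition(cfg, seed = 42)
  expect_identical(a, b)
  ra <- simulate_reads(a[[4]], cfg, seed = 7)
  rb <- simulate_reads(b[[4]], cfg, seed = 7)
  expect_identical(ra$counts, rb$counts)
  # seeded simulation must not disturb the caller's RNG stream
  set.seed(123); x1 <- stats::runif(1)
  set.seed(123); invisible(simulate_competition(cfg, seed = 9))
  x2 <- stats::runif(1)
  expect_identical(x1, x2)
})

test_that("read sampling sums to depth, honours length bias, rejects depth 0", {
  cfg <- simulation_config(n_genes = 4, initial_cells = 1e6, n_passages = 0,
                           read_depth = 4e6)
  st <- simulate_competition(cfg)[[1]]
  smp <- simulate_reads(st, cfg, seed = 1)
  expect_identical(sum(smp$counts), 4000000L)
  # lambda = 0, uniform pool: each count ~ 1e6 within sampling error
  expect_true(all(abs(smp$counts - 1e6) < 5 * sqrt(1e6 * 0.75)))

  # lambda > 0 with lengths spread 0.3-8 kb induces a negative
  # length-count correlation in nearly every seeded repeat
  n <- 150
  set.seed(5)
  lens <- stats::runif(n, 300, 8000)
  cfgL <- simulation_config(n_genes = n, initial_cells = 1e6, n_passages = 0,
                            read_depth = 2e5, insert_lengths = lens,
                            length_bias_rate = 2e-4)
  stL <- simulate_competition(cfgL)[[1]]
  neg <- vapply(1:40, function(s) {
    cts <- simulate_reads(stL, cfgL, seed = s)$counts
    stats::cor(lens, cts) < 0
  }, logical(1))
  expect_gte(mean(neg), 0.95)

  expect_error(simulate_reads(st, cfg, read_depth = 0), "read_depth")
})

test_that("mutant lineages arise, persist, and sweep", {
  cfg <- simulation_config(n_genes = 100, initial_cells = 1e5,
                           n_passages = 5, read_depth = 1e5,
                           mutation_rate = 5e-5, mutation_bonus = 0.6)
  states <- simulate_competition(cfg, seed = 11)
  reg <- states[[6]]$mutant_registry
  expect_gt(nrow(reg), 0)
  expect_true(all(reg$passage >= 1 & reg$passage <= 5))
  # a lineage with +0.6 fitness per generation for several passages
  # outgrows the neutral background
  total_mut_share <- sum(states[[6]]$mutant_abundances) /
    sum(states[[6]]$abundances)
  expect_gt(total_mut_share, 0.01)
})

test_that("ko screen generator validates inputs and plants group effects", {
  cfg <- simulation_config(n_genes = 30, initial_cells = 1e5,
                           read_depth = 1e4)
  groups <- rep("other", 30)
  expect_error(simulate_ko_screen(cfg, groups, conditions = "YPDX"),
               "unknown condition")
  expect_error(simulate_ko_screen(cfg, groups, n_replicates = 1),
               "at least 2")
  expect_error(simulate_ko_screen(cfg, groups[-1]), "assign each")

  groups[1:5] <- "GroupI"
  samples <- simulate_ko_screen(cfg, groups, n_replicates = 2, seed = 3)
  expect_length(samples, 3 * 2 * 2)  # condition x replicate x timepoint
  expect_true(all(vapply(samples, function(s) sum(s$counts) == 1e4,
                         logical(1))))
  metas <- lapply(samples, `[[`, "meta")
  expect_setequal(unique(vapply(metas, `[[`, "", "condition")),
                  c("YPD", "Na", "NaCa"))
  expect_setequal(unique(vapply(metas, `[[`, "", "timepoint")),
                  c("before", "after"))
})

test_that("od curve generator produces the stated kinetics", {
  gc <- simulate_od_curve(rate = 1, od0 = 0.05, duration_h = 8)
  expect_s3_class(gc, "growth_curve")
  expect_equal(gc$od[1], 0.05)
  i <- which.min(abs(gc$times - 3))
  expect_equal(gc$od[i], min(0.05 * 2^(gc$times[i]), 1.5), tolerance = 1e-12)
  expect_true(all(gc$od <= 1.5))
  # reproducible noise
  a <- simulate_od_curve(0.5, 0.05, 10, noise_sd = 0.01, seed = 4)
  b <- simulate_od_curve(0.5, 0.05, 10, noise_sd = 0.01, seed = 4)
  expect_identical(a, b)
  expect_error(simulate_od_curve(1, 0, 10), "od0")
  expect_error(simulate_od_curve(-1, 0.05, 10), "rate")
})
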