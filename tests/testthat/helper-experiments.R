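# Build a full synthetic profiling experiment (baseline + replicate
# endpoints) ready for run_profiling(). One baseline sample per pool is
# sequenced from the initial equal-abundance pool; each replicate is an
# independent competition ending after `n_passages` passages.
sim_profiling_experiment <- function(n_genes = 1000, fitness = 1,
                                     n_replicates = 4, n_passages = 4,
                                     read_depth = 1e6,
                                     initial_cells = 1e6,
                                     mutation_rate = 0,
                                     mutation_bonus = 0.6,
                                     pool = "poolA", condition = "stress",
                                     seed = 1) {
  cfg <- simulation_config(
    n_genes = n_genes, fitness = fitness, n_passages = n_passages,
    read_depth = read_depth, initial_cells = initial_cells,
    mutation_rate = mutation_rate, mutation_bonus = mutation_bonus
  )
  set.seed(seed)
  gen_final <- n_passages * cfg$generations_per_passage

  cfg0 <- cfg
  cfg0$n_passages <- 0L
  st0 <- simulate_competition(cfg0)[[1L]]
  base <- simulate_reads(st0, cfg)

  counts <- matrix(0L, nrow = n_genes, ncol = n_replicates + 1L,
                   dimnames = list(cfg$gene_ids,
                                   c(paste0(pool, "_g0"),
                                     paste0(pool, "_r", seq_len(n_replicates)))))
  counts[, 1L] <- base$counts
  for (r in seq_len(n_replicates)) {
    states <- simulate_competition(cfg)
    counts[, r + 1L] <- simulate_reads(states[[length(states)]], cfg)$counts
  }
  meta <- data.frame(
    sample = colnames(counts),
    pool = pool,
    condition = condition,
    generation = c(0, rep(gen_final, n_replicates)),
    replicate = c("0", as.character(seq_len(n_replicates))),
    stringsAsFactors = FALSE
  )
  list(counts = counts, meta = meta, config = cfg)
}

# Knockout screen with planted Group I / Group II genes, as a count matrix
# plus metadata for run_ko_profiling().
sim_ko_experiment <- function(n_genes = 600, n_group1 = 40, n_group2 = 40,
                              n_replicates = 3, read_depth = 5e5,
                              initial_cells = 1e6, effect_z = 2,
                              fitness_sd = 0.02, seed = 1) {
  groups <- rep("other", n_genes)
  groups[seq_len(n_group1)] <- "GroupI"
  groups[n_group1 + seq_len(n_group2)] <- "GroupII"
  cfg <- simulation_config(n_genes = n_genes, read_depth = read_depth,
                           initial_cells = initial_cells)
  samples <- simulate_ko_screen(cfg, groups, n_replicates = n_replicates,
                                effect_z = effect_z,
                                fitness_sd = fitness_sd, seed = seed)
  sm <- samples_to_matrix(samples)
  list(counts = sm$counts, meta = sm$meta, groups = groups,
       gene_ids = cfg$gene_ids)
}
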