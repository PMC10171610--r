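#' Configuration for a pooled competitive-culture simulation
#'
#' Describes a pool of overexpression (or knockout) strains competing through
#' serial-dilution passages. Each passage regrows the diluted culture to
#' saturation, which at a 1:250 dilution corresponds to about eight bulk
#' doublings (`generations_per_passage = log2(1/dilution)`); the passage
#' bottleneck then draws `initial_cells` cells multinomially from the
#' post-growth composition. Per-strain relative fitness `w` scales the number
#' of doublings a strain achieves: a strain's expected post-growth share is
#' proportional to `n_i * 2^(g * w_i)`.
#'
#' @param n_genes Number of strains (plasmid inserts / barcodes) in the pool.
#'   Defaults to 5751, the size of a genome-wide yeast overexpression library.
#' @param gene_ids Optional character vector of strain identifiers; defaults to
#'   `g0001 ...`.
#' @param initial_cells Cells surviving each dilution bottleneck. `Inf` selects
#'   expectation mode: abundances are carried as exact expected shares with no
#'   drift (only valid with `mutation_rate = 0`). Bottleneck census sizes are
#'   rarely reported for real screens, so this is a free parameter; the
#'   default 1e6 keeps drift small relative to selection.
#' @param dilution Serial-passage dilution ratio in (0, 1); default 1/250.
#' @param generations_per_passage Bulk doublings per passage; default
#'   `log2(1/dilution)` (~7.97 for 1:250), so dilution times regrowth returns
#'   the culture to saturation.
#' @param n_passages Number of passages to simulate.
#' @param fitness Per-strain relative fitness: a numeric vector of length
#'   `n_genes` (recycled if length 1), or a named list of such vectors keyed by
#'   condition label. `NULL` means all strains neutral (w = 1). All values must
#'   be finite and non-negative.
#' @param read_depth Sequencing reads drawn per sample.
#' @param insert_lengths Insert length per gene in bp, used by the
#'   length-biased read sampler; `NULL` means unbiased lengths irrelevant.
#' @param length_bias_rate Detection-bias rate lambda (per bp, >= 0): the
#'   probability a read is sampled from strain i is proportional to
#'   `abundance_i * exp(-lambda * length_i)`. 0 disables the bias.
#' @param mutation_rate Per-cell, per-passage probability that a cell founds a
#'   spontaneous adaptive lineage (fitness `w_i + mutation_bonus` thereafter).
#'   Models background adaptation that produces replicate-specific sweeps
#'   unrelated to the plasmid insert.
#' @param mutation_bonus Fitness increment carried by spontaneous mutants.
#' @param seed Default seed for simulation calls made with this config.
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' cfg <- simulation_config(n_genes = 4, n_passages = 2, initial_cells = 1e4,
#'                          read_depth = 1e4)
#' states <- simulate_competition(cfg, seed = 1)
#' length(states)  # initial state plus one per passage
simulation_config <- function(n_genes = 5751L,
                              gene_ids = NULL,
                              initial_cells = 1e6,
                              dilution = 1 / 250,
                              generations_per_passage = log2(1 / dilution),
                              n_passages = 4L,
                              fitness = NULL,
                              read_depth = 1e6,
                              insert_lengths = NULL,
                              length_bias_rate = 0,
                              mutation_rate = 0,
                              mutation_bonus = 0.3,
                              seed = NULL) {
  assert_scalar_number(n_genes, "n_genes", lower = 1)
  assert_scalar_number(initial_cells, "initial_cells", lower = 1,
                       allow_inf = TRUE)
  assert_scalar_number(dilution, "dilution", lower = .Machine$double.xmin,
                       upper = 1 - 1e-12)
  assert_scalar_number(generations_per_passage, "generations_per_passage",
                       lower = .Machine$double.xmin)
  assert_scalar_number(n_passages, "n_passages", lower = 0)
  assert_scalar_number(read_depth, "read_depth", lower = 1)
  assert_scalar_number(length_bias_rate, "length_bias_rate", lower = 0)
  assert_scalar_number(mutation_rate, "mutation_rate", lower = 0, upper = 1)
  assert_scalar_number(mutation_bonus, "mutation_bonus", lower = 0)
  n_genes <- as.integer(n_genes)
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("g%0*d", max(4L, nchar(n_genes)), seq_len(n_genes))
  }
  if (length(gene_ids) != n_genes || anyDuplicated(gene_ids)) {
    stop("`gene_ids` must be ", n_genes, " unique identifiers", call. = FALSE)
  }

  check_w <- function(w, label) {
    if (length(w) == 1L) w <- rep(w, n_genes)
    if (length(w) != n_genes) {
      stop("fitness vector `", label, "` must have length ", n_genes,
           call. = FALSE)
    }
    if (!is.null(names(w))) w <- w[gene_ids]
    if (any(!is.finite(w)) || any(w < 0)) {
      stop("fitness values in `", label,
           "` must be finite and non-negative", call. = FALSE)
    }
    stats::setNames(as.numeric(w), gene_ids)
  }
  if (is.null(fitness)) {
    fitness <- check_w(1, "fitness")
  } else if (is.list(fitness)) {
    if (is.null(names(fitness)) || any(!nzchar(names(fitness)))) {
      stop("a fitness list must be named by condition", call. = FALSE)
    }
    fitness <- lapply(stats::setNames(nm = names(fitness)), function(cond) {
      check_w(fitness[[cond]], cond)
    })
  } else {
    fitness <- check_w(fitness, "fitness")
  }

  if (!is.null(insert_lengths)) {
    if (length(insert_lengths) == 1L) {
      insert_lengths <- rep(insert_lengths, n_genes)
    }
    if (length(insert_lengths) != n_genes || any(insert_lengths <= 0)) {
      stop("`insert_lengths` must be ", n_genes, " positive lengths",
           call. = FALSE)
    }
    if (!is.null(names(insert_lengths))) {
      insert_lengths <- insert_lengths[gene_ids]
    }
    insert_lengths <- stats::setNames(as.numeric(insert_lengths), gene_ids)
  }
  if (is.infinite(initial_cells) && mutation_rate > 0) {
    stop("expectation mode (initial_cells = Inf) requires mutation_rate = 0",
         call. = FALSE)
  }

  structure(
    list(
      n_genes = n_genes, gene_ids = gene_ids,
      initial_cells = initial_cells, dilution = dilution,
      generations_per_passage = generations_per_passage,
      n_passages = as.integer(n_passages),
      fitness = fitness, read_depth = as.integer(read_depth),
      insert_lengths = insert_lengths,
      length_bias_rate = length_bias_rate,
      mutation_rate = mutation_rate, mutation_bonus = mutation_bonus,
      seed = seed
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Pooled competition simulation config\n")
  cat(sprintf("  strains: %d   passages: %d   dilution: 1:%.0f (g = %.3f)\n",
              x$n_genes, x$n_passages, 1 / x$dilution,
              x$generations_per_passage))
  cat(sprintf("  bottleneck: %s cells   read depth: %s\n",
              format(x$initial_cells, big.mark = ","),
              format(x$read_depth, big.mark = ",")))
  conds <- if (is.list(x$fitness)) names(x$fitness) else "(single)"
  cat("  fitness conditions:", paste(conds, collapse = ", "), "\n")
  if (x$mutation_rate > 0) {
    cat(sprintf("  spontaneous mutants: rate %.3g, bonus %.3g\n",
                x$mutation_rate, x$mutation_bonus))
  }
  invisible(x)
}

config_fitness <- function(config, condition = NULL) {
  f <- config$fitness
  if (!is.list(f)) return(f)
  if (is.null(condition)) {
    stop("config defines per-condition fitness; supply `condition`",
         call. = FALSE)
  }
  if (!condition %in% names(f)) {
    stop("no fitness defined for condition '", condition, "'", call. = FALSE)
  }
  f[[condition]]
}

new_pool_state <- function(base, mutant, passage_index, registry, gene_ids) {
  structure(
    list(
      abundances = stats::setNames(base + mutant, gene_ids),
      base_abundances = base,
      mutant_abundances = mutant,
      passage_index = passage_index,
      mutant_registry = registry
    ),
    class = "pool_state"
  )
}

#' @export
print.pool_state <- function(x, ...) {
  cat(sprintf("Pool state after passage %d: %d strains, %s cells, %d mutant lineage(s)\n",
              x$passage_index, length(x$abundances),
              format(sum(x$abundances), big.mark = ","),
              nrow(x$mutant_registry)))
  invisible(x)
}

#' Simulate competitive serial-passage culture of a pooled library
#'
#' Starting from equal (or supplied) strain abundances, each passage (i)
#' optionally spawns spontaneous adaptive mutant lineages, (ii) grows the pool
#' deterministically so strain i's expected share becomes
#' `n_i * 2^(g * w_i) / sum_j n_j * 2^(g * w_j)` with
#' `g = generations_per_passage`, and (iii) applies the dilution bottleneck as
#' a multinomial draw of `initial_cells` cells from those shares. Mutant
#' lineages carry `w_i + mutation_bonus` from the passage after they arise.
#'
#' @param config A [simulation_config()].
#' @param condition Condition label selecting a fitness vector when the config
#'   defines fitness per condition.
#' @param initial_abundances Optional starting cell counts per gene; defaults
#'   to an equal split of `initial_cells` (exactly equal shares in expectation
#'   mode).
#' @param seed Seed for the run; defaults to `config$seed`.
#' @return A list of `pool_state` objects of length `n_passages + 1`: the
#'   initial pool (passage 0) followed by the state after each passage.
#' @export
simulate_competition <- function(config, condition = NULL,
                                 initial_abundances = NULL,
                                 seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  w <- config_fitness(config, condition)
  g <- config$generations_per_passage
  n <- config$n_genes
  expectation_mode <- is.infinite(config$initial_cells)

  if (is.null(initial_abundances)) {
    if (expectation_mode) {
      base <- rep(1 / n, n)
    } else {
      base <- rep(floor(config$initial_cells / n), n)
      if (sum(base) == 0) {
        stop("initial_cells too small to seed ", n, " strains", call. = FALSE)
      }
    }
  } else {
    if (length(initial_abundances) != n || any(initial_abundances < 0)) {
      stop("`initial_abundances` must be ", n, " non-negative values",
           call. = FALSE)
    }
    base <- as.numeric(initial_abundances)
  }
  if (sum(base) <= 0) stop("pool is extinct at passage 0", call. = FALSE)

  mutant <- numeric(n)
  mutant_bonus <- config$mutation_bonus
  registry <- data.frame(gene = character(), passage = integer(),
                         bonus = numeric(), stringsAsFactors = FALSE)

  with_seed(seed, {
    states <- vector("list", config$n_passages + 1L)
    states[[1L]] <- new_pool_state(base, mutant, 0L, registry, config$gene_ids)
    if (config$n_passages == 0L) return(states)

    for (p in seq_len(config$n_passages)) {
      # spontaneous adaptive lineages arise among bottleneck survivors
      if (config$mutation_rate > 0) {
        n_new <- stats::rbinom(n, size = as.integer(base),
                               prob = config$mutation_rate)
        if (any(n_new > 0)) {
          base <- base - n_new
          mutant <- mutant + n_new
          for (i in which(n_new > 0)) {
            registry <- rbind(registry, data.frame(
              gene = config$gene_ids[i], passage = p,
              bonus = mutant_bonus, stringsAsFactors = FALSE))
          }
        }
      }

      # deterministic expected growth; factor out max exponent for stability
      lw <- c(g * w, g * (w + mutant_bonus))
      ab <- c(base, mutant)
      live <- ab > 0
      if (!any(live)) stop("pool extinct at passage ", p, call. = FALSE)
      weights <- numeric(2L * n)
      weights[live] <- ab[live] * 2^(lw[live] - max(lw[live]))
      shares <- weights / sum(weights)

      if (expectation_mode) {
        base <- shares[seq_len(n)]
        mutant <- shares[n + seq_len(n)]
      } else {
        draw <- as.numeric(stats::rmultinom(1L, size = config$initial_cells,
                                            prob = shares))
        base <- draw[seq_len(n)]
        mutant <- draw[n + seq_len(n)]
        if (sum(base) + sum(mutant) <= 0) {
          stop("pool extinct at passage ", p, call. = FALSE)
        }
      }
      states[[p + 1L]] <- new_pool_state(base, mutant, p, registry,
                                         config$gene_ids)
    }
    states
  })
}

#' Draw sequencing reads from a pool state
#'
#' Read counts are a multinomial draw of `read_depth` reads with per-strain
#' probability proportional to `abundance_i * exp(-lambda * length_i)`, where
#' lambda is the config's `length_bias_rate`. This reproduces the empirical
#' tendency of long plasmid inserts to yield fewer reads; `lambda = 0` gives
#' unbiased sampling of the pool composition.
#'
#' @param state A `pool_state` (from [simulate_competition()]).
#' @param config The [simulation_config()] used to generate the state.
#' @param meta Named list of sample metadata (pool, condition, generation,
#'   replicate, ...) carried through unchanged.
#' @param read_depth Reads to draw; defaults to `config$read_depth`.
#' @param seed Seed for the draw.
#' @return A `synthetic_sample`: list with integer `counts` (named by gene,
#'   summing exactly to `read_depth`) and `meta`.
#' @export
simulate_reads <- function(state, config, meta = list(),
                           read_depth = config$read_depth, seed = NULL) {
  stopifnot(inherits(state, "pool_state"), inherits(config, "sim_config"))
  assert_scalar_number(read_depth, "read_depth", lower = 1)
  ab <- state$abundances
  if (sum(ab) <= 0) stop("cannot sequence an extinct pool", call. = FALSE)
  lambda <- config$length_bias_rate
  if (lambda > 0) {
    if (is.null(config$insert_lengths)) {
      stop("length_bias_rate > 0 requires `insert_lengths` in the config",
           call. = FALSE)
    }
    # rescale relative to the shortest insert so weights stay well above
    # double underflow for multi-kb inserts
    len <- config$insert_lengths
    wts <- ab * exp(-lambda * (len - min(len)))
  } else {
    wts <- ab
  }
  counts <- with_seed(seed, {
    as.integer(stats::rmultinom(1L, size = as.integer(read_depth),
                                prob = wts / sum(wts)))
  })
  structure(
    list(counts = stats::setNames(counts, config$gene_ids), meta = meta),
    class = "synthetic_sample"
  )
}

#' @export
print.synthetic_sample <- function(x, ...) {
  meta <- if (length(x$meta)) {
    paste(names(x$meta), unlist(lapply(x$meta, format)), sep = "=",
          collapse = " ")
  } else "(no metadata)"
  cat(sprintf("Synthetic sample: %d genes, %s reads [%s]\n",
              length(x$counts), format(sum(x$counts), big.mark = ","), meta))
  invisible(x)
}

#' Simulate a pooled knockout fitness screen across conditions
#'
#' Generates barcode-count samples before and after `n_passages` (default 2)
#' competitive passages in each condition, in `n_replicates` replicates, for a
#' knockout pool in which planted genes respond condition-specifically:
#' "GroupI" knockouts grow poorly in rich medium (YPD) but normally under salt
#' (Na), with no further response to calcium; "GroupII" knockouts grow
#' normally in YPD, poorly under salt, and are rescued by calcium (NaCa).
#' All other genes carry a baseline fitness with per-gene jitter
#' (`fitness_sd`), which is the dominant source of spread in the downstream
#' fitness Z-scores; planted effects are expressed in units of that spread
#' (`effect_z` standard deviations).
#'
#' @param config A [simulation_config()]; its `fitness` slot is ignored and
#'   rebuilt from the group assignments.
#' @param group_assignments Character vector (length `n_genes`, values
#'   `"GroupI"`, `"GroupII"` or `"other"`) assigning each gene a planted
#'   response class.
#' @param conditions Condition labels; the recognised set is YPD, Na, NaCa.
#' @param n_replicates Replicates per condition (>= 2).
#' @param n_passages Competitive passages between the before and after
#'   samples (default 2).
#' @param effect_z Planted effect size in units of the baseline fitness
#'   jitter's standard deviation (default 2).
#' @param fitness_sd Standard deviation of the per-gene baseline fitness
#'   jitter around w = 1 (default 0.02).
#' @param seed Seed for the whole screen.
#' @return List of `synthetic_sample` objects, one per condition x replicate x
#'   timepoint, with metadata fields `condition`, `replicate`, `timepoint`
#'   ("before"/"after") and `generation`.
#' @export
simulate_ko_screen <- function(config, group_assignments,
                               conditions = c("YPD", "Na", "NaCa"),
                               n_replicates = 3L,
                               n_passages = 2L,
                               effect_z = 2,
                               fitness_sd = 0.02,
                               seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  known <- c("YPD", "Na", "NaCa")
  if (!all(conditions %in% known)) {
    stop("unknown condition label(s): ",
         paste(setdiff(conditions, known), collapse = ", "), call. = FALSE)
  }
  if (n_replicates < 2L) {
    stop("`n_replicates` must be at least 2", call. = FALSE)
  }
  n <- config$n_genes
  if (length(group_assignments) != n ||
      !all(group_assignments %in% c("GroupI", "GroupII", "other"))) {
    stop("`group_assignments` must assign each of the ", n,
         " genes to GroupI, GroupII or other", call. = FALSE)
  }
  assert_scalar_number(effect_z, "effect_z", lower = 0)
  assert_scalar_number(fitness_sd, "fitness_sd", lower = 0)

  with_seed(seed, {
    w0 <- pmax(stats::rnorm(n, mean = 1, sd = fitness_sd), 0)
    delta <- effect_z * fitness_sd
    w_by_cond <- list(
      YPD  = w0 - delta * (group_assignments == "GroupI"),
      Na   = w0 - delta * (group_assignments == "GroupII"),
      NaCa = w0  # calcium restores GroupII; GroupI never responds to Ca
    )
    w_by_cond <- lapply(w_by_cond, function(w) {
      stats::setNames(pmax(w, 0), config$gene_ids)
    })

    cfg <- config
    cfg$fitness <- w_by_cond[known]
    cfg$n_passages <- as.integer(n_passages)
    g <- cfg$generations_per_passage

    samples <- list()
    for (cond in conditions) {
      for (r in seq_len(n_replicates)) {
        states <- simulate_competition(cfg, condition = cond, seed = NULL)
        before <- simulate_reads(states[[1L]], cfg,
                                 meta = list(condition = cond, replicate = r,
                                             timepoint = "before",
                                             generation = 0))
        after <- simulate_reads(states[[length(states)]], cfg,
                                meta = list(condition = cond, replicate = r,
                                            timepoint = "after",
                                            generation = n_passages * g))
        samples[[paste(cond, r, "before", sep = "_")]] <- before
        samples[[paste(cond, r, "after", sep = "_")]] <- after
      }
    }
    samples
  })
}

#' Simulate an OD660 growth curve
#'
#' Logistic-free toy kinetics: `OD(t) = min(od0 * 2^(rate * t), carrying_cap)`
#' plus optional Gaussian reading noise, sampled on a regular grid. Used to
#' exercise the growth-rate estimator.
#'
#' @param rate Exponential growth rate in doublings per hour (>= 0).
#' @param od0 Initial OD660 (> 0).
#' @param duration_h Total recording time in hours.
#' @param interval_min Sampling interval in minutes (default 10, matching a
#'   plate-reader cadence).
#' @param noise_sd Standard deviation of additive reading noise (default 0).
#' @param carrying_cap Saturation OD (default 1.5).
#' @param seed Seed for the noise.
#' @return A [growth_curve()] object.
#' @export
simulate_od_curve <- function(rate, od0, duration_h, interval_min = 10,
                              noise_sd = 0, carrying_cap = 1.5, seed = NULL) {
  assert_scalar_number(rate, "rate", lower = 0)
  if (!is.numeric(od0) || length(od0) != 1L || !is.finite(od0) || od0 <= 0) {
    stop("`od0` must be a single positive number", call. = FALSE)
  }
  assert_scalar_number(duration_h, "duration_h", lower = 1e-9)
  assert_scalar_number(interval_min, "interval_min", lower = 1e-9)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  times <- seq(0, duration_h, by = interval_min / 60)
  od <- pmin(od0 * 2^(rate * times), carrying_cap)
  if (noise_sd > 0) {
    od <- with_seed(seed, od + stats::rnorm(length(od), sd = noise_sd))
    od <- pmax(od, 1e-6)  # keep readings positive for the log2 fit
  }
  growth_curve(times, od)
}
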