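# End-to-end orchestration: overexpression profiling (counts -> fold
# changes -> hits -> replicate-overlap test -> diversity) and knockout
# fitness profiling (counts -> Z-scores -> between-condition screen ->
# group classification), with TSV outputs and a run manifest.

check_meta <- function(sample_meta, counts, need) {
  missing <- setdiff(need, names(sample_meta))
  if (length(missing)) {
    stop("sample metadata lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(sample_meta$sample, colnames(counts))
  if (length(absent)) {
    stop("metadata lists sample(s) absent from the count matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

run_manifest <- function(seed, params, files = character()) {
  checksums <- if (length(files)) {
    as.list(tools::md5sum(files))
  } else {
    list()
  }
  list(
    package = "oeprof",
    version = as.character(utils::packageVersion("oeprof")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = seed,
    parameters = params,
    input_md5 = checksums
  )
}

write_tsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full overexpression profiling analysis
#'
#' From a gene x sample count matrix and its sample metadata: identifies each
#' pool's baseline sample (generation `baseline_generation`) and each
#' replicate's endpoint sample (its largest generation), computes
#' per-replicate RPM fold changes with chi-square/BH testing
#' ([fold_change_table()]), calls hits ([call_hits()]), tests the replicate
#' overlap of hit genes by permutation ([overlap_permutation_test()]) over
#' the union of genes testable in any replicate, and reports per-sample
#' Gini-Simpson diversity.
#'
#' @param counts Integer matrix, genes x samples (dimnames required).
#' @param sample_meta Data.frame with columns sample, pool, condition,
#'   generation, replicate.
#' @param config A [hit_call_config()].
#' @param baseline_generation Generation of the baseline samples (default 0).
#' @param n_permutations Permutations for the overlap test (default 10000).
#' @param seed Seed for the permutation test.
#' @param output_dir Optional directory; when given, writes
#'   fold_changes.tsv, hits.tsv, overlap_test.tsv, diversity.tsv, the input
#'   counts/metadata and manifest.yaml there.
#' @return List with elements `fold_changes` (per-replicate tables with hit
#'   flags), `hits_by_replicate`, `overlap` (when >= 2 replicates),
#'   `diversity`, `universe`, `manifest`.
#' @export
run_profiling <- function(counts, sample_meta,
                          config = hit_call_config(),
                          baseline_generation = 0,
                          n_permutations = 10000L,
                          seed = NULL,
                          output_dir = NULL) {
  check_meta(sample_meta, counts,
             c("sample", "pool", "condition", "generation", "replicate"))
  stopifnot(inherits(config, "hit_call_config"))

  pools <- unique(sample_meta$pool)
  baselines <- lapply(stats::setNames(nm = pools), function(p) {
    rows <- sample_meta$pool == p &
      sample_meta$generation == baseline_generation
    if (!any(rows)) {
      stop("missing baseline sample for (pool ", p, ", generation ",
           baseline_generation, ")", call. = FALSE)
    }
    sample_meta$sample[rows][1L]
  })

  endpoint <- sample_meta[sample_meta$generation != baseline_generation, ,
                          drop = FALSE]
  if (nrow(endpoint) == 0L) {
    stop("no post-culture samples in the metadata", call. = FALSE)
  }
  endpoint$replicate_id <- paste(endpoint$pool, endpoint$replicate,
                                 sep = "-")
  # endpoint of each replicate = its latest generation
  keep <- unlist(lapply(split(seq_len(nrow(endpoint)),
                              endpoint$replicate_id), function(i) {
    i[which.max(endpoint$generation[i])]
  }))
  endpoint <- endpoint[sort(keep), , drop = FALSE]

  fc_tables <- list()
  hits_by_replicate <- list()
  for (i in seq_len(nrow(endpoint))) {
    rid <- endpoint$replicate_id[i]
    s0 <- baselines[[endpoint$pool[i]]]
    sn <- endpoint$sample[i]
    tb <- fold_change_table(counts[, s0], counts[, sn])
    tb <- call_hits(tb, config)
    tb$gene <- rownames(tb)
    tb$replicate_id <- rid
    tb$sample_before <- s0
    tb$sample_after <- sn
    fc_tables[[rid]] <- tb
    hits_by_replicate[[rid]] <- attr(tb, "hits")
  }

  universe <- sort(unique(unlist(lapply(fc_tables, function(tb) {
    tb$gene[tb$status == "ok"]
  }))))

  overlap <- NULL
  if (length(fc_tables) >= 2L) {
    overlap <- overlap_permutation_test(hits_by_replicate,
                                        universe = universe,
                                        n_permutations = n_permutations,
                                        seed = seed)
  }

  diversity <- data.frame(
    sample = colnames(counts),
    gini_simpson = unname(gini_simpson(counts[, , drop = FALSE])),
    stringsAsFactors = FALSE
  )

  manifest <- run_manifest(
    seed,
    params = list(log2fc_threshold = config$log2fc_threshold,
                  fdr_threshold = config$fdr_threshold,
                  baseline_generation = baseline_generation,
                  n_permutations = n_permutations,
                  n_genes = nrow(counts), n_samples = ncol(counts))
  )

  result <- list(fold_changes = fc_tables,
                 hits_by_replicate = hits_by_replicate,
                 overlap = overlap, diversity = diversity,
                 universe = universe, manifest = manifest)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    in_counts <- file.path(output_dir, "input_counts.tsv")
    in_meta <- file.path(output_dir, "input_sample_meta.tsv")
    write_count_matrix(counts, in_counts)
    write_sample_meta(sample_meta, in_meta)
    manifest$input_md5 <- as.list(tools::md5sum(c(in_counts, in_meta)))
    result$manifest <- manifest

    all_fc <- do.call(rbind, lapply(fc_tables, function(tb) {
      rownames(tb) <- NULL
      tb
    }))
    write_tsv(all_fc, output_dir, "fold_changes.tsv")
    hit_df <- do.call(rbind, lapply(names(hits_by_replicate), function(r) {
      h <- hits_by_replicate[[r]]
      if (length(h) == 0L) return(NULL)
      data.frame(replicate_id = r, gene = h, stringsAsFactors = FALSE)
    }))
    if (is.null(hit_df)) {
      hit_df <- data.frame(replicate_id = character(), gene = character())
    }
    write_tsv(hit_df, output_dir, "hits.tsv")
    if (!is.null(overlap)) {
      write_tsv(overlap$table, output_dir, "overlap_test.tsv")
    }
    write_tsv(diversity, output_dir, "diversity.tsv")
    yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))
  }
  result
}

#' Run the knockout fitness profiling analysis
#'
#' From barcode counts with before/after samples per condition x replicate:
#' computes per-replicate fitness Z-scores ([fitness_z()]), screens for genes
#' with condition-specific fitness loss between `screen_pair[1]` and
#' `screen_pair[2]` ([delta_z_screen()]), and classifies genes by the
#' `classify_pair` contrast ([classify_groups()]).
#'
#' @param counts Integer matrix, genes x samples.
#' @param sample_meta Data.frame with columns sample, condition, replicate,
#'   timepoint ("before"/"after").
#' @param screen_pair Conditions (A, B) for the fitness-loss screen; default
#'   `c("NaCa", "Na")`, i.e. genes less fit with calcium added to salt.
#' @param classify_pair Conditions (numerator, reference) for group
#'   classification; default `c("Na", "YPD")`.
#' @param delta_z_threshold,fdr_threshold Screen thresholds (defaults -1 and
#'   0.05).
#' @param gene_subset Optional gene subset for classification.
#' @param output_dir Optional output directory (z_scores.tsv, screen.tsv,
#'   groups.tsv, manifest.yaml).
#' @return List with `z_tables` (condition -> list of per-replicate tables),
#'   `mean_z` (condition -> named vector), `screen`, `groups`, `manifest`.
#' @export
run_ko_profiling <- function(counts, sample_meta,
                             screen_pair = c("NaCa", "Na"),
                             classify_pair = c("Na", "YPD"),
                             delta_z_threshold = -1,
                             fdr_threshold = 0.05,
                             gene_subset = NULL,
                             output_dir = NULL) {
  check_meta(sample_meta, counts,
             c("sample", "condition", "replicate", "timepoint"))
  conditions <- unique(sample_meta$condition)

  z_tables <- list()
  for (cond in conditions) {
    sub <- sample_meta[sample_meta$condition == cond, , drop = FALSE]
    reps <- unique(sub$replicate)
    if (length(reps) < 2L) {
      stop("condition ", cond, " has fewer than 2 replicates",
           call. = FALSE)
    }
    z_tables[[cond]] <- lapply(stats::setNames(nm = as.character(reps)),
                               function(r) {
      rows <- sub$replicate == r
      pick <- function(tp) {
        s <- sub$sample[rows & sub$timepoint == tp]
        if (length(s) != 1L) {
          stop("condition ", cond, ", replicate ", r, ": expected exactly ",
               "one '", tp, "' sample, found ", length(s), call. = FALSE)
        }
        s
      }
      fitness_z(counts[, pick("before")], counts[, pick("after")])
    })
  }

  z_mats <- lapply(z_tables, align_z_matrix)
  mean_z <- lapply(z_mats, rowMeans)

  screen <- NULL
  if (all(screen_pair %in% conditions)) {
    screen <- delta_z_screen(z_mats[[screen_pair[1L]]],
                             z_mats[[screen_pair[2L]]],
                             delta_z_threshold = delta_z_threshold,
                             fdr_threshold = fdr_threshold)
  }
  groups <- NULL
  if (all(classify_pair %in% conditions)) {
    groups <- classify_groups(mean_z[[classify_pair[1L]]],
                              mean_z[[classify_pair[2L]]],
                              gene_subset = gene_subset)
  }

  manifest <- run_manifest(
    seed = NULL,
    params = list(screen_pair = screen_pair,
                  classify_pair = classify_pair,
                  delta_z_threshold = delta_z_threshold,
                  fdr_threshold = fdr_threshold,
                  n_genes = nrow(counts), n_samples = ncol(counts))
  )

  result <- list(z_tables = z_tables, mean_z = mean_z, screen = screen,
                 groups = groups, manifest = manifest)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    z_long <- do.call(rbind, unlist(lapply(names(z_tables), function(cond) {
      lapply(names(z_tables[[cond]]), function(r) {
        tb <- z_tables[[cond]][[r]]
        data.frame(condition = cond, replicate = r, tb,
                   stringsAsFactors = FALSE)
      })
    }), recursive = FALSE))
    write_tsv(z_long, output_dir, "z_scores.tsv")
    if (!is.null(screen)) write_tsv(screen, output_dir, "screen.tsv")
    if (!is.null(groups)) write_tsv(groups, output_dir, "groups.tsv")
    yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))
  }
  result
}
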