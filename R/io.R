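# Standard-format readers/writers: count matrices and metadata as TSV, read
# and locus intervals as BED (via rtracklayer), OD curves as 2-column TSV,
# simulation configs as YAML.

#' Write / read a gene x sample count matrix as TSV
#'
#' First column `gene_id`, one column per sample (header row of sample ids).
#'
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @param path File path.
#' @return `read_count_matrix` returns the matrix; `write_count_matrix`
#'   returns `path` invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene_id") {
    stop("count matrix file must start with a `gene_id` column: ", path,
         call. = FALSE)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  m
}

#' Write / read sample metadata as TSV
#'
#' Columns: sample, pool, condition, generation, replicate.
#'
#' @param meta Data.frame of sample metadata.
#' @param path File path.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_meta
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "pool", "condition", "generation", "replicate")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    stop("sample metadata file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  meta$sample <- as.character(meta$sample)
  meta$replicate <- as.character(meta$replicate)
  meta$generation <- as.numeric(meta$generation)
  meta
}

#' Write / read intervals as BED
#'
#' Loci are written as 6-column BED with the gene id in the name field; reads
#' with the read id. BED is 0-based half-open, matching the package's
#' internal convention, so coordinates round-trip unchanged.
#'
#' @param intervals Data.frame from [insert_loci()] or [read_intervals()].
#' @param path File path.
#' @param name_col Column holding the BED name field.
#' @export
write_bed <- function(intervals, path,
                      name_col = if ("gene_id" %in% names(intervals))
                        "gene_id" else "read_id") {
  gr <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(intervals$start + 1, intervals$end),
    name = intervals[[name_col]],
    score = 0L
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_bed
#' @param as One of "loci" or "reads": which table shape to return.
#' @export
read_bed <- function(path, as = c("loci", "reads")) {
  as <- match.arg(as)
  gr <- rtracklayer::import(path, format = "BED")
  start0 <- GenomicRanges::start(gr) - 1
  end0 <- GenomicRanges::end(gr)
  nm <- gr$name
  if (is.null(nm)) nm <- paste0("iv", seq_along(gr))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  if (as == "loci") {
    insert_loci(nm, chrom, start0, end0)
  } else {
    read_intervals(nm, chrom, start0, end0)
  }
}

#' Write / read an OD660 time series as 2-column TSV (hours, od)
#'
#' @param curve A [growth_curve()].
#' @param path File path.
#' @export
write_od_curve <- function(curve, path) {
  stopifnot(inherits(curve, "growth_curve"))
  utils::write.table(data.frame(hours = curve$times, od = curve$od),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_od_curve
#' @export
read_od_curve <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("hours", "od") %in% names(df))) {
    stop("OD file ", path, " must have columns `hours` and `od`",
         call. = FALSE)
  }
  growth_curve(df$hours, df$od)
}

#' Write / read a simulation config as YAML
#'
#' All scalar fields plus the fitness map(s) and insert lengths are stored;
#' [read_sim_config()] revalidates through [simulation_config()].
#'
#' @param config A [simulation_config()].
#' @param path File path.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  if (is.infinite(x$initial_cells)) x$initial_cells <- "Inf"
  x$fitness <- if (is.list(config$fitness)) {
    lapply(config$fitness, as.list)
  } else {
    as.list(config$fitness)
  }
  if (!is.null(x$insert_lengths)) x$insert_lengths <- as.list(x$insert_lengths)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  unlist_named <- function(v) {
    if (is.null(v)) return(NULL)
    out <- unlist(v)
    stats::setNames(as.numeric(out), names(out))
  }
  fitness <- x$fitness
  if (!is.null(fitness)) {
    nested <- all(vapply(fitness, is.list, logical(1)))
    fitness <- if (nested) lapply(fitness, unlist_named) else
      unlist_named(fitness)
  }
  simulation_config(
    n_genes = x$n_genes,
    gene_ids = unlist(x$gene_ids),
    initial_cells = if (identical(x$initial_cells, "Inf")) Inf else
      x$initial_cells,
    dilution = x$dilution,
    generations_per_passage = x$generations_per_passage,
    n_passages = x$n_passages,
    fitness = fitness,
    read_depth = x$read_depth,
    insert_lengths = unlist_named(x$insert_lengths),
    length_bias_rate = x$length_bias_rate,
    mutation_rate = x$mutation_rate,
    mutation_bonus = x$mutation_bonus,
    seed = x$seed
  )
}

#' Collect synthetic samples into a count matrix plus metadata
#'
#' @param samples List of `synthetic_sample` objects (e.g. from
#'   [simulate_ko_screen()]); names become sample ids.
#' @return List with `counts` (genes x samples integer matrix) and `meta`
#'   (data.frame: sample plus the union of metadata fields).
#' @export
samples_to_matrix <- function(samples) {
  stopifnot(length(samples) > 0,
            all(vapply(samples, inherits, logical(1), "synthetic_sample")))
  ids <- names(samples)
  if (is.null(ids)) ids <- paste0("s", seq_along(samples))
  counts <- vapply(samples, function(s) s$counts,
                   numeric(length(samples[[1L]]$counts)))
  colnames(counts) <- ids
  storage.mode(counts) <- "integer"
  meta_fields <- unique(unlist(lapply(samples, function(s) names(s$meta))))
  meta <- data.frame(sample = ids, stringsAsFactors = FALSE)
  for (f in meta_fields) {
    meta[[f]] <- vapply(samples, function(s) {
      v <- s$meta[[f]]
      if (is.null(v)) NA else as.character(v)
    }, character(1))
  }
  if ("generation" %in% names(meta)) {
    meta$generation <- as.numeric(meta$generation)
  }
  if ("replicate" %in% names(meta)) {
    meta$replicate <- as.character(meta$replicate)
  }
  list(counts = counts, meta = meta)
}
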