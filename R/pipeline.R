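# End-to-end orchestration: simulate/load -> quality gate -> competitive
# classification -> contamination quantification, with a JSON provenance
# manifest.

#' Default pipeline configuration
#'
#' All stage defaults in one serialisable list: quality threshold 30,
#' minimum span 20, subsample 1e6 reads, seed length 25 with 0 seed
#' mismatches.  The synthetic block states the simulated world: a 20 kb
#' genome pair at 0.15 divergence, 50-base single-end reads, 0.1%
#' substitution error, and two groups whose contamination fractions
#' differ (cellular 5%, exosomal 15%).
#'
#' @param seed top-level integer seed.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    genome = list(length = 20000, divergence = 0.15),
    simulate = list(n_samples_per_group = 3,
                    contamination = c(cellular = 0.05, exosomal = 0.15),
                    n_reads = 2000, read_length = 50, error_rate = 0.001),
    qc = list(threshold_q = 30, min_span = 20, subsample = 1e6,
              trim = TRUE),
    align = list(seed_length = 25, seed_mismatches = 0, min_score = 50),
    quantify = list(numerator_group = "exosomal",
                    denominator_group = "cellular"))
}

#' Run the contamination-quantification pipeline
#'
#' Executes simulate (or load) -> quality gate -> competitive
#' classification -> quantification, writing stage outputs and a JSON
#' provenance manifest into `out_dir`.  Samples whose optimal read
#' span fails the minimum-span rule are discarded with a warning and
#' excluded from quantification (the run still succeeds); samples with
#' an undefined contamination index are likewise excluded.
#'
#' @param config a configuration list, see [default_config()].  To run
#'   on real inputs instead of synthetic data, supply `config$refs`
#'   (list with FASTA paths `a`, `b`) and `config$samples` (data frame
#'   `sample_id`, `group`, `fastq`) in place of `genome`/`simulate`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `indices`, `comparison`, `discarded`
#'   and `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1

  # --- references and reads ----------------------------------------------
  if (!is.null(config$refs)) {
    genome_a <- read_fasta(config$refs$a)[[1]]
    genome_b <- read_fasta(config$refs$b)[[1]]
    samples <- config$samples
    reads_of <- lapply(seq_len(nrow(samples)),
                       function(i) read_fastq(samples$fastq[i]))
  } else {
    pair <- evolve_genome_pair(config$genome$length,
                               config$genome$divergence,
                               seed = .derive_seed(seed, 11L))
    genome_a <- pair$seq_a; genome_b <- pair$seq_b
    write_fasta(c(genomeA = genome_a, genomeB = genome_b),
                file.path(out_dir, "references.fasta"))
    sim <- config$simulate
    groups <- rep(names(sim$contamination),
                  each = sim$n_samples_per_group)
    samples <- data.frame(
      sample_id = sprintf("%s_%d", groups,
                          rep(seq_len(sim$n_samples_per_group),
                              times = length(sim$contamination))),
      group = groups, stringsAsFactors = FALSE)
    reads_of <- lapply(seq_len(nrow(samples)), function(i)
      simulate_reads(pair, sim$n_reads,
                     contamination = sim$contamination[[samples$group[i]]],
                     read_length = sim$read_length,
                     error_rate = sim$error_rate,
                     quality_model = sim$quality_model,
                     seed = .derive_seed(seed, 100L + i)))
  }

  qc <- config$qc
  ap <- align_params(seed_length = config$align$seed_length,
                     seed_mismatches = config$align$seed_mismatches %||% 0,
                     min_score = config$align$min_score %||%
                       (2 * config$align$seed_length))

  # --- per-sample qc + classification ------------------------------------
  discarded <- character(0)
  idx_rows <- list()
  class_counts <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    rs <- reads_of[[i]]
    span <- optimal_read_span(position_quality_summary(rs),
                              threshold_q = qc$threshold_q,
                              min_span = qc$min_span)
    if (!span$pass) {
      .warnf("sample '%s' discarded: optimal span %d < %d", sid,
             span$span_length, qc$min_span)
      discarded <- c(discarded, sid)
      next
    }
    if (isTRUE(qc$trim)) rs <- trim_reads_to_span(rs, span)
    rs <- subsample_reads(rs, qc$subsample, seed = .derive_seed(seed, 200L + i))
    cl <- classify_reads(rs, genome_a, genome_b, ap)
    class_counts[[sid]] <- c(n_specific_a = cl$n_specific_a,
                             n_specific_b = cl$n_specific_b,
                             n_both = cl$n_both, n_neither = cl$n_neither)
    ci <- tryCatch(contamination_index(cl, sample_id = sid),
                   serascan_undefined_index = function(e) {
                     .warnf("%s", conditionMessage(e)); NULL
                   })
    if (is.null(ci)) { discarded <- c(discarded, sid); next }
    idx_rows[[sid]] <- data.frame(sample_id = sid,
                                  group = samples$group[i],
                                  n_specific_a = ci$n_specific_a,
                                  n_specific_b = ci$n_specific_b,
                                  r = ci$r, stringsAsFactors = FALSE)
  }
  empty_idx <- data.frame(sample_id = character(0), group = character(0),
                          n_specific_a = integer(0),
                          n_specific_b = integer(0), r = numeric(0))
  indices <- if (length(idx_rows)) do.call(rbind, idx_rows) else empty_idx
  rownames(indices) <- NULL

  counts_df <- cbind(data.frame(sample_id = names(class_counts) %||%
                                  character(0),
                                stringsAsFactors = FALSE),
                     do.call(rbind, class_counts))
  write_tsv(counts_df, file.path(out_dir, "classification_counts.tsv"))
  write_tsv(indices, file.path(out_dir, "contamination_indices.tsv"))

  # --- quantification ----------------------------------------------------
  num <- config$quantify$numerator_group
  den <- config$quantify$denominator_group
  if (is.null(indices) || !any(indices$group == num) ||
      !any(indices$group == den)) {
    .warnf("quantification skipped: a comparison group has no usable samples")
    comparison <- NULL
  } else {
    comparison <- compare_groups(indices, num, den)
    write_tsv(comparison$table, file.path(out_dir, "group_report.tsv"))
    jsonlite::write_json(comparison$test,
                         file.path(out_dir, "test_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  # --- provenance manifest ------------------------------------------------
  outputs <- c("classification_counts.tsv", "contamination_indices.tsv",
               if (!is.null(comparison)) c("group_report.tsv",
                                           "test_report.json"))
  if (is.null(config$refs)) outputs <- c("references.fasta", outputs)
  paths <- file.path(out_dir, outputs)
  manifest <- list(
    package = "serascan",
    version = as.character(utils::packageVersion("serascan")),
    config = config,
    discarded_samples = discarded,
    outputs = lapply(seq_along(outputs), function(i)
      list(file = outputs[i],
           md5 = unname(tools::md5sum(paths[i])))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(indices = indices, comparison = comparison,
                 discarded = discarded, manifest = manifest,
                 out_dir = out_dir))
}
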