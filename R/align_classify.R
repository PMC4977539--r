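# Competitive dual-genome read classification.  Each read is aligned
# independently against two reference genomes with a seed-and-extend
# local aligner (exact seed, ungapped extension); species-specific
# reads are those aligning to exactly one genome.

#' Alignment parameters
#'
#' Parameters of the built-in local aligner, mirroring the contract of
#' a local-mode short-read aligner run with a 25-base exact seed: local
#' alignment, seed length 25 with 0 seed mismatches, match +2 /
#' mismatch -4, both strands searched.  The default `min_score` of
#' `2 * seed_length` means a perfect 25-base local segment suffices to
#' call a read mapped.
#'
#' @param seed_length exact-seed length in bases (>= 10, <= 31).
#' @param seed_mismatches mismatches tolerated inside the seed (0 or 1).
#' @param match,mismatch alignment scores (match > 0, mismatch < 0).
#' @param min_score minimum local alignment score to call a hit.
#' @param search_both_strands also align the reverse complement.
#' @return Object of class `align_params`.
#' @export
align_params <- function(seed_length = 25, seed_mismatches = 0,
                         match = 2, mismatch = -4,
                         min_score = 2 * seed_length,
                         search_both_strands = TRUE) {
  .check_number(seed_length, "seed_length", lower = 10, upper = 31,
                integerish = TRUE)
  if (!seed_mismatches %in% c(0, 1))
    .stopf("seed_mismatches must be 0 or 1")
  .check_number(min_score, "min_score", lower = 1)
  stopifnot(match > 0, mismatch < 0)
  structure(list(seed_length = as.integer(seed_length),
                 seed_mismatches = as.integer(seed_mismatches),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 min_score = as.integer(min_score),
                 search_both_strands = isTRUE(search_both_strands),
                 mode = "local"),
            class = "align_params")
}

#' Build an exact-match seed index over a genome
#'
#' Maps every `seed_length`-mer of the forward genome to its 0-based
#' start positions.  Ambiguous bases (anything outside A/C/G/T)
#' produce no seeds.  Reverse-strand alignment is handled by querying
#' the reverse complement of the read, so only the forward genome is
#' indexed.
#'
#' @param genome a nucleotide string (or a single named element of
#'   [read_fasta()] output).
#' @param seed_length seed length in bases.
#' @return Object of class `seed_index` (holds the genome and an
#'   external-pointer k-mer map).
#' @export
build_index <- function(genome, seed_length = 25) {
  genome <- toupper(as.character(genome)[1])
  .check_number(seed_length, "seed_length", lower = 1, upper = 31,
                integerish = TRUE)
  if (nchar(genome) < seed_length)
    .stopf("genome (%d bases) shorter than seed_length (%d)",
           nchar(genome), seed_length)
  structure(list(ptr = cpp_build_index(genome, as.integer(seed_length)),
                 seed_length = as.integer(seed_length),
                 genome_length = nchar(genome)),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("<seed_index> %d bp genome, %d-mer seeds (%d stored)\n",
              x$genome_length, x$seed_length, cpp_index_n_seeds(x$ptr)))
  invisible(x)
}

#' Query a seed index for the exact positions of one k-mer
#'
#' @param index a [build_index()] object.
#' @param kmer a string of length `seed_length`.
#' @return Integer vector of 0-based genome start positions (empty if
#'   absent or ambiguous).
#' @export
query_index <- function(index, kmer) {
  stopifnot(inherits(index, "seed_index"))
  cpp_query_index(index$ptr, toupper(kmer))
}

.hits_from_batch <- function(df, min_score) {
  df  # already thresholded in C++
}

#' Align one read against an indexed genome
#'
#' Seed-and-extend local alignment: every exact (or, with
#' `seed_mismatches = 1`, near-exact) seed hit is extended ungapped in
#' both directions under the match/mismatch scores, keeping the
#' best-scoring segment that contains the seed.  The highest-scoring
#' hit is reported iff its score reaches `min_score`; ties break to the
#' lowest genome position, then the + strand.
#'
#' @param read a nucleotide string.
#' @param index a [build_index()] object.
#' @param params an [align_params()] object.
#' @return A one-row data frame (`score`, `start`, `end`, `strand`;
#'   0-based half-open forward-strand interval), or `NULL` when the
#'   read has no qualifying hit (reads shorter than the seed are
#'   unmappable, not an error).
#' @export
align_read <- function(read, index, params = align_params()) {
  stopifnot(inherits(index, "seed_index"), inherits(params, "align_params"))
  if (params$seed_length != index$seed_length)
    .stopf("params$seed_length (%d) != index seed_length (%d)",
           params$seed_length, index$seed_length)
  df <- cpp_align_batch(toupper(as.character(read)[1]), index$ptr,
                        params$seed_mismatches, params$match,
                        params$mismatch, params$min_score,
                        params$search_both_strands)
  if (is.na(df$score[1])) return(NULL)
  df
}

.category_from_hits <- function(mapped_a, mapped_b) {
  ifelse(mapped_a & mapped_b, "both",
         ifelse(mapped_a, "specific_a",
                ifelse(mapped_b, "specific_b", "neither")))
}

.new_classification <- function(ids, category, params) {
  structure(list(
    n_specific_a = sum(category == "specific_a"),
    n_specific_b = sum(category == "specific_b"),
    n_both = sum(category == "both"),
    n_neither = sum(category == "neither"),
    per_read = data.frame(id = ids, category = category,
                          stringsAsFactors = FALSE),
    params = params),
    class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  n <- nrow(x$per_read)
  cat(sprintf(paste0("<classification_result> %d reads: specific_a %d, ",
                     "specific_b %d, both %d, neither %d\n"),
              n, x$n_specific_a, x$n_specific_b, x$n_both, x$n_neither))
  invisible(x)
}

#' Competitively classify reads against two genomes
#'
#' Aligns every read independently to genome A (host) and genome B
#' (contaminant) and assigns each to one of four mutually exclusive
#' categories: `specific_a` (aligns to A only), `specific_b` (B only),
#' `both`, or `neither`.  Species-specific reads are those aligning to
#' exactly one genome; multi-mapping within one genome does not affect
#' the category (any qualifying hit counts as mapped).
#'
#' @param reads a [read_set()] or a character vector of sequences.
#' @param genome_a,genome_b nucleotide strings, or a single
#'   [genome_pair][evolve_genome_pair()] passed as `genome_a`.
#' @param params an [align_params()] object.
#' @return Object of class `classification_result` with counts
#'   `n_specific_a`, `n_specific_b`, `n_both`, `n_neither`, a
#'   `per_read` data frame (`id`, `category`) and the `params` used.
#' @export
classify_reads <- function(reads, genome_a, genome_b = NULL,
                           params = align_params()) {
  if (inherits(genome_a, "genome_pair")) {
    genome_b <- genome_a$seq_b
    genome_a <- genome_a$seq_a
  }
  seqs <- if (inherits(reads, "read_set")) reads$seq else as.character(reads)
  ids <- if (inherits(reads, "read_set")) reads$id
         else sprintf("read%06d", seq_along(seqs))
  if (!length(seqs))
    return(.new_classification(character(0), character(0), params))
  ia <- build_index(genome_a, params$seed_length)
  ib <- build_index(genome_b, params$seed_length)
  ha <- cpp_align_batch(toupper(seqs), ia$ptr, params$seed_mismatches,
                        params$match, params$mismatch, params$min_score,
                        params$search_both_strands)
  hb <- cpp_align_batch(toupper(seqs), ib$ptr, params$seed_mismatches,
                        params$match, params$mismatch, params$min_score,
                        params$search_both_strands)
  res <- .new_classification(ids,
                             .category_from_hits(!is.na(ha$score),
                                                 !is.na(hb$score)),
                             params)
  res$hits_a <- ha
  res$hits_b <- hb
  res
}

#' Exhaustive-oracle read classification
#'
#' Same classification contract as [classify_reads()], computed by the
#' independent exhaustive aligner: for every strand, read offset and
#' genome position the seed window is tested by direct character
#' comparison (no k-mer index) and extended ungapped.  Quadratic and
#' slow; intended to verify the seeded aligner on small instances.
#'
#' @inheritParams classify_reads
#' @return A `classification_result`.
#' @export
oracle_classify_reads <- function(reads, genome_a, genome_b = NULL,
                                  params = align_params()) {
  if (inherits(genome_a, "genome_pair")) {
    genome_b <- genome_a$seq_b
    genome_a <- genome_a$seq_a
  }
  seqs <- if (inherits(reads, "read_set")) reads$seq else as.character(reads)
  ids <- if (inherits(reads, "read_set")) reads$id
         else sprintf("read%06d", seq_along(seqs))
  if (!length(seqs))
    return(.new_classification(character(0), character(0), params))
  ha <- cpp_oracle_align_batch(toupper(seqs), toupper(genome_a),
                               params$seed_length, params$seed_mismatches,
                               params$match, params$mismatch,
                               params$min_score, params$search_both_strands)
  hb <- cpp_oracle_align_batch(toupper(seqs), toupper(genome_b),
                               params$seed_length, params$seed_mismatches,
                               params$match, params$mismatch,
                               params$min_score, params$search_both_strands)
  res <- .new_classification(ids,
                             .category_from_hits(!is.na(ha$score),
                                                 !is.na(hb$score)),
                             params)
  res$hits_a <- ha
  res$hits_b <- hb
  res
}

#' Classify reads from two external alignment files
#'
#' Ingestion path for an external aligner: the same categorical logic
#' as [classify_reads()], driven solely by the mapped/unmapped status
#' of each read in two SAM files (one per genome).  Secondary (0x100)
#' and supplementary (0x800) records are ignored; mapped means flag
#' 0x4 unset.
#'
#' @param sam_a,sam_b paths to SAM files of the same reads aligned to
#'   genome A and genome B (or data frames from [read_sam()]).
#' @param params optional [align_params()] recorded in the result.
#' @return A `classification_result`.
#' @export
classify_from_alignments <- function(sam_a, sam_b, params = NULL) {
  a <- if (is.data.frame(sam_a)) sam_a else read_sam(sam_a)
  b <- if (is.data.frame(sam_b)) sam_b else read_sam(sam_b)
  only_a <- setdiff(a$id, b$id)
  only_b <- setdiff(b$id, a$id)
  if (length(only_a))
    .stopf("read id '%s' present in alignment A but absent from B", only_a[1])
  if (length(only_b))
    .stopf("read id '%s' present in alignment B but absent from A", only_b[1])
  mb <- b$mapped[match(a$id, b$id)]
  .new_classification(a$id, .category_from_hits(a$mapped, mb), params)
}
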