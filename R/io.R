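# Shared format readers/writers: FASTQ (4-line, PHRED+33), FASTA
# (80-column wrap), SAM (flag-driven mapped status only), and TSV with
# '#'-prefixed metadata lines.  Gzip is detected by magic bytes, not
# extension.

.is_gzipped <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  length(magic) == 2 && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

.read_lines_auto <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (.is_gzipped(path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    readLines(con)
  } else readLines(path)
}

#' Read a FASTQ file
#'
#' Strict 4-line-record FASTQ with PHRED+33 qualities; gzip input is
#' detected transparently.  Truncated records, sequence/quality length
#' mismatches and out-of-range quality bytes raise a format error
#' naming the offending record.
#'
#' @param path input file (optionally gzipped).
#' @return A [read_set()].
#' @export
read_fastq <- function(path) {
  lines <- .read_lines_auto(path)
  if (!length(lines)) {
    .warnf("empty FASTQ file: %s", path)
    return(read_set(character(0), character(0), character(0)))
  }
  if (length(lines) %% 4 != 0)
    .stopf("truncated FASTQ record at end of %s (%d lines)", path,
           length(lines))
  idx <- seq(1, length(lines), by = 4)
  rec <- (idx - 1) %/% 4 + 1
  heads <- lines[idx]
  bad <- which(substr(heads, 1, 1) != "@")
  if (length(bad))
    .stopf("record %d: header does not start with '@'", rec[bad[1]])
  plus <- lines[idx + 2]
  bad <- which(substr(plus, 1, 1) != "+")
  if (length(bad))
    .stopf("record %d: separator line does not start with '+'", rec[bad[1]])
  seqs <- lines[idx + 1]
  quals <- lines[idx + 3]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    .stopf("record %d: sequence and quality lengths differ", rec[bad[1]])
  bad <- grep("[^\\x21-\\x7e]", quals, perl = TRUE)
  if (length(bad))
    .stopf("record %d: quality byte outside PHRED+33 printable range",
           rec[bad[1]])
  ids <- sub("^@", "", vapply(strsplit(heads, "[ \t]"), `[`, character(1), 1))
  read_set(ids, seqs, quals)
}

#' Write a FASTQ file
#'
#' @param reads a [read_set()].
#' @param path output path; a `.gz` suffix writes gzip.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- character(4 * nrow(reads))
  if (nrow(reads)) {
    lines[seq(1, length(lines), 4)] <- paste0("@", reads$id)
    lines[seq(2, length(lines), 4)] <- reads$seq
    lines[seq(3, length(lines), 4)] <- "+"
    lines[seq(4, length(lines), 4)] <- reads$qual
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a FASTA file
#'
#' Multi-line sequences are concatenated per record.
#'
#' @param path input file (optionally gzipped).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- .read_lines_auto(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) .stopf("empty FASTA file: %s", path)
  is_hdr <- substr(lines, 1, 1) == ">"
  if (!is_hdr[1])
    .stopf("line 1: FASTA must start with a '>' header")
  grp <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  names_ <- vapply(strsplit(headers, "[ \t]"), `[`, character(1), 1)
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]),
                 paste, character(1), collapse = "")
  empty <- setdiff(seq_along(headers), as.integer(names(seqs)))
  if (length(empty))
    .stopf("FASTA record '%s' has no sequence", names_[empty[1]])
  names(seqs) <- names_[as.integer(names(seqs))]
  seqs
}

#' Write a FASTA file (80-column wrap)
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width wrap width (default 80).
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i] %||% sprintf("seq%d", i)), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read mapped/unmapped status from a SAM file
#'
#' Parses only what competitive classification needs: the read id and
#' the flag field of primary records.  Secondary (0x100) and
#' supplementary (0x800) records are skipped; a read is mapped iff
#' flag bit 0x4 is unset.
#'
#' @param path a SAM text file.
#' @return Data frame with columns `id`, `mapped` (one row per primary
#'   record).
#' @export
read_sam <- function(path) {
  lines <- .read_lines_auto(path)
  body <- which(substr(lines, 1, 1) != "@")
  ids <- character(0); flags <- integer(0)
  if (length(body)) {
    fields <- strsplit(lines[body], "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf < 11)
    if (length(bad))
      .stopf("line %d: SAM record has %d fields (expected >= 11)",
             body[bad[1]], nf[bad[1]])
    ids <- vapply(fields, `[`, character(1), 1)
    flags <- suppressWarnings(as.integer(vapply(fields, `[`,
                                                character(1), 2)))
    bad <- which(is.na(flags))
    if (length(bad))
      .stopf("line %d: non-numeric SAM flag", body[bad[1]])
  }
  primary <- bitwAnd(flags, bitwOr(256L, 2048L)) == 0L
  data.frame(id = ids[primary],
             mapped = bitwAnd(flags[primary], 4L) == 0L,
             stringsAsFactors = FALSE)
}

#' Write a truth-label sidecar TSV for simulated reads
#'
#' @param reads a labelled [read_set()] from [simulate_reads()].
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
write_truth_tsv <- function(reads, path) {
  stopifnot("origin" %in% names(reads))
  write_tsv(reads[c("id", "origin", "chrom", "start", "end", "strand")],
            path)
}

#' Write a TSV with optional '#'-prefixed metadata lines
#'
#' @param df data frame.
#' @param path output path.
#' @param metadata optional named list written as `# key: value` lines.
#' @return The path, invisibly.
#' @export
write_tsv <- function(df, path, metadata = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  if (!is.null(metadata))
    writeLines(sprintf("# %s: %s", names(metadata),
                       vapply(metadata, function(v)
                         paste(format(v, scientific = FALSE),
                               collapse = ","), character(1))), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with '#'-prefixed metadata lines
#'
#' @param path input path.
#' @return Data frame (metadata lines skipped).
#' @export
read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
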