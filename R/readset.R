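#' Construct a read set
#'
#' A `read_set` is the package's container for sequencing reads: a
#' data frame with columns `id`, `seq` and `qual` (PHRED+33 quality
#' string, same length as the sequence).  Simulated reads additionally
#' carry ground-truth columns `origin` (`"A"` host / `"B"` contaminant),
#' `chrom`, `start`, `end` (0-based half-open, forward strand) and
#' `strand`.
#'
#' @param id character vector of read identifiers.
#' @param seq character vector of nucleotide sequences.
#' @param qual character vector of PHRED+33 quality strings.
#' @param origin,chrom,start,end,strand optional truth annotation
#'   vectors (see Details).
#' @return A data frame of class `read_set`.
#' @export
read_set <- function(id, seq, qual, origin = NULL, chrom = NULL,
                     start = NULL, end = NULL, strand = NULL) {
  id <- as.character(id); seq <- as.character(seq)
  qual <- as.character(qual)
  if (length(seq) != length(id) || length(qual) != length(id))
    .stopf("id, seq and qual must have equal length")
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    .stopf("sequence/quality length mismatch at read %d ('%s')",
           bad[1], id[bad[1]])
  df <- data.frame(id = id, seq = seq, qual = qual,
                   stringsAsFactors = FALSE)
  if (!is.null(origin)) {
    stopifnot(all(origin %in% c("A", "B")))
    df$origin <- origin
    df$chrom <- chrom
    df$start <- as.integer(start)
    df$end <- as.integer(end)
    df$strand <- strand
  }
  class(df) <- c("read_set", "data.frame")
  df
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads, lengths %s%s\n", nrow(x),
              if (nrow(x)) paste(range(nchar(x$seq)), collapse = "-")
              else "-",
              if ("origin" %in% names(x)) sprintf(
                ", labelled (%.1f%% contaminant)",
                100 * mean(x$origin == "B")) else ""))
  invisible(x)
}

.as_read_set <- function(df) {
  class(df) <- c("read_set", "data.frame")
  df
}

# decode PHRED+33 quality strings into a list of integer vectors
.qual_to_phred <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

.phred_to_qual <- function(phred) {
  vapply(phred, function(p) intToUtf8(p + 33L), character(1))
}

#' Reverse-complement nucleotide sequences
#'
#' Vectorised reverse complement over `A`/`C`/`G`/`T` (case preserved,
#' other characters become `N`).
#'
#' @param x character vector of sequences.
#' @return character vector of reverse-complemented sequences.
#' @export
revcomp <- function(x) cpp_revcomp(as.character(x))
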