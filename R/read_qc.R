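# Read-quality gate: per-cycle quality summary, longest
# above-threshold cycle span, dataset discard rule, trimming, and
# seeded subsampling.

#' Per-cycle quality summary
#'
#' Arithmetic mean PHRED score per sequencing cycle, averaged over all
#' reads long enough to cover that cycle (the in-package stand-in for
#' an external QC report).
#'
#' @param reads a [read_set()] (PHRED+33 qualities).
#' @param stat `"mean"` (default) or `"median"` per-cycle aggregate.
#' @return Object of class `position_quality_summary`: list with
#'   `per_position_q` (numeric, one value per cycle) and
#'   `n_reads_summarized`.
#' @export
position_quality_summary <- function(reads, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (!nrow(reads)) .stopf("empty read set")
  bad <- grep("[^\\x21-\\x7e]", reads$qual, perl = TRUE)
  if (length(bad))
    .stopf("non-PHRED+33 quality character in record %d ('%s')",
           bad[1], reads$id[bad[1]])
  phred <- .qual_to_phred(reads$qual)
  L <- max(lengths(phred))
  m <- matrix(NA_real_, length(phred), L)
  for (i in seq_along(phred)) m[i, seq_along(phred[[i]])] <- phred[[i]]
  per <- if (stat == "mean") colMeans(m, na.rm = TRUE)
         else apply(m, 2, stats::median, na.rm = TRUE)
  structure(list(per_position_q = per,
                 n_reads_summarized = nrow(reads), stat = stat),
            class = "position_quality_summary")
}

#' @export
print.position_quality_summary <- function(x, ...) {
  cat(sprintf("<position_quality_summary> %d cycles, %d reads, %s Q %.1f-%.1f\n",
              length(x$per_position_q), x$n_reads_summarized, x$stat,
              min(x$per_position_q), max(x$per_position_q)))
  invisible(x)
}

#' Optimal read span
#'
#' The longest uninterrupted run of cycles whose summary quality
#' strictly exceeds `threshold_q` (exactly `threshold_q` does not
#' qualify).  Ties between equal-length runs are broken towards the
#' smallest start, preserving 5' sequence.  A dataset whose optimal
#' span is shorter than `min_span` fails the gate and is discarded
#' from downstream analysis.
#'
#' @param summary a [position_quality_summary()] (or a bare numeric
#'   vector of per-cycle qualities).
#' @param threshold_q PHRED threshold (default 30).
#' @param min_span minimum span length in bases to pass (default 20).
#' @return Object of class `span_report`: list with `start`, `end`
#'   (0-based half-open over cycles), `span_length`, `pass`,
#'   `threshold_q`, `min_span`.
#' @export
optimal_read_span <- function(summary, threshold_q = 30, min_span = 20) {
  q <- if (inherits(summary, "position_quality_summary"))
    summary$per_position_q else as.numeric(summary)
  if (!length(q)) .stopf("empty quality summary")
  ok <- q > threshold_q
  best_len <- 0L; best_start <- 0L
  run_start <- NA_integer_
  for (i in seq_along(ok)) {
    if (ok[i]) {
      if (is.na(run_start)) run_start <- i
      len <- i - run_start + 1L
      if (len > best_len) { best_len <- len; best_start <- run_start }
    } else run_start <- NA_integer_
  }
  start0 <- if (best_len > 0L) best_start - 1L else 0L
  structure(list(start = start0, end = start0 + best_len,
                 span_length = best_len, pass = best_len >= min_span,
                 threshold_q = threshold_q, min_span = min_span),
            class = "span_report")
}

#' @export
print.span_report <- function(x, ...) {
  cat(sprintf("<span_report> [%d, %d) length %d, Q>%g, %s (min_span %d)\n",
              x$start, x$end, x$span_length, x$threshold_q,
              if (x$pass) "PASS" else "DISCARD", x$min_span))
  invisible(x)
}

#' Trim reads to an optimal span
#'
#' Slices every read's sequence and quality to the span's `[start, end)`
#' cycle interval.  Reads shorter than `end` are truncated at their own
#' length, and dropped entirely if the remaining slice is shorter than
#' the span's `min_span`.
#'
#' @param reads a [read_set()].
#' @param span a passing [span_report][optimal_read_span()].
#' @return The trimmed [read_set()] (truth columns preserved; origin
#'   coordinates are left untouched -- they describe the untrimmed
#'   fragment).
#' @export
trim_reads_to_span <- function(reads, span) {
  stopifnot(inherits(span, "span_report"))
  if (!span$pass)
    .stopf("span failed the quality gate (length %d < min_span %d); dataset should be discarded",
           span$span_length, span$min_span)
  from <- span$start + 1L
  to <- span$end
  out <- reads
  out$seq <- substr(reads$seq, from, to)
  out$qual <- substr(reads$qual, from, to)
  keep <- nchar(out$seq) >= span$min_span
  .as_read_set(out[keep, , drop = FALSE])
}

#' Random subsample of reads
#'
#' Uniform sample without replacement of `min(n, nrow(reads))` reads,
#' returned in input-file order; used to put samples of very different
#' depth on a common footing (default one million reads).
#'
#' @param reads a [read_set()].
#' @param n sample size (default `1e6`).
#' @param seed integer seed.
#' @return A [read_set()] subset.
#' @export
subsample_reads <- function(reads, n = 1e6, seed = NULL) {
  .check_number(n, "n", lower = 1, integerish = TRUE)
  if (n >= nrow(reads)) return(reads)
  .with_seed(.derive_seed(seed, 5L), {
    keep <- sort(sample.int(nrow(reads), n))
    .as_read_set(reads[keep, , drop = FALSE])
  })
}
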