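# Independent brute-force oracles used by property and acceptance tests.
# These deliberately avoid the code paths they verify.

# O(L^2) interval maximizer: longest interval whose cycles are ALL
# strictly above thr; leftmost on ties.  Returns c(start0, end0) 0-based
# half-open.
span_oracle <- function(q, thr) {
  L <- length(q)
  best <- c(0L, 0L)
  for (s in seq_len(L)) {
    for (e in s:L) {
      if (all(q[s:e] > thr) && (e - s + 1L) > (best[2] - best[1])) {
        best <- c(s - 1L, e)
      }
    }
  }
  best
}

# Exact Mann-Whitney oracle by direct pair counting over every group
# assignment (the implementation uses midranks instead).
mw_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  ustat <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  ux_obs <- ustat(x, y)
  splits <- combn(n + m, n)
  ux_all <- apply(splits, 2, function(ix) ustat(pooled[ix], pooled[-ix]))
  eps <- 1e-9
  p <- min(1, 2 * min(mean(ux_all <= ux_obs + eps),
                      mean(ux_all >= ux_obs - eps)))
  list(U = min(ux_obs, n * m - ux_obs), p = p)
}

# random PHRED+33 read set
random_read_set <- function(n, len, qmin = 2, qmax = 40, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
  quals <- vapply(seq_len(n), function(i)
    intToUtf8(sample(qmin:qmax, len, replace = TRUE) + 33L), character(1))
  read_set(sprintf("r%03d", seq_len(n)), seqs, quals)
}

# minimal SAM writer for ingestion tests
write_mini_sam <- function(path, ids, flags, rname = "ref") {
  lines <- c("@HD\tVN:1.6", sprintf("@SQ\tSN:%s\tLN:1000", rname),
             sprintf("%s\t%d\t%s\t1\t60\t10M\t*\t0\t0\tACGTACGTAC\t**********",
                     ids, flags, ifelse(bitwAnd(flags, 4L) == 4L, "*", rname)))
  writeLines(lines, path)
  path
}
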