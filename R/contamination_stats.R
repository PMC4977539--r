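# Contamination-index statistics: the contaminant/host specific-read
# ratio, group fold changes, exact Mann-Whitney U and unpaired t tests,
# and inversion of the index to a mixture fraction.

#' Contamination index of a classified sample
#'
#' The ratio of contaminant-specific to host-specific read counts,
#' `r = n_specific_b / n_specific_a`.  Using host-specific reads as the
#' denominator normalises for variable mapping rates between samples.
#' Undefined when no host-specific reads exist; such samples are
#' excluded downstream with a warning rather than assigned an infinite
#' index.
#'
#' @param result a [classify_reads()] result, or a list/vector with
#'   elements `n_specific_a` and `n_specific_b`.
#' @param sample_id optional label stored in the output.
#' @return Object of class `contamination_index`: list with
#'   `sample_id`, `n_specific_a`, `n_specific_b`, `r`.
#' @export
contamination_index <- function(result, sample_id = NA_character_) {
  a <- result[["n_specific_a"]]
  b <- result[["n_specific_b"]]
  if (is.null(a) || is.null(b))
    .stopf("input must carry n_specific_a and n_specific_b")
  if (a == 0)
    stop(structure(class = c("serascan_undefined_index", "error",
                             "condition"),
                   list(message = sprintf(
                     "contamination index undefined for sample '%s': no host-specific reads",
                     sample_id), call = NULL)))
  structure(list(sample_id = sample_id, n_specific_a = a,
                 n_specific_b = b, r = b / a),
            class = "contamination_index")
}

#' @export
print.contamination_index <- function(x, ...) {
  cat(sprintf("<contamination_index> %s: %d/%d = %.4g\n",
              x$sample_id, x$n_specific_b, x$n_specific_a, x$r))
  invisible(x)
}

.mean_sem <- function(x) {
  n <- length(x)
  c(mean = mean(x), sem = if (n > 1) sd(x) / sqrt(n) else NA_real_, n = n)
}

#' Fold change between two groups of contamination indices
#'
#' `FC = mean(numerator group) / mean(denominator group)`, the ratio of
#' group means (the definition consistent with reporting group means
#' +/- SEM alongside the fold change).  SEM is undefined (reported
#' `NA`) for singleton groups.
#'
#' @param group_numerator,group_denominator numeric vectors of indices
#'   (e.g. exosomal vs cellular samples).
#' @return List with `fc`, `mean_numerator`, `sem_numerator`,
#'   `mean_denominator`, `sem_denominator`, `n_numerator`,
#'   `n_denominator`.
#' @export
fold_change <- function(group_numerator, group_denominator) {
  if (!length(group_numerator) || !length(group_denominator))
    .stopf("both groups must be non-empty")
  ms_n <- .mean_sem(group_numerator)
  ms_d <- .mean_sem(group_denominator)
  if (ms_d[["mean"]] <= 0)
    .stopf("fold change undefined: denominator group mean is %g",
           ms_d[["mean"]])
  list(fc = ms_n[["mean"]] / ms_d[["mean"]],
       mean_numerator = ms_n[["mean"]], sem_numerator = ms_n[["sem"]],
       mean_denominator = ms_d[["mean"]], sem_denominator = ms_d[["sem"]],
       n_numerator = as.integer(ms_n[["n"]]),
       n_denominator = as.integer(ms_d[["n"]]))
}

# Mann-Whitney U of x against y with midrank tie credit
.u_statistic <- function(x, y) {
  n <- length(x)
  r <- rank(c(x, y))
  sum(r[seq_len(n)]) - n * (n + 1) / 2
}

#' Exact two-tailed Mann-Whitney U test
#'
#' U is computed with midrank credit for ties
#' (`U_x = #\{x_i < y_j\} + 0.5 #\{ties\}`); the reported statistic is
#' `min(U_x, U_y)`.  When `choose(n + m, n) <= exact_limit` the null
#' distribution is enumerated exactly over all group assignments of the
#' observed (possibly tied) values, and the two-tailed p is twice the
#' smaller tail probability, capped at 1.  Larger problems use the
#' normal approximation with tie-corrected variance and continuity
#' correction, flagged as `method = "approx"`.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param exact_limit enumeration bound on `choose(n + m, n)`.
#' @return List with `U`, `U_x`, `U_y`, `p`, `method`.
#' @export
mann_whitney_exact <- function(x, y, exact_limit = 1e5) {
  if (!length(x) || !length(y)) .stopf("both samples must be non-empty")
  n <- length(x); m <- length(y)
  ux <- .u_statistic(x, y)
  uy <- n * m - ux
  pooled <- c(x, y)
  if (choose(n + m, n) <= exact_limit) {
    r <- rank(pooled)
    splits <- combn(n + m, n)
    ux_all <- colSums(matrix(r[splits], nrow = n)) - n * (n + 1) / 2
    eps <- 1e-9
    p_lo <- mean(ux_all <= ux + eps)
    p_hi <- mean(ux_all >= ux - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n * m / 2
    ties <- table(pooled)
    N <- n + m
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    cc <- 0.5
    z <- if (ux > mu) (ux - mu - cc) / sqrt(sigma2)
         else if (ux < mu) (ux - mu + cc) / sqrt(sigma2) else 0
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "approx"
  }
  list(U = min(ux, uy), U_x = ux, U_y = uy, p = p, method = method)
}

#' Unpaired two-tailed t-test (pooled variance)
#'
#' Classical two-sample pooled-variance t statistic with `n + m - 2`
#' degrees of freedom.  When both groups have zero variance: equal
#' means give `t = 0, p = 1` by convention; unequal means give an
#' infinite statistic and `p = 0`.
#'
#' @param x,y numeric vectors with at least 2 values each.
#' @return List with `t`, `df`, `p`.
#' @export
t_test_unpaired <- function(x, y) {
  n <- length(x); m <- length(y)
  if (n < 2 || m < 2) .stopf("each group needs at least 2 values")
  df <- n + m - 2
  sp2 <- ((n - 1) * stats::var(x) + (m - 1) * stats::var(y)) / df
  d <- mean(x) - mean(y)
  if (sp2 == 0) {
    if (d == 0) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(d) * Inf, df = df, p = 0))
  }
  tt <- d / sqrt(sp2 * (1 / n + 1 / m))
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

#' Estimate the contaminant mixture fraction from the index
#'
#' Inverts the contamination index to a fraction of contaminant reads,
#' `c_hat = r / (1 + r)`.  This is exact when cross-species mapping is
#' symmetric (both-mapping reads are excluded from both specific
#' counts in proportion), and an approximation otherwise.
#'
#' @param r a contamination index value or [contamination_index()]
#'   object.
#' @return Estimated contaminant fraction in `[0, 1)`.
#' @export
estimate_mixture_fraction <- function(r) {
  if (inherits(r, "contamination_index")) r <- r$r
  .check_number(r, "r", lower = 0)
  r / (1 + r)
}

#' Group comparison of contamination indices
#'
#' Builds the per-dataset summary (group means +/- SEM, fold change)
#' and runs the global two-tailed Mann-Whitney U test across all
#' samples (a single global test; within-dataset testing is not
#' meaningful at these sample sizes).
#'
#' @param indices data frame with columns `sample_id`, `group`, `r`
#'   and optionally `dataset`.
#' @param numerator_group,denominator_group group labels forming the
#'   fold change (numerator conventionally the exRNA fraction).
#' @return List with `table` (one row per dataset: means, SEMs, FC, n)
#'   and `test` (global [mann_whitney_exact()] result).
#' @export
compare_groups <- function(indices, numerator_group = "exosomal",
                           denominator_group = "cellular") {
  stopifnot(all(c("sample_id", "group", "r") %in% names(indices)))
  if (is.null(indices$dataset)) indices$dataset <- "all"
  rows <- lapply(split(indices, indices$dataset), function(d) {
    num <- d$r[d$group == numerator_group]
    den <- d$r[d$group == denominator_group]
    if (!length(num) || !length(den)) return(NULL)
    fc <- fold_change(num, den)
    data.frame(dataset = d$dataset[1],
               mean_denominator = fc$mean_denominator,
               sem_denominator = fc$sem_denominator,
               mean_numerator = fc$mean_numerator,
               sem_numerator = fc$sem_numerator,
               fc = fc$fc,
               n = sprintf("%d vs %d", fc$n_denominator, fc$n_numerator),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(tab) <- NULL
  test <- mann_whitney_exact(indices$r[indices$group == numerator_group],
                             indices$r[indices$group == denominator_group])
  list(table = tab, test = test)
}
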