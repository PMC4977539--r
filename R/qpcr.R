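# qPCR analytics: delta-Cq relative quantification and geNorm
# multi-reference normalisation (gene stability M-values and per-sample
# normalisation factors).

#' Relative quantity from a target/reference Cq pair
#'
#' Standard delta-Cq quantification: `RQ = E^(Cq_reference - Cq_target)`
#' with amplification efficiency `E` (2 = perfect doubling).  A
#' one-cycle increase in the target Cq halves RQ at `E = 2`.
#'
#' @param cq_target,cq_reference quantification cycles (finite).
#' @param efficiency amplification efficiency in `(1, 2]`.
#' @return Relative quantity (vectorised).
#' @export
relative_quantity <- function(cq_target, cq_reference, efficiency = 2) {
  if (efficiency <= 1) .stopf("efficiency must exceed 1")
  if (any(!is.finite(cq_target)) || any(!is.finite(cq_reference)))
    .stopf("Cq values must be finite")
  efficiency^(cq_reference - cq_target)
}

.cq_matrix <- function(cq) {
  if (inherits(cq, "cq_table")) cq$cq else as.matrix(cq)
}

# per-gene relative quantities: E^(min Cq across samples - Cq), so the
# best-expressed sample of each gene has quantity 1
.cq_quantities <- function(m, efficiency = 2) {
  efficiency^(apply(m, 1, min) - m)
}

#' geNorm gene-stability values
#'
#' For each candidate reference gene j, computes the standard deviation
#' across samples of the log2 quantity ratio against every other
#' candidate k, and averages: `M(j) = mean_k sd_s(log2 q_js / q_ks)`.
#' Lower M means more stable expression.  Quantities are derived per
#' gene as `E^(min Cq - Cq)`.
#'
#' @param cq a [simulate_cq_table()] object or a genes x samples Cq
#'   matrix.
#' @param genes candidate gene names (default: all rows).
#' @param efficiency amplification efficiency (default 2).
#' @return Named numeric vector of M-values (sorted as given).
#' @export
genorm_m_values <- function(cq, genes = NULL, efficiency = 2) {
  m <- .cq_matrix(cq)
  if (is.null(genes)) genes <- rownames(m)
  if (length(genes) < 2) .stopf("geNorm needs at least 2 candidate genes")
  if (ncol(m) < 2) .stopf("geNorm needs at least 2 samples")
  if (!all(genes %in% rownames(m)))
    .stopf("unknown gene(s): %s",
           paste(setdiff(genes, rownames(m)), collapse = ", "))
  lq <- log2(.cq_quantities(m[genes, , drop = FALSE], efficiency))
  vapply(seq_along(genes), function(j) {
    others <- setdiff(seq_along(genes), j)
    mean(vapply(others, function(k) sd(lq[j, ] - lq[k, ]), numeric(1)))
  }, numeric(1)) -> M
  names(M) <- genes
  M
}

#' Iterative geNorm ranking (optional elimination mode)
#'
#' Repeatedly removes the least stable gene (highest M) and recomputes,
#' producing the classic geNorm stability ranking.  The default
#' analysis uses a fixed control panel without elimination; this mode
#' is for choosing a panel.
#'
#' @inheritParams genorm_m_values
#' @return Data frame `gene`, `rank` (1 = most stable; the final two
#'   genes share rank 1), `m_at_elimination`.
#' @export
genorm_rank <- function(cq, genes = NULL, efficiency = 2) {
  m <- .cq_matrix(cq)
  if (is.null(genes)) genes <- rownames(m)
  remaining <- genes
  out <- list()
  while (length(remaining) > 2) {
    M <- genorm_m_values(m, remaining, efficiency)
    worst <- names(which.max(M))
    out[[worst]] <- max(M)
    remaining <- setdiff(remaining, worst)
  }
  M2 <- genorm_m_values(m, remaining, efficiency)
  res <- data.frame(
    gene = c(remaining, rev(names(out))),
    rank = c(1L, 1L, seq.int(2L, length.out = length(out))),
    m_at_elimination = c(M2, rev(unlist(out))),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' geNorm normalisation factors
#'
#' Per-sample geometric mean of the control genes' relative
#' quantities; target gene quantities divided by this factor are
#' normalised for RNA input.
#'
#' @param cq a `cq_table` or genes x samples Cq matrix.
#' @param control_genes names of the reference panel (>= 2).
#' @param efficiency amplification efficiency.
#' @return Named numeric vector of per-sample factors (> 0).
#' @export
genorm_normalization_factor <- function(cq, control_genes = NULL,
                                        efficiency = 2) {
  if (is.null(control_genes) && inherits(cq, "cq_table"))
    control_genes <- cq$controls
  m <- .cq_matrix(cq)
  if (length(control_genes) < 2) .stopf("need at least 2 control genes")
  if (!all(control_genes %in% rownames(m)))
    .stopf("unknown control gene(s): %s",
           paste(setdiff(control_genes, rownames(m)), collapse = ", "))
  q <- .cq_quantities(m[control_genes, , drop = FALSE], efficiency)
  exp(colMeans(log(q)))
}

#' Normalised relative quantities with detection flags
#'
#' Divides each target gene's relative quantity by the geNorm
#' normalisation factor.  Wells at or beyond the no-amplification
#' ceiling (Cq >= `ceiling`, default 40) are flagged undetected; their
#' normalised values are reported but should be interpreted as
#' upper bounds.
#'
#' @param cq a `cq_table` or genes x samples Cq matrix.
#' @param targets target gene names (default: non-control genes).
#' @param control_genes reference panel (>= 2).
#' @param efficiency amplification efficiency.
#' @param ceiling no-detection Cq ceiling (default 40).
#' @return List with `normalized` (targets x samples), `undetected`
#'   (logical matrix), `factor` (per-sample).
#' @export
normalize_rq <- function(cq, targets = NULL, control_genes = NULL,
                         efficiency = 2, ceiling = 40) {
  if (inherits(cq, "cq_table")) {
    control_genes <- control_genes %||% cq$controls
    ceiling <- if (is.null(cq$ceiling)) ceiling else cq$ceiling
  }
  m <- .cq_matrix(cq)
  if (is.null(targets)) targets <- setdiff(rownames(m), control_genes)
  f <- genorm_normalization_factor(m, control_genes, efficiency)
  q <- .cq_quantities(m[targets, , drop = FALSE], efficiency)
  norm <- sweep(q, 2, f, "/")
  list(normalized = norm,
       undetected = m[targets, , drop = FALSE] >= ceiling,
       factor = f)
}
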