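# RNA composition analytics: reads-per-million normalisation, biotype
# fractions, top-k feature ranking, depletion efficiency, and
# Pearson-correlation hierarchical clustering of log profiles.

.counts_matrix <- function(table) {
  if (inherits(table, "biotype_count_table")) table$counts
  else as.matrix(table)
}

#' Reads-per-million normalisation
#'
#' Scales every sample (column) to reads per million mapped:
#' `rpm = count / sample_total * 1e6`.
#'
#' @param table a [simulate_count_table()] object or a features x
#'   samples count matrix.
#' @return Numeric matrix of the same shape; every column sums to 1e6.
#' @export
rpm_normalize <- function(table) {
  counts <- .counts_matrix(table)
  if (any(counts < 0)) .stopf("counts must be non-negative")
  totals <- colSums(counts)
  zero <- which(totals == 0)
  if (length(zero))
    .stopf("sample '%s' has zero total mapped reads",
           colnames(counts)[zero[1]] %||% as.character(zero[1]))
  sweep(counts, 2, totals, "/") * 1e6
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Biotype composition per sample
#'
#' Sums RPM within each biotype and reports per-sample fractions, plus
#' per-group mean +/- SEM when a grouping is available.  Features with
#' no biotype annotation are assigned `"other"` with a warning.
#'
#' @param rpm an RPM matrix from [rpm_normalize()] (or a
#'   `biotype_count_table`, normalised internally).
#' @param feature_biotype named character vector mapping features to
#'   biotypes (taken from the table if omitted).
#' @param sample_group optional named character vector of group labels.
#' @return List with `fractions` (biotypes x samples), and when groups
#'   are given `group_mean` and `group_sem` (biotypes x groups).
#' @export
biotype_composition <- function(rpm, feature_biotype = NULL,
                                sample_group = NULL) {
  if (inherits(rpm, "biotype_count_table")) {
    feature_biotype <- feature_biotype %||% rpm$feature_biotype
    sample_group <- sample_group %||% rpm$sample_group
    rpm <- rpm_normalize(rpm)
  }
  if (is.null(feature_biotype)) .stopf("feature_biotype annotation required")
  bt <- feature_biotype[rownames(rpm)]
  if (anyNA(bt)) {
    .warnf("%d unannotated feature(s) assigned biotype 'other'",
           sum(is.na(bt)))
    bt[is.na(bt)] <- "other"
  }
  sums <- rowsum(rpm, group = bt)
  fractions <- sums / 1e6
  out <- list(fractions = fractions)
  if (!is.null(sample_group)) {
    g <- sample_group[colnames(rpm)]
    out$group_mean <- sapply(unique(g), function(gg)
      rowMeans(fractions[, g == gg, drop = FALSE]))
    out$group_sem <- sapply(unique(g), function(gg) {
      sub <- fractions[, g == gg, drop = FALSE]
      if (ncol(sub) > 1) apply(sub, 1, sd) / sqrt(ncol(sub))
      else rep(NA_real_, nrow(sub))
    })
  }
  out
}

#' Top-k features of a biotype by mean abundance
#'
#' @param rpm an RPM matrix (features x samples).
#' @param feature_biotype named biotype annotation; `NULL` ranks all
#'   features.
#' @param biotype biotype to filter on (e.g. `"miRNA"`); `NULL` for all.
#' @param k number of features to return; values beyond the feature
#'   count return everything.
#' @return Data frame `feature`, `mean_rpm` sorted by mean RPM
#'   descending, ties broken alphabetically by feature name.
#' @export
top_k_features <- function(rpm, feature_biotype = NULL, biotype = NULL,
                           k = 10) {
  .check_number(k, "k", lower = 1, integerish = TRUE)
  keep <- rownames(rpm)
  if (!is.null(biotype)) {
    if (is.null(feature_biotype)) .stopf("feature_biotype required to filter")
    keep <- keep[feature_biotype[keep] %in% biotype]
  }
  mu <- rowMeans(rpm[keep, , drop = FALSE])
  ord <- order(-mu, names(mu))
  res <- data.frame(feature = names(mu)[ord], mean_rpm = unname(mu[ord]),
                    stringsAsFactors = FALSE)
  head(res, k)
}

#' Depletion efficiency of an ultracentrifugation step
#'
#' The pellet-to-supernatant abundance ratio of an RNA species; values
#' above 1 mean ultracentrifugation pellets the species efficiently.
#' The Cq overload converts quantification cycles to abundances at
#' perfect doubling: `ratio = 2^(Cq_supernatant - Cq_pellet)`.
#'
#' @param pellet,supernatant abundances (both > 0), or Cq values when
#'   `from_cq = TRUE`.
#' @param from_cq interpret inputs as Cq values.
#' @return Depletion efficiency ratio(s).
#' @export
depletion_efficiency <- function(pellet, supernatant, from_cq = FALSE) {
  if (from_cq) {
    if (any(!is.finite(pellet)) || any(!is.finite(supernatant)))
      .stopf("Cq values must be finite")
    return(2^(supernatant - pellet))
  }
  if (any(pellet <= 0) || any(supernatant <= 0))
    .stopf("abundances must be positive")
  pellet / supernatant
}

#' Percent of RNA removed into the pellet
#'
#' `100 * pellet / (pellet + supernatant)` -- the share of total RNA
#' mass pelleted by ultracentrifugation.
#'
#' @param pellet_mass,supernatant_mass RNA masses (>= 0, sum > 0).
#' @return Percentage in `[0, 100]`.
#' @export
percent_removed <- function(pellet_mass, supernatant_mass) {
  if (any(pellet_mass < 0) || any(supernatant_mass < 0))
    .stopf("masses must be non-negative")
  tot <- pellet_mass + supernatant_mass
  if (any(tot == 0)) .stopf("total mass is zero")
  100 * pellet_mass / tot
}

#' Pearson-correlation hierarchical clustering of samples
#'
#' Clusters samples on their log-transformed RPM profiles with
#' distance `d(i, j) = 1 - Pearson r` and agglomerative linkage
#' (average by default).  Pearson correlation is shift- and
#' scale-invariant, so after RPM and log transformation the tree does
#' not depend on library size.
#'
#' @param rpm an RPM matrix (features x samples), or a
#'   `biotype_count_table` (normalised internally).
#' @param pseudocount added before the log (default 1).
#' @param log_base logarithm base (default 10).
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @return Object of class `cluster_tree`: list with `hclust` (the
#'   stats::hclust tree), `dist` and the parameters used.
#' @export
pearson_cluster <- function(rpm, pseudocount = 1, log_base = 10,
                            linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  if (inherits(rpm, "biotype_count_table")) rpm <- rpm_normalize(rpm)
  if (ncol(rpm) < 2 || nrow(rpm) < 2)
    .stopf("need at least 2 samples and 2 features")
  lm_ <- log(rpm + pseudocount, base = log_base)
  vars <- apply(lm_, 2, stats::var)
  if (any(vars == 0))
    .stopf("sample '%s' has a zero-variance profile; correlation undefined",
           colnames(lm_)[which(vars == 0)[1]])
  d <- as.dist(1 - cor(lm_))
  hc <- hclust(d, method = linkage)
  structure(list(hclust = hc, dist = d, pseudocount = pseudocount,
                 log_base = log_base, linkage = linkage),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree> %d samples, %s linkage on 1 - Pearson(log%g(RPM + %g))\n",
              length(x$hclust$labels), x$linkage, x$log_base,
              x$pseudocount))
  invisible(x)
}

#' Top split of a cluster tree
#'
#' The bipartition of samples induced by cutting the dendrogram at its
#' root (two clusters).
#'
#' @param tree a [pearson_cluster()] result.
#' @return List of two character vectors of sample names.
#' @export
top_split <- function(tree) {
  stopifnot(inherits(tree, "cluster_tree"))
  ct <- cutree(tree$hclust, k = 2)
  split(names(ct), ct)
}

#' Write a cluster tree as Newick
#'
#' @param tree a [pearson_cluster()] result.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "cluster_tree"))
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
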