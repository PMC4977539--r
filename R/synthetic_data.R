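# Synthetic-data module: every input the pipeline consumes can be
# generated here with known ground truth -- a diverged genome pair, read
# mixtures at a known contamination fraction, grouped biotype count
# tables, and qPCR Cq tables.

#' Simulate a pair of diverged reference genomes
#'
#' Draws a random ancestral sequence and derives a second genome by
#' substituting each position independently with probability
#' `divergence` (to a uniformly chosen different base).  This is a
#' desk-scale surrogate for a host/contaminant genome pair (e.g. human
#' GRCh38 vs bovine UMD3.1.1); the substitution-only model (no indels)
#' keeps the ungapped alignment oracle exact.
#'
#' @param length genome length in bases (>= 1000).
#' @param divergence per-site substitution probability in `[0, 1]`.
#' @param seed integer seed; identical seeds give identical pairs.
#' @return An object of class `genome_pair` with elements `seq_a`
#'   (host), `seq_b` (contaminant), `divergence`, `length`, `seed`.
#' @examples
#' gp <- evolve_genome_pair(2000, divergence = 0.15, seed = 1)
#' @export
evolve_genome_pair <- function(length, divergence, seed = NULL) {
  .check_number(length, "length", lower = 1000, integerish = TRUE)
  .check_number(divergence, "divergence", lower = 0, upper = 1)
  bases <- c("A", "C", "G", "T")
  .with_seed(.derive_seed(seed, 1L), {
    a <- sample(bases, length, replace = TRUE)
    b <- a
    mut <- which(runif(length) < divergence)
    if (length(mut)) {
      # substitute to a uniformly chosen *different* base
      shift <- sample.int(3L, length(mut), replace = TRUE)
      b[mut] <- bases[(match(a[mut], bases) - 1L + shift) %% 4L + 1L]
    }
    structure(list(seq_a = paste(a, collapse = ""),
                   seq_b = paste(b, collapse = ""),
                   divergence = divergence, length = as.integer(length),
                   seed = seed),
              class = "genome_pair")
  })
}

#' @export
print.genome_pair <- function(x, ...) {
  cat(sprintf("<genome_pair> %d bp, divergence %.3f (realized %.4f)\n",
              x$length, x$divergence, genome_divergence(x)))
  invisible(x)
}

#' Realized per-site mismatch fraction of a genome pair
#'
#' @param pair a [genome_pair][evolve_genome_pair()].
#' @return Fraction of positions differing between the two genomes.
#' @export
genome_divergence <- function(pair) {
  stopifnot(inherits(pair, "genome_pair"))
  a <- utf8ToInt(pair$seq_a)
  b <- utf8ToInt(pair$seq_b)
  mean(a != b)
}

#' Simulate a labelled read mixture from a genome pair
#'
#' Emulates a single-end FASTQ file from a culture contaminated with a
#' second species.  Each read's genome of origin is Bernoulli(`contamination`)
#' (B = contaminant), its start uniform, its strand uniform (minus-strand
#' reads are emitted as reverse complements).  Sequencing errors are
#' i.i.d. base substitutions at `error_rate`.  Qualities follow
#' `quality_model` (expected PHRED per cycle) with integer jitter of
#' +/-2, floored at 2 and capped at 40 -- a linear 3' quality decay
#' typical of the platform.  Truth labels and forward-strand origin
#' coordinates are retained for every read.
#'
#' @param pair a [genome_pair][evolve_genome_pair()].
#' @param n_reads number of reads.
#' @param contamination probability `c` in `[0, 1]` that a read
#'   originates from the contaminant genome (`seq_b`).
#' @param read_length read length in bases (default 50, single-end).
#' @param error_rate per-base substitution error probability in `[0, 1)`.
#' @param quality_model numeric vector of expected PHRED values per
#'   cycle (length `read_length`); default a linear decay from 38 to 28.
#' @param seed integer seed; identical seeds give byte-identical reads.
#' @return A [read_set()] with truth columns `origin`, `chrom`, `start`,
#'   `end`, `strand`; the generating configuration is attached as
#'   attribute `config`.
#' @examples
#' gp <- evolve_genome_pair(2000, 0.15, seed = 1)
#' rs <- simulate_reads(gp, 100, contamination = 0.3, seed = 2)
#' table(rs$origin)
#' @export
simulate_reads <- function(pair, n_reads, contamination,
                           read_length = 50, error_rate = 0.001,
                           quality_model = NULL, seed = NULL) {
  stopifnot(inherits(pair, "genome_pair"))
  .check_number(n_reads, "n_reads", lower = 1, integerish = TRUE)
  .check_number(contamination, "contamination", lower = 0, upper = 1)
  .check_number(read_length, "read_length", lower = 1, integerish = TRUE)
  if (read_length > pair$length)
    .stopf("read_length (%d) exceeds genome length (%d)",
           read_length, pair$length)
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 1)
    .stopf("error_rate must be in [0, 1)")
  if (is.null(quality_model))
    quality_model <- seq(38, 28, length.out = read_length)
  if (length(quality_model) != read_length)
    .stopf("quality_model must have length read_length (%d)", read_length)

  n <- as.integer(n_reads)
  L <- as.integer(read_length)
  .with_seed(.derive_seed(seed, 2L), {
    origin <- ifelse(runif(n) < contamination, "B", "A")
    start <- sample.int(pair$length - L + 1L, n, replace = TRUE) - 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    genome <- ifelse(origin == "A", pair$seq_a, pair$seq_b)
    seqs <- substring(genome, start + 1L, start + L)

    # substitution sequencing errors
    if (error_rate > 0) {
      n_err <- rbinom(n, L, error_rate)
      idx <- which(n_err > 0L)
      bases <- c("A", "C", "G", "T")
      for (i in idx) {
        s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        at <- sample.int(L, n_err[i])
        shift <- sample.int(3L, n_err[i], replace = TRUE)
        s[at] <- bases[(match(s[at], bases) - 1L + shift) %% 4L + 1L]
        seqs[i] <- paste(s, collapse = "")
      }
    }
    minus <- strand == "-"
    if (any(minus)) seqs[minus] <- cpp_revcomp(seqs[minus])

    # per-cycle expected quality + integer jitter in [-2, 2], floor 2, cap 40
    q <- matrix(rep(as.integer(round(quality_model)), each = n), n, L) +
      sample(-2:2, n * L, replace = TRUE)
    q <- pmin(pmax(q, 2L), 40L)
    qchars <- vapply(0:40, function(v) intToUtf8(v + 33L), character(1))
    m <- matrix(qchars[q + 1L], n, L)
    qual <- do.call(paste0, lapply(seq_len(L), function(j) m[, j]))

    rs <- read_set(id = sprintf("read%06d", seq_len(n)),
                   seq = seqs, qual = qual, origin = origin,
                   chrom = ifelse(origin == "A", "genomeA", "genomeB"),
                   start = start, end = start + L, strand = strand)
    attr(rs, "config") <- list(n_reads = n, contamination = contamination,
                               read_length = L, error_rate = error_rate,
                               divergence = pair$divergence, seed = seed)
    rs
  })
}

#' Default biotype profiles for the two serum fractions
#'
#' Biotype proportion vectors emulating the RNA composition of
#' ultracentrifugation pellet (EV-enriched: miRNA/rRNA-rich) and
#' supernatant (EV-depleted: mRNA/snoRNA-rich) fractions of fetal
#' bovine serum.
#'
#' @return Named list of two named proportion vectors (`pellet`,
#'   `supernatant`), each summing to 1.
#' @export
fraction_profiles <- function() {
  list(
    pellet      = c(miRNA = 0.30, mRNA = 0.15, rRNA = 0.30, snoRNA = 0.05,
                    antisense = 0.05, YRNA = 0.05, other = 0.10),
    supernatant = c(miRNA = 0.12, mRNA = 0.30, rRNA = 0.18, snoRNA = 0.15,
                    antisense = 0.08, YRNA = 0.07, other = 0.10))
}

#' Simulate a grouped biotype count table
#'
#' Draws per-sample feature counts from a multinomial (or
#' Dirichlet-multinomial when `dispersion > 0`) around each group's
#' proportion profile.
#'
#' @param n_samples_per_group samples per group (recycled over groups).
#' @param group_profiles named list of named proportion vectors, one per
#'   group, each summing to 1 over a common feature set; default
#'   [fraction_profiles()].
#' @param library_sizes total counts per sample (scalar or vector
#'   recycled across samples).
#' @param dispersion Dirichlet-multinomial overdispersion; `0` means
#'   plain multinomial, larger values spread per-sample proportions
#'   (Dirichlet concentration `profile / dispersion`).
#' @param feature_biotype optional named character vector mapping
#'   feature to biotype; by default features are their own biotype.
#' @param seed integer seed.
#' @return An object of class `biotype_count_table`: list with `counts`
#'   (features x samples integer matrix), `feature_biotype`,
#'   `sample_group`.
#' @export
simulate_count_table <- function(n_samples_per_group = 3,
                                 group_profiles = fraction_profiles(),
                                 library_sizes = 1e6, dispersion = 0,
                                 feature_biotype = NULL, seed = NULL) {
  if (!is.list(group_profiles) || length(group_profiles) < 2)
    .stopf("need two or more group profiles")
  feats <- names(group_profiles[[1]])
  for (g in names(group_profiles)) {
    p <- group_profiles[[g]]
    if (is.null(names(p)) || !identical(names(p), feats))
      .stopf("all profiles must share one named feature set")
    if (abs(sum(p) - 1) > 1e-6)
      .stopf("profile '%s' sums to %.6f, not 1", g, sum(p))
    if (any(p < 0)) .stopf("profile '%s' has negative entries", g)
  }
  .check_number(dispersion, "dispersion", lower = 0)
  n_per <- rep_len(as.integer(n_samples_per_group), length(group_profiles))
  n_tot <- sum(n_per)
  sizes <- rep_len(as.integer(library_sizes), n_tot)
  if (any(sizes <= 0)) .stopf("library_sizes must be positive")

  .with_seed(.derive_seed(seed, 3L), {
    counts <- matrix(0L, length(feats), n_tot,
                     dimnames = list(feats, NULL))
    groups <- character(n_tot)
    s <- 0L
    for (gi in seq_along(group_profiles)) {
      g <- names(group_profiles)[gi]
      prof <- group_profiles[[gi]]
      for (r in seq_len(n_per[gi])) {
        s <- s + 1L
        p <- if (dispersion > 0) {
          a <- rgamma(length(prof), shape = prof / dispersion, rate = 1)
          if (sum(a) == 0) prof else a / sum(a)
        } else prof
        counts[, s] <- rmultinom(1, sizes[s], p)[, 1]
        groups[s] <- g
      }
    }
    colnames(counts) <- sprintf("%s_%d", groups,
                                unlist(lapply(n_per, seq_len)))
    names(groups) <- colnames(counts)
    if (is.null(feature_biotype))
      feature_biotype <- structure(feats, names = feats)
    structure(list(counts = counts, feature_biotype = feature_biotype,
                   sample_group = groups),
              class = "biotype_count_table")
  })
}

#' @export
print.biotype_count_table <- function(x, ...) {
  cat(sprintf("<biotype_count_table> %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$sample_group), collapse = " / ")))
  invisible(x)
}

#' Simulate a qPCR Cq table
#'
#' Generates `Cq[g, s] = mean[g] + offset[s] + bio[g, s] + eps`, where
#' `offset` is a per-sample N(0, `offset_sd`) term shared across genes
#' (emulating RNA-input variation, which reference-gene normalisation
#' should remove), `bio` is gene-specific biological variation
#' N(0, `bio_sd`) applied only to genes *not* listed as stable controls,
#' and `eps` is technical noise N(0, `noise_sd`).
#'
#' @param n_samples number of samples (>= 2).
#' @param gene_means named vector of mean Cq values per gene.
#' @param stable_controls names of genes with no gene-specific
#'   biological term (>= 2 required; geNorm is undefined otherwise).
#' @param noise_sd technical noise SD in Cq units.
#' @param bio_sd biological variation SD (Cq units) of non-control genes.
#' @param offset_sd SD of the shared per-sample offset (Cq units).
#' @param seed integer seed.
#' @return An object of class `cq_table`: list with `cq` (genes x
#'   samples matrix), `controls`, `efficiency` (2), `ceiling` (40) and
#'   the true `sample_offset` vector (for recovery tests).
#' @export
simulate_cq_table <- function(n_samples, gene_means, stable_controls,
                              noise_sd = 0.2, bio_sd = 1.5,
                              offset_sd = 1, seed = NULL) {
  .check_number(n_samples, "n_samples", lower = 2, integerish = TRUE)
  if (is.null(names(gene_means)))
    .stopf("gene_means must be named")
  if (length(stable_controls) < 2)
    .stopf("at least 2 stable controls required (geNorm undefined)")
  if (!all(stable_controls %in% names(gene_means)))
    .stopf("stable_controls must be a subset of gene_means names")
  .with_seed(.derive_seed(seed, 4L), {
    g <- length(gene_means)
    n <- as.integer(n_samples)
    offset <- rnorm(n, 0, offset_sd)
    cq <- matrix(rep(gene_means, n), g, n) +
      matrix(rep(offset, each = g), g, n) +
      matrix(rnorm(g * n, 0, noise_sd), g, n)
    volatile <- !(names(gene_means) %in% stable_controls)
    if (any(volatile) && bio_sd > 0)
      cq[volatile, ] <- cq[volatile, , drop = FALSE] +
        matrix(rnorm(sum(volatile) * n, 0, bio_sd), sum(volatile), n)
    dimnames(cq) <- list(names(gene_means), sprintf("sample_%d", seq_len(n)))
    structure(list(cq = cq, controls = stable_controls, efficiency = 2,
                   ceiling = 40, sample_offset = offset),
              class = "cq_table")
  })
}

#' @export
print.cq_table <- function(x, ...) {
  cat(sprintf("<cq_table> %d genes x %d samples, controls: %s\n",
              nrow(x$cq), ncol(x$cq), paste(x$controls, collapse = ", ")))
  invisible(x)
}
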