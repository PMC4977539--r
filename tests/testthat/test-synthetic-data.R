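test_that("evolve_genome_pair: identity at zero divergence, parameter errors", {
  gp <- evolve_genome_pair(5000, divergence = 0, seed = 1)
  expect_identical(gp$seq_a, gp$seq_b)
  expect_error(evolve_genome_pair(5000, 1.2, seed = 1), "divergence")
  expect_error(evolve_genome_pair(500, 0.1, seed = 1), "length")
  expect_true(all(strsplit(gp$seq_a, "")[[1]] %in% c("A", "C", "G", "T")))
})

test_that("evolve_genome_pair: realized divergence is calibrated (3 binomial SD)", {
  gp <- evolve_genome_pair(20000, divergence = 0.15, seed = 7)
  expect_equal(nchar(gp$seq_a), 20000)
  expect_equal(nchar(gp$seq_b), 20000)
  tol <- 3 * sqrt(0.15 * 0.85 / 20000)
  expect_lt(abs(genome_divergence(gp) - 0.15), tol)
  # determinism
  gp2 <- evolve_genome_pair(20000, divergence = 0.15, seed = 7)
  expect_identical(gp$seq_b, gp2$seq_b)
})

test_that("simulate_reads: labels, coordinates and strands are truthful", {
  gp <- evolve_genome_pair(4000, 0.2, seed = 3)
  rs <- simulate_reads(gp, 500, contamination = 0.4, error_rate = 0,
                       seed = 9)
  expect_s3_class(rs, "read_set")
  expect_equal(nrow(rs), 500)
  expect_true(all(nchar(rs$seq) == 50))
  expect_true(all(nchar(rs$qual) == 50))
  # error-free reads must equal the genome slice (or its reverse complement)
  genome <- ifelse(rs$origin == "A", gp$seq_a, gp$seq_b)
  frag <- substring(genome, rs$start + 1, rs$end)
  expect_identical(rs$seq[rs$strand == "+"], frag[rs$strand == "+"])
  expect_identical(rs$seq[rs$strand == "-"],
                   revcomp(frag[rs$strand == "-"]))
})

test_that("simulate_reads: contamination fraction and edge cases", {
  gp <- evolve_genome_pair(4000, 0.2, seed = 3)
  expect_true(all(simulate_reads(gp, 200, 0, seed = 1)$origin == "A"))
  expect_true(all(simulate_reads(gp, 200, 1, seed = 1)$origin == "B"))
  # label frequency converges to c (3 binomial SD at n = 1e5)
  rs <- simulate_reads(gp, 1e5, contamination = 0.3, seed = 4)
  expect_lt(abs(mean(rs$origin == "B") - 0.3),
            3 * sqrt(0.3 * 0.7 / 1e5))
  expect_error(simulate_reads(gp, 100, 0.1, read_length = 5000), "read_length")
  expect_error(simulate_reads(gp, 100, 0.1, error_rate = 1), "error_rate")
})

test_that("simulate_reads: identical seeds give byte-identical FASTQ", {
  gp <- evolve_genome_pair(2000, 0.15, seed = 5)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(simulate_reads(gp, 300, 0.2, seed = 42), f1)
  write_fastq(simulate_reads(gp, 300, 0.2, seed = 42), f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- tempfile(fileext = ".fastq")
  write_fastq(simulate_reads(gp, 300, 0.2, seed = 43), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("simulate_reads: error rate injects roughly the right number of mismatches", {
  gp <- evolve_genome_pair(4000, 0, seed = 3)  # identical genomes
  rs <- simulate_reads(gp, 2000, 0.5, error_rate = 0.02, seed = 6)
  frag <- substring(gp$seq_a, rs$start + 1, rs$end)
  frag[rs$strand == "-"] <- revcomp(frag[rs$strand == "-"])
  mism <- mapply(function(a, b)
    sum(utf8ToInt(a) != utf8ToInt(b)), rs$seq, frag)
  rate <- sum(mism) / (2000 * 50)
  expect_lt(abs(rate - 0.02), 3 * sqrt(0.02 * 0.98 / (2000 * 50)))
})

test_that("simulate_count_table: shapes, determinism and parameter errors", {
  tab <- simulate_count_table(3, seed = 1)
  expect_s3_class(tab, "biotype_count_table")
  expect_equal(ncol(tab$counts), 6)
  expect_true(all(colSums(tab$counts) == 1e6))
  expect_identical(tab$counts, simulate_count_table(3, seed = 1)$counts)
  bad <- fraction_profiles(); bad$pellet["miRNA"] <- 0.5
  expect_error(simulate_count_table(3, bad), "sums to")
  expect_error(simulate_count_table(3, library_sizes = 0), "positive")
  expect_error(simulate_count_table(3, fraction_profiles()["pellet"]),
               "two or more")
})

test_that("simulate_count_table: dispersion spreads per-sample proportions", {
  t0 <- simulate_count_table(20, library_sizes = 1e5, dispersion = 0,
                             seed = 2)
  t1 <- simulate_count_table(20, library_sizes = 1e5, dispersion = 0.05,
                             seed = 2)
  v0 <- var(t0$counts["miRNA", t0$sample_group == "pellet"] / 1e5)
  v1 <- var(t1$counts["miRNA", t1$sample_group == "pellet"] / 1e5)
  expect_gt(v1, v0)
})

test_that("simulate_cq_table: structure, stability of controls, errors", {
  means <- c(U6 = 20, U2 = 22, miR103 = 24, miR24 = 25,
             target1 = 28, target2 = 30)
  ctrl <- c("U6", "U2", "miR103", "miR24")
  tab <- simulate_cq_table(6, means, ctrl, noise_sd = 0, bio_sd = 2,
                           seed = 1)
  expect_s3_class(tab, "cq_table")
  expect_equal(dim(tab$cq), c(6, 6))
  # with zero technical noise, control Cq differences across samples are
  # exactly the shared offset -> geNorm M = 0 for the control panel
  M <- genorm_m_values(tab, ctrl)
  expect_equal(unname(M), rep(0, 4), tolerance = 1e-12)
  expect_error(simulate_cq_table(1, means, ctrl), "n_samples")
  expect_error(simulate_cq_table(6, means, "U6"), "2 stable controls")
  expect_error(simulate_cq_table(6, means, c("U6", "nope")), "subset")
})
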