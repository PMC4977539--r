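rand_genome <- function(L, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

test_that("build_index and query_index locate seeds", {
  genome <- paste(rep("ACGT", 25), collapse = "")  # 100 bp, period 4
  idx <- build_index(genome, 25)
  pos <- query_index(idx, substr(genome, 1, 25))
  expect_true(0 %in% pos)
  expect_equal(pos, seq(0, 72, by = 4))  # periodic genome
  # all-N genome indexes nothing
  expect_error(build_index(paste(rep("N", 10), collapse = ""), 25),
               "shorter")
  idxN <- build_index(paste(rep("N", 60), collapse = ""), 25)
  expect_equal(serascan:::cpp_index_n_seeds(idxN$ptr), 0)
  # self-lookup completeness on a random genome
  g <- rand_genome(2000, 13)
  idx <- build_index(g, 25)
  for (p in seq(0, 2000 - 25, by = 97)) {
    expect_true(p %in% query_index(idx, substr(g, p + 1, p + 25)))
  }
})

test_that("align_read finds exact substrings and reverse complements", {
  g <- rand_genome(3000, 21)
  idx <- build_index(g, 25)
  read <- substr(g, 501, 550)
  hit <- align_read(read, idx)
  expect_equal(hit$score, 100)  # 50 matches x 2
  expect_equal(c(hit$start, hit$end), c(500, 550))
  expect_equal(hit$strand, "+")
  rc <- revcomp(read)
  hit2 <- align_read(rc, idx)
  expect_equal(c(hit2$start, hit2$end), c(500, 550))
  expect_equal(hit2$strand, "-")
  expect_equal(hit2$score, 100)
  # read shorter than the seed is unmappable, not an error
  expect_null(align_read("ACGTACGTAC", idx))
  # a read sharing no 25-mer with the genome does not map
  expect_null(align_read(paste(rep("A", 50), collapse = ""), idx))
})

test_that("classification partition, identical-genome and junk-read cases", {
  gp0 <- evolve_genome_pair(2000, 0, seed = 4)
  rs <- simulate_reads(gp0, 300, 0.5, error_rate = 0, seed = 5)
  cl <- classify_reads(rs, gp0)
  expect_equal(cl$n_both, 300)  # identical genomes: every read maps to both
  expect_equal(cl$n_specific_a + cl$n_specific_b + cl$n_both + cl$n_neither,
               300)
  junk <- vapply(1:20, function(i)
    paste(rep(c("A", "C")[i %% 2 + 1], 50), collapse = ""), character(1))
  clj <- classify_reads(junk, gp0)
  expect_equal(clj$n_neither, 20)
  # empty input: zero counts, not an error
  cle <- classify_reads(character(0), gp0)
  expect_equal(nrow(cle$per_read), 0)
  expect_equal(cle$n_both, 0)
})

test_that("swapping genomes swaps the specific counts", {
  gp <- evolve_genome_pair(3000, 0.15, seed = 8)
  rs <- simulate_reads(gp, 400, 0.3, error_rate = 0.005, seed = 9)
  cl <- classify_reads(rs, gp$seq_a, gp$seq_b)
  sw <- classify_reads(rs, gp$seq_b, gp$seq_a)
  expect_equal(cl$n_specific_a, sw$n_specific_b)
  expect_equal(cl$n_specific_b, sw$n_specific_a)
  expect_equal(cl$n_both, sw$n_both)
  expect_equal(cl$n_neither, sw$n_neither)
})

test_that("n_both decreases with divergence; high divergence gives specific calls", {
  n_both <- vapply(c(0, 0.05, 0.1, 0.2, 0.4), function(d) {
    gp <- evolve_genome_pair(4000, d, seed = 31)
    rs <- simulate_reads(gp, 500, 0.5, error_rate = 0, seed = 32)
    classify_reads(rs, gp)$n_both
  }, numeric(1))
  expect_true(all(diff(n_both) <= 0))
  expect_equal(n_both[1], 500)
})

test_that("sensitivity: error-free host reads classify specific-A (divergence 0.25)", {
  # at divergence 0.20 the expected chance cross-match rate (an exact
  # 25-mer run at 80% identity) is ~2%, so >= 99% is only attainable
  # from divergence ~0.25 up; see the methods vignette
  gp <- evolve_genome_pair(20000, 0.25, seed = 12)
  rs <- simulate_reads(gp, 5000, 0, error_rate = 0, seed = 13)
  cl <- classify_reads(rs, gp)
  expect_gte(cl$n_specific_a / 5000, 0.99)
})

test_that("seeded aligner equals the exhaustive oracle (with errors and 1-mismatch seeds)", {
  gp <- evolve_genome_pair(2000, 0.15, seed = 17)
  rs <- simulate_reads(gp, 200, 0.3, error_rate = 0.02, seed = 18)
  for (nm in 0:1) {
    par <- align_params(seed_mismatches = nm)
    cl <- classify_reads(rs, gp, params = par)
    orc <- oracle_classify_reads(rs, gp, params = par)
    expect_identical(cl$per_read$category, orc$per_read$category)
    expect_identical(cl$hits_a, orc$hits_a)
    expect_identical(cl$hits_b, orc$hits_b)
  }
})

test_that("classify_from_alignments follows SAM flags and checks consistency", {
  sam_a <- tempfile(fileext = ".sam")
  sam_b <- tempfile(fileext = ".sam")
  write_mini_sam(sam_a, c("r1", "r2", "r3", "r4"), c(0L, 0L, 4L, 4L))
  write_mini_sam(sam_b, c("r1", "r2", "r3", "r4"), c(4L, 0L, 0L, 4L))
  cl <- classify_from_alignments(sam_a, sam_b)
  expect_equal(cl$per_read$category[cl$per_read$id == "r1"], "specific_a")
  expect_equal(cl$per_read$category[cl$per_read$id == "r2"], "both")
  expect_equal(cl$per_read$category[cl$per_read$id == "r3"], "specific_b")
  expect_equal(cl$per_read$category[cl$per_read$id == "r4"], "neither")
  # secondary/supplementary records ignored
  sam_c <- tempfile(fileext = ".sam")
  writeLines(c(readLines(sam_a),
               "r1\t256\tref\t5\t60\t10M\t*\t0\t0\tACGTACGTAC\t**********",
               "r2\t2048\tref\t5\t60\t10M\t*\t0\t0\tACGTACGTAC\t**********"),
             sam_c)
  expect_equal(nrow(read_sam(sam_c)), 4)
  # missing id -> consistency error naming the id
  sam_d <- tempfile(fileext = ".sam")
  write_mini_sam(sam_d, c("r1", "r2", "r3"), c(0L, 0L, 0L))
  expect_error(classify_from_alignments(sam_a, sam_d), "r4")
})
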