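test_that("contamination_index arithmetic and degenerate cases", {
  ci <- contamination_index(list(n_specific_a = 1000, n_specific_b = 95))
  expect_equal(ci$r, 0.095)
  expect_equal(contamination_index(list(n_specific_a = 10,
                                        n_specific_b = 0))$r, 0)
  expect_error(contamination_index(list(n_specific_a = 0,
                                        n_specific_b = 5)),
               class = "serascan_undefined_index")
  # monotonicity: more contaminant-specific reads -> larger index
  r1 <- contamination_index(list(n_specific_a = 100, n_specific_b = 10))$r
  r2 <- contamination_index(list(n_specific_a = 100, n_specific_b = 11))$r
  r3 <- contamination_index(list(n_specific_a = 101, n_specific_b = 10))$r
  expect_gt(r2, r1)
  expect_lt(r3, r1)
})

test_that("fold_change is the ratio of group means, with SEM bookkeeping", {
  fc <- fold_change(c(1, 2, 3), c(1, 2, 3))
  expect_equal(fc$fc, 1)
  expect_equal(fc$sem_numerator, sd(1:3) / sqrt(3))
  # singleton group: SEM undefined
  fc1 <- fold_change(0.473, 0.166)
  expect_true(is.na(fc1$sem_denominator) || is.na(fc1$sem_numerator))
  expect_error(fold_change(c(1, 2), c(0, 0)), "denominator")
  expect_error(fold_change(numeric(0), 1), "non-empty")
})

test_that("published fold changes reproduce from the printed group means", {
  tab <- read_tsv(system.file("extdata", "table1_public_datasets.tsv",
                              package = "serascan"))
  hb <- tab[tab$dataset == "SRP046046", ]
  expect_equal(signif(fold_change(hb$exosomal_mean,
                                  hb$cellular_mean)$fc, 3), 2.32)
  lim <- tab[tab$dataset == "SRP031761", ]
  expect_equal(signif(fold_change(lim$exosomal_mean,
                                  lim$cellular_mean)$fc, 3), 2.85)
})

test_that("mann_whitney_exact: worked examples and identities", {
  r <- mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)  # 2 * (1/20)
  expect_equal(r$method, "exact")
  r2 <- mann_whitney_exact(c(1, 2), c(3, 4))
  expect_equal(r2$U, 0)
  expect_equal(r2$p, 1 / 3, tolerance = 1e-12)
  # U_x + U_y = n*m
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(sample(2:6, 1)); y <- rnorm(sample(2:6, 1))
    r <- mann_whitney_exact(x, y)
    expect_equal(r$U_x + r$U_y, length(x) * length(y))
  }
  expect_error(mann_whitney_exact(numeric(0), 1:3), "non-empty")
})

test_that("exact p equals the brute-force enumeration oracle (with ties)", {
  set.seed(11)
  for (i in 1:60) {
    n <- sample(1:5, 1); m <- sample(1:5, 1)
    vals <- sample(1:4, n + m, replace = TRUE)  # ties likely
    x <- vals[seq_len(n)]; y <- vals[-seq_len(n)]
    got <- mann_whitney_exact(x, y)
    want <- mw_oracle(x, y)
    expect_equal(got$U, want$U)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("approximate branch engages above the enumeration limit", {
  set.seed(5)
  x <- rnorm(12); y <- rnorm(13)  # choose(25,12) >> 1e5
  r <- mann_whitney_exact(x, y)
  expect_equal(r$method, "approx")
  expect_equal(r$p, wilcox.test(x, y, correct = TRUE,
                                exact = FALSE)$p.value, tolerance = 1e-9)
})

test_that("null exact p is super-uniform at n = m = 4", {
  set.seed(21)
  p <- replicate(1500, mann_whitney_exact(rnorm(4), rnorm(4))$p)
  expect_lte(mean(p <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 1500))
})

test_that("t_test_unpaired matches hand computation and base R", {
  r <- t_test_unpaired(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3/(1 * sqrt(2/3)), tolerance = 1e-6)
  expect_equal(round(r$t, 3), -3.674)
  expect_equal(r$df, 4)
  expect_equal(t_test_unpaired(c(2, 4), c(2, 4))$p, 1)
  expect_equal(t_test_unpaired(c(1, 1), c(2, 2))$p, 0)
  expect_error(t_test_unpaired(1, 2), "at least 2")
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), 0.5)
    got <- t_test_unpaired(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("estimate_mixture_fraction inverts the index", {
  expect_equal(estimate_mixture_fraction(0), 0)
  expect_equal(estimate_mixture_fraction(1), 0.5)
  # end-to-end recovery at reduced scale (full scale in acceptance)
  gp <- evolve_genome_pair(10000, 0.15, seed = 41)
  rs <- simulate_reads(gp, 2e4, contamination = 0.3, error_rate = 0,
                       seed = 42)
  ci <- contamination_index(classify_reads(rs, gp), "sim")
  expect_lt(abs(estimate_mixture_fraction(ci) - 0.3), 0.02)
})

test_that("compare_groups builds the per-dataset table and a global test", {
  idx <- data.frame(
    sample_id = sprintf("s%d", 1:10),
    dataset = rep(c("d1", "d2"), each = 5),
    group = rep(c("cellular", "cellular", "exosomal", "exosomal",
                  "exosomal"), 2),
    r = c(0.01, 0.03, 0.10, 0.12, 0.14, 0.02, 0.04, 0.20, 0.22, 0.24))
  cmp <- compare_groups(idx)
  expect_equal(nrow(cmp$table), 2)
  d1 <- cmp$table[cmp$table$dataset == "d1", ]
  expect_equal(d1$fc, mean(c(0.10, 0.12, 0.14)) / mean(c(0.01, 0.03)))
  expect_equal(cmp$test$method, "exact")
  expect_lt(cmp$test$p, 0.05)  # clearly separated groups
})
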