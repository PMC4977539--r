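test_that("rpm_normalize scales every sample to one million", {
  m <- matrix(c(10, 90, 5, 15), 2, 2,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  rpm <- rpm_normalize(m)
  expect_equal(rpm[, "s1"], c(f1 = 1e5, f2 = 9e5))
  expect_equal(unname(colSums(rpm)), c(1e6, 1e6))
  # single feature -> all 1e6
  expect_equal(unname(rpm_normalize(matrix(7, 1, 1,
    dimnames = list("f", "s")))[1, 1]), 1e6)
  m0 <- m; m0[, 2] <- 0
  expect_error(rpm_normalize(m0), "s2")
  # conservation on simulated data
  tab <- simulate_count_table(3, seed = 3)
  expect_equal(unname(colSums(rpm_normalize(tab))), rep(1e6, 6),
               tolerance = 1e-9)
})

test_that("biotype_composition fractions and group recovery", {
  m <- matrix(c(250000, 750000), 2, 1,
              dimnames = list(c("f1", "f2"), "s1"))
  comp <- biotype_composition(m, c(f1 = "miRNA", f2 = "mRNA"))
  expect_equal(unname(comp$fractions["miRNA", 1]), 0.25)
  expect_equal(unname(comp$fractions["mRNA", 1]), 0.75)
  # all one biotype -> fraction 1
  comp1 <- biotype_composition(m, c(f1 = "miRNA", f2 = "miRNA"))
  expect_equal(unname(comp1$fractions[1, 1]), 1)
  # unannotated features fall into "other" with a warning
  expect_warning(co <- biotype_composition(m, c(f1 = "miRNA")), "other")
  expect_true("other" %in% rownames(co$fractions))
  # group means recover the generating profiles within 3 SEM
  tab <- simulate_count_table(5, seed = 9)
  comp <- biotype_composition(tab)
  prof <- fraction_profiles()
  for (g in names(prof)) {
    dev <- abs(comp$group_mean[names(prof[[g]]), g] - prof[[g]])
    lim <- 3 * comp$group_sem[names(prof[[g]]), g] + 1e-4
    expect_true(all(dev <= lim))
  }
})

test_that("top_k_features ranks by mean RPM with alphabetical ties", {
  m <- matrix(c(100, 50, 50), 3, 1,
              dimnames = list(c("y", "x", "b"), "s1"))
  expect_equal(top_k_features(m, k = 1)$feature, "y")
  expect_equal(top_k_features(m, k = 3)$feature, c("y", "b", "x"))
  # k beyond the feature count returns everything
  expect_equal(nrow(top_k_features(m, k = 10)), 3)
  # biotype filter
  bt <- c(y = "miRNA", x = "mRNA", b = "miRNA")
  expect_equal(top_k_features(m, bt, "miRNA", k = 5)$feature, c("y", "b"))
  # a dominant simulated feature ranks first under resampling
  prof <- list(g1 = c(a = 0.7, b = 0.1, c = 0.1, d = 0.1),
               g2 = c(a = 0.7, b = 0.1, c = 0.1, d = 0.1))
  for (s in 1:5) {
    tab <- simulate_count_table(2, prof, library_sizes = 1e4, seed = s)
    expect_equal(top_k_features(rpm_normalize(tab), k = 1)$feature, "a")
  }
})

test_that("depletion_efficiency and percent_removed arithmetic", {
  expect_equal(depletion_efficiency(2, 1), 2)
  expect_equal(depletion_efficiency(3, 3), 1)
  expect_equal(depletion_efficiency(24, 26, from_cq = TRUE), 4)
  expect_error(depletion_efficiency(0, 1), "positive")
  expect_equal(percent_removed(25, 75), 25)
  expect_equal(percent_removed(0, 10), 0)
  expect_equal(percent_removed(33, 67), 33)
  expect_error(percent_removed(0, 0), "zero")
})

test_that("pearson_cluster: duplicates, invariance and errors", {
  tab <- simulate_count_table(3, seed = 5)
  rpm <- rpm_normalize(tab)
  # distances within bounds
  tree <- pearson_cluster(rpm)
  expect_true(all(tree$dist >= 0 & tree$dist <= 2))
  # duplicated sample merges first at height 0
  rpm2 <- cbind(rpm, dup = rpm[, 1])
  t2 <- pearson_cluster(rpm2)
  expect_equal(min(t2$hclust$height), 0)
  expect_setequal(colnames(rpm2)[-t2$hclust$merge[1, ]],
                  c(colnames(rpm)[1], "dup"))
  # scaling one sample's raw counts leaves the tree unchanged
  counts <- tab$counts
  counts_scaled <- counts
  counts_scaled[, 2] <- counts_scaled[, 2] * 10
  ta <- pearson_cluster(rpm_normalize(counts))
  tb <- pearson_cluster(rpm_normalize(counts_scaled))
  expect_equal(ta$hclust$merge, tb$hclust$merge)
  expect_equal(ta$hclust$height, tb$hclust$height, tolerance = 1e-12)
  # feature order invariance
  tc <- pearson_cluster(rpm[rev(rownames(rpm)), ])
  expect_equal(ta$hclust$merge, tc$hclust$merge)
  # zero-variance profile is an error naming the sample
  flat <- matrix(5, 3, 2, dimnames = list(letters[1:3], c("ok", "flat")))
  flat[, 1] <- c(1, 5, 9)
  expect_error(pearson_cluster(flat), "flat")
})

test_that("top split separates the two simulated fractions", {
  tab <- simulate_count_table(3, seed = 1)
  tree <- pearson_cluster(rpm_normalize(tab))
  halves <- top_split(tree)
  groups <- lapply(halves, function(h) unique(tab$sample_group[h]))
  expect_equal(lengths(groups), c(`1` = 1L, `2` = 1L))
})

test_that("write_newick emits a tree ape can parse with the right leaves", {
  tab <- simulate_count_table(3, seed = 2)
  tree <- pearson_cluster(rpm_normalize(tab))
  f <- tempfile(fileext = ".nwk")
  write_newick(tree, f)
  phy <- ape::read.tree(f)
  expect_setequal(phy$tip.label, colnames(tab$counts))
})
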