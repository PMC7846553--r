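test_that("BH adjustment matches hand evaluation and never shrinks p", {
  expect_equal(bh_adjust(0.03), 0.03)
  # p(i) * m / i with monotone step-up enforcement
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(1)
  for (i in 1:20) {
    p <- runif(50)
    q <- bh_adjust(p)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    expect_false(is.unsorted(q[order(p)]))   # order-preserving
  }
})

test_that("ecdf area: worked values and the hi - mean identity", {
  expect_equal(ecdf_area(0.2, 0, 1), 0.8)
  expect_equal(ecdf_area(c(0, 1), 0, 1), 0.5)
  set.seed(2)
  for (i in 1:25) {
    lo <- runif(1, -5, 0); hi <- runif(1, 1, 5)
    x <- runif(sample(2:40, 1), lo, hi)
    expect_equal(ecdf_area(x, lo, hi), hi - mean(x), tolerance = 1e-12)
  }
  expect_error(ecdf_area(c(0.5, 2), 0, 1), "outside")
  expect_error(ecdf_area(numeric(0), 0, 1), "empty")
})

test_that("shannon entropy: degenerate, uniform and split cases", {
  g <- discretization_grid(0, 1, 10)
  expect_equal(shannon_entropy(rep(0.25, 7), g), 0)
  expect_equal(shannon_entropy(seq(0.05, 0.95, by = 0.1), g), log2(10))
  g2 <- discretization_grid(0, 1, 2)
  expect_equal(shannon_entropy(c(rep(0.2, 4), rep(0.8, 4)), g2), 1)
  # invariant under affine transforms that preserve bin counts
  x <- runif(30)
  g3 <- discretization_grid(0, 10, 10)
  expect_equal(shannon_entropy(x, g), shannon_entropy(10 * x, g3))
  expect_error(shannon_entropy(c(0.5, 1.5), g), "outside")
  expect_error(discretization_grid(1, 0), "lower")
  expect_error(discretization_grid(0, 1, 1), "n_bins")
})

test_that("ME criterion: identity case, degenerate probes, direction", {
  set.seed(3)
  m1 <- matrix(rnorm(20 * 6), 20)
  ds <- expression_dataset(cbind(m1, m1), rep(c("a", "b"), each = 6))
  me <- me_differential(ds)
  expect_true(all(me$me_delta == 0))
  expect_false(any(me$me_significant, na.rm = TRUE))

  m <- matrix(rnorm(4 * 12), 4)
  m[1, ] <- 5                       # constant in both groups
  m[2, 7:12] <- m[2, 7:12] + 10     # huge up-shift
  ds2 <- expression_dataset(m, rep(c("a", "b"), each = 6))
  me2 <- me_differential(ds2)
  expect_true(me2$degenerate[1])
  expect_true(is.na(me2$me_p[1]))
  expect_identical(me2$me_direction[2], "up")
  expect_true(me2$me_significant[2])
})

test_that("CD criterion: identical groups, disjoint supports, ME collinearity", {
  set.seed(4)
  m1 <- matrix(rnorm(10 * 8), 10)
  ds <- expression_dataset(cbind(m1, m1), rep(c("a", "b"), each = 8))
  cd <- cd_differential(ds)
  expect_true(all(cd$ks_d == 0))
  expect_true(all(cd$ks_p == 1))
  expect_equal(cd$cd_delta, rep(0, 10))

  ds2 <- expression_dataset(rbind(c(1, 2, 3, 4, 5, 6)),
                            rep(c("a", "b"), each = 3))
  cd2 <- cd_differential(ds2)
  expect_equal(unname(cd2$ks_d), 1)

  # over a shared support the area difference is minus the mean difference
  ds3 <- tiny_dataset(30, 10, 12, seed = 8)
  cd3 <- cd_differential(ds3)
  me3 <- me_differential(ds3)
  expect_equal(cd3$cd_delta, -me3$me_delta, tolerance = 1e-12)
})

test_that("SE criterion: forced direction, determinism, argument checks", {
  set.seed(5)
  # group1 packed into one end, group2 spread over the full range
  m <- rbind(c(runif(10, 0, 0.05), runif(12, 0, 1)),
             c(runif(10, 0.9, 1), runif(12, 0, 1)))
  ds <- expression_dataset(m, rep(c("a", "b"), c(10, 12)))
  se <- se_bootstrap_differential(ds, n_boot = 300, seed = 2)
  expect_true(all(se$se_direction == "gain"))
  expect_true(all(se$se_delta > 0))
  se_b <- se_bootstrap_differential(ds, n_boot = 300, seed = 2)
  expect_identical(se, se_b)
  expect_error(se_bootstrap_differential(ds, n_boot = 1), "n_boot")
  # entropy columns respect the log2(n_bins) bound
  ds2 <- tiny_dataset(15, 8, 9, seed = 6)
  se2 <- se_bootstrap_differential(ds2, n_bins = 8, n_boot = 100,
                                   seed = 3)
  expect_true(all(se2$se_group1 >= 0 & se2$se_group1 <= log2(8)))
  expect_true(all(se2$se_group2 >= 0 & se2$se_group2 <= log2(8)))
})

test_that("the three SE significance methods rank as their constructions imply", {
  # on two independent same-distribution samples the collection t-test is
  # anticonservative, the permutation and boot-z tests are not
  out <- generate_dataset(null_config(n_probes = 150, seed = 13))
  pv <- sapply(c("permutation", "boot-z", "collection"), function(m)
    mean(se_bootstrap_differential(out$dataset, n_boot = 200, seed = 4,
                                   method = m)$se_p < 0.05))
  expect_lt(pv[["permutation"]], 0.12)
  expect_lt(pv[["boot-z"]], 0.15)
  expect_gt(pv[["collection"]], 0.5)
})

test_that("criteria correlations hit +/-1 for identical/negated relative changes", {
  rec <- data.frame(probe_id = sprintf("p%d", 1:10),
                    me_group1 = 1, me_group2 = seq(0.5, 5, length.out = 10),
                    cd_group1 = 1, cd_group2 = seq(0.5, 5, length.out = 10),
                    se_group1 = 1, se_group2 = -seq(0.5, 5, length.out = 10))
  cc <- criteria_correlations(rec)
  expect_equal(unname(cc["cd_me"]), 1)
  expect_equal(unname(cc["se_me"]), -1)
  expect_error(criteria_correlations(rec[1:2, ]), "3 usable")
})

test_that("relative profile is a sorted ratio curve with homogeneity", {
  rec <- data.frame(probe_id = sprintf("p%d", 1:8),
                    me_group1 = c(2, 4, 1, 5, 2, 8, 0, 3),
                    me_group2 = c(4, 2, 3, 5, 1, 8, 1, 9),
                    me_significant = rep(c(TRUE, FALSE), 4))
  expect_warning(pr <- relative_profile(rec, "me"), "zero")
  expect_equal(nrow(pr), 7)
  expect_true(all(diff(pr$relative) <= 0))
  rec2 <- rec; rec2$me_group2 <- 2 * rec2$me_group2
  suppressWarnings(pr2 <- relative_profile(rec2, "me"))
  expect_equal(pr2$relative, 2 * pr$relative)
  # identical groups give the constant curve at 1
  rec3 <- rec; rec3$me_group2 <- rec3$me_group1; rec3 <- rec3[-7, ]
  pr3 <- relative_profile(rec3, "me")
  expect_true(all(pr3$relative == 1))
})

test_that("complete-linkage ordering matches a direct agglomeration oracle", {
  m <- rbind(a = c(0, 0, 0), b = c(0, 0, 0.01), c = c(5, 5, 5),
             d = c(9, 9, 9))
  ho <- hierarchical_order(m)
  # the two near-identical rows merge first, near height 0
  expect_equal(hclust_merged_sets(ho$hclust)[[1]], c(1, 2))
  expect_lt(ho$height[1], 0.02)

  set.seed(7)
  for (i in 1:5) {
    m <- matrix(rnorm(7 * 4), 7)
    ho <- hierarchical_order(m)
    oc <- oracle_complete_linkage(m)
    expect_equal(ho$height, oc$heights, tolerance = 1e-10)
    expect_identical(hclust_merged_sets(ho$hclust), oc$merged_sets)
  }
})

test_that("row z-scoring standardizes rows and flags constant rows", {
  m <- rbind(rnorm(6), rnorm(6), rep(2, 6))
  expect_warning(ho <- hierarchical_order(m, zscore_rows = TRUE),
                 "zero-variance")
  expect_identical(ho$zscore_skipped, 3L)
  set.seed(8)
  m2 <- matrix(rnorm(5 * 8), 5)
  ho2 <- hierarchical_order(m2, zscore_rows = TRUE)
  # recompute: the clustering input rows had mean 0 / SD 1
  z <- t(scale(t(m2)))
  expect_equal(ho2$height,
               hierarchical_order(z)$height, tolerance = 1e-10)
})
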