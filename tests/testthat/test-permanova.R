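# Distance construction, PERMANOVA partitioning and permutation p-values,
# and the pairwise permutation machinery.

test_that("Euclidean distances match a brute-force double loop", {
  expect_equal(as.numeric(euclideanDistances(
    data.frame(a = c(0, 3), b = c(0, 4)), c("a", "b"),
    standardize = FALSE)), 5)
  expect_equal(as.numeric(euclideanDistances(
    data.frame(a = c(1, 1), b = c(2, 2)), c("a", "b"),
    standardize = FALSE)), 0)
  set.seed(11)
  tb <- data.frame(x = rnorm(6), y = rnorm(6), z = rnorm(6))
  d <- as.matrix(euclideanDistances(tb, c("x", "y", "z"),
                                    standardize = FALSE))
  expect_equal(d, bruteDist(as.matrix(tb)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(euclideanDistances(data.frame(x = c(1, 1), y = 1:2),
                                  c("x", "y")), "constant trait.*x")
})

test_that("sequential SS, pseudo-F and R2 match the summed univariate
           ANOVA oracle and vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(21)
  for (rep in 1:5) {
    tb <- data.frame(site = sample(c("A", "B", "C"), 12, replace = TRUE),
                     pl = sample(c("x", "y"), 12, replace = TRUE),
                     t1 = rnorm(12), t2 = rnorm(12), t3 = rnorm(12))
    if (length(unique(tb$site)) < 2 || length(unique(tb$pl)) < 2) next
    d <- euclideanDistances(tb, c("t1", "t2", "t3"), standardize = FALSE)
    pv <- permanova(d, tb, c("site", "pl"), n_perm = 9, seed = 1)
    # oracle 1: per-trait sequential aov sums of squares, summed
    orc <- aovSeqOracle(tb, c("t1", "t2", "t3"), c("site", "pl"))
    expect_equal(pv$aov_table$ss, orc$ss, tolerance = 1e-8)
    expect_equal(pv$ss_resid, orc$ss_resid, tolerance = 1e-8)
    # oracle 2: vegan
    ad <- vegan::adonis2(d ~ site + pl, data = tb, permutations = 9,
                         by = "terms")
    expect_equal(pv$aov_table$pseudo_F, ad$F[1:2], tolerance = 1e-8)
    expect_equal(pv$aov_table$R2, ad$R2[1:2], tolerance = 1e-8)
  }
})

test_that("exact enumeration reproduces the complete permutation null", {
  tb <- data.frame(g = rep(c("a", "b"), c(3, 3)),
                   x = c(0.3, 1.2, -0.5, 2.8, 3.6, 2.1))
  d <- dist(tb$x)
  pe <- permanova(d, tb, "g", exact = TRUE)
  # independent enumeration: univariate sequential-ANOVA F over all 6!
  # row orders
  Fobs <- summary(stats::aov(x ~ g, data = tb))[[1]]$`F value`[1]
  perms <- sporescope:::.allPermutations(6)
  cnt <- 0L
  for (r in seq_len(nrow(perms))) {
    tp <- tb; tp$x <- tb$x[perms[r, ]]
    Fp <- summary(stats::aov(x ~ g, data = tp))[[1]]$`F value`[1]
    if (Fp >= Fobs - 1e-12) cnt <- cnt + 1L
  }
  expect_equal(pe$aov_table$p_perm, cnt / factorial(6))
})

test_that("a strong two-group offset gives R2 > 0.9 and the permutation
           floor; degenerate terms error", {
  set.seed(5)
  tb <- data.frame(g = rep(c("a", "b"), each = 4),
                   x = c(rnorm(4), rnorm(4) + 50), y = rnorm(8))
  d <- euclideanDistances(tb, c("x", "y"), standardize = FALSE)
  pv <- permanova(d, tb, "g", n_perm = 999, seed = 3)
  expect_gt(pv$aov_table$R2, 0.9)
  # permutation floor: only the 2/70 label partitions reproducing the
  # observed split reach the observed F
  expect_lte(pv$aov_table$p_perm, 0.06)
  expect_gte(pv$aov_table$p_perm, 1 / 1000)  # never exactly 0

  tb$one <- "only"
  expect_error(permanova(d, tb, "one", n_perm = 9), "fewer than 2 levels")
  expect_error(permanova(d, tb, "g", n_perm = 0), "n_perm")
  expect_error(permanova(dist(1:5), tb, "g"), "does not match")
})

test_that("restricted permutation within strata leaves stratum membership
           invariant and stays seeded-reproducible", {
  set.seed(8)
  tb <- data.frame(g = rep(c("a", "b"), 6),
                   s = rep(c("S1", "S2"), each = 6),
                   x = rnorm(12), y = rnorm(12))
  d <- euclideanDistances(tb, c("x", "y"), standardize = FALSE)
  p1 <- permanova(d, tb, "g", n_perm = 99, seed = 4, strata = "s")
  p2 <- permanova(d, tb, "g", n_perm = 99, seed = 4, strata = "s")
  expect_identical(p1$aov_table, p2$aov_table)
})

test_that("pairwise permutation tests: exchangeable groups give large p,
           Holm is applied across pairs, single pair is unadjusted", {
  # literally identical groups: observed centroid distance is 0, every
  # permutation ties or beats it
  set.seed(31)
  half <- data.frame(x = rnorm(10), y = rnorm(10))
  tb <- cbind(g = rep(c("a", "b"), each = 10), rbind(half, half))
  pw <- pairwisePermutationTests(tb, c("x", "y"), "g", n_perm = 1000,
                                 seed = 2)
  expect_gte(pw$p_raw, 0.5)
  expect_equal(pw$p_holm, pw$p_raw)   # m = 1

  tb3 <- data.frame(g = rep(c("a", "b", "c"), each = 6),
                    x = c(rnorm(6), rnorm(6) + 8, rnorm(6) + 16),
                    y = rnorm(18))
  pw3 <- pairwisePermutationTests(tb3, c("x", "y"), "g", n_perm = 500,
                                  seed = 2)
  expect_equal(nrow(pw3), 3L)
  expect_equal(pw3$p_holm, holmAdjust(pw3$p_raw))
  expect_true(all(pw3$p_holm >= pw3$p_raw))

  # a level with < 2 rows is skipped with a warning
  tb4 <- rbind(tb3, data.frame(g = "d", x = 0, y = 0))
  expect_warning(pw4 <- pairwisePermutationTests(tb4, c("x", "y"), "g",
                                                 n_perm = 99, seed = 1),
                 "skipping")
  expect_equal(nrow(pw4), 3L)
})

test_that("Holm adjustment matches hand computation, dominates raw
           p-values and respects the step-down order", {
  expect_equal(holmAdjust(0.2), 0.2)
  expect_equal(holmAdjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holmAdjust(c(1, 1)), c(1, 1))
  expect_error(holmAdjust(c(0.5, 1.2)), "0, 1")
  set.seed(13)
  for (i in 1:50) {
    p <- runif(sample(1:8, 1))
    adj <- holmAdjust(p)
    expect_equal(adj, p.adjust(p, "holm"))          # independent oracle
    expect_true(all(adj >= p))                      # dominance
    expect_true(all(adj <= 1))
    # adjusted significance set is a subset of the raw one
    expect_true(all(p[adj < 0.05] < 0.05))
  }
})
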