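test_that("cluster summary reproduces the published high-low cluster row", {
  # 39 dyads: 38 caries mothers, 19 caries children, 19 both, 1 neither
  mother <- c(rep(1, 38), 0)
  child <- c(rep(1, 19), rep(0, 20))
  # order so that exactly 19 dyads have both and 1 has neither:
  # rows 1..19 both; rows 20..38 mother only; row 39 neither
  out <- tibble::tibble(cluster = 2L, mother = mother, child = child)
  s <- summarize_clusters(out, overall = FALSE)
  expect_equal(s$n_dyads, 39)
  expect_equal(s$mother_pct, 97.44)
  expect_equal(s$child_pct, 48.72)
  expect_equal(s$both_pct, 48.72)
  expect_equal(s$neither_pct, 2.56)
  expect_equal(s$individuals_n, 57)
  expect_equal(s$individuals_pct, 73.08)
})

test_that("summary satisfies partition and pooling identities", {
  set.seed(12)
  out <- tibble::tibble(
    cluster = sample(1:3, 120, replace = TRUE),
    mother = rbinom(120, 1, 0.9),
    child = rbinom(120, 1, 0.5)
  )
  s <- summarize_clusters(out)
  per <- s[s$cluster != "Overall", ]
  # both + mother-only + child-only + neither = n
  expect_equal(per$both_n + (per$mother_n - per$both_n) +
                 (per$child_n - per$both_n) + per$neither_n,
               per$n_dyads)
  expect_equal(per$individuals_n, per$mother_n + per$child_n)
  ov <- s[s$cluster == "Overall", ]
  expect_equal(ov$n_dyads, sum(per$n_dyads))
  expect_equal(ov$mother_n, sum(per$mother_n))
  # percentage -> count round trip at the stated rounding
  expect_equal(count_from_percent(per$mother_pct, per$n_dyads), per$mother_n)
  expect_equal(count_from_percent(per$individuals_pct, 2 * per$n_dyads),
               per$individuals_n)

  one <- tibble::tibble(cluster = 1L, mother = 1, child = 1)
  s1 <- summarize_clusters(one, overall = FALSE)
  expect_equal(s1$both_pct, 100)
  expect_equal(s1$neither_pct, 0)
})

test_that("pooling printed per-cluster rows reproduces published overall cells", {
  # printed per-cluster percentages and sizes; counts recovered, then pooled
  sizes <- c(122, 39, 14)
  mother_pct <- c(93.44, 97.44, 85.71)
  neither_pct <- c(3.28, 2.56, 7.14)
  child_pct <- c(57.38, 48.72, 64.29)
  both_pct <- c(54.10, 48.72, 57.14)
  per <- tibble::tibble(
    cluster = as.character(1:3),
    n_dyads = sizes,
    both_n = count_from_percent(both_pct, sizes),
    mother_n = count_from_percent(mother_pct, sizes),
    child_n = count_from_percent(child_pct, sizes),
    neither_n = count_from_percent(neither_pct, sizes)
  )
  per$individuals_n <- per$mother_n + per$child_n
  ov <- pool_overall(per)
  expect_equal(ov$mother_n, 164)
  expect_equal(ov$mother_pct, 93.71)
  expect_equal(ov$neither_n, 6)
  expect_equal(ov$neither_pct, 3.43)
  # per-cluster pooled-individual rates ("Total with Caries")
  expect_equal(round_half_up(100 * per$individuals_n / (2 * sizes), 2),
               c(75.41, 73.08, 75.00))

  single <- pool_overall(per[2, ])
  expect_equal(single$mother_pct, 97.44)
})

test_that("odds ratios exponentiate coefficients", {
  expect_equal(odds_ratio_from_coef(0.417, digits = 2), 1.52)
  expect_equal(odds_ratio_from_coef(0), 1)
  expect_equal(odds_ratio_from_coef(-0.6931472, digits = 2), 0.5)
  expect_error(odds_ratio_from_coef(Inf), "finite")
})

test_that("cross-cluster tests behave on degenerate and determined factors", {
  labels <- rep(1:3, each = 30)
  const <- rep("a", 90)
  res <- compare_across_clusters(labels, const)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)

  # factor perfectly determined by cluster
  determined <- rep(c("a", "b", "c"), each = 30)
  res2 <- compare_across_clusters(labels, determined)
  expect_lt(res2$p_value, 0.001)

  # hand-stated 2x3 table: chi-square = sum (O-E)^2 / E
  lab <- rep(1:2, c(30, 30))
  val <- c(rep(c("x", "y", "z"), c(15, 10, 5)),
           rep(c("x", "y", "z"), c(5, 10, 15)))
  tab <- table(lab, val)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  byhand <- sum((tab - E)^2 / E)
  res3 <- compare_across_clusters(lab, val)
  expect_equal(res3$statistic, byhand, tolerance = 1e-12)

  # invariance to cluster relabeling
  relab <- c(2L, 1L)[lab]
  res4 <- compare_across_clusters(relab, val)
  expect_equal(res4$statistic, res3$statistic)
  expect_equal(res4$p_value, res3$p_value)

  # abundance comparisons use Kruskal-Wallis
  y <- c(rnorm(30), rnorm(30, 2), rnorm(30))
  res5 <- compare_across_clusters(labels, y)
  expect_identical(res5$method, "kruskal-wallis")
  kw <- stats::kruskal.test(y, factor(labels))
  expect_equal(res5$statistic, unname(kw$statistic))
})

test_that("BH adjustment matches the brute-force suffix minimum", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(99)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), bh_brute(p))
  }
  # monotone in the sorted order
  p <- runif(30)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_error(bh_adjust(c(0.5, 1.2)), "pvalues")
})

test_that("significance buckets split at the published thresholds", {
  expect_equal(as.character(p_value_bucket(c(0.0005, 0.005, 0.04, 0.2))),
               c("<0.001", "<0.01", "<0.05", "ns"))
})

test_that("multi-variable comparison table carries adjusted p-values", {
  set.seed(4)
  labels <- rep(1:3, each = 40)
  df <- tibble::tibble(
    shifted = c(rnorm(40), rnorm(40, 3), rnorm(40)),
    null1 = rnorm(120),
    null2 = rnorm(120)
  )
  res <- compare_clusters_table(df, labels)
  expect_equal(nrow(res), 3L)
  expect_equal(res$p_adjusted, bh_adjust(res$p_value))
  expect_lt(res$p_adjusted[res$variable == "shifted"], 0.01)
})
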