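test_that("initialization splits separated covariate blocks and is deterministic", {
  X <- rbind(matrix(0, 20, 3), matrix(10, 20, 3)) +
    matrix(rnorm(120, sd = 0.01), 40, 3)
  y <- rep(c(0, 1), 20)
  d <- make_dyad_data(X, y)
  lab <- initialize_labels(d, 2, seed = 4)
  expect_equal(length(lab), 20L)
  expect_equal(length(unique(lab[1:10])), 1L)
  expect_equal(length(unique(lab[11:20])), 1L)
  expect_false(lab[1] == lab[20])
  expect_identical(lab, initialize_labels(d, 2, seed = 4))
  expect_equal(unname(initialize_labels(d, 1, seed = 1)), rep(1L, 20))
  expect_error(initialize_labels(d, 50, seed = 1), "exceeds")
})

test_that("trajectory k-means separates tight probability groups", {
  pts <- rbind(matrix(0.1, 10, 2), matrix(0.9, 10, 2)) +
    matrix(runif(40, -0.02, 0.02), 20, 2)
  lab <- kmeans_trajectories(pts, 2, seed = 3)
  expect_equal(length(unique(lab[1:10])), 1L)
  expect_equal(length(unique(lab[11:20])), 1L)
  expect_false(lab[1] == lab[11])

  # k = n: every point its own cluster, zero inertia
  pts2 <- cbind(seq(0.1, 0.9, length.out = 5), seq(0.9, 0.1, length.out = 5))
  lab2 <- kmeans_trajectories(pts2, 5, seed = 1)
  expect_equal(sort(unique(as.integer(lab2))), 1:5)
  expect_equal(attr(lab2, "inertia"), 0)

  expect_error(kmeans_trajectories(pts2, 6, seed = 1), "exceeds")
  expect_error(kmeans_trajectories(pts2 * 2, 2, seed = 1), "\\[0, 1\\]")
})

test_that("trajectory k-means attains the exhaustive-partition optimum", {
  set.seed(14)
  for (rep in 1:5) {
    pts <- matrix(runif(12), 6, 2)
    lab <- kmeans_trajectories(pts, 2, seed = rep, restarts = 20)
    oracle <- best_partition_inertia(pts, 2)
    expect_equal(attr(lab, "inertia"), oracle$inertia, tolerance = 1e-12)
  }
})

test_that("adjusted Rand index matches its contingency-table definition", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(rep(1, 8), c(1, 2, 1, 2, 1, 2, 1, 2)), 0)
  a <- c(1, 1, 2, 2, 3, 3)
  b <- c(1, 2, 2, 2, 3, 1)
  # hand evaluation via the contingency formula
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2)); sb <- sum(choose(colSums(tab), 2))
  ex <- sa * sb / choose(6, 2)
  hand <- (sij - ex) / ((sa + sb) / 2 - ex)
  expect_equal(adjusted_rand_index(a, b), hand)
  skip_if_not_installed("mclust")
  expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  expect_error(adjusted_rand_index(1:3, 1:4), "lengths differ")
})

test_that("alternating run honors contracts for k = 1 and max_iter = 1", {
  sim <- generate_dyads(synthetic_config(
    "custom", k = 2, dyads_per_cluster = c(15, 15), p = 4, support_size = 1,
    effect_size = 2, intercepts = c(-1, 1), seed = 8))
  res1 <- run_alternating(sim$data, k = 1, seed = 1, n_lambda = 5)
  expect_true(res1$converged)
  expect_lte(res1$n_iterations, 2L)
  expect_true(all(res1$labels$cluster == 1L))

  res_cap <- run_alternating(sim$data, k = 3, seed = 5, max_iter = 1,
                             n_lambda = 5)
  expect_equal(res_cap$n_iterations, 1L)
  if (res_cap$iteration_log$n_changed[1] > 0) {
    expect_false(res_cap$converged)
  }
})

test_that("clustering is deterministic and converges to a fixed point", {
  sim <- generate_dyads(synthetic_config(
    "strong-separation", dyads_per_cluster = c(20, 20, 20), seed = 12))
  a <- run_alternating(sim$data, k = 3, seed = 6, n_lambda = 8)
  b <- run_alternating(sim$data, k = 3, seed = 6, n_lambda = 8)
  expect_identical(a$labels, b$labels)
  expect_identical(a$probabilities, b$probabilities)

  # one row per dyad: members share the cluster label by construction
  expect_equal(nrow(a$labels), 60L)
  expect_equal(sort(unique(sim$data$dyad_id)), sort(a$labels$dyad_id))

  if (a$converged) {
    # fixed point: one more outer iteration leaves labels unchanged
    again <- run_alternating(sim$data, k = 3, seed = a$config$seed +
                               a$n_iterations - 1,
                             max_iter = 1, n_lambda = 8,
                             init = a$labels$cluster)
    expect_equal(again$labels$cluster, a$labels$cluster)
  }
})

test_that("result accessors expose tidy structures", {
  sim <- generate_dyads(synthetic_config(
    "custom", k = 2, dyads_per_cluster = c(12, 12), p = 3, support_size = 1,
    effect_size = 2, intercepts = c(-1.5, 1.5), seed = 21))
  res <- run_alternating(sim$data, k = 2, seed = 2, n_lambda = 5)
  td <- tidy(res)
  expect_true(all(c("dyad_id", "cluster", "p_mother", "p_child") %in%
                    names(td)))
  expect_equal(nrow(td), 24L)
  gl <- glance(res)
  expect_equal(gl$k, 2)
  expect_s3_class(autoplot(res), "ggplot")
  expect_true(all(td$p_mother >= 0 & td$p_mother <= 1))
})
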