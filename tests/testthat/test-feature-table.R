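write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("read_feature_table parses both orientations and validates cells", {
  path <- write_tsv_fixture(c(
    "feature\ts1\ts2\ts3",
    "otuA\t1\t2\t3",
    "otuB\t4\t5\t6"
  ))
  ft <- read_feature_table(path, orientation = "features-rows")
  expect_s3_class(ft, "feature_table")
  expect_equal(dim(feature_matrix(ft)), c(3L, 2L))
  expect_equal(feature_names(ft), c("otuA", "otuB"))
  expect_equal(unname(feature_matrix(ft)["s2", "otuB"]), 5)

  ft2 <- read_feature_table(write_tsv_fixture(c(
    "sample_id\totuA\totuB",
    "s1\t1\t4",
    "s2\t2\t5"
  )), orientation = "samples-rows")
  expect_equal(ft2$sample_id, c("s1", "s2"))

  dup <- write_tsv_fixture(c("feature\ts1\ts2", "otuA\t1\t2", "otuA\t3\t4"))
  expect_error(read_feature_table(dup, orientation = "features-rows"),
               "duplicate feature")

  bad <- write_tsv_fixture(c("feature\ts1\ts2", "otuA\t1\tNA"))
  expect_error(read_feature_table(bad, orientation = "features-rows"),
               "row 'otuA', column 's2'")

  empty <- write_tsv_fixture(character())
  expect_error(read_feature_table(empty), "empty|parse")
})

test_that("abundance filter keeps features reaching min_count in enough samples", {
  tab <- feature_table(cbind(
    kept = c(5, 5, 0, 0, 0),      # 2/5 = 40% of samples at >= 4
    below = c(3, 3, 3, 3, 3),     # never reaches 4
    rare = c(10, 0, 0, 0, 0)      # 1/5 = 20%: kept at exactly the boundary
  ))
  out <- filter_low_abundance(tab)
  expect_equal(feature_names(out), c("kept", "rare"))
  rep <- removal_report(out)
  expect_equal(rep$feature_id, "below")
  expect_equal(rep$rule, "low-abundance")

  # 10-sample version of the rare feature: 10% < 20% -> removed
  tab10 <- feature_table(cbind(rare = c(10, rep(0, 9)), ok = rep(5, 10)))
  out10 <- filter_low_abundance(tab10)
  expect_equal(feature_names(out10), "ok")
  expect_error(filter_low_abundance(tab, min_prevalence = 1.2), "min_prevalence")
  expect_error(filter_low_abundance(to_relative_abundance(tab)), "counts-scale")
})

test_that("abundance filter is idempotent and reports are consistent", {
  set.seed(42)
  M <- matrix(rpois(20 * 30, 2), 20, 30,
              dimnames = list(NULL, paste0("f", 1:30)))
  tab <- feature_table(M)
  once <- filter_low_abundance(tab)
  twice <- filter_low_abundance(once)
  expect_equal(feature_names(twice), feature_names(once))
  expect_equal(length(feature_names(once)) + nrow(removal_report(once)),
               length(feature_names(tab)))
})

test_that("low-variance filter drops the smallest-spread features with stable ties", {
  set.seed(7)
  M <- matrix(rnorm(50 * 10), 50, 10, dimnames = list(NULL, paste0("f", 1:10)))
  M[, 4] <- 3 # constant feature: zero IQR
  tab <- feature_table(abs(M))
  out <- filter_low_variance(tab, drop_fraction = 0.1)
  expect_equal(removal_report(out)$feature_id, "f4")
  expect_equal(length(feature_names(out)), 9L)

  # drop_fraction = 0 is the identity
  expect_equal(feature_names(filter_low_variance(tab, 0)), feature_names(tab))

  # all features identical -> earliest-listed removed first
  tied <- feature_table(matrix(rep(c(1, 5, 9), 4), 3, 4,
                               dimnames = list(NULL, paste0("t", 1:4))))
  out_tied <- filter_low_variance(tied, drop_fraction = 0.25)
  expect_equal(removal_report(out_tied)$feature_id, "t1")
  expect_error(filter_low_variance(tab, 1), "drop_fraction")
})

test_that("relative abundance normalizes rows and rejects zero-sum samples", {
  tab <- feature_table(matrix(c(2, 2, 1, 3), 2, 2, byrow = TRUE,
                              dimnames = list(c("a", "b"), c("x", "y"))))
  rel <- to_relative_abundance(tab)
  expect_equal(unname(feature_matrix(rel)["a", ]), c(0.5, 0.5))
  expect_true(all(abs(rowSums(feature_matrix(rel)) - 1) < 1e-12))
  expect_identical(attr(rel, "scale"), "proportions")

  zero <- feature_table(matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE,
                               dimnames = list(c("ok", "empty"), c("x", "y"))))
  expect_error(to_relative_abundance(zero), "empty")
})

test_that("assemble_dyads pairs members, validates, and drops incomplete dyads", {
  M <- matrix(1:16, 4, 4,
              dimnames = list(c("m1", "c1", "m2", "c2"), paste0("f", 1:4)))
  tab <- feature_table(M)
  meta <- tibble::tibble(
    sample_id = c("m1", "c1", "m2", "c2"),
    dyad_id = c("d1", "d1", "d2", "d2"),
    role = c("mother", "child", "mother", "child"),
    outcome = c(1, 0, 1, 1)
  )
  dd <- assemble_dyads(tab, meta)
  expect_s3_class(dd, "dyad_data")
  expect_equal(nrow(dd), 4L)
  expect_equal(n_dyads(dd), 2L)
  # two rows per dyad, mother first
  expect_equal(as.character(dd$role), rep(c("mother", "child"), 2))
  expect_equal(dd$dyad_id, rep(c("d1", "d2"), each = 2))
  # covariates are relative abundances by default
  expect_true(all(abs(rowSums(as.matrix(dd[, dyad_feature_names(dd)])) - 1)
                  < 1e-9))

  meta_incomplete <- meta[-2, ] # d1 loses its child
  expect_warning(dd2 <- assemble_dyads(tab, meta_incomplete), "dropped")
  expect_equal(n_dyads(dd2), 1L)
  expect_error(assemble_dyads(tab, meta_incomplete, strict = TRUE),
               "mother and one child")

  meta_bad <- meta
  meta_bad$outcome[1] <- 2
  expect_error(assemble_dyads(tab, meta_bad), "0/1")

  meta_missing <- meta
  meta_missing$sample_id[1] <- "ghost"
  expect_error(assemble_dyads(tab, meta_missing), "absent")
})
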