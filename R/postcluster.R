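#' Per-cluster caries summary
#'
#' Tabulates, for each cluster of dyads, the count and percentage of dyads
#' where both members have caries, where the mother has caries, where the
#' child has caries, where neither does, and the pooled share of individual
#' members with caries (out of `2 * n_dyads`). Percentages are rounded
#' half-up to 2 decimals, the convention of the printed summary tables.
#'
#' @param outcomes A per-dyad tibble with columns `cluster`, `mother`,
#'   `child` (binary outcomes), e.g. from [dyad_outcomes()].
#' @param overall Append the pooled overall row (default `TRUE`).
#' @return A `caries_summary` tibble: one row per cluster (+ `"Overall"`),
#'   with `*_n` count and `*_pct` percentage columns.
#' @export
summarize_clusters <- function(outcomes, overall = TRUE) {
  req <- c("cluster", "mother", "child")
  if (!all(req %in% names(outcomes))) {
    .stopf("outcomes must have columns %s", paste(req, collapse = ", "))
  }
  if (!all(unlist(outcomes[, c("mother", "child")]) %in% c(0, 1))) {
    .stopf("outcomes must be coded 0/1")
  }
  cl <- outcomes$cluster
  if (is.factor(cl) && any(table(cl) == 0)) {
    .stopf("empty cluster label present: %s",
           paste(levels(cl)[table(cl) == 0], collapse = ", "))
  }
  per <- outcomes |>
    dplyr::group_by(cluster = .data$cluster) |>
    dplyr::summarise(
      n_dyads = dplyr::n(),
      both_n = sum(.data$mother == 1 & .data$child == 1),
      mother_n = sum(.data$mother == 1),
      child_n = sum(.data$child == 1),
      neither_n = sum(.data$mother == 0 & .data$child == 0),
      individuals_n = sum(.data$mother) + sum(.data$child),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$cluster) |>
    dplyr::mutate(cluster = as.character(.data$cluster))
  per <- .add_pct(per)
  if (overall) per <- dplyr::bind_rows(per, pool_overall(per))
  tibble::new_tibble(per, class = "caries_summary")
}

.add_pct <- function(per) {
  per |>
    dplyr::mutate(
      both_pct = round_half_up(100 * .data$both_n / .data$n_dyads, 2),
      mother_pct = round_half_up(100 * .data$mother_n / .data$n_dyads, 2),
      child_pct = round_half_up(100 * .data$child_n / .data$n_dyads, 2),
      neither_pct = round_half_up(100 * .data$neither_n / .data$n_dyads, 2),
      individuals_pct = round_half_up(
        100 * .data$individuals_n / (2 * .data$n_dyads), 2)
    )
}

#' Pool per-cluster caries counts into an overall row
#'
#' Sums the integer counts across clusters and divides by the total number
#' of dyads (or members, for the individuals column); pooled percentages
#' are computed from summed counts, never by averaging percentages.
#'
#' @param summary A per-cluster [summarize_clusters()] tibble (counts
#'   required; any existing `"Overall"` row is ignored).
#' @return A single-row tibble labeled `"Overall"`.
#' @export
pool_overall <- function(summary) {
  per <- dplyr::filter(summary, .data$cluster != "Overall")
  if (nrow(per) == 0) .stopf("no cluster rows to pool")
  tot <- per |>
    dplyr::summarise(
      cluster = "Overall",
      n_dyads = sum(.data$n_dyads),
      both_n = sum(.data$both_n),
      mother_n = sum(.data$mother_n),
      child_n = sum(.data$child_n),
      neither_n = sum(.data$neither_n),
      individuals_n = sum(.data$individuals_n)
    )
  .add_pct(tot)
}

#' Reconstruct an integer count from a printed percentage
#'
#' Inverts the 2-decimal percentage display: `round(pct * n / 100)`. Used to
#' recover the integer dyad counts behind published per-cluster percentage
#' tables before pooling them with [pool_overall()].
#'
#' @param pct Percentage (e.g. 93.44).
#' @param n Denominator.
#' @return Integer count.
#' @export
count_from_percent <- function(pct, n) as.integer(round(pct * n / 100))

#' Odds ratio of a logit-scale coefficient
#'
#' `exp(beta)`: the multiplicative change in the odds of caries per one-unit
#' increase of the covariate (for relative-abundance covariates, per unit
#' relative abundance), holding other covariates fixed and ignoring the
#' random intercept.
#'
#' @param beta Logit-scale coefficient(s).
#' @param digits If non-`NULL`, round half-up to this many decimals for
#'   display.
#' @return Odds ratio(s).
#' @export
odds_ratio_from_coef <- function(beta, digits = NULL) {
  if (!all(is.finite(beta))) .stopf("coefficient must be finite")
  or <- exp(beta)
  if (!is.null(digits)) or <- round_half_up(or, digits)
  or
}

#' Compare one variable across clusters
#'
#' Categorical variables get a chi-square test of independence on the
#' cluster-by-level contingency table, switching to a seeded Monte-Carlo
#' permutation p-value (`(1 + #extreme) / (1 + B)`) when any expected cell
#' is below 5; abundance variables get a Kruskal-Wallis rank test across
#' clusters. A variable that is constant everywhere returns `p = 1` with
#' the `degenerate` flag set.
#'
#' @param labels Cluster label per observation.
#' @param values The variable (factor/character for categorical, numeric
#'   for abundance).
#' @param kind `"categorical"` or `"abundance"`; `"auto"` (default) picks by
#'   type.
#' @param n_perm Monte-Carlo permutations for sparse tables (default 10000).
#' @param seed Seed for the permutation p-value.
#' @return A one-row tibble: `method`, `statistic`, `p_value`, `degenerate`.
#' @export
compare_across_clusters <- function(labels, values,
                                    kind = c("auto", "categorical",
                                             "abundance"),
                                    n_perm = 10000, seed = 1) {
  kind <- match.arg(kind)
  if (length(labels) != length(values)) .stopf("length mismatch")
  keep <- !is.na(values) & !is.na(labels)
  labels <- factor(labels[keep])
  values <- values[keep]
  if (nlevels(labels) < 2) .stopf("need >= 2 non-empty clusters")
  if (kind == "auto") {
    kind <- if (is.numeric(values)) "abundance" else "categorical"
  }
  if (length(unique(values)) == 1) {
    return(tibble::tibble(method = kind, statistic = NA_real_,
                          p_value = 1, degenerate = TRUE))
  }
  if (kind == "categorical") {
    tab <- table(labels, values)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      set.seed(seed)
      ct <- suppressWarnings(
        stats::chisq.test(tab, simulate.p.value = TRUE, B = n_perm))
      method <- "chi-square (permutation)"
    } else {
      ct <- stats::chisq.test(tab, correct = FALSE)
      method <- "chi-square"
    }
    tibble::tibble(method = method,
                   statistic = unname(ct$statistic),
                   p_value = unname(ct$p.value), degenerate = FALSE)
  } else {
    kt <- stats::kruskal.test(values, labels)
    tibble::tibble(method = "kruskal-wallis",
                   statistic = unname(kt$statistic),
                   p_value = unname(kt$p.value), degenerate = FALSE)
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control: sort ascending, take
#' `min_{j >= i} (m * p_(j) / j)` capped at 1, return in the original order.
#'
#' @param pvalues Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order.
#' @export
bh_adjust <- function(pvalues) {
  .assert_prob_range(pvalues, "pvalues")
  stats::p.adjust(pvalues, method = "BH")
}

#' Significance bucket of an adjusted p-value
#'
#' The display buckets used alongside cross-cluster comparison figures.
#'
#' @param p Adjusted p-values.
#' @return Ordered factor with levels `"<0.001"`, `"<0.01"`, `"<0.05"`,
#'   `"ns"`.
#' @export
p_value_bucket <- function(p) {
  .assert_prob_range(p, "p")
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("<0.001", "<0.01", "<0.05", "ns"),
      right = FALSE, ordered_result = TRUE)
}

#' Compare several variables across clusters with FDR control
#'
#' Maps [compare_across_clusters()] over a set of columns and adjusts the
#' resulting p-values with [bh_adjust()], mirroring the post-clustering
#' screens of maternal factors and selected OTUs.
#'
#' @param data A data frame of per-observation variables.
#' @param labels Cluster label per row of `data`.
#' @param variables Column names to test (default: all columns).
#' @param ... Passed to [compare_across_clusters()].
#' @return A tibble: one row per variable with raw and BH-adjusted p-values
#'   and the significance bucket.
#' @export
compare_clusters_table <- function(data, labels, variables = names(data),
                                   ...) {
  res <- purrr::map_dfr(variables, function(v) {
    dplyr::mutate(compare_across_clusters(labels, data[[v]], ...),
                  variable = v, .before = 1)
  })
  res$p_adjusted <- bh_adjust(res$p_value)
  res$bucket <- p_value_bucket(res$p_adjusted)
  res
}
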