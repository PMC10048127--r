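#' Assemble paired mother-child model inputs
#'
#' Joins a feature table with sample metadata into the per-observation layout
#' the clustering model consumes: one row per family member, two rows per
#' dyad (mother first, then child), with the binary caries outcome
#' (`1` = caries, `0` = no caries), the dyad grouping id, and the covariate
#' columns. Dyads missing a member (or carrying a duplicated role) are
#' dropped with a warning, or raise an error under `strict = TRUE`; the
#' random-intercept model requires complete pairs.
#'
#' @param table A [feature_table()] whose samples cover the metadata.
#' @param metadata A data frame with columns `sample_id`, `dyad_id`, `role`
#'   (`"mother"`/`"child"`), `outcome` (0/1), plus optional categorical
#'   factor columns.
#' @param strict If `TRUE`, incomplete dyads are an error instead of being
#'   dropped.
#' @param covariate_scale Scale on which covariates enter the model:
#'   `"proportions"` (relative abundances, the default, so coefficients read
#'   per unit relative abundance), `"counts"` (table values as-is), or
#'   `"log-proportions"` (`log(p + pseudocount)`).
#' @param pseudocount Offset for `"log-proportions"` (default 1e-6).
#' @return A tibble of class `dyad_data`: columns `sample_id`, `dyad_id`,
#'   `role`, `outcome`, any metadata factor columns, then one column per
#'   feature. Attributes `feature_names` and `factor_names` record which
#'   columns are which.
#' @export
assemble_dyads <- function(table, metadata, strict = FALSE,
                           covariate_scale = c("proportions", "counts",
                                               "log-proportions"),
                           pseudocount = 1e-6) {
  covariate_scale <- match.arg(covariate_scale)
  validate_feature_table(table)
  metadata <- tibble::as_tibble(metadata)
  required <- c("sample_id", "dyad_id", "role", "outcome")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols) > 0) {
    .stopf("metadata is missing required column(s): %s",
           paste(missing_cols, collapse = ", "))
  }
  absent <- setdiff(metadata$sample_id, table$sample_id)
  if (length(absent) > 0) {
    .stopf("metadata sample(s) absent from feature table: %s",
           paste(utils::head(absent, 5), collapse = ", "))
  }
  if (anyDuplicated(metadata$sample_id)) .stopf("duplicate sample_id in metadata")
  bad_role <- setdiff(unique(metadata$role), c("mother", "child"))
  if (length(bad_role) > 0) {
    .stopf("role must be 'mother' or 'child'; found: %s",
           paste(bad_role, collapse = ", "))
  }
  if (!all(metadata$outcome %in% c(0, 1))) {
    .stopf("outcome must be coded 0/1 (caries = 1, no caries = 0); found: %s",
           paste(setdiff(unique(metadata$outcome), c(0, 1)), collapse = ", "))
  }

  counts_per <- metadata |>
    dplyr::count(.data$dyad_id, .data$role) |>
    tidyr::pivot_wider(names_from = "role", values_from = "n",
                       values_fill = 0L)
  if (!"mother" %in% names(counts_per)) counts_per$mother <- 0L
  if (!"child" %in% names(counts_per)) counts_per$child <- 0L
  complete <- counts_per$dyad_id[counts_per$mother == 1L & counts_per$child == 1L]
  incomplete <- setdiff(counts_per$dyad_id, complete)
  if (length(incomplete) > 0) {
    msg <- sprintf("dyad(s) without exactly one mother and one child: %s",
                   paste(utils::head(incomplete, 5), collapse = ", "))
    if (strict) .stopf("%s", msg)
    warning(sprintf("%s; dropped", msg), call. = FALSE)
    metadata <- dplyr::filter(metadata, .data$dyad_id %in% complete)
  }
  if (nrow(metadata) == 0) .stopf("no complete dyads remain")

  if (covariate_scale != "counts" &&
      identical(attr(table, "scale"), "counts")) {
    table <- to_relative_abundance(table)
  }
  M <- feature_matrix(table)
  if (covariate_scale == "log-proportions") M <- log(M + pseudocount)

  factor_names <- setdiff(names(metadata), required)
  ord <- metadata |>
    dplyr::mutate(role = factor(.data$role, levels = c("mother", "child"))) |>
    dplyr::arrange(.data$dyad_id, .data$role)
  out <- dplyr::bind_cols(
    ord,
    tibble::as_tibble(M[ord$sample_id, , drop = FALSE], .name_repair = "minimal")
  )
  out$outcome <- as.integer(out$outcome)
  tibble::new_tibble(out,
                     feature_names = colnames(M),
                     factor_names = factor_names,
                     class = "dyad_data")
}

#' @rdname assemble_dyads
#' @param data A `dyad_data` tibble.
#' @export
dyad_feature_names <- function(data) attr(data, "feature_names")

# internal: matrix view of a dyad_data tibble.
# Returns X (2n x p), y (2n), Y2 (n x 2, mother|child), E (n x 2 row indices),
# dyad_ids (n). Row order within dyad is mother then child.
.dyad_matrices <- function(data, features = dyad_feature_names(data)) {
  if (!inherits(data, "dyad_data")) .stopf("expected a dyad_data tibble")
  miss <- setdiff(features, names(data))
  if (length(miss) > 0) {
    .stopf("covariate(s) absent from data: %s",
           paste(utils::head(miss, 5), collapse = ", "))
  }
  X <- as.matrix(data[, features, drop = FALSE])
  storage.mode(X) <- "double"
  y <- as.integer(data$outcome)
  ids <- unique(data$dyad_id)
  mrow <- which(data$role == "mother")
  crow <- which(data$role == "child")
  # rows are ordered dyad-wise mother-then-child by construction
  stopifnot(length(mrow) == length(crow),
            identical(data$dyad_id[mrow], ids),
            identical(data$dyad_id[crow], ids))
  E <- cbind(mother = mrow, child = crow)
  list(X = X, y = y, Y2 = cbind(y[mrow], y[crow]), E = E, dyad_ids = ids)
}

#' Number of dyads in a dyad_data tibble
#' @param data A `dyad_data` tibble.
#' @return Integer count of complete pairs.
#' @export
n_dyads <- function(data) length(unique(data$dyad_id))

#' Per-dyad outcome pairs
#'
#' Reshapes a `dyad_data` tibble to one row per dyad with the mother and
#' child outcomes side by side, optionally attaching cluster labels; this is
#' the input layout for [summarize_clusters()].
#'
#' @param data A `dyad_data` tibble.
#' @param clusters Optional: a `dyad_clusters` result or an integer vector of
#'   labels (one per dyad, in `unique(data$dyad_id)` order).
#' @return A tibble with columns `dyad_id`, `mother`, `child` and, when
#'   labels are supplied, `cluster`.
#' @export
dyad_outcomes <- function(data, clusters = NULL) {
  md <- .dyad_matrices(data)
  out <- tibble::tibble(dyad_id = md$dyad_ids,
                        mother = md$Y2[, 1], child = md$Y2[, 2])
  if (!is.null(clusters)) {
    if (inherits(clusters, "dyad_clusters")) {
      out <- dplyr::left_join(out, clusters$labels, by = "dyad_id")
    } else {
      out$cluster <- as.integer(clusters)
    }
  }
  out
}
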