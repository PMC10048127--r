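#' Construct a feature table
#'
#' A feature table holds per-sample abundances of microbial features (OTUs or
#' other taxon proxies) as a tibble whose first column is `sample_id` and
#' whose remaining columns are numeric feature abundances. The table carries
#' a `scale` attribute recording whether entries are raw `"counts"` or
#' row-normalized `"proportions"`.
#'
#' @param x A data frame or matrix, samples in rows. If a data frame with a
#'   `sample_id` column (or a first character column), that column supplies
#'   sample ids; for a matrix, rownames are used.
#' @param scale Either `"counts"` or `"proportions"`.
#' @return A tibble of class `feature_table`.
#' @export
feature_table <- function(x, scale = c("counts", "proportions")) {
  scale <- match.arg(scale)
  if (is.matrix(x)) {
    ids <- rownames(x)
    if (is.null(ids)) ids <- paste0("sample", seq_len(nrow(x)))
    x <- dplyr::bind_cols(
      tibble::tibble(sample_id = ids),
      tibble::as_tibble(x, .name_repair = "minimal")
    )
  } else {
    x <- tibble::as_tibble(x)
    if (!"sample_id" %in% names(x)) {
      if (is.character(x[[1]])) {
        names(x)[1] <- "sample_id"
      } else {
        x <- dplyr::bind_cols(
          tibble::tibble(sample_id = paste0("sample", seq_len(nrow(x)))), x
        )
      }
    }
    x <- dplyr::relocate(x, "sample_id")
  }
  out <- tibble::new_tibble(x, scale = scale, class = "feature_table")
  validate_feature_table(out)
}

#' Validate a feature table
#'
#' Checks the invariants: unique sample and feature ids, numeric non-negative
#' abundances, and (for proportion-scale tables) unit row sums within 1e-9.
#'
#' @param table A [feature_table()].
#' @return The table, invisibly unchanged, or an error.
#' @export
validate_feature_table <- function(table) {
  if (!inherits(table, "feature_table")) .stopf("not a feature_table")
  ids <- table$sample_id
  if (anyDuplicated(ids)) {
    .stopf("duplicate sample id(s): %s",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  feats <- feature_names(table)
  if (length(feats) == 0) .stopf("feature table has no feature columns")
  if (anyDuplicated(feats)) {
    .stopf("duplicate feature id(s): %s",
           paste(unique(feats[duplicated(feats)]), collapse = ", "))
  }
  M <- feature_matrix(table)
  if (!is.numeric(M)) .stopf("feature columns must be numeric")
  if (anyNA(M)) .stopf("feature table contains missing values")
  if (any(M < 0)) .stopf("feature table contains negative abundances")
  if (identical(attr(table, "scale"), "proportions")) {
    rs <- rowSums(M)
    bad <- which(abs(rs - 1) > 1e-9)
    if (length(bad) > 0) {
      .stopf("proportion-scale rows must sum to 1; offending sample(s): %s",
             paste(ids[bad], collapse = ", "))
    }
  }
  table
}

#' @rdname feature_table
#' @param table A `feature_table`.
#' @export
feature_names <- function(table) {
  nm <- names(table)
  nm[nm != "sample_id"] # keeps duplicates so validation can catch them
}

#' @rdname feature_table
#' @export
feature_matrix <- function(table) {
  M <- as.matrix(table[, names(table) != "sample_id", drop = FALSE])
  rownames(M) <- table$sample_id
  M
}

#' Read a feature table from a delimited file
#'
#' Reads a TSV/CSV abundance table in either orientation and returns a
#' validated, samples-in-rows [feature_table()]. Cells that fail numeric
#' parsing (including literal `NA`) raise an error naming the offending
#' row and column, so malformed exports fail loudly rather than silently
#' propagating missing values into the model.
#'
#' @param path Path to a delimited text file; first column holds row ids,
#'   header holds column ids.
#' @param delimiter Field delimiter; defaults to `"\t"` unless the file
#'   extension is `.csv`.
#' @param orientation `"samples-rows"` (default) or `"features-rows"`.
#' @param scale Declared scale of the values, `"counts"` or `"proportions"`.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, delimiter = NULL,
                               orientation = c("samples-rows", "features-rows"),
                               scale = c("counts", "proportions")) {
  orientation <- match.arg(orientation)
  scale <- match.arg(scale)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- tryCatch(
    utils::read.delim(path, sep = delimiter, header = TRUE,
                      check.names = FALSE, colClasses = "character",
                      row.names = NULL),
    error = function(e) .stopf("cannot parse %s: %s", path, conditionMessage(e))
  )
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    .stopf("empty or degenerate feature table: %s", path)
  }
  row_ids <- raw[[1]]
  col_ids <- names(raw)[-1]
  vals <- matrix(NA_real_, nrow(raw), length(col_ids))
  for (j in seq_along(col_ids)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      .stopf("non-numeric value '%s' at row '%s', column '%s' in %s",
             raw[[j + 1]][bad[1]], row_ids[bad[1]], col_ids[j], path)
    }
    vals[, j] <- v
  }
  if (orientation == "features-rows") {
    vals <- t(vals)
    tmp <- row_ids; row_ids <- col_ids; col_ids <- tmp
  }
  # duplicates must be caught before tibble construction repairs names
  if (anyDuplicated(row_ids)) {
    .stopf("duplicate sample id(s) in %s: %s", path,
           paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  }
  if (anyDuplicated(col_ids)) {
    .stopf("duplicate feature id(s) in %s: %s", path,
           paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))
  }
  rownames(vals) <- row_ids
  colnames(vals) <- col_ids
  feature_table(vals, scale = scale)
}

#' Write a feature table to a delimited file
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @param delimiter Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, delimiter = "\t") {
  utils::write.table(as.data.frame(table), path, sep = delimiter,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

.attach_report <- function(table, report) {
  attr(table, "removal_report") <- report
  table
}

#' Removal report of a filtered feature table
#'
#' The filtering functions record which features they removed and why; this
#' accessor returns that record as a tibble with columns `feature_id`,
#' `rule`, and `statistic`.
#'
#' @param table A filtered [feature_table()].
#' @return A tibble (zero rows if nothing was removed or never filtered).
#' @export
removal_report <- function(table) {
  rep <- attr(table, "removal_report")
  if (is.null(rep)) {
    rep <- tibble::tibble(feature_id = character(), rule = character(),
                          statistic = double())
  }
  rep
}

#' Remove low-abundance, low-prevalence features
#'
#' Applies the prevalence filter used for sparse OTU tables: a feature is
#' kept if and only if its count reaches `min_count` in at least
#' `ceiling(min_prevalence * n_samples)` samples. Everything else is removed
#' and listed in the removal report (see [removal_report()]), with the number
#' of samples reaching the threshold as the reported statistic.
#'
#' @param table A counts-scale [feature_table()].
#' @param min_count Per-sample count threshold (default 4).
#' @param min_prevalence Minimum fraction of samples reaching `min_count`
#'   (default 0.2).
#' @return The filtered `feature_table` with a removal report attached.
#' @export
filter_low_abundance <- function(table, min_count = 4, min_prevalence = 0.2) {
  validate_feature_table(table)
  if (!identical(attr(table, "scale"), "counts")) {
    .stopf("abundance filtering requires a counts-scale table")
  }
  if (!is.numeric(min_prevalence) || min_prevalence < 0 || min_prevalence > 1) {
    .stopf("`min_prevalence` must lie in [0, 1]")
  }
  M <- feature_matrix(table)
  need <- ceiling(min_prevalence * nrow(M))
  hits <- colSums(M >= min_count)
  keep <- hits >= need
  report <- tibble::tibble(
    feature_id = colnames(M)[!keep],
    rule = "low-abundance",
    statistic = as.double(hits[!keep])
  )
  out <- table[, c("sample_id", colnames(M)[keep]), drop = FALSE]
  out <- tibble::new_tibble(out, scale = attr(table, "scale"),
                            class = "feature_table")
  .attach_report(out, dplyr::bind_rows(removal_report(table), report))
}

#' Remove the lowest-spread features
#'
#' Drops the `floor(drop_fraction * n_features)` features with the smallest
#' spread statistic (interquartile range by default, optionally variance).
#' Ties are broken by column order: earlier-listed features are removed
#' first.
#'
#' @param table A [feature_table()].
#' @param drop_fraction Fraction of features to drop, in `[0, 1)`
#'   (default 0.10).
#' @param spread Spread statistic, `"iqr"` or `"variance"`.
#' @return The filtered `feature_table` with a removal report attached.
#' @export
filter_low_variance <- function(table, drop_fraction = 0.10,
                                spread = c("iqr", "variance")) {
  validate_feature_table(table)
  spread <- match.arg(spread)
  if (!is.numeric(drop_fraction) || drop_fraction < 0 || drop_fraction >= 1) {
    .stopf("`drop_fraction` must lie in [0, 1)")
  }
  M <- feature_matrix(table)
  stat <- switch(spread,
    iqr = apply(M, 2, stats::IQR),
    variance = apply(M, 2, stats::var)
  )
  n_drop <- floor(drop_fraction * ncol(M))
  drop_idx <- utils::head(order(stat), n_drop) # order() is stable: ties fall earliest-first
  keep <- setdiff(seq_len(ncol(M)), drop_idx)
  report <- tibble::tibble(
    feature_id = colnames(M)[drop_idx],
    rule = "low-variance",
    statistic = as.double(stat[drop_idx])
  )
  out <- table[, c("sample_id", colnames(M)[keep]), drop = FALSE]
  out <- tibble::new_tibble(out, scale = attr(table, "scale"),
                            class = "feature_table")
  .attach_report(out, dplyr::bind_rows(removal_report(table), report))
}

#' Convert counts to relative abundances
#'
#' Divides each sample row by its total, yielding compositional proportions;
#' model coefficients fitted on such covariates are interpreted per unit
#' relative abundance.
#'
#' @param table A counts-scale [feature_table()] with positive row sums.
#' @return A proportions-scale `feature_table`.
#' @export
to_relative_abundance <- function(table) {
  validate_feature_table(table)
  if (!identical(attr(table, "scale"), "counts")) {
    .stopf("table is already on the proportions scale")
  }
  M <- feature_matrix(table)
  rs <- rowSums(M)
  if (any(rs <= 0)) {
    .stopf("zero-sum sample(s): %s",
           paste(table$sample_id[rs <= 0], collapse = ", "))
  }
  P <- M / rs
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = table$sample_id),
    tibble::as_tibble(P, .name_repair = "minimal")
  )
  out <- tibble::new_tibble(out, scale = "proportions", class = "feature_table")
  .attach_report(out, removal_report(table))
}
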