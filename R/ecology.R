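#' Shannon diversity index
#'
#' Entropy \eqn{H = -\sum_i p_i \log p_i} of a sample's composition over its
#' nonzero proportions; scale-invariant, so counts and proportions of the
#' same composition agree. Natural log by default.
#'
#' @param counts Non-negative abundance vector with positive sum.
#' @param base Logarithm base (default `exp(1)`).
#' @return Scalar `H >= 0`.
#' @export
shannon_index <- function(counts, base = exp(1)) {
  if (anyNA(counts) || any(counts < 0)) .stopf("counts must be non-negative")
  if (sum(counts) <= 0) .stopf("all-zero abundance vector")
  as.numeric(vegan::diversity(matrix(counts, nrow = 1), index = "shannon",
                              base = base))
}

#' Per-sample Shannon diversity of a feature table
#'
#' @param table A [feature_table()].
#' @param base Logarithm base.
#' @return A tibble: `sample_id`, `shannon`.
#' @export
shannon_table <- function(table, base = exp(1)) {
  M <- feature_matrix(table)
  tibble::tibble(sample_id = rownames(M),
                 shannon = as.numeric(vegan::diversity(M, index = "shannon",
                                                       base = base)))
}

#' Bray-Curtis dissimilarity between two samples
#'
#' \eqn{\sum_i |x_i - y_i| / \sum_i (x_i + y_i)}, in `[0, 1]`: 0 for
#' identical vectors, 1 for disjoint supports.
#'
#' @param x,y Non-negative abundance vectors of equal length, each with at
#'   least one positive entry.
#' @return Scalar dissimilarity.
#' @export
bray_curtis_distance <- function(x, y) {
  if (length(x) != length(y)) .stopf("vectors differ in length")
  if (any(c(x, y) < 0)) .stopf("abundances must be non-negative")
  if (sum(x) <= 0 || sum(y) <= 0) .stopf("each vector needs a positive entry")
  as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

#' Bray-Curtis distance matrix of a feature table
#'
#' @param table A [feature_table()] (or samples-by-features matrix).
#' @return A symmetric `dist_matrix` (plain matrix, zero diagonal, sample
#'   ids as dimnames).
#' @export
bray_curtis_matrix <- function(table) {
  M <- if (inherits(table, "feature_table")) feature_matrix(table)
       else as.matrix(table)
  D <- as.matrix(vegan::vegdist(M, method = "bray"))
  diag(D) <- 0
  structure(D, class = c("dist_matrix", "matrix", "array"))
}

.validate_dist <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) .stopf("distance matrix must be square")
  if (max(abs(D - t(D))) > 1e-12) .stopf("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 0)) .stopf("distance matrix diagonal must be 0")
  if (any(D < 0)) .stopf("distances must be non-negative")
  D
}

#' Write / read a distance matrix as square TSV
#'
#' Square tab-delimited layout with the ids as both header row and first
#' column.
#'
#' @param D A square symmetric distance matrix.
#' @param path File path.
#' @return `path` invisibly / the matrix.
#' @export
write_distance_matrix <- function(D, path) {
  D <- .validate_dist(D)
  ids <- rownames(D)
  if (is.null(ids)) ids <- paste0("sample", seq_len(nrow(D)))
  df <- data.frame(id = ids, D, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  ids <- df[[1]]
  D <- as.matrix(df[, -1, drop = FALSE])
  dimnames(D) <- list(ids, ids)
  structure(.validate_dist(D), class = c("dist_matrix", "matrix", "array"))
}

#' Principal coordinate analysis (classical MDS)
#'
#' Double-centers \eqn{-\tfrac12 D^2}, eigendecomposes, and returns the top
#' axes by eigenvalue. Negative eigenvalues (which arise for non-Euclidean
#' dissimilarities such as Bray-Curtis) are reported but excluded from the
#' percent-explained denominator; no Lingoes/Cailliez correction is applied.
#'
#' @param D A square symmetric distance matrix (zero diagonal).
#' @param n_axes Number of axes to return (default 2; at most `n - 1`).
#' @return A `pcoa_embedding` list: `coordinates` tibble (`sample_id`,
#'   `Axis1`, ...), `eigenvalues` (all `n` of them), and
#'   `percent_explained` for the returned axes.
#' @export
pcoa_embedding <- function(D, n_axes = 2) {
  D <- .validate_dist(D)
  n <- nrow(D)
  if (n_axes > n - 1) .stopf("n_axes must be <= n - 1")
  ids <- rownames(D)
  if (is.null(ids)) ids <- paste0("sample", seq_len(n))
  fit <- stats::cmdscale(stats::as.dist(D), k = n_axes, eig = TRUE)
  coords <- fit$points
  if (ncol(coords) < n_axes) { # cmdscale drops axes with non-positive eigenvalues
    coords <- cbind(coords, matrix(0, n, n_axes - ncol(coords)))
  }
  colnames(coords) <- paste0("Axis", seq_len(n_axes))
  pos <- fit$eig[fit$eig > 0]
  pct <- 100 * pmax(fit$eig[seq_len(n_axes)], 0) / sum(pos)
  structure(
    list(
      coordinates = dplyr::bind_cols(tibble::tibble(sample_id = ids),
                                     tibble::as_tibble(coords)),
      eigenvalues = fit$eig,
      percent_explained = pct
    ),
    class = "pcoa_embedding"
  )
}

#' @export
autoplot.pcoa_embedding <- function(object, colour = NULL, ...) {
  df <- object$coordinates
  if (!is.null(colour)) df$.colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$Axis1, y = .data$Axis2)) +
    ggplot2::labs(
      x = sprintf("PCoA 1 (%.1f%%)", object$percent_explained[1]),
      y = sprintf("PCoA 2 (%.1f%%)", object$percent_explained[2])
    ) +
    ggplot2::theme_minimal()
  if (is.null(colour)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$.colour)) +
    ggplot2::labs(colour = "group")
}

#' Permutational multivariate ANOVA (PERMANOVA)
#'
#' Pseudo-F test of group differences on a distance matrix, with the
#' permutation p-value `(1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`. Backed
#' by [vegan::adonis2()] with seeded label permutations.
#'
#' @param D A square symmetric distance matrix.
#' @param labels Group label per sample (`>= 2` non-empty groups).
#' @param n_perm Number of permutations (default 999).
#' @param seed Seed for the permutations.
#' @return A one-row tibble: `pseudo_f`, `r_squared`, `df_between`,
#'   `df_within`, `p_value`, `n_perm`.
#' @export
permanova_test <- function(D, labels, n_perm = 999, seed = 1) {
  D <- .validate_dist(D)
  labels <- factor(labels)
  if (length(labels) != nrow(D)) .stopf("labels must match matrix dimension")
  if (nlevels(droplevels(labels)) < 2) .stopf("need >= 2 groups")
  df <- data.frame(group = droplevels(labels))
  set.seed(seed)
  fit <- vegan::adonis2(stats::as.dist(D) ~ group, data = df,
                        permutations = n_perm)
  tibble::tibble(
    pseudo_f = fit$F[1],
    r_squared = fit$R2[1],
    df_between = fit$Df[1],
    df_within = fit$Df[2],
    p_value = fit$`Pr(>F)`[1],
    n_perm = n_perm
  )
}
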