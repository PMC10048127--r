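#' Run the full filtering-clustering-reporting pipeline
#'
#' End-to-end orchestration: read the feature table and metadata, apply the
#' two-stage feature filter (low-abundance/low-prevalence, then low spread),
#' assemble complete mother-child dyads on relative-abundance covariates,
#' run the alternating GLMM-LASSO / trajectory k-means clustering, and write
#' the post-clustering outputs. Every output directory carries the
#' configuration (including the master seed and a content hash) so a run is
#' reproducible from its emitted config alone.
#'
#' Outputs written to `out_dir`: `filtered_features.tsv`,
#' `removal_report.tsv`, `labels.tsv` (`dyad_id<TAB>cluster`),
#' `cluster_coefficients.json`, `iteration_log.tsv`, `caries_summary.tsv`,
#' `diversity.tsv` (per-sample Shannon), `permanova.json` (Bray-Curtis
#' distances vs. cluster labels), and `config.json`.
#'
#' @param features_path Feature table file (TSV/CSV; counts).
#' @param metadata_path Metadata CSV with columns
#'   `sample_id,dyad_id,role,outcome` (+ optional factor columns).
#' @param out_dir Output directory (created if needed).
#' @param orientation Feature-table orientation (see [read_feature_table()]).
#' @param delimiter Feature-table delimiter override.
#' @param k Number of clusters (default 3).
#' @param seed Master seed (default 1).
#' @param min_count,min_prevalence Abundance filter (see
#'   [filter_low_abundance()]).
#' @param drop_variance_fraction Spread filter (see [filter_low_variance()]).
#' @param covariate_scale Covariate scale fed to the model (see
#'   [assemble_dyads()]).
#' @param probability_mode,max_iter,n_lambda,restarts Clustering controls
#'   (see [run_alternating()]).
#' @param strict Error (rather than drop) on incomplete dyads.
#' @return Invisibly, a list with the `result` (`dyad_clusters`), the
#'   `summary` tibble, the `permanova` tibble, and the output `paths`.
#' @export
run_pipeline <- function(features_path, metadata_path, out_dir,
                         orientation = "samples-rows", delimiter = NULL,
                         k = 3, seed = 1, min_count = 4, min_prevalence = 0.2,
                         drop_variance_fraction = 0.10,
                         covariate_scale = "proportions",
                         probability_mode = "marginal", max_iter = 50,
                         n_lambda = 25, restarts = 10, strict = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  table <- read_feature_table(features_path, delimiter = delimiter,
                              orientation = orientation)
  metadata <- tryCatch(
    tibble::as_tibble(utils::read.csv(metadata_path)),
    error = function(e) .stopf("cannot read metadata %s: %s", metadata_path,
                               conditionMessage(e))
  )
  table <- filter_low_abundance(table, min_count = min_count,
                                min_prevalence = min_prevalence)
  table <- filter_low_variance(table, drop_fraction = drop_variance_fraction)
  data <- assemble_dyads(table, metadata, strict = strict,
                         covariate_scale = covariate_scale)
  result <- run_alternating(data, k = k, seed = seed, max_iter = max_iter,
                            restarts = restarts, n_lambda = n_lambda,
                            probability_mode = probability_mode)

  summary <- summarize_clusters(dyad_outcomes(data, result))
  shannon <- shannon_table(table)
  D <- bray_curtis_matrix(table[match(data$sample_id, table$sample_id), ])
  sample_cluster <- result$labels$cluster[match(data$dyad_id,
                                                result$labels$dyad_id)]
  perma <- if (length(unique(sample_cluster)) >= 2) {
    permanova_test(D, sample_cluster, n_perm = 999, seed = seed)
  } else {
    tibble::tibble(pseudo_f = NA_real_, r_squared = NA_real_,
                   df_between = NA_integer_, df_within = NA_integer_,
                   p_value = NA_real_, n_perm = 0L)
  }

  paths <- list(
    filtered_features = file.path(out_dir, "filtered_features.tsv"),
    removal_report = file.path(out_dir, "removal_report.tsv"),
    labels = file.path(out_dir, "labels.tsv"),
    coefficients = file.path(out_dir, "cluster_coefficients.json"),
    iteration_log = file.path(out_dir, "iteration_log.tsv"),
    summary = file.path(out_dir, "caries_summary.tsv"),
    diversity = file.path(out_dir, "diversity.tsv"),
    permanova = file.path(out_dir, "permanova.json"),
    config = file.path(out_dir, "config.json")
  )
  write_feature_table(table, paths$filtered_features)
  utils::write.table(as.data.frame(removal_report(table)),
                     paths$removal_report, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_labels(result, paths$labels)
  coef_json <- lapply(result$fits, function(f) {
    if (is.null(f)) NULL else jsonlite::fromJSON(glmm_to_json(f))
  })
  jsonlite::write_json(coef_json, paths$coefficients, auto_unbox = TRUE,
                       digits = NA, null = "null")
  utils::write.table(as.data.frame(result$iteration_log),
                     paths$iteration_log, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(summary), paths$summary, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(shannon), paths$diversity, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(perma), paths$permanova, auto_unbox = TRUE,
                       digits = NA)

  config <- list(
    features_path = features_path, metadata_path = metadata_path,
    orientation = orientation, k = k, seed = seed, min_count = min_count,
    min_prevalence = min_prevalence,
    drop_variance_fraction = drop_variance_fraction,
    covariate_scale = covariate_scale, probability_mode = probability_mode,
    max_iter = max_iter, n_lambda = n_lambda, restarts = restarts,
    strict = strict
  )
  config$config_hash <- rlang::hash(config)
  jsonlite::write_json(config, paths$config, auto_unbox = TRUE, digits = NA)

  invisible(list(result = result, summary = summary, permanova = perma,
                 paths = paths))
}
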