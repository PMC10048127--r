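#' Configuration for the synthetic dyad generator
#'
#' Describes a mixture of sparse logistic random-intercept models over
#' mother-child dyads with correlated covariates. Two presets are bundled:
#'
#' * `"strong-separation"`: 3 balanced clusters of 60 dyads, 9 gaussian
#'   covariates, disjoint 3-feature supports with slopes of magnitude 3
#'   (alternating sign), `sigma_b = 0.5`. Cluster-mean shifts of 0.15 and
#'   role contrasts of (0, +2.2/9, -2.2/9) on each cluster's own support,
#'   with intercepts (-3.55, -1.35, -1.35), place the three cluster centers
#'   at the corners of probability space: a low-low cluster near
#'   (0.10, 0.10), a high-low cluster near (0.90, 0.10), and a low-high
#'   cluster near (0.10, 0.90) --- mirroring the typical / high-low /
#'   low-high caries patterns the method targets. Pairwise center distances
#'   of at least 0.8 leave a wide margin over the within-cluster spread of
#'   fitted probabilities, including the extra spread an occasional
#'   AIC-admitted spurious feature adds through its unpenalized refit ---
#'   the regime the recovery benchmarks require.
#' * `"paper-scale"`: cluster sizes 122/39/14, 184 compositional
#'   (log-normal, row-normalized) features, supports of sizes 1/14/4,
#'   `sigma_b = 1` --- the dimensions of the motivating caries study, used
#'   to exercise the method at realistic scale (its small third cluster
#'   makes reliable recovery impossible by design).
#'
#' @param preset `"strong-separation"`, `"paper-scale"`, or `"custom"`.
#' @param k Number of clusters.
#' @param dyads_per_cluster Integer vector of cluster sizes (length `k`).
#' @param p Number of covariate features.
#' @param support_size Per-cluster number of nonzero slopes (length `k`);
#'   supports are disjoint consecutive blocks.
#' @param effect_size Magnitude of nonzero slopes (signs alternate +,-,+,...).
#' @param intercepts Per-cluster intercepts on the logit scale (length `k`).
#' @param sigma_b Random-intercept SD shared by all clusters.
#' @param within_dyad_corr Correlation `rho` between mother and child latent
#'   covariate vectors; the child vector is
#'   `mu + rho * (mother - mu) + sqrt(1 - rho^2) * noise`, so `rho = 1`
#'   duplicates the mother exactly.
#' @param covariate_model `"gaussian"` (latent vectors used directly) or
#'   `"lognormal-proportions"` (exponentiated with feature-specific means
#'   and row-normalized, mimicking compositional OTU relative abundances).
#' @param cluster_shift Mean shift applied to each cluster's own support
#'   features (sign-matched to its slopes).
#' @param role_contrast Per-cluster scalar (length `k`): the mother's latent
#'   mean on the cluster's own support is shifted by `+role_contrast`
#'   (sign-matched) and the child's by `-role_contrast`, emulating taxa
#'   systematically enriched in mothers versus children. This is what
#'   separates "high-low" from "low-high" caries patterns under a shared
#'   coefficient vector.
#' @param within_sd Within-cluster SD of the latent covariates.
#' @param log_sd Log-scale SD for `"lognormal-proportions"` (default 2,
#'   giving the heavy-tailed abundance skew typical of OTU tables).
#' @param seed Integer seed; generation is deterministic given the config.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(preset = c("strong-separation", "paper-scale",
                                        "custom"),
                             k = NULL, dyads_per_cluster = NULL, p = NULL,
                             support_size = NULL, effect_size = NULL,
                             intercepts = NULL, sigma_b = NULL,
                             within_dyad_corr = NULL, covariate_model = NULL,
                             cluster_shift = NULL, role_contrast = NULL,
                             within_sd = NULL, log_sd = NULL, seed = 1) {
  preset <- match.arg(preset)
  base <- switch(preset,
    "strong-separation" = list(
      k = 3, dyads_per_cluster = c(60, 60, 60), p = 9,
      support_size = c(3, 3, 3), effect_size = 3,
      intercepts = c(-3.55, -1.35, -1.35), sigma_b = 0.5,
      within_dyad_corr = 0.25, covariate_model = "gaussian",
      cluster_shift = 0.15, role_contrast = c(0, 2.2, -2.2) / 9,
      within_sd = 0.05, log_sd = 2
    ),
    "paper-scale" = list(
      k = 3, dyads_per_cluster = c(122, 39, 14), p = 184,
      support_size = c(1, 14, 4), effect_size = 5,
      intercepts = c(1.2, 1.0, 0.8), sigma_b = 1,
      within_dyad_corr = 0.5, covariate_model = "lognormal-proportions",
      cluster_shift = 0.5, role_contrast = c(0, 0.3, -0.3),
      within_sd = 1, log_sd = 2
    ),
    "custom" = list(
      k = 1, dyads_per_cluster = 100, p = 10, support_size = 2,
      effect_size = 1, intercepts = 0, sigma_b = 0.5,
      within_dyad_corr = 0.5, covariate_model = "gaussian",
      cluster_shift = 0, role_contrast = 0, within_sd = 1, log_sd = 2
    )
  )
  supplied <- list(k = k, dyads_per_cluster = dyads_per_cluster, p = p,
                   support_size = support_size, effect_size = effect_size,
                   intercepts = intercepts, sigma_b = sigma_b,
                   within_dyad_corr = within_dyad_corr,
                   covariate_model = covariate_model,
                   cluster_shift = cluster_shift,
                   role_contrast = role_contrast, within_sd = within_sd,
                   log_sd = log_sd)
  for (nm in names(supplied)) {
    if (!is.null(supplied[[nm]])) base[[nm]] <- supplied[[nm]]
  }
  cfg <- base
  cfg$seed <- as.integer(seed)
  cfg$dyads_per_cluster <- rep_len(cfg$dyads_per_cluster, cfg$k)
  cfg$support_size <- rep_len(cfg$support_size, cfg$k)
  cfg$intercepts <- rep_len(cfg$intercepts, cfg$k)
  cfg$role_contrast <- rep_len(cfg$role_contrast, cfg$k)
  cfg$covariate_model <- match.arg(cfg$covariate_model,
                                   c("gaussian", "lognormal-proportions"))
  if (any(cfg$dyads_per_cluster < 1) || cfg$p < 1) {
    .stopf("cluster sizes and p must be positive")
  }
  if (any(cfg$support_size > cfg$p)) .stopf("support_size exceeds p")
  if (sum(cfg$support_size) > cfg$p) {
    .stopf("disjoint supports require sum(support_size) <= p")
  }
  if (cfg$within_dyad_corr < 0 || cfg$within_dyad_corr > 1) {
    .stopf("within_dyad_corr must lie in [0, 1]")
  }
  if (cfg$sigma_b < 0) .stopf("sigma_b must be >= 0")
  structure(cfg, class = "synthetic_config")
}

#' Generate synthetic dyad data with known truth
#'
#' Draws, per dyad: a cluster label; a latent mother covariate vector (the
#' cluster's mean plus gaussian noise) and a `rho`-correlated child copy;
#' optionally a compositional transform (exponentiate with feature-specific
#' log-means, normalize rows to 1); a shared random intercept
#' `b_i ~ N(0, sigma_b^2)`; and each member's binary outcome from
#' `Bernoulli(plogis(beta0_c + x' beta_c + b_i))`. Deterministic given the
#' config's seed.
#'
#' @param config A [synthetic_config()].
#' @return A list: `data`, a `dyad_data` tibble ready for the model, and
#'   `truth`, holding per-dyad generating labels and random intercepts, the
#'   per-cluster coefficient vectors (`beta`, a p-by-k matrix), intercepts,
#'   `sigma_b`, and support indices.
#' @export
generate_dyads <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, config)
  }
  set.seed(config$seed)
  k <- config$k
  p <- config$p
  n <- sum(config$dyads_per_cluster)
  labels <- rep(seq_len(k), config$dyads_per_cluster)
  rho <- config$within_dyad_corr

  offsets <- cumsum(c(0, config$support_size))[seq_len(k)]
  supports <- lapply(seq_len(k), function(c) {
    if (config$support_size[c] == 0) integer(0)
    else offsets[c] + seq_len(config$support_size[c])
  })
  beta <- matrix(0, p, k)
  mu <- matrix(0, p, k)  # cluster-specific latent means
  nu <- matrix(0, p, k)  # mother-vs-child contrast (mother +nu, child -nu)
  for (c in seq_len(k)) {
    s <- supports[[c]]
    if (length(s) > 0) {
      signs <- rep_len(c(1, -1), length(s))
      beta[s, c] <- config$effect_size * signs
      mu[s, c] <- config$cluster_shift * signs
      nu[s, c] <- config$role_contrast[c] * signs
    }
  }
  feat <- sprintf("otu%03d", seq_len(p))
  rownames(beta) <- rownames(mu) <- rownames(nu) <- feat
  log_mu <- stats::rnorm(p) # feature-specific log-abundance means

  dyad_id <- sprintf("dyad%03d", seq_len(n))
  b_i <- stats::rnorm(n, 0, config$sigma_b)
  mean_m <- t(mu[, labels]) + t(nu[, labels])
  mean_c <- t(mu[, labels]) - t(nu[, labels])
  Zm <- mean_m + matrix(stats::rnorm(n * p, sd = config$within_sd), n, p)
  Zc <- mean_c + rho * (Zm - mean_m) +
    sqrt(1 - rho^2) * matrix(stats::rnorm(n * p, sd = config$within_sd), n, p)
  latent_to_x <- function(Z) {
    if (config$covariate_model == "gaussian") return(Z)
    W <- exp(sweep(config$log_sd * Z, 2, log_mu, "+"))
    W / rowSums(W)
  }
  Xm <- latent_to_x(Zm)
  Xc <- latent_to_x(Zc)
  colnames(Xm) <- colnames(Xc) <- feat

  eta_m <- config$intercepts[labels] +
    rowSums(Xm * t(beta[, labels, drop = FALSE])) + b_i
  eta_c <- config$intercepts[labels] +
    rowSums(Xc * t(beta[, labels, drop = FALSE])) + b_i
  y_m <- stats::rbinom(n, 1, stats::plogis(eta_m))
  y_c <- stats::rbinom(n, 1, stats::plogis(eta_c))

  rows <- tibble::tibble(
    sample_id = c(rbind(paste0(dyad_id, "_m"), paste0(dyad_id, "_c"))),
    dyad_id = rep(dyad_id, each = 2),
    role = factor(rep(c("mother", "child"), n), levels = c("mother", "child")),
    outcome = as.integer(c(rbind(y_m, y_c)))
  )
  Xall <- matrix(0, 2 * n, p, dimnames = list(NULL, feat))
  Xall[seq(1, 2 * n, by = 2), ] <- Xm
  Xall[seq(2, 2 * n, by = 2), ] <- Xc
  data <- tibble::new_tibble(
    dplyr::bind_cols(rows, tibble::as_tibble(Xall, .name_repair = "minimal")),
    feature_names = feat, factor_names = character(),
    class = "dyad_data"
  )
  truth <- list(
    labels = tibble::tibble(dyad_id = dyad_id, cluster = labels),
    beta = beta, intercepts = config$intercepts, sigma_b = config$sigma_b,
    supports = supports,
    b = tibble::tibble(dyad_id = dyad_id, b = b_i),
    config = config
  )
  list(data = data, truth = truth)
}

#' Export generated dyads as the pipeline's on-disk formats
#'
#' Writes the feature table (TSV, samples in rows) and the metadata CSV that
#' [read_feature_table()] and [run_pipeline()] consume, so the end-to-end
#' command-line path can be exercised on generated data. Proportion-valued
#' covariates can be rescaled to integer counts by a fixed sequencing depth,
#' which is what a real OTU table would contain.
#'
#' @param data A `dyad_data` tibble from [generate_dyads()].
#' @param dir Output directory (created if needed).
#' @param as_counts Convert covariates to integer pseudo-counts
#'   (default `TRUE`).
#' @param depth Total count per sample used for the conversion.
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_dyad_tables <- function(data, dir, as_counts = TRUE, depth = 50000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  feats <- dyad_feature_names(data)
  M <- as.matrix(data[, feats, drop = FALSE])
  if (as_counts) {
    rs <- rowSums(M)
    rs[rs <= 0] <- 1
    M <- round(M / rs * depth)
  }
  rownames(M) <- data$sample_id
  ft_path <- file.path(dir, "features.tsv")
  utils::write.table(
    data.frame(sample_id = rownames(M), M, check.names = FALSE),
    ft_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  md_path <- file.path(dir, "metadata.csv")
  meta_cols <- intersect(c("sample_id", "dyad_id", "role", "outcome",
                           attr(data, "factor_names")), names(data))
  utils::write.csv(as.data.frame(data[, meta_cols]), md_path,
                   row.names = FALSE, quote = FALSE)
  invisible(c(features = ft_path, metadata = md_path))
}
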