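#' Initialize cluster labels from covariates
#'
#' K-means on one vector per dyad formed from the standardized mother and
#' child covariate rows --- concatenated by default (averaging available),
#' treating each dyad as a single observation. The outcome variable is not
#' used. The best of `restarts` seeded restarts by within-cluster sum of
#' squares is kept.
#'
#' @param data A `dyad_data` tibble.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param restarts Number of k-means restarts (default 10).
#' @param combine `"concatenate"` (default) or `"average"` the two member
#'   rows.
#' @return Integer labels in `1..k`, one per dyad, named by dyad id.
#' @export
initialize_labels <- function(data, k, seed = 1, restarts = 10,
                              combine = c("concatenate", "average")) {
  combine <- match.arg(combine)
  md <- .dyad_matrices(data)
  n <- nrow(md$Y2)
  if (k > n) .stopf("k (%d) exceeds the number of dyads (%d)", k, n)
  Xm <- md$X[md$E[, 1], , drop = FALSE]
  Xc <- md$X[md$E[, 2], , drop = FALSE]
  Z <- if (combine == "concatenate") cbind(Xm, Xc) else (Xm + Xc) / 2
  Z <- .standardize(Z)$X
  if (k == 1) return(stats::setNames(rep(1L, n), md$dyad_ids))
  set.seed(seed)
  km <- stats::kmeans(Z, centers = k, nstart = restarts, iter.max = 100)
  stats::setNames(as.integer(km$cluster), md$dyad_ids)
}

#' Euclidean k-means on dyad probability trajectories
#'
#' Lloyd's algorithm on each dyad's `(p_mother, p_child)` pair --- the
#' two-point response trajectory --- with squared Euclidean distance.
#' Assignment ties go to the lowest cluster index; an emptied cluster is
#' reseeded at the point farthest from its assigned center; the best of
#' `restarts` seeded restarts by inertia is kept.
#'
#' @param points An `n x 2` matrix or a tibble with `p_mother`/`p_child`
#'   columns; all values must lie in `[0, 1]`.
#' @param k Number of clusters (`k <= n`).
#' @param seed Integer seed.
#' @param restarts Number of restarts (default 10).
#' @param max_iter Lloyd iteration cap per restart (default 100).
#' @return Integer labels in `1..k` with attribute `inertia`.
#' @export
kmeans_trajectories <- function(points, k, seed = 1, restarts = 10,
                                max_iter = 100) {
  if (is.data.frame(points)) {
    points <- as.matrix(points[, c("p_mother", "p_child")])
  }
  if (!is.matrix(points) || ncol(points) != 2) .stopf("points must be n x 2")
  .assert_prob_range(points, "points")
  n <- nrow(points)
  if (k > n) .stopf("k (%d) exceeds the number of points (%d)", k, n)
  set.seed(seed)
  best_labels <- NULL
  best_inertia <- Inf
  for (r in seq_len(restarts)) {
    centers <- points[sample.int(n, k), , drop = FALSE]
    labels <- rep(1L, n)
    for (it in seq_len(max_iter)) {
      d2 <- outer(points[, 1], centers[, 1], "-")^2 +
        outer(points[, 2], centers[, 2], "-")^2
      new_labels <- max.col(-d2, ties.method = "first")
      # empty-cluster repair: reseed at the point farthest from its center
      for (rep_try in seq_len(k)) {
        empty <- setdiff(seq_len(k), unique(new_labels))
        if (length(empty) == 0) break
        dist_own <- d2[cbind(seq_len(n), new_labels)]
        far <- which.max(dist_own)
        centers[empty[1], ] <- points[far, ]
        d2[, empty[1]] <- (points[, 1] - centers[empty[1], 1])^2 +
          (points[, 2] - centers[empty[1], 2])^2
        new_labels <- max.col(-d2, ties.method = "first")
      }
      changed <- !identical(new_labels, labels)
      labels <- new_labels
      for (j in seq_len(k)) {
        centers[j, ] <- colMeans(points[labels == j, , drop = FALSE])
      }
      if (!changed && it > 1) break
    }
    d2 <- outer(points[, 1], centers[, 1], "-")^2 +
      outer(points[, 2], centers[, 2], "-")^2
    inertia <- sum(d2[cbind(seq_len(n), labels)])
    if (inertia < best_inertia - 1e-12) {
      best_inertia <- inertia
      best_labels <- labels
    }
  }
  structure(best_labels, inertia = best_inertia)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement under the permutation model: 1 for identical
#' partitions, around 0 for independent ones.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) .stopf("label lengths differ")
  tab <- table(labels_a, labels_b)
  n <- length(labels_a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

# greedily relabel `new` so its clusters maximally overlap `old`
# (fresh k-means permutes ids arbitrarily; convergence is a statement about
# the partition, so we compare in a matched labeling)
.match_labels <- function(new, old, k) {
  tab <- matrix(0, k, k)
  for (i in seq_along(new)) tab[new[i], old[i]] <- tab[new[i], old[i]] + 1
  map <- rep(NA_integer_, k)
  used <- logical(k)
  for (step in seq_len(k)) {
    idx <- which(tab == max(tab), arr.ind = TRUE)[1, ]
    map[idx[1]] <- idx[2]
    tab[idx[1], ] <- -1
    tab[, idx[2]] <- -1
    used[idx[2]] <- TRUE
  }
  map[is.na(map)] <- setdiff(seq_len(k), map[!is.na(map)])
  map[new]
}

#' Alternating GLMM-LASSO / trajectory k-means clustering
#'
#' The two-stage alternating algorithm. After covariate-based
#' initialization ([initialize_labels()]), each outer iteration (1) fits,
#' within every cluster, an L1-penalized logistic random-intercept model
#' with its penalty chosen by AIC ([select_lambda()]), re-estimates the
#' selected coefficients without penalty ([refit_unpenalized()]), and
#' predicts each member's caries probability from the refit
#' ([predict_probabilities()]); then (2) re-groups all dyads by Euclidean
#' k-means on their `(p_mother, p_child)` pairs
#' ([kmeans_trajectories()]). The loop stops when cluster membership is
#' unchanged between consecutive iterations (`converged = TRUE`), when a
#' previously visited membership recurs (a cycle; the visited state with the
#' smallest AIC sum is returned with `converged = FALSE`), or at `max_iter`.
#'
#' Clusters smaller than `min_cluster_dyads`, with constant outcomes, or
#' whose fit fails are handled by the separation-safe intercept-only
#' fallback instead of aborting the run. All randomness flows from `seed`:
#' the initialization uses `seed` itself and the trajectory k-means at outer
#' iteration `i` uses `seed + i`.
#'
#' @param data A `dyad_data` tibble.
#' @param k Number of clusters (default 3).
#' @param seed Master seed (default 1).
#' @param max_iter Outer iteration cap (default 50).
#' @param restarts K-means restarts for both stages (default 10).
#' @param probability_mode `"marginal"` (default) or `"conditional"` dyad
#'   probabilities fed to the k-means stage.
#' @param min_cluster_dyads Clusters below this size get the fallback fit
#'   (default 3).
#' @param n_lambda,lambda_min_ratio Penalty grid controls (see
#'   [select_lambda()]).
#' @param nodes Gauss-Hermite nodes.
#' @param init_combine Dyad representation for initialization (see
#'   [initialize_labels()]).
#' @param init Optional explicit initial labels (integer vector per dyad),
#'   bypassing [initialize_labels()].
#' @param verbose Print one line per outer iteration.
#' @return A `dyad_clusters` object: `labels` tibble (`dyad_id`,
#'   `cluster`), per-cluster `fits` (unpenalized refits), `penalized_fits`,
#'   `probabilities` tibble, `n_iterations`, `converged`, `cycle`,
#'   `label_history`, and an `iteration_log` tibble (cluster sizes, chosen
#'   penalties, AIC sum, labels changed).
#' @export
run_alternating <- function(data, k = 3, seed = 1, max_iter = 50,
                            restarts = 10,
                            probability_mode = c("marginal", "conditional"),
                            min_cluster_dyads = 3, n_lambda = 25,
                            lambda_min_ratio = 1e-3, nodes = 15,
                            init_combine = "concatenate", init = NULL,
                            verbose = FALSE) {
  probability_mode <- match.arg(probability_mode)
  if (k < 1 || max_iter < 1) .stopf("k and max_iter must be >= 1")
  md <- .dyad_matrices(data)
  nd <- nrow(md$Y2)
  dyad_ids <- md$dyad_ids
  labels <- if (is.null(init)) {
    as.integer(initialize_labels(data, k, seed = seed, restarts = restarts,
                                 combine = init_combine))
  } else {
    as.integer(init)
  }
  if (length(labels) != nd) .stopf("init labels must have one entry per dyad")

  seen <- new.env(parent = emptyenv())
  seen[[paste(labels, collapse = ",")]] <- 0L
  history <- list(labels)
  states <- list()
  log_rows <- list()
  converged <- FALSE
  cycle <- FALSE
  n_iter <- 0

  fit_cluster <- function(rows_idx) {
    sub <- data[rows_idx, , drop = FALSE]
    sub <- tibble::new_tibble(sub, feature_names = dyad_feature_names(data),
                              factor_names = attr(data, "factor_names"),
                              class = "dyad_data")
    smd <- .dyad_matrices(sub)
    if (nrow(smd$Y2) < max(min_cluster_dyads, 2) ||
        length(unique(smd$y)) == 1) {
      fb <- .fallback_fit(smd, dyad_feature_names(data), "small-or-degenerate")
      return(list(pen = fb, refit = fb, lambda = NA_real_, sub = sub))
    }
    tryCatch({
      path <- select_lambda(sub, n_lambda = n_lambda,
                            lambda_min_ratio = lambda_min_ratio,
                            nodes = nodes)
      refit <- refit_unpenalized(sub, path$best_fit$support, nodes = nodes,
                                 se = FALSE)
      list(pen = path$best_fit, refit = refit,
           lambda = path$chosen_lambda, sub = sub)
    }, error = function(e) {
      warning(sprintf("cluster fit failed (%s); using fallback",
                      conditionMessage(e)), call. = FALSE)
      fb <- .fallback_fit(smd, dyad_feature_names(data), "fit-error")
      list(pen = fb, refit = fb, lambda = NA_real_, sub = sub)
    })
  }

  for (it in seq_len(max_iter)) {
    n_iter <- it
    fits <- vector("list", k)
    pen_fits <- vector("list", k)
    lambdas <- rep(NA_real_, k)
    probs <- matrix(NA_real_, nd, 2)
    for (c in seq_len(k)) {
      dy <- which(labels == c)
      if (length(dy) == 0) next
      rows_idx <- sort(c(md$E[dy, 1], md$E[dy, 2]))
      res <- fit_cluster(rows_idx)
      fits[[c]] <- res$refit
      pen_fits[[c]] <- res$pen
      lambdas[c] <- res$lambda
      pr <- predict_probabilities(res$sub, res$refit, mode = probability_mode)
      probs[match(pr$dyad_id, dyad_ids), ] <- cbind(pr$p_mother, pr$p_child)
    }
    aic_sum <- sum(vapply(Filter(Negate(is.null), pen_fits), compute_aic,
                          double(1)))
    new_labels <- as.integer(kmeans_trajectories(probs, k, seed = seed + it,
                                                 restarts = restarts))
    new_labels <- .match_labels(new_labels, labels, k)
    n_changed <- sum(new_labels != labels)
    log_rows[[it]] <- tibble::tibble(
      iteration = it,
      sizes = paste(tabulate(labels, k), collapse = "/"),
      lambdas = paste(signif(lambdas, 3), collapse = "/"),
      aic_sum = aic_sum,
      n_changed = n_changed
    )
    states[[it]] <- list(labels = labels, fits = fits, pen_fits = pen_fits,
                         probs = probs, aic_sum = aic_sum)
    if (verbose) {
      message(sprintf("iter %d: sizes %s, AIC sum %.2f, %d changed",
                      it, log_rows[[it]]$sizes, aic_sum, n_changed))
    }
    if (n_changed == 0) {
      converged <- TRUE
      break
    }
    key <- paste(new_labels, collapse = ",")
    history[[length(history) + 1]] <- new_labels
    if (!is.null(seen[[key]])) {
      cycle <- TRUE
      labels <- new_labels
      break
    }
    seen[[key]] <- it
    labels <- new_labels
  }

  final <- states[[n_iter]]
  if (cycle) {
    best <- which.min(vapply(states, function(s) s$aic_sum, double(1)))
    final <- states[[best]]
  }
  structure(
    list(
      labels = tibble::tibble(dyad_id = dyad_ids,
                              cluster = final$labels),
      fits = final$fits,
      penalized_fits = final$pen_fits,
      probabilities = tibble::tibble(
        dyad_id = dyad_ids, cluster = final$labels,
        p_mother = final$probs[, 1], p_child = final$probs[, 2],
        mode = probability_mode
      ),
      n_iterations = n_iter,
      converged = converged,
      cycle = cycle,
      label_history = history,
      iteration_log = dplyr::bind_rows(log_rows),
      config = list(k = k, seed = seed, max_iter = max_iter,
                    restarts = restarts, probability_mode = probability_mode,
                    min_cluster_dyads = min_cluster_dyads,
                    n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
                    nodes = nodes, init_combine = init_combine)
    ),
    class = "dyad_clusters"
  )
}

#' @rdname run_alternating
#' @param ... Passed to [run_alternating()].
#' @export
cluster_dyads <- function(data, k = 3, ...) run_alternating(data, k = k, ...)

#' @export
print.dyad_clusters <- function(x, ...) {
  cat(sprintf("Alternating GLMM-LASSO clustering: k = %d, %d dyads\n",
              x$config$k, nrow(x$labels)))
  cat(sprintf("  %d iteration(s), converged: %s%s\n", x$n_iterations,
              x$converged, if (x$cycle) " (cycle detected)" else ""))
  cat("  cluster sizes: ",
      paste(tabulate(x$labels$cluster, x$config$k), collapse = "/"), "\n")
  invisible(x)
}

#' Tidy a clustering result
#'
#' @param x A `dyad_clusters` object.
#' @param ... Unused.
#' @return One row per dyad: label and predicted probability pair.
#' @export
tidy.dyad_clusters <- function(x, ...) x$probabilities

#' @rdname tidy.dyad_clusters
#' @export
glance.dyad_clusters <- function(x, ...) {
  tibble::tibble(
    k = x$config$k,
    n_dyads = nrow(x$labels),
    n_iterations = x$n_iterations,
    converged = x$converged,
    cycle = x$cycle,
    aic_sum = x$iteration_log$aic_sum[nrow(x$iteration_log)]
  )
}

#' Plot dyad probability pairs colored by cluster
#'
#' @param object A `dyad_clusters` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dyad_clusters <- function(object, ...) {
  ggplot2::ggplot(object$probabilities,
                  ggplot2::aes(x = .data$p_mother, y = .data$p_child,
                               colour = factor(.data$cluster))) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "P(caries), mother", y = "P(caries), child",
                  colour = "cluster") +
    ggplot2::theme_minimal()
}

#' Write cluster labels as TSV
#'
#' @param result A `dyad_clusters` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(result, path) {
  utils::write.table(as.data.frame(result$labels), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
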