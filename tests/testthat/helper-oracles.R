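# Independent oracles and small fixture builders shared across tests.

# Build a dyad_data tibble directly from matrices: X has 2 rows per dyad
# (mother then child), y likewise.
make_dyad_data <- function(X, y) {
  n <- nrow(X) / 2
  stopifnot(n == floor(n), length(y) == nrow(X))
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  dyad_id <- sprintf("d%03d", rep(seq_len(n), each = 2))
  df <- dplyr::bind_cols(
    tibble::tibble(
      sample_id = paste0(dyad_id, c("_m", "_c")),
      dyad_id = dyad_id,
      role = factor(rep(c("mother", "child"), n),
                    levels = c("mother", "child")),
      outcome = as.integer(y)
    ),
    tibble::as_tibble(X, .name_repair = "minimal")
  )
  tibble::new_tibble(df, feature_names = colnames(X),
                     factor_names = character(), class = "dyad_data")
}

# random small dyad dataset for likelihood checks
random_dyad_data <- function(n_dyads, p, seed, beta0 = 0, beta = numeric(p),
                             sigma_b = 0.5) {
  set.seed(seed)
  X <- matrix(stats::rnorm(2 * n_dyads * p), 2 * n_dyads, p)
  b <- rep(stats::rnorm(n_dyads, 0, sigma_b), each = 2)
  eta <- beta0 + as.numeric(X %*% beta) + b
  y <- stats::rbinom(2 * n_dyads, 1, stats::plogis(eta))
  make_dyad_data(X, y)
}

# Brute-force marginal log-likelihood by trapezoid quadrature on a dense grid
# over b in [-K*sigma, K*sigma]; the independent oracle for the AGQ path.
trapezoid_loglik <- function(data, beta0, beta, sigma_b, npts = 2001, K = 10) {
  feats <- dyad_feature_names(data)
  X <- as.matrix(data[, feats, drop = FALSE])
  eta <- beta0 + as.numeric(X %*% beta)
  y <- data$outcome
  ids <- unique(data$dyad_id)
  if (sigma_b < 1e-12) {
    mu <- stats::plogis(eta)
    return(sum(y * log(mu) + (1 - y) * log(1 - mu)))
  }
  bs <- seq(-K * sigma_b, K * sigma_b, length.out = npts)
  total <- 0
  for (id in ids) {
    rows <- which(data$dyad_id == id)
    f <- stats::dnorm(bs, 0, sigma_b)
    for (r in rows) {
      mu <- stats::plogis(eta[r] + bs)
      f <- f * (if (y[r] == 1) mu else 1 - mu)
    }
    total <- total + log(pracma::trapz(bs, f))
  }
  total
}

# Brute-force BH step-up: explicit minimum over suffixes.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Exhaustive best 2-cluster partition by k-means inertia (centroid = mean).
best_partition_inertia <- function(points, k = 2) {
  n <- nrow(points)
  best <- Inf
  best_lab <- NULL
  labs <- rep(1L, n)
  repeat {
    if (length(unique(labs)) == k) {
      inertia <- 0
      for (c in unique(labs)) {
        pts <- points[labs == c, , drop = FALSE]
        ctr <- colMeans(pts)
        inertia <- inertia + sum(sweep(pts, 2, ctr)^2)
      }
      if (inertia < best) {
        best <- inertia
        best_lab <- labs
      }
    }
    # increment base-k counter
    i <- n
    while (i >= 1) {
      if (labs[i] < k) {
        labs[i] <- labs[i] + 1L
        if (i < n) labs[(i + 1):n] <- 1L
        break
      }
      i <- i - 1
    }
    if (i == 0) break
  }
  list(labels = best_lab, inertia = best)
}

# empirical phi coefficient between the two members' outcomes
phi_coefficient <- function(y_m, y_c) {
  suppressWarnings(stats::cor(y_m, y_c))
}
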