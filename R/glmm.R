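## Logistic random-intercept likelihood core.
##
## The marginal likelihood integrates a shared per-dyad intercept b ~ N(0,
## sigma_b^2) out of a product of two Bernoulli terms (mother, child). The
## integral is evaluated by adaptive Gauss-Hermite quadrature: per dyad the
## integrand's mode and curvature are found by a few Newton steps (vectorized
## over dyads), the Gauss-Hermite grid is centered and scaled there, and the
## weighted sum is accumulated in log space. With 15 nodes the approximation
## is accurate to well below 1e-6 per dyad for sigma_b up to ~1.5, the
## regime of interest for caries dyads.

.gh_cache <- new.env(parent = emptyenv())

.gh_nodes <- function(nodes) {
  key <- as.character(nodes)
  if (is.null(.gh_cache[[key]])) {
    .gh_cache[[key]] <- statmod::gauss.quad(nodes, kind = "hermite")
  }
  .gh_cache[[key]]
}

# log(1 + exp(x)), overflow-safe and vectorized
.log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# Core AGQ evaluation. eta2, y2: n x 2 matrices (mother, child columns).
# Returns the total log-likelihood and, if want_resid, the posterior-weighted
# residuals E[y - mu(eta + b) | y] per member (used for the beta gradient)
# and the posterior modes bhat. Thin wrapper over the compiled kernel.
.agq_core <- function(eta2, y2, sigma, nodes = 15, want_resid = FALSE) {
  gh <- .gh_nodes(nodes)
  res <- agq_core_cpp(eta2, matrix(as.double(y2), nrow(eta2), 2), sigma,
                      gh$nodes, log(gh$weights) + gh$nodes^2, want_resid)
  list(ll = res$ll, bhat = as.numeric(res$bhat),
       resid2 = if (want_resid) res$resid2)
}

# pure-R reference implementation of the same kernel (kept for cross-checks)
.agq_core_r <- function(eta2, y2, sigma, nodes = 15, want_resid = FALSE) {
  n <- nrow(eta2)
  if (sigma < 1e-8) {
    # integral collapses: plain Bernoulli sum, log P(y|eta) = y*eta - log(1+e^eta)
    ll <- sum(y2 * eta2 - .log1pexp(eta2))
    return(list(ll = ll,
                resid2 = if (want_resid) y2 - stats::plogis(eta2),
                bhat = numeric(n)))
  }
  gh <- .gh_nodes(nodes)
  K <- length(gh$nodes)
  isig2 <- 1 / sigma^2
  b <- numeric(n)
  for (it in 1:25) { # Newton for the per-dyad integrand mode
    mu <- stats::plogis(eta2 + b)
    g <- (y2[, 1] - mu[, 1]) + (y2[, 2] - mu[, 2]) - b * isig2
    h <- mu[, 1] * (1 - mu[, 1]) + mu[, 2] * (1 - mu[, 2]) + isig2
    step <- g / h
    b <- b + step
    if (max(abs(step)) < 1e-10) break
  }
  mu <- stats::plogis(eta2 + b)
  shat <- 1 / sqrt(mu[, 1] * (1 - mu[, 1]) + mu[, 2] * (1 - mu[, 2]) + isig2)
  bk <- b + shat %o% (sqrt(2) * gh$nodes) # n x K quadrature abscissae
  e1 <- eta2[, 1] + bk
  e2 <- eta2[, 2] + bk
  lf <- y2[, 1] * e1 - .log1pexp(e1) + y2[, 2] * e2 - .log1pexp(e2)
  # + log phi(bk; 0, sigma) + GH constants, accumulated in log space
  lw <- lf - 0.5 * (bk * bk) * isig2 +
    rep(log(gh$weights) + gh$nodes^2, each = n)
  m0 <- lw[cbind(seq_len(n), max.col(lw))]
  sumw <- rowSums(exp(lw - m0))
  li <- m0 + log(sumw) + log(shat) + 0.5 * log(2) -
    log(sigma) - 0.5 * log(2 * pi)
  out <- list(ll = sum(li), bhat = b)
  if (want_resid) {
    w <- exp(lw - m0) / sumw # posterior node weights, rows sum to 1
    r2 <- cbind(y2[, 1] - rowSums(w * stats::plogis(e1)),
                y2[, 2] - rowSums(w * stats::plogis(e2)))
    out$resid2 <- r2
  }
  out
}

# scatter an n x 2 member matrix back to the 2n-row observation order
.to_obs <- function(M2, E) {
  v <- numeric(max(E))
  v[E[, 1]] <- M2[, 1]
  v[E[, 2]] <- M2[, 2]
  v
}

.eta2 <- function(md, beta0, beta) {
  eta <- as.numeric(beta0 + md$X %*% beta)
  cbind(eta[md$E[, 1]], eta[md$E[, 2]])
}

#' Marginal log-likelihood of a logistic random-intercept model
#'
#' Evaluates \eqn{\ell = \sum_i \log \int \prod_m \mathrm{Bern}(y_{im} \mid
#' \mathrm{logit}^{-1}(\beta_0 + x_{im}^\top\beta + b))\,\phi(b; 0,
#' \sigma_b^2)\,db} over dyads \eqn{i} and members \eqn{m}, by adaptive
#' Gauss-Hermite quadrature. When `sigma_b = 0` the integral collapses to
#' the ordinary Bernoulli log-likelihood.
#'
#' @param data A `dyad_data` tibble (see [assemble_dyads()]).
#' @param beta0 Intercept, logit scale.
#' @param beta Slope vector (length = number of features, original covariate
#'   scale), or a named vector covering a subset of features (others 0).
#' @param sigma_b Random-intercept standard deviation, `>= 0`.
#' @param nodes Number of Gauss-Hermite nodes (default 15).
#' @return The scalar log-likelihood.
#' @export
marginal_loglik <- function(data, beta0, beta, sigma_b, nodes = 15) {
  if (!all(is.finite(c(beta0, beta, sigma_b)))) .stopf("non-finite parameters")
  if (sigma_b < 0) .stopf("sigma_b must be >= 0")
  feats <- dyad_feature_names(data)
  if (!is.null(names(beta)) && !setequal(names(beta), feats)) {
    full <- stats::setNames(numeric(length(feats)), feats)
    full[names(beta)] <- beta
    beta <- full
  }
  if (length(beta) != length(feats)) {
    .stopf("beta has length %d but data has %d features",
           length(beta), length(feats))
  }
  md <- .dyad_matrices(data)
  .agq_core(.eta2(md, beta0, beta), md$Y2, sigma_b, nodes)$ll
}

## ---- penalized fitting -----------------------------------------------------

# negative marginal loglik and its gradient wrt (b0, bs) on standardized scale
.nll_grad <- function(theta, Xs, md, sigma, nodes) {
  b0 <- theta[1]
  bs <- theta[-1]
  eta <- as.numeric(b0 + Xs %*% bs)
  eta2 <- cbind(eta[md$E[, 1]], eta[md$E[, 2]])
  core <- .agq_core(eta2, md$Y2, sigma, nodes, want_resid = TRUE)
  r <- .to_obs(core$resid2, md$E)
  list(value = -core$ll, grad = c(-sum(r), as.numeric(-crossprod(Xs, r))))
}

.nll_value <- function(theta, Xs, md, sigma, nodes) {
  eta <- as.numeric(theta[1] + Xs %*% theta[-1])
  eta2 <- cbind(eta[md$E[, 1]], eta[md$E[, 2]])
  -.agq_core(eta2, md$Y2, sigma, nodes)$ll
}

.soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# Monotone FISTA on F(theta) = nll(theta) + lambda * sum(|theta[-1]|),
# intercept unpenalized. Backtracking line search on the quadratic
# majorization; momentum step only kept when it does not increase F.
.prox_descent <- function(theta, Xs, md, sigma, lambda, nodes,
                          tol, max_iter, t0 = 1) {
  pen <- function(th) lambda * sum(abs(th[-1]))
  g <- .nll_grad(theta, Xs, md, sigma, nodes)
  Fx <- g$value + pen(theta)
  x <- theta
  yv <- theta
  gy <- g
  tk <- 1
  tstep <- t0
  trace <- Fx
  for (it in seq_len(max_iter)) {
    repeat {
      z <- c(yv[1] - tstep * gy$grad[1],
             .soft(yv[-1] - tstep * gy$grad[-1], tstep * lambda))
      dz <- z - yv
      fz <- .nll_value(z, Xs, md, sigma, nodes)
      if (fz <= gy$value + sum(gy$grad * dz) + sum(dz^2) / (2 * tstep) + 1e-12) break
      tstep <- tstep / 2
      if (tstep < 1e-14) break
    }
    Fz <- fz + pen(z)
    if (Fz <= Fx) {
      x_new <- z
      F_new <- Fz
    } else {      # monotone safeguard: keep previous iterate
      x_new <- x
      F_new <- Fx
    }
    t_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
    yv <- x_new + (tk / t_next) * (z - x_new) +
      ((tk - 1) / t_next) * (x_new - x)
    step_size <- max(abs(x_new - x))
    x <- x_new
    Fx <- F_new
    trace <- c(trace, Fx)
    tk <- t_next
    tstep <- tstep * 1.5
    gy <- .nll_grad(yv, Xs, md, sigma, nodes)
    if (step_size < tol && it > 1) break
  }
  list(theta = x, objective = Fx, trace = trace, tstep = tstep)
}

.optimize_sigma <- function(theta, Xs, md, nodes, sigma = 0.5,
                            lower = 1e-6, upper = 8, narrow = TRUE) {
  f <- function(ls) .nll_value(theta, Xs, md, exp(ls), nodes)
  lo <- if (narrow) max(lower, sigma / 3) else lower
  hi <- if (narrow) min(upper, sigma * 3 + 0.1) else upper
  opt <- stats::optimize(f, interval = log(c(lo, hi)), tol = 1e-8)
  exp(opt$minimum)
}

# intercept-plus-variance model by alternating 1-D optimizations; this is
# both the lambda_max anchor and the warm start of every penalized fit
.null_model <- function(md, nodes) {
  n <- nrow(md$Y2)
  Y2 <- md$Y2
  beta0 <- stats::qlogis(min(max(mean(md$y), 1e-3), 1 - 1e-3))
  sigma <- 0.5
  for (round in 1:12) {
    ob <- stats::optimize(
      function(b0) -.agq_core(matrix(b0, n, 2), Y2, sigma, nodes)$ll,
      interval = c(beta0 - 4, beta0 + 4), tol = 1e-8)
    delta <- abs(ob$minimum - beta0)
    beta0 <- ob$minimum
    os <- stats::optimize(
      function(ls) -.agq_core(matrix(beta0, n, 2), Y2, exp(ls), nodes)$ll,
      interval = log(c(1e-6, 8)), tol = 1e-7)
    delta <- max(delta, abs(exp(os$minimum) - sigma))
    sigma <- exp(os$minimum)
    if (delta < 1e-8) break
  }
  list(beta0 = beta0, sigma = max(sigma, 1e-6))
}

.fallback_fit <- function(md, feats, reason, lambda = NA_real_) {
  y <- md$y
  rate <- (sum(y) + 0.5) / (length(y) + 1)
  beta0 <- stats::qlogis(rate)
  ll <- sum(y * log(rate) + (1 - y) * log(1 - rate))
  new_dyad_glmm(
    beta0 = beta0,
    beta = stats::setNames(numeric(length(feats)), feats),
    sigma_b = 0, loglik = ll, lambda = lambda,
    converged = TRUE, fallback = reason,
    scale_info = NULL, n_obs = length(y), n_dyads = nrow(md$Y2),
    objective_trace = -ll
  )
}

new_dyad_glmm <- function(beta0, beta, sigma_b, loglik, lambda, converged,
                          fallback = NULL, scale_info = NULL, se = NULL,
                          n_obs = NA_integer_, n_dyads = NA_integer_,
                          objective_trace = numeric(), penalized = !is.na(lambda)) {
  sigma_rep <- if (sigma_b < 1e-4) 0 else sigma_b
  support <- names(beta)[beta != 0]
  df <- length(support) + 1L + as.integer(sigma_rep > 0)
  structure(
    list(beta0 = beta0, beta = beta, sigma_b = sigma_rep,
         support = support, df = df, loglik = loglik, lambda = lambda,
         converged = converged, fallback = fallback, se = se,
         scale_info = scale_info, n_obs = n_obs, n_dyads = n_dyads,
         objective_trace = objective_trace, penalized = penalized),
    class = "dyad_glmm"
  )
}

#' Smallest penalty that zeroes every slope
#'
#' Computes \eqn{\lambda_{\max}}, the supremum-norm of the marginal
#' log-likelihood gradient with respect to the standardized slopes at the
#' intercept-plus-variance null model. For any `lambda >= lambda_max` the
#' penalized fit keeps all slopes at exactly zero (soft-threshold
#' stationarity), so the penalty grid is anchored there.
#'
#' @inheritParams marginal_loglik
#' @return Scalar `lambda_max`.
#' @export
lambda_max <- function(data, nodes = 15) {
  md <- .dyad_matrices(data)
  std <- .standardize(md$X)
  null <- .null_model(md, nodes)
  g <- .nll_grad(c(null$beta0, numeric(ncol(std$X))), std$X, md,
                 null$sigma, nodes)
  max(abs(g$grad[-1]))
}

#' Fit an L1-penalized logistic random-intercept model
#'
#' Maximizes the adaptive-quadrature marginal log-likelihood minus
#' `lambda * sum(|beta_std|)`, the LASSO penalty applied to slopes on the
#' internally standardized covariate scale (intercept and variance component
#' unpenalized). Optimization alternates monotone accelerated
#' proximal-gradient steps on `(beta0, beta)` with bounded one-dimensional
#' optimization of `log sigma_b`, stopping when the parameter change drops
#' below `tol`. Returned slopes are mapped back to the original covariate
#' scale; zeros are exact.
#'
#' Degenerate clusters (constant outcome) fall back to an intercept-only
#' model at the clipped rate `(r + 0.5) / (n + 1)` with `sigma_b = 0`,
#' flagged via the `fallback` field.
#'
#' @inheritParams marginal_loglik
#' @param lambda Penalty level, `>= 0`.
#' @param sigma_fixed If non-`NULL`, `sigma_b` is held at this value instead
#'   of being profiled.
#' @param tol Convergence tolerance on the parameter change (default 1e-6).
#' @param max_iter Cap on proximal-gradient iterations (default 500).
#' @param init Optional warm start: a list with `beta0s`, `betas` (both on
#'   the standardized scale) and `sigma`.
#' @return A `dyad_glmm` fit: coefficients on the original scale, `sigma_b`,
#'   marginal log-likelihood `loglik`, degrees of freedom `df` (nonzero
#'   slopes + intercept + variance component when `sigma_b > 0`), the active
#'   `support`, a `converged` flag, and the penalized objective trace.
#' @export
fit_penalized <- function(data, lambda, nodes = 15, tol = 1e-6,
                          max_iter = 500, sigma_fixed = NULL, init = NULL) {
  if (!is.numeric(lambda) || lambda < 0) .stopf("lambda must be >= 0")
  md <- .dyad_matrices(data)
  feats <- dyad_feature_names(data)
  if (nrow(md$Y2) < 2) .stopf("need at least 2 dyads")
  if (length(unique(md$y)) == 1) {
    return(.fallback_fit(md, feats, "constant-outcome", lambda))
  }
  std <- .standardize(md$X)
  Xs <- std$X
  p <- ncol(Xs)
  if (!is.null(init)) {
    theta <- c(init$beta0s, init$betas)
    sigma <- init$sigma
  } else {
    null <- .null_model(md, nodes)
    theta <- c(null$beta0, numeric(p))
    sigma <- null$sigma
  }
  if (!is.null(sigma_fixed)) sigma <- sigma_fixed
  trace <- numeric(0)
  converged <- FALSE
  tstep <- 1
  iter_used <- 0
  for (outer in 1:25) {
    res <- .prox_descent(theta, Xs, md, sigma, lambda, nodes,
                         tol = tol, max_iter = min(100, max_iter - iter_used),
                         t0 = tstep)
    iter_used <- iter_used + length(res$trace) - 1
    tstep <- res$tstep
    delta_beta <- max(abs(res$theta - theta))
    theta <- res$theta
    trace <- c(trace, res$trace[-1])
    delta_sigma <- 0
    dF_sigma <- 0
    if (is.null(sigma_fixed)) {
      sigma_new <- .optimize_sigma(theta, Xs, md, nodes, sigma = sigma)
      # accept only if it does not increase the objective (optimize() is
      # approximate; keep the trace monotone)
      f_old <- .nll_value(theta, Xs, md, sigma, nodes)
      f_new <- .nll_value(theta, Xs, md, sigma_new, nodes)
      if (f_new <= f_old + 1e-12) {
        delta_sigma <- abs(sigma_new - sigma)
        dF_sigma <- f_old - f_new
        sigma <- sigma_new
        trace <- c(trace, f_new + lambda * sum(abs(theta[-1])))
      }
    }
    # sigma's profile can be numerically flat near its optimum, leaving
    # Brent jitter above tol; treat it as converged once its objective
    # improvement is negligible
    if (delta_beta < tol && (delta_sigma < tol || dF_sigma < 1e-8)) {
      converged <- TRUE
      break
    }
    if (iter_used >= max_iter) break
  }
  # numerical polish: a slope that converged to a value indistinguishable
  # from zero is set to exact zero when that does not worsen the objective
  tiny <- which(theta[-1] != 0 & abs(theta[-1]) < 1e-8)
  if (length(tiny) > 0) {
    theta_z <- theta
    theta_z[1 + tiny] <- 0
    f_cur <- .nll_value(theta, Xs, md, sigma, nodes) + lambda * sum(abs(theta[-1]))
    f_z <- .nll_value(theta_z, Xs, md, sigma, nodes) +
      lambda * sum(abs(theta_z[-1]))
    if (f_z <= f_cur + 1e-9) theta <- theta_z
  }
  beta_s <- theta[-1]
  beta <- beta_s / std$scale
  beta0 <- theta[1] - sum(beta_s * std$center / std$scale)
  ll <- -.nll_value(theta, Xs, md, sigma, nodes)
  new_dyad_glmm(
    beta0 = beta0, beta = stats::setNames(beta, feats), sigma_b = sigma,
    loglik = ll, lambda = lambda, converged = converged,
    scale_info = list(center = std$center, scale = std$scale,
                      beta0s = theta[1], betas = beta_s, sigma = sigma),
    n_obs = length(md$y), n_dyads = nrow(md$Y2), objective_trace = trace
  )
}

#' Re-estimate a model without penalty on a fixed support
#'
#' Maximum (adaptive-quadrature) likelihood fit of the logistic
#' random-intercept model using only the covariates in `support` --- the
#' debiasing refit applied after LASSO selection, with no shrinkage. Standard
#' errors come from the inverse numerical Hessian of the marginal
#' log-likelihood at the optimum.
#'
#' Perfect separation (unbounded likelihood, detected as a standardized
#' slope exceeding 15 in magnitude) and constant outcomes trigger the
#' intercept-only fallback fit, flagged in the result.
#'
#' @inheritParams marginal_loglik
#' @param support Feature names (or integer indices) to retain; may be empty.
#' @param se Compute standard errors (default `TRUE`).
#' @return A `dyad_glmm` fit with `penalized = FALSE` and, when requested,
#'   a named `se` vector for `(Intercept)` and each support coefficient.
#' @export
refit_unpenalized <- function(data, support, nodes = 15, se = TRUE) {
  feats <- dyad_feature_names(data)
  if (is.numeric(support)) support <- feats[support]
  if (!all(support %in% feats)) .stopf("support names not in data")
  md <- .dyad_matrices(data)
  if (length(support) >= length(md$y)) .stopf("support larger than data")
  if (length(unique(md$y)) == 1) {
    return(.fallback_fit(md, feats, "constant-outcome"))
  }
  Xsub <- md$X[, support, drop = FALSE]
  std <- .standardize(Xsub)
  Xs <- std$X
  k <- length(support)
  par0 <- c(stats::qlogis(mean(md$y)), numeric(k), log(0.5))
  fn <- function(par) .nll_value(par[1:(k + 1)], Xs, md, exp(par[k + 2]), nodes)
  gr <- function(par) {
    g <- .nll_grad(par[1:(k + 1)], Xs, md, exp(par[k + 2]), nodes)
    h <- 1e-5
    gs <- (fn(par + c(numeric(k + 1), h)) - fn(par - c(numeric(k + 1), h))) / (2 * h)
    c(g$grad, gs)
  }
  opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      lower = c(rep(-Inf, k + 1), log(1e-6)),
                      upper = c(rep(Inf, k + 1), log(8)),
                      control = list(maxit = 500, factr = 1e4))
  beta_s <- opt$par[seq_len(k) + 1]
  if (!all(is.finite(opt$par)) || (k > 0 && max(abs(beta_s)) > 15)) {
    return(.fallback_fit(md, feats, "separation"))
  }
  sigma <- exp(opt$par[k + 2])
  # the sigma profile flattens near 0; collapse to the boundary when that
  # loses nothing, so "no dyad effect" cases report an exact zero
  if (sigma < 0.01) {
    theta_hat <- opt$par[1:(k + 1)]
    if (.nll_value(theta_hat, Xs, md, 0, nodes) <= opt$value + 1e-8) {
      sigma <- 0
      ob0 <- stats::optimize(
        function(b0) .nll_value(c(b0, theta_hat[-1]), Xs, md, 0, nodes),
        interval = opt$par[1] + c(-2, 2), tol = 1e-9)
      opt$par[1] <- ob0$minimum
      opt$value <- ob0$objective
    }
  }
  beta_sup <- beta_s / std$scale
  beta0 <- opt$par[1] - sum(beta_s * std$center / std$scale)
  beta <- stats::setNames(numeric(length(feats)), feats)
  beta[support] <- beta_sup
  se_vec <- NULL
  if (se) {
    # Hessian on the original-scale parametrization (beta0, beta_support,
    # log sigma); invert and read the coefficient block.
    fn_orig <- function(par) {
      eta <- par[1] + if (k > 0) as.numeric(Xsub %*% par[seq_len(k) + 1]) else 0
      eta2 <- cbind(eta[md$E[, 1]], eta[md$E[, 2]])
      -.agq_core(eta2, md$Y2, exp(par[k + 2]), nodes)$ll
    }
    par_orig <- c(beta0, beta_sup, log(max(sigma, 1e-6)))
    H <- tryCatch(pracma::hessian(fn_orig, par_orig), error = function(e) NULL)
    V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
    if (!is.null(V)) {
      d <- diag(V)[seq_len(k + 1)]
      se_vec <- stats::setNames(sqrt(pmax(d, 0)), c("(Intercept)", support))
    }
  }
  new_dyad_glmm(
    beta0 = beta0, beta = beta, sigma_b = sigma, loglik = -opt$value,
    lambda = NA_real_, converged = opt$convergence == 0,
    se = se_vec,
    scale_info = list(center = std$center, scale = std$scale),
    n_obs = length(md$y), n_dyads = nrow(md$Y2)
  )
}

#' Akaike information criterion of a dyad GLMM fit
#'
#' `AIC = -2 * loglik + 2 * df`, where `df` counts the nonzero slopes, the
#' intercept, and the variance component when `sigma_b` is above the
#' boundary tolerance.
#'
#' @param fit A `dyad_glmm`.
#' @return Scalar AIC.
#' @export
compute_aic <- function(fit) {
  if (!is.finite(fit$loglik)) .stopf("fit has non-finite log-likelihood")
  -2 * fit$loglik + 2 * fit$df
}

#' @export
AIC.dyad_glmm <- function(object, ..., k = 2) -2 * object$loglik + k * object$df

#' @export
logLik.dyad_glmm <- function(object, ...) {
  structure(object$loglik, df = object$df, class = "logLik")
}

#' Select the penalty level by AIC along a decreasing grid
#'
#' Fits [fit_penalized()] at each grid value (warm-started from the previous,
#' larger penalty), computes the AIC of each fit, and selects the minimizer.
#' Ties go to the largest penalty, i.e. the sparsest model. The default grid
#' is 25 log-spaced values from [lambda_max()] down to `1e-3 * lambda_max`,
#' recomputed per call because cluster composition changes between outer
#' iterations of the alternating algorithm.
#'
#' @inheritParams fit_penalized
#' @param lambda Optional explicit penalty grid (any order; used as sorted
#'   decreasing unique values).
#' @param n_lambda Grid length when `lambda` is `NULL` (default 25).
#' @param lambda_min_ratio Ratio of smallest to largest grid value
#'   (default 1e-3).
#' @return A `lambda_path` object: a `path` tibble (`lambda`, `loglik`,
#'   `df`, `aic`, `n_nonzero`, `converged`), the list of `fits`, the
#'   `chosen_lambda`, and `best_fit`.
#' @export
select_lambda <- function(data, lambda = NULL, n_lambda = 25,
                          lambda_min_ratio = 1e-3, nodes = 15, tol = 1e-6,
                          max_iter = 500) {
  if (is.null(lambda)) {
    lmax <- lambda_max(data, nodes)
    if (!is.finite(lmax) || lmax <= 0) lmax <- 1
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = n_lambda))
  }
  lambda <- sort(unique(as.numeric(lambda)), decreasing = TRUE)
  if (length(lambda) == 0 || any(lambda < 0)) {
    .stopf("lambda grid must be non-empty and >= 0")
  }
  fits <- vector("list", length(lambda))
  init <- NULL
  for (i in seq_along(lambda)) {
    fits[[i]] <- fit_penalized(data, lambda[i], nodes = nodes, tol = tol,
                               max_iter = max_iter, init = init)
    si <- fits[[i]]$scale_info
    if (!is.null(si)) {
      init <- list(beta0s = si$beta0s, betas = si$betas, sigma = si$sigma)
    }
  }
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(conv)) {
    .stopf("no penalized fit converged; lambda grid: %s",
           paste(signif(lambda, 3), collapse = ", "))
  }
  aic <- vapply(fits, compute_aic, double(1))
  path <- tibble::tibble(
    lambda = lambda,
    loglik = vapply(fits, function(f) f$loglik, double(1)),
    df = vapply(fits, function(f) f$df, double(1)),
    aic = aic,
    n_nonzero = vapply(fits, function(f) length(f$support), integer(1)),
    converged = conv
  )
  # grid is decreasing, so the first index within tolerance of the minimum
  # is the largest (sparsest) lambda among ties
  best <- which(aic <= min(aic) + 1e-8)[1]
  structure(
    list(path = path, fits = fits, chosen_lambda = lambda[best],
         best_fit = fits[[best]]),
    class = "lambda_path"
  )
}

#' Predicted caries probabilities per dyad member
#'
#' Computes each member's fitted probability under a `dyad_glmm`. Marginal
#' mode sets the random intercept to zero, matching the coefficient
#' interpretation that ignores the random intercepts; conditional mode adds
#' the posterior mode \eqn{\hat b_i} of the dyad's random intercept given its
#' observed outcomes (an empirical-BLUP analogue). Probabilities are clipped
#' to `[1e-12, 1 - 1e-12]`.
#'
#' @inheritParams marginal_loglik
#' @param fit A `dyad_glmm`.
#' @param mode `"marginal"` (default) or `"conditional"`.
#' @return A tibble: `dyad_id`, `p_mother`, `p_child`, `mode`.
#' @export
predict_probabilities <- function(data, fit, mode = c("marginal", "conditional")) {
  mode <- match.arg(mode)
  feats <- dyad_feature_names(data)
  if (!setequal(names(fit$beta), feats)) {
    miss <- setdiff(names(fit$beta)[fit$beta != 0], feats)
    if (length(miss) > 0) {
      .stopf("fit covariate(s) absent from data: %s", paste(miss, collapse = ", "))
    }
  }
  beta <- stats::setNames(numeric(length(feats)), feats)
  common <- intersect(names(fit$beta), feats)
  beta[common] <- fit$beta[common]
  md <- .dyad_matrices(data)
  eta2 <- .eta2(md, fit$beta0, beta)
  if (mode == "conditional" && fit$sigma_b > 0) {
    eta2 <- eta2 + .agq_core(eta2, md$Y2, fit$sigma_b, nodes = 15)$bhat
  }
  p2 <- pmin(pmax(stats::plogis(eta2), 1e-12), 1 - 1e-12)
  tibble::tibble(dyad_id = md$dyad_ids, p_mother = p2[, 1],
                 p_child = p2[, 2], mode = mode)
}

#' @export
print.dyad_glmm <- function(x, ...) {
  kind <- if (isTRUE(x$penalized)) {
    sprintf("L1-penalized (lambda = %.4g)", x$lambda)
  } else "unpenalized refit"
  cat(sprintf("Logistic random-intercept model, %s\n", kind))
  cat(sprintf("  dyads: %d  obs: %d  support: %d feature(s)\n",
              x$n_dyads, x$n_obs, length(x$support)))
  cat(sprintf("  beta0 = %.4f  sigma_b = %.4f  loglik = %.4f  df = %d\n",
              x$beta0, x$sigma_b, x$loglik, x$df))
  if (!is.null(x$fallback)) cat(sprintf("  fallback: %s\n", x$fallback))
  if (length(x$support) > 0) {
    cat("  nonzero slopes:\n")
    print(round(x$beta[x$support], 4))
  }
  invisible(x)
}

#' Tidy a dyad GLMM fit
#'
#' @param x A `dyad_glmm`.
#' @param all Include zero coefficients (default `FALSE`).
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `odds_ratio`, and `std_error`
#'   (refits only).
#' @export
tidy.dyad_glmm <- function(x, all = FALSE, ...) {
  terms <- c("(Intercept)", names(x$beta))
  est <- c(x$beta0, x$beta)
  out <- tibble::tibble(
    term = terms, estimate = est, odds_ratio = exp(est),
    std_error = if (!is.null(x$se)) x$se[terms] else NA_real_
  )
  if (!all) out <- out[out$term == "(Intercept)" | out$estimate != 0, ]
  out
}

#' @rdname tidy.dyad_glmm
#' @export
glance.dyad_glmm <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik, df = x$df, aic = compute_aic(x),
    sigma_b = x$sigma_b, n_support = length(x$support),
    n_dyads = x$n_dyads, converged = x$converged,
    fallback = x$fallback %||% NA_character_
  )
}

#' @export
tidy.lambda_path <- function(x, ...) x$path

#' Serialize a fit to JSON
#'
#' Coefficients keyed by feature name plus `sigma_b`, log-likelihood, df and
#' penalty level, suitable for the pipeline's per-cluster coefficient output.
#'
#' @param fit A `dyad_glmm`.
#' @return A JSON string.
#' @export
glmm_to_json <- function(fit) {
  jsonlite::toJSON(list(
    intercept = fit$beta0,
    coefficients = as.list(fit$beta[fit$support]),
    sigma_b = fit$sigma_b,
    loglik = fit$loglik,
    df = fit$df,
    lambda = fit$lambda,
    converged = fit$converged,
    fallback = fit$fallback %||% NA
  ), auto_unbox = TRUE, digits = NA, na = "null")
}
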