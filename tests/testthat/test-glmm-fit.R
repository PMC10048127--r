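test_that("all slopes are exactly zero at and above lambda_max", {
  d <- random_dyad_data(30, 5, seed = 21, beta = c(1, -0.5, 0, 0, 0),
                        sigma_b = 0.6)
  lmax <- lambda_max(d)
  for (lam in c(lmax, 1.5 * lmax)) {
    fit <- fit_penalized(d, lam)
    expect_identical(unname(fit$beta), rep(0, 5))
    expect_length(fit$support, 0)
  }
  # just below lambda_max the optimized objective is no worse than the null's
  fit99 <- fit_penalized(d, 0.99 * lmax)
  null_obj <- -marginal_loglik(d, fit99$beta0, numeric(5), fit99$sigma_b)
  expect_lte(min(fit99$objective_trace), null_obj + 1e-6)
})

test_that("lambda = 0 with sigma_b fixed at 0 recovers the logistic MLE", {
  d <- random_dyad_data(40, 3, seed = 31, beta = c(0.8, -0.8, 0))
  fit <- fit_penalized(d, 0, sigma_fixed = 0)
  df <- data.frame(outcome = d$outcome,
                   as.data.frame(d[, dyad_feature_names(d)]))
  mle <- stats::glm(outcome ~ ., data = df, family = stats::binomial)
  expect_equal(unname(c(fit$beta0, fit$beta)), unname(stats::coef(mle)),
               tolerance = 1e-4)
})

test_that("penalized objective never increases across iterations", {
  for (seed in c(5, 6)) {
    d <- random_dyad_data(25, 8, seed = seed, sigma_b = 0.5)
    fit <- fit_penalized(d, lambda = lambda_max(d) / 10)
    expect_true(all(diff(fit$objective_trace) <= 1e-9))
  }
})

test_that("penalized fit finds a strong predictor and keeps nulls sparse", {
  p <- 50
  beta <- numeric(p)
  beta[7] <- 2
  d <- random_dyad_data(200, p, seed = 42, beta = beta, sigma_b = 0.5)
  fit <- fit_penalized(d, lambda_max(d) / 10)
  expect_true("f7" %in% fit$support)
  null_zero <- mean(fit$beta[-7] == 0)
  expect_gte(null_zero, 0.9)
})

test_that("fitted probabilities are invariant to caller-side rescaling", {
  d <- random_dyad_data(30, 4, seed = 41, beta = c(1, 0, -1, 0),
                        sigma_b = 0.4)
  fit <- fit_penalized(d, 0.5)
  p1 <- predict_probabilities(d, fit)
  # rescale covariates by hand and refit: probabilities must match
  feats <- dyad_feature_names(d)
  X <- as.matrix(d[, feats])
  Xs <- sweep(sweep(X, 2, colMeans(X)), 2, apply(X, 2, sd), "/")
  d2 <- make_dyad_data(Xs, d$outcome)
  fit2 <- fit_penalized(d2, 0.5)
  p2 <- predict_probabilities(d2, fit2)
  expect_equal(p1$p_mother, p2$p_mother, tolerance = 1e-6)
  expect_equal(p1$p_child, p2$p_child, tolerance = 1e-6)
})

test_that("constant outcomes trigger the clipped-rate fallback", {
  d <- make_dyad_data(matrix(rnorm(8), 8, 1), rep(1, 8))
  fit <- fit_penalized(d, 1)
  expect_identical(fit$fallback, "constant-outcome")
  expect_equal(fit$beta0, stats::qlogis((8 + 0.5) / (8 + 1)))
  expect_equal(fit$sigma_b, 0)
  rfit <- refit_unpenalized(d, integer(0))
  expect_identical(rfit$fallback, "constant-outcome")
})

test_that("empty-support refit without dyad effect recovers logit(mean)", {
  set.seed(55)
  # discordant pairs: negative within-dyad association drives sigma_b to
  # its boundary, where the model collapses to independent Bernoulli
  y <- rep(c(1L, 0L), 40)
  d <- make_dyad_data(matrix(stats::rnorm(80), 80, 1), y)
  fit <- refit_unpenalized(d, integer(0))
  expect_equal(fit$beta0, stats::qlogis(mean(y)), tolerance = 1e-4)
  expect_equal(fit$sigma_b, 0)
})

test_that("refit matches brute-force profile of the quadrature oracle", {
  # 8 dyads, 1 covariate: profile (beta0, beta, sigma) over a fine grid
  # around the optimum found independently of the fitting code
  d <- random_dyad_data(8, 1, seed = 91, beta0 = 0.2, beta = 1, sigma_b = 0.7)
  fit <- refit_unpenalized(d, "f1")
  obj <- function(par) {
    -trapezoid_loglik(d, par[1], par[2], exp(par[3]))
  }
  oracle <- stats::optim(c(0, 0, log(0.5)), obj, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-12))
  expect_equal(fit$beta0, oracle$par[1], tolerance = 1e-3)
  expect_equal(unname(fit$beta["f1"]), oracle$par[2], tolerance = 1e-3)
  expect_equal(-fit$loglik, oracle$value, tolerance = 1e-4)
})

test_that("refit agrees with glmer on a small paired dataset", {
  skip_if_not_installed("lme4")
  d <- random_dyad_data(60, 2, seed = 13, beta0 = -0.3, beta = c(1, -0.6),
                        sigma_b = 0.8)
  fit <- refit_unpenalized(d, c("f1", "f2"))
  df <- data.frame(y = d$outcome, d[, c("f1", "f2")], g = d$dyad_id)
  gm <- lme4::glmer(y ~ f1 + f2 + (1 | g), data = df,
                    family = stats::binomial, nAGQ = 15)
  expect_equal(unname(c(fit$beta0, fit$beta[c("f1", "f2")])),
               unname(lme4::fixef(gm)), tolerance = 1e-3)
  expect_equal(fit$sigma_b,
               sqrt(unname(unlist(lme4::VarCorr(gm)))), tolerance = 1e-2)
})

test_that("AIC follows the df accounting", {
  fake <- structure(list(loglik = -10, df = 3), class = "dyad_glmm")
  expect_equal(compute_aic(fake), 26)
  d <- random_dyad_data(50, 3, seed = 61, beta = c(1.2, -1.2, 0),
                        sigma_b = 1.2)
  fit <- refit_unpenalized(d, c("f1", "f2"))
  if (fit$sigma_b > 0) {
    expect_equal(fit$df, 2 + 1 + 1)
    expect_equal(compute_aic(fit), -2 * fit$loglik + 8)
  }
  # at fixed df, AIC decreases in the log-likelihood
  expect_lt(compute_aic(structure(list(loglik = -5, df = 3),
                                  class = "dyad_glmm")),
            compute_aic(fake))
})

test_that("select_lambda returns the AIC arg-min with sparse tie-breaking", {
  d <- random_dyad_data(40, 6, seed = 71, beta = c(1.5, rep(0, 5)),
                        sigma_b = 0.4)
  path <- select_lambda(d, n_lambda = 8)
  expect_equal(path$chosen_lambda,
               path$path$lambda[which.min(path$path$aic)])
  # independent recomputation of AIC at each grid value (cold starts)
  recomputed <- vapply(path$path$lambda, function(l) {
    compute_aic(fit_penalized(d, l))
  }, double(1))
  expect_equal(which.min(recomputed), which.min(path$path$aic))
  # a one-value grid returns that value
  single <- select_lambda(d, lambda = 0.7)
  expect_equal(single$chosen_lambda, 0.7)
  # largest lambda wins exact AIC ties (duplicated grid entry collapses,
  # so construct a flat stretch above lambda_max where AIC is constant)
  lmax <- lambda_max(d)
  flat <- select_lambda(d, lambda = c(2 * lmax, 3 * lmax))
  expect_equal(flat$chosen_lambda, 3 * lmax)
})

test_that("probability predictions respect link monotonicity and modes", {
  d <- random_dyad_data(20, 2, seed = 81, sigma_b = 0.8)
  null_fit <- structure(
    list(beta0 = 0, beta = stats::setNames(numeric(2), c("f1", "f2")),
         sigma_b = 0, support = character(), penalized = FALSE),
    class = "dyad_glmm")
  pp <- predict_probabilities(d, null_fit)
  expect_true(all(pp$p_mother == 0.5 & pp$p_child == 0.5))

  fit <- refit_unpenalized(d, "f1")
  pm <- predict_probabilities(d, fit, mode = "marginal")
  eta <- fit$beta0 + as.matrix(d[d$role == "mother", "f1"]) * fit$beta["f1"]
  expect_equal(order(pm$p_mother), order(as.numeric(eta)))

  # conditional mode pulls probabilities toward the dyad's outcomes
  X <- matrix(0, 6, 1)
  y <- c(1, 1, 1, 1, 0, 0)
  d2 <- make_dyad_data(X, y)
  fit2 <- structure(
    list(beta0 = 0, beta = stats::setNames(0, "f1"), sigma_b = 1,
         support = character(), penalized = FALSE),
    class = "dyad_glmm")
  pc <- predict_probabilities(d2, fit2, mode = "conditional")
  pm2 <- predict_probabilities(d2, fit2, mode = "marginal")
  expect_gt(pc$p_mother[1], pm2$p_mother[1]) # y = (1,1) dyad
  expect_gt(pc$p_child[1], pm2$p_child[1])
  expect_lt(pc$p_mother[3], pm2$p_mother[3]) # y = (0,0) dyad
})

test_that("fits serialize to JSON with named coefficients", {
  d <- random_dyad_data(20, 2, seed = 86, beta = c(1, 0), sigma_b = 0.3)
  fit <- refit_unpenalized(d, "f1")
  parsed <- jsonlite::fromJSON(glmm_to_json(fit))
  expect_equal(parsed$coefficients$f1, unname(fit$beta["f1"]))
  expect_equal(parsed$df, fit$df)
})
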