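# Closed-form oracles for the penalized solver, then the selection layer.

test_that("lambda -> 0 on a full-rank design recovers least squares", {
  X <- toy_design(30, 5, seed = 11)
  set.seed(12)
  y <- X %*% c(1, -2, 0.5, 0, 1) + rnorm(30, 0, 0.3)
  fit <- elastic_net_solve(X, y, rho = 1, lambda = 0, tolerance = 1e-14)
  ols <- unname(coef(lm(y ~ X)))
  expect_lt(max(abs(c(fit$intercept, fit$beta) - ols)), 1e-6)

  # fitted values through predict()
  en_fit <- structure(list(intercept = fit$intercept,
                           coefficients = fit$beta,
                           columns = NULL, preprocessor = NULL),
                      class = "expn_enet_fit")
  expect_equal(predict(en_fit, X), unname(fitted(lm(y ~ X))),
               tolerance = 1e-6)
  # single-row prediction equals the batch entry
  expect_equal(predict(en_fit, X[3, , drop = FALSE]),
               predict(en_fit, X)[3])
})

test_that("orthonormal design with rho = 1 soft-thresholds the OLS fit", {
  set.seed(13)
  n <- 40; p <- 6
  raw <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
  Q <- qr.Q(qr(raw))          # orthonormal, columns still mean-zero
  expect_equal(crossprod(Q), diag(p), tolerance = 1e-12,
               ignore_attr = TRUE)
  y <- rnorm(n)
  lambda <- 0.004
  fit <- elastic_net_solve(Q, y, rho = 1, lambda = lambda,
                           tolerance = 1e-14)
  ols <- as.numeric(crossprod(Q, y - mean(y)))
  # unit-norm (not unit-variance) columns: threshold level is n * lambda
  shrunk <- sign(ols) * pmax(abs(ols) - n * lambda, 0) # / q_j'q_j = 1
  expect_lt(max(abs(fit$beta - shrunk)), 1e-6)
})

test_that("lambda at or above lambda_max gives the exact null model", {
  X <- toy_design(20, 8, seed = 14)
  set.seed(15)
  y <- rnorm(20)
  for (rho in c(0.1, 0.5, 1)) {
    lmax <- elastic_net_lambda_max(X, y, rho)
    # the stated formula
    expect_equal(lmax,
                 max(abs(crossprod(X, y - mean(y)))) / (nrow(X) * rho))
    fit <- elastic_net_solve(X, y, rho, lmax * (1 + 1e-10))
    expect_identical(unname(fit$beta), rep(0, 8))
    expect_equal(fit$intercept, mean(y))
    # strictly below lambda_max at least one coefficient activates
    fit2 <- elastic_net_solve(X, y, rho, lmax * 0.99)
    expect_gt(sum(fit2$beta != 0), 0)
  }
})

test_that("pure ridge matches the closed form (l1 term disabled)", {
  X <- toy_design(25, 6, seed = 16)
  set.seed(17)
  y <- rnorm(25)
  n <- nrow(X)
  for (lambda in c(0.05, 0.5, 3)) {
    fit <- elastic_net_solve(X, y, rho = 0, lambda = lambda,
                             tolerance = 1e-14)
    Xc <- scale(X, scale = FALSE)
    closed <- solve(crossprod(Xc) + n * lambda * diag(6),
                    crossprod(Xc, y - mean(y)))
    expect_lt(max(abs(fit$beta - closed)), 1e-6)
  }
})

test_that("l1 norm shrinks monotonically along increasing lambda", {
  X <- toy_design(15, 10, seed = 18)
  set.seed(19)
  y <- X[, 1] - 0.5 * X[, 2] + rnorm(15, 0, 0.5)
  for (rho in c(0.3, 1)) {
    lmax <- elastic_net_lambda_max(X, y, rho)
    lambdas <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = 40))
    path <- expandnet:::enet_path_cpp(X, y, rho, lambdas, 1e-10, 1e6)
    l1 <- colSums(abs(path$betas))
    expect_true(all(diff(l1) >= -1e-8))   # lambdas decrease along the path
  }
})

test_that("returned solutions never do worse than the null objective", {
  for (seed in 20:24) {
    X <- toy_design(12, 20, seed = seed)
    set.seed(seed + 100)
    y <- rnorm(12)
    rho <- runif(1, 0.1, 1)
    lambda <- runif(1, 0.001, 0.5)
    fit <- elastic_net_solve(X, y, rho, lambda)
    obj <- elastic_net_objective(X, y, fit$beta, fit$intercept, rho,
                                 lambda)
    null_obj <- elastic_net_objective(X, y, rep(0, 20), mean(y), rho,
                                      lambda)
    expect_lte(obj, null_obj + 1e-12)
  }
})

test_that("solver agrees with glmnet across random penalties", {
  skip_if_not_installed("glmnet")
  set.seed(25)
  X <- toy_design(30, 8, seed = 25)
  y <- X[, 1] * 1.5 - X[, 4] + rnorm(30, 0, 0.5)
  for (case in 1:4) {
    rho <- sample(c(0.2, 0.5, 0.9, 1), 1)
    lambda <- runif(1, 0.01, 0.3)
    ours <- elastic_net_solve(X, y, rho, lambda, tolerance = 1e-14)
    g <- glmnet::glmnet(X, y, alpha = rho, lambda = lambda,
                        standardize = FALSE, thresh = 1e-14)
    # compare through the objective: both should reach the optimum, and
    # ours must never be the worse of the two
    o_ours <- elastic_net_objective(X, y, ours$beta, ours$intercept,
                                    rho, lambda)
    o_glm <- elastic_net_objective(X, y, as.numeric(g$beta),
                                   as.numeric(g$a0), rho, lambda)
    expect_lte(o_ours, o_glm + 1e-10)
    # glmnet's single-lambda solutions are loose along flat directions,
    # so coefficients only agree coarsely even at matching objectives
    expect_lt(max(abs(ours$beta - as.numeric(g$beta))), 0.1)
  }
})

test_that("an unreachable iteration cap raises a convergence error", {
  X <- toy_design(20, 5, seed = 26)
  set.seed(26)
  y <- X[, 1] + X[, 2] + rnorm(20, 0, 0.1)
  expect_error(elastic_net_solve(X, y, 0.5, 0.01, tolerance = 1e-14,
                                 max_iterations = 1),
               "converge.*rho")
})

test_that("cross-validated fit selects by inner LOO and refits", {
  X <- toy_design(14, 6, seed = 27)
  set.seed(28)
  y <- X[, 1] * 0.9 - X[, 3] * 0.7 + rnorm(14, 0, 0.4)
  cfg <- elastic_net_config(lambda_path_size = 30)
  fit <- fit_elastic_net(X, y, cfg)

  expect_s3_class(fit, "expn_enet_fit")
  expect_true(fit$rho %in% cfg$l1_ratio_grid)
  expect_equal(dim(fit$cv_mse), c(6, 30))
  expect_setequal(fit$retained_features,
                  names(fit$coefficients)[fit$coefficients != 0])

  # the refit matches a direct solve at the selected penalty (cold and
  # warm-started runs agree to solver tolerance)
  direct <- elastic_net_solve(X, y, fit$rho, fit$lambda)
  expect_equal(unname(fit$coefficients), direct$beta, tolerance = 1e-3)
  o_fit <- elastic_net_objective(X, y, fit$coefficients, fit$intercept,
                                 fit$rho, fit$lambda)
  o_direct <- elastic_net_objective(X, y, direct$beta, direct$intercept,
                                    fit$rho, fit$lambda)
  expect_equal(o_fit, o_direct, tolerance = 1e-6)

  # pure-R re-derivation of one cv_mse row (smallest rho)
  rho <- cfg$l1_ratio_grid[1]
  lams <- fit$lambdas[1, ]
  errs <- sapply(seq_len(14), function(i) {
    betas <- expandnet:::enet_path_cpp(X[-i, ], y[-i], rho, lams,
                                       1e-7, 1e6)
    (y[i] - (as.numeric(betas$intercepts) + X[i, ] %*% betas$betas))^2
  })
  expect_equal(unname(fit$cv_mse[1, ]), unname(rowMeans(errs)),
               tolerance = 1e-6)
})

test_that("exact cv ties resolve to larger lambda, then smaller rho", {
  # constant response: every (rho, lambda) cell fits the null model with
  # identical (zero) cv error, so the declared preference decides
  X <- toy_design(10, 4, seed = 29)
  y <- rep(2, 10)
  cfg <- elastic_net_config(lambda_path_size = 12)
  fit <- fit_elastic_net(X, y, cfg)
  expect_equal(fit$rho, min(cfg$l1_ratio_grid))
  expect_equal(fit$lambda, fit$lambdas[1, 1])
  expect_equal(unname(fit$coefficients), rep(0, 4))
  expect_equal(fit$intercept, 2)
})

test_that("prediction from raw features applies the stored preprocessor", {
  coh <- random_cohort(default_schema(), n = 12, seed = 30,
                       missing_rate = 0.1)
  y <- derive_response(coh)
  feats <- encode_features(coh)
  pp <- fit_preprocessor(feats)
  fit <- fit_elastic_net(apply_preprocessor(pp, feats), y,
                         fast_enet(), preprocessor = pp)
  manual <- predict(fit, apply_preprocessor(pp, feats)$values)
  via_raw <- predict(fit, feats)
  expect_equal(via_raw, manual)

  # column mismatch is a schema error
  expect_error(predict(fit, feats$values[, 1:10]), "column count")
  expect_error(predict(fit, encode_features(coh, "tumor")),
               "does not match")
})
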