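test_that("baseline MSE is the denominator-n empirical variance", {
  expect_equal(baseline_mse(c(0, 2)), 1)
  expect_equal(baseline_mse(c(5, 5, 5)), 0)
  expect_equal(baseline_mse(c(1, 2, 3)), 2 / 3)
  expect_error(baseline_mse(3), ">= 2")
  set.seed(40)
  y <- rnorm(17)
  expect_equal(baseline_mse(y), mean((y - mean(y))^2))
})

test_that("variance explained reproduces the reported arithmetic", {
  ve <- variance_explained(0.176, 0.838)
  expect_equal(round(100 * ve$raw), 79)
  expect_equal(variance_explained(0, 2)$raw, 1)
  expect_equal(variance_explained(4, 1), list(raw = -3, nominal = 0))
  expect_equal(variance_explained(0.5, 0.5), list(raw = 0, nominal = 0))
  expect_error(variance_explained(1, 0), "> 0")
})

test_that("leave-one-out mean model satisfies the exact error identity", {
  # held-out error of the training-mean predictor is (n/(n-1)) (y_i - ybar),
  # so its LOOCV MSE is (n/(n-1))^2 times the baseline MSE, for any y
  for (rep in 1:100) {
    set.seed(rep)
    n <- sample(4:10, 1)
    counts <- as.integer(rpois(n, 30))
    coh <- random_cohort(tiny_schema(), n = n, seed = rep)
    coh$data$expanded_clone_count <- counts
    res <- run_loocv(coh, model_spec = "mean")
    y <- derive_response(coh)
    expect_equal(res$mse, (n / (n - 1))^2 * baseline_mse(y),
                 tolerance = 1e-12)
    expect_equal(res$predictions,
                 vapply(seq_len(n), function(i) mean(y[-i]), 0))
  }
})

test_that("a 21-patient cohort yields 21 folds, deterministically", {
  sim <- simulate_cohort(simulation_config(seed = 44))
  res <- run_loocv(sim$cohort, config = fast_enet())
  expect_length(res$predictions, 21)
  expect_length(res$squared_errors, 21)
  expect_equal(nrow(res$folds), 21)
  expect_equal(res$mse, mean(res$squared_errors))
  expect_equal(res$variance_explained_raw,
               1 - res$mse / res$baseline_mse)
  expect_equal(res$variance_explained_nominal,
               max(0, res$variance_explained_raw))
  res2 <- run_loocv(sim$cohort, config = fast_enet())
  expect_identical(res$predictions, res2$predictions)
  expect_identical(res$folds, res2$folds)
})

test_that("held-out predictions ignore the held-out patient's features", {
  sim <- simulate_cohort(simulation_config(seed = 45, missing_rate = 0))
  coh <- sim$cohort
  res <- run_loocv(coh, config = fast_enet())

  # corrupt patient 4's attributes (not the response); every other fold
  # changes, but fold 4's prediction must not depend on its own features
  # beyond the predict step, i.e. the fitted fold-4 model is unchanged.
  coh2 <- coh
  for (nm in coh$schema$name) {
    if (coh$schema$kind[coh$schema$name == nm] == "continuous") {
      coh2$data[[nm]][4] <- coh$data[[nm]][4] * 3 + 1
    }
  }
  coh2 <- validate_cohort(coh2)
  res2 <- run_loocv(coh2, config = fast_enet())
  # fold 4's training data are untouched, so the entire fitted fold-4
  # pipeline — hyperparameters, coefficients, intercept — is identical:
  # nothing about the held-out patient leaked into training
  expect_equal(res$folds[4, c("rho", "lambda", "n_retained")],
               res2$folds[4, c("rho", "lambda", "n_retained")])
  expect_equal(res$fold_betas[, 4], res2$fold_betas[, 4])
  expect_equal(res$fold_intercepts[4], res2$fold_intercepts[4])
  # applying that unchanged model to the patient's original features
  # reproduces the original held-out prediction
  feats <- encode_features(coh)
  rest <- setdiff(1:21, 4)
  pp <- fit_preprocessor(structure(
    list(values = feats$values[rest, ], columns = feats$columns),
    class = "expn_features"))
  x4 <- apply_preprocessor(pp, structure(
    list(values = feats$values[4, , drop = FALSE],
         columns = feats$columns), class = "expn_features"))$values
  expect_equal(res2$fold_intercepts[4] +
                 as.numeric(x4 %*% res2$fold_betas[, 4]),
               res$predictions[4], tolerance = 1e-9)
})

test_that("run_loocv matches a manual single-fold pipeline", {
  sim <- simulate_cohort(simulation_config(seed = 46))
  coh <- sim$cohort
  cfg <- fast_enet()
  res <- run_loocv(coh, config = cfg)
  y <- derive_response(coh)

  i <- 5
  rest <- setdiff(seq_len(21), i)
  feats <- encode_features(coh)
  train <- structure(list(values = feats$values[rest, ],
                          columns = feats$columns),
                     class = "expn_features")
  pp <- fit_preprocessor(train)
  fit <- fit_elastic_net(apply_preprocessor(pp, train), y[rest], cfg,
                         preprocessor = pp)
  held <- structure(list(values = feats$values[i, , drop = FALSE],
                         columns = feats$columns),
                    class = "expn_features")
  expect_equal(res$predictions[i], predict(fit, held),
               tolerance = 1e-8)
  expect_equal(res$folds$rho[i], fit$rho)
  expect_equal(res$folds$lambda[i], fit$lambda, tolerance = 1e-12)
})

test_that("ablation drops exactly one category per run", {
  sim <- simulate_cohort(simulation_config(seed = 47))
  ab <- ablate_categories(sim$cohort, model_spec = "mean")
  expect_named(ab, c("all", "clinical", "tumor", "circulating"))
  for (r in ab) expect_length(r$predictions, 21)
  expect_equal(ab$tumor$include_categories,
               c("clinical", "circulating"))
  tab <- ablation_table(ab)
  expect_equal(tab$excluded, c("none", "clinical", "tumor",
                               "circulating"))
  # mean model ignores features: all four runs identical
  expect_equal(ab$all$mse, ab$tumor$mse)
})

test_that("excluding the signal-bearing category degrades prediction", {
  sim <- simulate_cohort(simulation_config(
    seed = 48, signal_categories = "tumor", missing_rate = 0))
  expect_true(all(sim$truth$columns$category[
    sim$truth$beta != 0] == "tumor"))
  full <- run_loocv(sim$cohort, config = fast_enet())
  no_tumor <- run_loocv(sim$cohort,
                        include_categories = c("clinical", "circulating"),
                        config = fast_enet())
  expect_gt(no_tumor$mse, full$mse)
})

test_that("LOOCV results serialize to TSV and JSON", {
  sim <- simulate_cohort(simulation_config(seed = 49))
  res <- run_loocv(sim$cohort, model_spec = "mean")
  tsv <- file.path(tempdir(), "loocv.tsv")
  js <- file.path(tempdir(), "loocv.json")
  s <- write_loocv(res, tsv, js)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 21)
  expect_equal(tab$prediction, res$predictions)
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(back$mse, res$mse)
  unlink(c(tsv, js))
})
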