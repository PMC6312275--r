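#' Baseline mean-squared error of the constant-mean predictor
#'
#' The in-sample MSE of the rule that predicts the cohort mean response for
#' every patient: `(1/n) * sum_i (y_i - mean(y))^2`, i.e. the empirical
#' variance with denominator `n`. This is the total variance of log clonal
#' expansion that patient features could explain, and the denominator of
#' the held-out variance-explained statistic.
#'
#' @param y numeric response vector, length >= 2.
#' @return Scalar baseline MSE.
#' @export
baseline_mse <- function(y) {
  y <- as.numeric(y)
  if (length(y) < 2 || anyNA(y)) stop("need >= 2 non-missing responses")
  mean((y - mean(y))^2)
}

#' Held-out variance explained
#'
#' One minus the ratio of the cross-validated MSE to the baseline MSE of
#' the constant-mean predictor. The raw value can be negative when the
#' model generalizes worse than the mean (overfitting); the nominal value
#' clamps at 0 for reporting, and both are returned.
#'
#' @param mse cross-validated mean squared error.
#' @param baseline baseline MSE, must be > 0.
#' @return List with `raw` and `nominal` (in `[0, 1]`).
#' @export
variance_explained <- function(mse, baseline) {
  if (!is.finite(baseline) || baseline <= 0) stop("baseline MSE must be > 0")
  raw <- 1 - mse / baseline
  list(raw = raw, nominal = max(0, raw))
}

#' Outer leave-one-out evaluation of a learning pipeline
#'
#' For each patient in turn, the patient is withheld, the entire pipeline —
#' feature encoding on the included categories, median imputation,
#' standardization, and (for the elastic net) hyperparameter selection by
#' inner leave-one-out — is fitted on the remaining patients, and the
#' held-out patient's log clonal expansion is predicted. The average
#' held-out squared error estimates the pipeline's error on previously
#' unseen patients; training-set error is never reported as a performance
#' measure.
#'
#' @param cohort an `expn_cohort` with responses recorded for all patients.
#' @param model_spec `"elastic_net"` (default), `"random_forest"` or
#'   `"mean"` (constant training-mean predictor).
#' @param include_categories attribute categories available to the model.
#' @param config model configuration ([elastic_net_config()] or
#'   [random_forest_config()]); defaults per model.
#' @param seed integer seed; per-fold substreams are derived from
#'   `(seed, patient_id)` so results do not depend on fold order. The
#'   elastic-net and mean pipelines are deterministic; the seed matters for
#'   the random forest.
#' @param pseudocount,log_base response transform, see [derive_response()].
#' @return An object of class `expn_loocv`: per-patient `predictions` and
#'   `squared_errors`, `mse`, `baseline_mse`, `variance_explained_raw`,
#'   `variance_explained_nominal`, and — for the elastic net — a `folds`
#'   data frame (per-fold selected rho, lambda, retained-feature count)
#'   plus the per-fold coefficient matrix `fold_betas` and
#'   `fold_intercepts`.
#' @export
run_loocv <- function(cohort,
                      model_spec = c("elastic_net", "random_forest", "mean"),
                      include_categories = c("clinical", "tumor",
                                             "circulating"),
                      config = NULL, seed = 1L,
                      pseudocount = 1, log_base = exp(1)) {
  stopifnot(inherits(cohort, "expn_cohort"))
  model_spec <- match.arg(model_spec)
  n <- n_patients(cohort)
  if (n < 3) stop("need at least 3 patients for leave-one-out evaluation")
  y <- derive_response(cohort, pseudocount = pseudocount,
                       log_base = log_base)
  ids <- cohort$data$patient_id
  feats <- encode_features(cohort, include_categories)

  folds <- NULL
  fold_betas <- NULL
  fold_intercepts <- NULL
  if (model_spec == "elastic_net") {
    if (is.null(config)) config <- elastic_net_config()
    res <- tryCatch(
      nested_loocv_enet_cpp(feats$values, y, config$l1_ratio_grid,
                            config$lambda_path_size,
                            config$lambda_min_ratio, config$tolerance,
                            config$max_iterations),
      error = function(e) {
        stop("leave-one-out evaluation failed: ", conditionMessage(e),
             call. = FALSE)
      })
    preds <- as.numeric(res$predictions)
    folds <- data.frame(patient_id = ids,
                        rho = as.numeric(res$rho),
                        lambda = as.numeric(res$lambda),
                        n_retained = as.integer(res$n_retained),
                        stringsAsFactors = FALSE)
    fold_betas <- res$betas
    rownames(fold_betas) <- colnames(feats$values)
    colnames(fold_betas) <- ids
    fold_intercepts <- as.numeric(res$intercepts)
  } else if (model_spec == "mean") {
    preds <- vapply(seq_len(n), function(i) mean(y[-i]), numeric(1))
  } else {
    if (is.null(config)) config <- random_forest_config(seed = seed)
    preds <- numeric(n)
    for (i in seq_len(n)) {
      train <- subset_features(feats, setdiff(seq_len(n), i))
      pp <- fit_preprocessor(train)
      fold_cfg <- config
      fold_cfg$seed <- substream_seed(seed, "rf-fold", ids[i])
      fit <- fit_random_forest(apply_preprocessor(pp, train), y[-i],
                               fold_cfg)
      held <- apply_preprocessor(pp, subset_features(feats, i))
      preds[i] <- predict(fit, held$values)
    }
  }

  sq <- (y - preds)^2
  mse <- mean(sq)
  base <- baseline_mse(y)
  ve <- variance_explained(mse, base)
  structure(list(patient_id = ids, y = unname(y),
                 predictions = preds, squared_errors = unname(sq),
                 mse = mse, baseline_mse = base,
                 variance_explained_raw = ve$raw,
                 variance_explained_nominal = ve$nominal,
                 folds = folds, fold_betas = fold_betas,
                 fold_intercepts = fold_intercepts,
                 model_spec = model_spec,
                 include_categories = include_categories, seed = seed),
            class = "expn_loocv")
}

#' @export
print.expn_loocv <- function(x, ...) {
  cat(sprintf(
    "<LOOCV (%s, %d patients): MSE %.3f, baseline %.3f, VE %.1f%% (nominal %.1f%%)>\n",
    x$model_spec, length(x$y), x$mse, x$baseline_mse,
    100 * x$variance_explained_raw, 100 * x$variance_explained_nominal))
  invisible(x)
}

#' Category-ablation analysis
#'
#' Repeats the leave-one-out evaluation with each attribute category
#' (clinical, tumor, circulating) excluded in turn, alongside the
#' all-categories reference run. A category whose removal collapses the
#' held-out variance explained carries information the remaining
#' categories cannot substitute.
#'
#' @inheritParams run_loocv
#' @param categories categories to ablate (default all three).
#' @return Named list of `expn_loocv` results: `all` for the reference run
#'   and, per category, the run with that category excluded.
#' @export
ablate_categories <- function(cohort,
                              model_spec = c("elastic_net", "random_forest",
                                             "mean"),
                              config = NULL, seed = 1L,
                              categories = c("clinical", "tumor",
                                             "circulating"),
                              pseudocount = 1, log_base = exp(1)) {
  model_spec <- match.arg(model_spec)
  all_cats <- c("clinical", "tumor", "circulating")
  out <- list(all = run_loocv(cohort, model_spec, all_cats, config, seed,
                              pseudocount, log_base))
  for (cat in categories) {
    out[[cat]] <- run_loocv(cohort, model_spec, setdiff(all_cats, cat),
                            config, seed, pseudocount, log_base)
  }
  out
}

#' Tabulate an ablation analysis
#'
#' @param ablation result of [ablate_categories()].
#' @return Data frame with one row per run: excluded category, MSE,
#'   baseline MSE and raw/nominal variance explained.
#' @export
ablation_table <- function(ablation) {
  do.call(rbind, lapply(names(ablation), function(nm) {
    r <- ablation[[nm]]
    data.frame(excluded = if (nm == "all") "none" else nm,
               mse = r$mse, baseline_mse = r$baseline_mse,
               variance_explained_raw = r$variance_explained_raw,
               variance_explained_nominal = r$variance_explained_nominal,
               stringsAsFactors = FALSE)
  }))
}

#' Serialize a LOOCV result
#'
#' Writes the per-patient table (id, response, held-out prediction, squared
#' error) as TSV and the summary statistics as JSON.
#'
#' @param loocv an `expn_loocv`.
#' @param path_tsv,path_json output paths (either may be `NULL` to skip).
#' @return Invisibly, the summary list written to JSON.
#' @export
write_loocv <- function(loocv, path_tsv = NULL, path_json = NULL) {
  stopifnot(inherits(loocv, "expn_loocv"))
  if (!is.null(path_tsv)) {
    d <- data.frame(patient_id = loocv$patient_id, y = loocv$y,
                    prediction = loocv$predictions,
                    squared_error = loocv$squared_errors,
                    stringsAsFactors = FALSE)
    write.table(d, path_tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  summary <- list(model_spec = loocv$model_spec,
                  include_categories = loocv$include_categories,
                  n = length(loocv$y), mse = loocv$mse,
                  baseline_mse = loocv$baseline_mse,
                  variance_explained_raw = loocv$variance_explained_raw,
                  variance_explained_nominal =
                    loocv$variance_explained_nominal,
                  seed = loocv$seed)
  if (!is.null(path_json)) {
    jsonlite::write_json(summary, path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(summary)
}
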