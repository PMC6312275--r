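#' Exact-valid permutation p-value
#'
#' One-sided: a small cross-validated error is evidence of association, so
#' `p = (#\{b : null_b <= observed\} + 1) / (B + 1)`. The add-one
#' convention makes the test exactly valid (the p-value is super-uniform
#' under the null) and bounds it below by `1/(B+1)`.
#'
#' @param observed observed statistic (LOOCV MSE on the unpermuted data).
#' @param null_draws numeric vector of B null statistics.
#' @return Scalar p-value in `[1/(B+1), 1]`.
#' @export
permutation_p_value <- function(observed, null_draws) {
  if (length(null_draws) < 1) stop("need at least one null draw")
  stopifnot(is.finite(observed), all(is.finite(null_draws)))
  (sum(null_draws <= observed) + 1) / (length(null_draws) + 1)
}

#' Global permutation test of feature–response association
#'
#' Tests the null hypothesis of no association between the pre-treatment
#' features and clonal expansion: the observed LOOCV MSE is compared with
#' the distribution of LOOCV MSEs obtained when patient responses are
#' permuted across the cohort uniformly at random. Every replicate reruns
#' the full pipeline — per-fold preprocessing and hyperparameter selection
#' included — on the permuted cohort. The null is rejected when the
#' observed error is unusually small.
#'
#' @inheritParams run_loocv
#' @param B number of permutation replicates (>= 1).
#' @param seed integer; replicate b uses an RNG substream derived from
#'   `(seed, b)`, so results are independent of execution order.
#' @return An object of class `expn_permtest`: `observed_stat`,
#'   `null_draws` (length B), `p_value`, `B`, `seed`,
#'   `permuted_target = "response"` and the observed `expn_loocv`.
#' @export
permute_response_test <- function(cohort,
                                  model_spec = c("elastic_net",
                                                 "random_forest", "mean"),
                                  include_categories = c("clinical",
                                                         "tumor",
                                                         "circulating"),
                                  B = 1000, config = NULL, seed = 1L,
                                  pseudocount = 1, log_base = exp(1)) {
  model_spec <- match.arg(model_spec)
  stopifnot(B >= 1)
  observed <- run_loocv(cohort, model_spec, include_categories, config,
                        seed, pseudocount, log_base)
  n <- n_patients(cohort)
  null_draws <- vapply(seq_len(B), function(b) {
    perm <- with_seed(substream_seed(seed, "perm-response", b),
                      sample.int(n))
    permuted <- cohort
    permuted$data$expanded_clone_count <-
      cohort$data$expanded_clone_count[perm]
    run_loocv(permuted, model_spec, include_categories, config,
              substream_seed(seed, "loocv", b), pseudocount, log_base)$mse
  }, numeric(1))
  new_permtest(observed, null_draws, B, seed, "response")
}

#' Conditional permutation test for one attribute category
#'
#' Tests whether the attributes of one category (clinical, tumor or
#' circulating) are associated with clonal expansion *given that the
#' remaining features stay available to the model*. Each replicate draws a
#' single random permutation of patients and applies it jointly to every
#' attribute of the category — the category block moves between patients
#' as a unit, at the raw-attribute level before encoding, so each
#' `(x, log(1+x))` column pair and the within-category correlation
#' structure stay intact. The full LOOCV pipeline is rerun on each
#' permuted cohort.
#'
#' @inheritParams permute_response_test
#' @param category the category whose attributes are permuted.
#' @return An `expn_permtest` with `permuted_target = category`.
#' @export
permute_category_test <- function(cohort, category,
                                  model_spec = c("elastic_net",
                                                 "random_forest", "mean"),
                                  B = 1000, config = NULL, seed = 1L,
                                  pseudocount = 1, log_base = exp(1)) {
  model_spec <- match.arg(model_spec)
  stopifnot(B >= 1)
  if (!category %in% cohort$schema$category) {
    stop("unknown category: ", category)
  }
  attrs <- cohort$schema$name[cohort$schema$category == category]
  observed <- run_loocv(cohort, model_spec,
                        c("clinical", "tumor", "circulating"), config,
                        seed, pseudocount, log_base)
  n <- n_patients(cohort)
  null_draws <- vapply(seq_len(B), function(b) {
    perm <- with_seed(substream_seed(seed, "perm-category", category, b),
                      sample.int(n))
    permuted <- cohort
    permuted$data[attrs] <- cohort$data[perm, attrs, drop = FALSE]
    run_loocv(permuted, model_spec,
              c("clinical", "tumor", "circulating"), config,
              substream_seed(seed, "loocv", category, b), pseudocount,
              log_base)$mse
  }, numeric(1))
  new_permtest(observed, null_draws, B, seed, category)
}

new_permtest <- function(observed_loocv, null_draws, B, seed, target) {
  structure(list(observed_stat = observed_loocv$mse,
                 null_draws = null_draws,
                 p_value = permutation_p_value(observed_loocv$mse,
                                               null_draws),
                 B = as.integer(B), seed = as.integer(seed),
                 permuted_target = target,
                 observed_loocv = observed_loocv),
            class = "expn_permtest")
}

#' @export
print.expn_permtest <- function(x, ...) {
  cat(sprintf(
    "<permutation test (%s, B = %d): observed MSE %.3f, p %s>\n",
    x$permuted_target, x$B, x$observed_stat, format_p(x$p_value, x$B)))
  invisible(x)
}

# report "p < k/(B+1)" style bounds for extreme p-values, else the value
format_p <- function(p, B) {
  k <- round(p * (B + 1))
  if (k <= max(1, B %/% 100)) sprintf("< %.3g", (k + 1) / (B + 1))
  else sprintf("= %.4g", p)
}

#' Serialize a permutation-test result to JSON
#'
#' @param test an `expn_permtest`.
#' @param path output path.
#' @return Invisibly, the list written.
#' @export
write_permtest <- function(test, path) {
  stopifnot(inherits(test, "expn_permtest"))
  out <- list(permuted_target = test$permuted_target,
              observed_stat = test$observed_stat,
              p_value = test$p_value, B = test$B, seed = test$seed,
              null_draws = test$null_draws)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(out)
}
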