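#' Default per-attribute generators for synthetic cohorts
#'
#' Marginal distributions emulating the shape of a pre-treatment bladder
#' cancer cohort: binary attributes are Bernoulli; count-like attributes
#' (mutation and neoantigen loads, TCR counts, chemotherapy history) are
#' rounded log-normals spanning realistic orders of magnitude; bounded
#' fractions (clonality, T-cell fraction, top-clone frequency) are scaled
#' Betas. Only marginal shapes are emulated; the joint attribute
#' covariance of a real cohort is not.
#'
#' @param schema an [attribute_schema()].
#' @return Named list of generator specs, one per schema attribute.
#' @export
default_attribute_generators <- function(schema = default_schema()) {
  gens <- list(
    prior_bcg = list(dist = "bernoulli", p = 0.33),
    age = list(dist = "lognormal", meanlog = log(65), sdlog = 0.12),
    albumin_lt_4 = list(dist = "bernoulli", p = 0.3),
    neutrophil_lymphocyte_ratio = list(dist = "lognormal",
                                       meanlog = log(3.5), sdlog = 0.45),
    days_since_last_chemo = list(dist = "lognormal", meanlog = log(300),
                                 sdlog = 0.8, round = TRUE),
    five_factor_score = list(dist = "lognormal", meanlog = log(1.2),
                             sdlog = 0.6, round = TRUE),
    chemo_regimen_count = list(dist = "lognormal", meanlog = log(1.5),
                               sdlog = 0.5, round = TRUE),
    missense_snv_count = list(dist = "lognormal", meanlog = log(150),
                              sdlog = 0.9, round = TRUE),
    expressed_missense_snv_count = list(dist = "lognormal",
                                        meanlog = log(80), sdlog = 0.9,
                                        round = TRUE),
    neoantigen_count = list(dist = "lognormal", meanlog = log(60),
                            sdlog = 0.9, round = TRUE),
    expressed_neoantigen_count = list(dist = "lognormal",
                                      meanlog = log(30), sdlog = 0.9,
                                      round = TRUE),
    tumor_clonality = list(dist = "beta", shape1 = 2, shape2 = 8,
                           scale = 1),
    tumor_diversity = list(dist = "lognormal", meanlog = log(300),
                           sdlog = 1),
    tumor_t_cell_fraction = list(dist = "beta", shape1 = 1.5, shape2 = 8,
                                 scale = 1),
    productive_tcr_count = list(dist = "lognormal", meanlog = log(3e4),
                                sdlog = 0.7, round = TRUE),
    blood_clonality = list(dist = "beta", shape1 = 2, shape2 = 10,
                           scale = 1),
    blood_diversity = list(dist = "lognormal", meanlog = log(1e5),
                           sdlog = 1),
    blood_t_cell_fraction = list(dist = "beta", shape1 = 4, shape2 = 6,
                                 scale = 1),
    top_clone_frequency = list(dist = "beta", shape1 = 1.5, shape2 = 20,
                               scale = 100)
  )
  missing <- setdiff(schema$name, names(gens))
  for (nm in missing) {
    gens[[nm]] <- if (schema$kind[schema$name == nm] == "binary") {
      list(dist = "bernoulli", p = 0.5)
    } else {
      list(dist = "lognormal", meanlog = 0, sdlog = 1)
    }
  }
  gens[schema$name]
}

#' Simulation configuration for synthetic cohorts
#'
#' Defines the study conditions the generator emulates: a small cohort
#' (default 21 patients) with the standard 19-attribute schema, a sparse
#' linear signal of `support_size` nonzero coefficients placed on
#' standardized encoded `log(1+x)` columns, Gaussian noise sized either
#' directly (`noise_sd`) or via the oracle variance explained
#' (`target_ve`, default 0.8 — a high but imperfect signal, the regime the
#' model is designed for with p = 36 > n = 21), occasional missingness on
#' continuous attributes, and a logistic link tying durable clinical
#' benefit to the noiseless linear predictor.
#'
#' @param n_patients cohort size (default 21).
#' @param schema an [attribute_schema()] (default [default_schema()]).
#' @param attribute_generators per-attribute distribution specs (default
#'   [default_attribute_generators()]).
#' @param missing_rate probability that a missingness-tolerant attribute
#'   value is masked, in `[0, 0.2]` (default 0.05).
#' @param support_size number of nonzero true coefficients k (0 = null
#'   cohort).
#' @param coefficient_scale magnitude of each true coefficient on the
#'   standardized encoded columns (default 1; signs are random).
#' @param noise_sd response noise standard deviation; `NULL` (default) to
#'   derive it from `target_ve`.
#' @param target_ve oracle variance explained
#'   `Var(lp) / (Var(lp) + sigma^2)` used to size the noise when
#'   `noise_sd` is `NULL` (default 0.8). Ignored when `support_size = 0`
#'   (noise defaults to sd 0.9).
#' @param signal_categories restrict the true support to encoded columns
#'   from these categories (`NULL` = any category).
#' @param response_intercept baseline log expansion level (default 2.5,
#'   i.e. a typical patient has about a dozen expanded clones).
#' @param dcb_link `c(intercept, slope)` of the logistic model
#'   `P(DCB = 1) = plogis(intercept + slope * z)` where `z` is the
#'   standardized noiseless linear predictor (defaults -0.3 and 1.5: DCB
#'   in roughly 40% of patients, positively linked to expansion).
#' @param pseudocount pseudocount of the response transform (default 1).
#' @param seed integer seed; all draws come from substreams keyed on it.
#' @return A list of class `expn_sim_config`.
#' @export
simulation_config <- function(n_patients = 21, schema = default_schema(),
                              attribute_generators =
                                default_attribute_generators(schema),
                              missing_rate = 0.05, support_size = 4,
                              coefficient_scale = 1, noise_sd = NULL,
                              target_ve = 0.8, signal_categories = NULL,
                              response_intercept = 2.5,
                              dcb_link = c(intercept = -0.3, slope = 1.5),
                              pseudocount = 1, seed = 1L) {
  stopifnot(n_patients >= 1, missing_rate >= 0, missing_rate <= 0.2,
            support_size >= 0, coefficient_scale >= 0,
            is.null(noise_sd) || noise_sd >= 0,
            is.null(target_ve) || (target_ve > 0 && target_ve < 1),
            length(dcb_link) == 2)
  miss <- setdiff(schema$name, names(attribute_generators))
  if (length(miss)) {
    stop("no generator for attribute(s): ", paste(miss, collapse = ", "))
  }
  structure(list(n_patients = as.integer(n_patients), schema = schema,
                 attribute_generators = attribute_generators,
                 missing_rate = missing_rate,
                 support_size = as.integer(support_size),
                 coefficient_scale = coefficient_scale,
                 noise_sd = noise_sd, target_ve = target_ve,
                 signal_categories = signal_categories,
                 response_intercept = response_intercept,
                 dcb_link = c(intercept = unname(dcb_link[1]),
                              slope = unname(dcb_link[2])),
                 pseudocount = pseudocount, seed = as.integer(seed)),
            class = "expn_sim_config")
}

draw_attribute <- function(gen, n) {
  v <- switch(gen$dist,
    bernoulli = rbinom(n, 1, gen$p),
    lognormal = exp(rnorm(n, gen$meanlog, gen$sdlog)),
    beta = gen$scale * stats::rbeta(n, gen$shape1, gen$shape2),
    stop("unknown generator distribution: ", gen$dist))
  if (isTRUE(gen$round)) v <- round(v)
  v
}

#' Simulate a cohort with known ground truth
#'
#' Draws attributes from the configured marginals, encodes and
#' standardizes them, places `support_size` true coefficients on encoded
#' columns (preferring the `log(1+x)` transforms, matching the model
#' family), and generates `response = intercept + X beta + N(0, sigma)`.
#' The expanded clone count is `max(0, round(exp(response) -
#' pseudocount))`, so the recorded count quantizes the latent response.
#' DCB labels follow the logistic link on the noiseless linear predictor,
#' missing cells are masked on missingness-tolerant attributes only, and a
#' `bajorin_score` fallback column and a PD-L1 comparator (weakly linked
#' to the signal) are attached. Fully reproducible from the seed.
#'
#' @param config an [simulation_config()].
#' @return List with `cohort` (a validated `expn_cohort`) and `truth`
#'   (class `expn_ground_truth`: named true `beta` over encoded columns,
#'   `intercept`, `noise_sd`, per-patient `linear_predictor` and
#'   pre-quantization `latent_response`, `support` and
#'   `oracle_ve = Var(lp) / (Var(lp) + sigma^2)`, variances with
#'   denominator n).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "expn_sim_config"))
  n <- config$n_patients
  s <- config$schema

  d <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                  stringsAsFactors = FALSE)
  attr_seed <- substream_seed(config$seed, "attributes")
  vals <- with_seed(attr_seed, {
    out <- list()
    for (nm in s$name) {
      out[[nm]] <- draw_attribute(config$attribute_generators[[nm]], n)
    }
    out
  })
  for (nm in s$name) d[[nm]] <- vals[[nm]]

  complete <- cohort_table(d, s)
  feats <- encode_features(complete)
  pp <- fit_preprocessor(feats)
  Xs <- apply_preprocessor(pp, feats)$values
  p <- ncol(Xs)

  # sparse truth on encoded columns; prefer log1p transforms (binary
  # columns are eligible when a category holds no continuous attribute)
  pool <- which(feats$columns$transform == "log1p")
  if (!is.null(config$signal_categories)) {
    pool <- intersect(pool,
                      which(feats$columns$category %in%
                              config$signal_categories))
    if (length(pool) == 0) {
      pool <- which(feats$columns$category %in% config$signal_categories)
    }
  }
  k <- config$support_size
  if (k > length(pool)) {
    stop(sprintf("support_size %d exceeds the %d eligible encoded columns",
                 k, length(pool)))
  }
  beta <- numeric(p)
  names(beta) <- feats$columns$name
  if (k > 0) {
    sup <- with_seed(substream_seed(config$seed, "support"), {
      idx <- pool[sample.int(length(pool), k)]
      signs <- sample(c(-1, 1), k, replace = TRUE)
      list(idx = idx, signs = signs)
    })
    beta[sup$idx] <- config$coefficient_scale * sup$signs
  }

  lp <- as.numeric(Xs %*% beta)
  var_lp <- mean((lp - mean(lp))^2)
  sigma <- config$noise_sd
  if (is.null(sigma)) {
    sigma <- if (k == 0 || var_lp == 0) 0.9
             else sqrt(var_lp * (1 - config$target_ve) / config$target_ve)
  }
  noise <- with_seed(substream_seed(config$seed, "noise"),
                     rnorm(n, 0, sigma))
  latent <- config$response_intercept + lp + noise
  d$expanded_clone_count <- pmax(0, round(exp(latent) -
                                            config$pseudocount))

  z <- if (var_lp > 0) (lp - mean(lp)) / sqrt(var_lp) else rep(0, n)
  d$dcb <- with_seed(substream_seed(config$seed, "dcb"), {
    rbinom(n, 1, plogis(config$dcb_link[["intercept"]] +
                          config$dcb_link[["slope"]] * z))
  })
  d$pd_l1_staining_pct <- with_seed(substream_seed(config$seed, "pdl1"), {
    round(100 * plogis(-0.8 + 0.7 * z + rnorm(n)), 1)
  })
  d$bajorin_score <- with_seed(substream_seed(config$seed, "bajorin"),
                               sample(0:2, n, replace = TRUE))

  if (config$missing_rate > 0) {
    maskable <- s$name[s$allow_missing]
    mask <- with_seed(substream_seed(config$seed, "missing"), {
      matrix(runif(n * length(maskable)) < config$missing_rate, n,
             length(maskable))
    })
    for (j in seq_along(maskable)) {
      d[[maskable[j]]][mask[, j]] <- NA
    }
  }

  truth <- structure(list(beta = beta, support = names(beta)[beta != 0],
                          intercept = config$response_intercept,
                          noise_sd = sigma, linear_predictor = lp,
                          latent_response = latent,
                          oracle_ve = if (var_lp + sigma^2 > 0) {
                            var_lp / (var_lp + sigma^2)
                          } else 0,
                          columns = feats$columns, seed = config$seed),
                     class = "expn_ground_truth")
  list(cohort = cohort_table(d, s), truth = truth)
}

#' Simulate a null cohort (no feature–response association)
#'
#' [simulate_cohort()] with `support_size = 0`: the response is pure noise
#' around the intercept and carries no signal from any attribute. Used for
#' calibration experiments.
#'
#' @param config an [simulation_config()]; its `support_size` is ignored.
#' @return As [simulate_cohort()], with an empty true support.
#' @export
null_cohort <- function(config = simulation_config()) {
  config$support_size <- 0L
  simulate_cohort(config)
}

#' Support-recovery and accuracy report against ground truth
#'
#' Compares a fitted model's retained features with the true support:
#' precision (`NA` when nothing is retained), recall (`NA` for a null
#' truth), sign agreement of the fitted coefficients on the recovered true
#' support, and achieved held-out variance explained against the oracle
#' value.
#'
#' @param truth an `expn_ground_truth`.
#' @param loocv an `expn_loocv` for the same cohort.
#' @param fit an `expn_enet_fit` on the full cohort.
#' @return List with `support_precision`, `support_recall`,
#'   `sign_agreement`, `achieved_ve_raw`, `oracle_ve`, `n_retained`,
#'   `support_size`.
#' @export
recovery_report <- function(truth, loocv, fit) {
  stopifnot(inherits(truth, "expn_ground_truth"),
            inherits(loocv, "expn_loocv"),
            inherits(fit, "expn_enet_fit"))
  if (!identical(names(truth$beta), names(fit$coefficients))) {
    stop("encoded columns of the fit do not match the ground truth")
  }
  retained <- fit$retained_features
  support <- truth$support
  tp <- intersect(retained, support)
  precision <- if (length(retained)) length(tp) / length(retained)
               else NA_real_
  recall <- if (length(support)) length(tp) / length(support)
            else NA_real_
  sign_agree <- if (length(tp)) {
    mean(sign(fit$coefficients[tp]) == sign(truth$beta[tp]))
  } else NA_real_
  list(support_precision = precision, support_recall = recall,
       sign_agreement = sign_agree,
       achieved_ve_raw = loocv$variance_explained_raw,
       oracle_ve = truth$oracle_ve,
       n_retained = length(retained), support_size = length(support))
}

#' Write simulation ground truth as JSON
#'
#' @param truth an `expn_ground_truth`.
#' @param path output path.
#' @return Invisibly, the list written.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "expn_ground_truth"))
  out <- list(beta = as.list(truth$beta[truth$beta != 0]),
              support = truth$support, intercept = truth$intercept,
              noise_sd = truth$noise_sd, oracle_ve = truth$oracle_ve,
              linear_predictor = truth$linear_predictor,
              seed = truth$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(out)
}
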