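#' Elastic-net configuration
#'
#' Settings for the penalized fit: the grid of l1-ratio candidates rho, the
#' length and depth of the geometric lambda path, and the coordinate-descent
#' stopping rule. Defaults follow common practice for elastic-net model
#' selection on small cohorts: rho candidates concentrated near the lasso
#' end plus one ridge-leaning value, a 100-point lambda path, tolerance
#' 1e-7 and a generous iteration cap.
#'
#' @param l1_ratio_grid numeric vector of rho values in (0, 1].
#' @param lambda_path_size number of lambda values per rho (default 100).
#' @param lambda_min_ratio ratio of the smallest to the largest lambda on
#'   the path (default 1e-3).
#' @param tolerance coordinate-descent convergence tolerance on the maximum
#'   coefficient change per sweep (default 1e-7).
#' @param max_iterations iteration cap per solve (default 1e6).
#' @return A list of class `expn_enet_config`.
#' @export
elastic_net_config <- function(l1_ratio_grid = c(0.1, 0.5, 0.7, 0.9, 0.95,
                                                 0.99),
                               lambda_path_size = 100,
                               lambda_min_ratio = 1e-3,
                               tolerance = 1e-7,
                               max_iterations = 1e6) {
  stopifnot(all(l1_ratio_grid > 0), all(l1_ratio_grid <= 1),
            lambda_path_size >= 1, lambda_min_ratio > 0,
            lambda_min_ratio <= 1, tolerance > 0, max_iterations >= 1)
  structure(list(l1_ratio_grid = sort(as.numeric(l1_ratio_grid)),
                 lambda_path_size = as.integer(lambda_path_size),
                 lambda_min_ratio = lambda_min_ratio,
                 tolerance = tolerance,
                 max_iterations = as.integer(max_iterations)),
            class = "expn_enet_config")
}

#' Solve the elastic net at a fixed penalty
#'
#' Minimizes `(1/(2n)) * RSS + lambda * (rho * ||b||_1 +
#' (1-rho)/2 * ||b||_2^2)` with an unpenalized intercept, by coordinate
#' descent on centered data. This is the solver primitive; model selection
#' over `(rho, lambda)` lives in [fit_elastic_net()]. `rho = 0` (pure
#' ridge) is accepted here so the solution can be compared against the
#' ridge closed form.
#'
#' @param X numeric matrix without missing values.
#' @param y numeric response vector.
#' @param rho l1 ratio in \[0, 1\].
#' @param lambda penalty strength, >= 0.
#' @param tolerance,max_iterations stopping rule (see
#'   [elastic_net_config()]).
#' @return List with `beta` (length `ncol(X)`) and `intercept`.
#' @export
elastic_net_solve <- function(X, y, rho, lambda, tolerance = 1e-9,
                              max_iterations = 1e6) {
  X <- as.matrix(X)
  stopifnot(!anyNA(X), !anyNA(y), nrow(X) == length(y),
            rho >= 0, rho <= 1, lambda >= 0)
  res <- enet_solve_cpp(X, as.numeric(y), rho, lambda, tolerance,
                        as.integer(max_iterations))
  list(beta = as.numeric(res$beta), intercept = as.numeric(res$intercept))
}

#' Smallest penalty that zeroes every coefficient
#'
#' `lambda_max(rho) = max_j |sum_i x_ij (y_i - mean(y))| / (n * rho)`; at or
#' above this value the elastic-net solution is exactly `beta = 0`,
#' `intercept = mean(y)`.
#'
#' @inheritParams elastic_net_solve
#' @return The scalar `lambda_max`.
#' @export
elastic_net_lambda_max <- function(X, y, rho) {
  X <- as.matrix(X)
  stopifnot(!anyNA(X), !anyNA(y), rho > 0)
  enet_lambda_max_cpp(X, as.numeric(y), rho)
}

#' Fit the elastic net with leave-one-out hyperparameter selection
#'
#' For every rho in the grid, a geometric path of `lambda_path_size` values
#' from `lambda_max(rho)` down to `lambda_max * lambda_min_ratio` is scored
#' by leave-one-out cross-validation on `(X, y)`: each row is held out in
#' turn, the path is fitted on the rest (warm-started), and the held-out
#' squared error is recorded per `(rho, lambda)`. The pair minimizing the
#' mean held-out error is refitted on all rows. Ties (within 1e-12) break
#' toward the largest lambda, then the smallest rho — the sparser, more
#' regularized model.
#'
#' @param X preprocessed (imputed, standardized) feature matrix, or an
#'   `expn_features` with no missing cells.
#' @param y numeric response vector.
#' @param config an [elastic_net_config()].
#' @param preprocessor optionally, the fitted `expn_preprocessor` that
#'   produced `X`; stored so [predict.expn_enet_fit()] can take raw
#'   features.
#' @return An object of class `expn_enet_fit`: `intercept`, `coefficients`
#'   (named by column), selected `rho` and `lambda`, `retained_features`
#'   (names with nonzero coefficients), the cross-validation error surface
#'   (`cv_mse`, `lambdas`), and the `preprocessor`/`columns` metadata when
#'   available.
#' @export
fit_elastic_net <- function(X, y, config = elastic_net_config(),
                            preprocessor = NULL) {
  columns <- NULL
  if (inherits(X, "expn_features")) {
    columns <- X$columns
    X <- X$values
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (anyNA(X)) stop("X has missing cells; preprocess before fitting")
  if (nrow(X) < 3) stop("need at least 3 rows")
  if (nrow(X) != length(y)) stop("nrow(X) != length(y)")
  stopifnot(inherits(config, "expn_enet_config"))
  if (is.null(columns) && !is.null(preprocessor)) {
    columns <- preprocessor$columns
  }
  res <- enet_cv_fit_cpp(X, y, config$l1_ratio_grid,
                         config$lambda_path_size, config$lambda_min_ratio,
                         config$tolerance, config$max_iterations)
  beta <- as.numeric(res$beta)
  names(beta) <- if (!is.null(colnames(X))) colnames(X)
                 else paste0("V", seq_len(ncol(X)))
  structure(list(intercept = as.numeric(res$intercept),
                 coefficients = beta,
                 rho = as.numeric(res$rho),
                 lambda = as.numeric(res$lambda),
                 retained_features = names(beta)[beta != 0],
                 cv_mse = res$cv_mse,
                 lambdas = res$lambdas,
                 config = config,
                 columns = columns,
                 preprocessor = preprocessor),
            class = "expn_enet_fit")
}

#' @export
print.expn_enet_fit <- function(x, ...) {
  cat(sprintf(
    "<elastic-net fit: rho = %g, lambda = %.4g, %d/%d features retained>\n",
    x$rho, x$lambda, length(x$retained_features), length(x$coefficients)))
  invisible(x)
}

#' Predict from an elastic-net fit
#'
#' If the fit stores a preprocessor and `newdata` is a raw `expn_features`,
#' the stored training-fold imputation/standardization is applied first;
#' a plain numeric matrix is assumed to be preprocessed already.
#'
#' @param object an `expn_enet_fit`.
#' @param newdata an `expn_features` or numeric matrix with matching
#'   columns.
#' @param ... unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.expn_enet_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "expn_features")) {
    if (!is.null(object$preprocessor)) {
      newdata <- apply_preprocessor(object$preprocessor, newdata)
    } else if (anyNA(newdata$values)) {
      stop("raw features contain missing cells and the fit stores no preprocessor")
    }
    if (!is.null(object$columns) &&
        !identical(object$columns$name, newdata$columns$name)) {
      stop("feature columns do not match the fit")
    }
    newdata <- newdata$values
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients)) {
    stop("column count does not match the fit")
  }
  as.numeric(object$intercept + newdata %*% object$coefficients)
}

#' Elastic-net objective value
#'
#' `(1/(2n)) * RSS + lambda * (rho * ||beta||_1 + (1-rho)/2 *
#' ||beta||_2^2)`; used for diagnostics and invariant checks (the returned
#' solution is never worse than the null fit `beta = 0`).
#'
#' @param X,y data (no missing values).
#' @param beta,intercept candidate solution.
#' @param rho,lambda penalty.
#' @return Scalar objective value.
#' @export
elastic_net_objective <- function(X, y, beta, intercept, rho, lambda) {
  X <- as.matrix(X)
  r <- y - intercept - as.numeric(X %*% beta)
  sum(r^2) / (2 * nrow(X)) +
    lambda * (rho * sum(abs(beta)) + (1 - rho) / 2 * sum(beta^2))
}
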