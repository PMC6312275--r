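#' Random-forest comparator configuration
#'
#' The nonlinear comparator model: a regression forest with 1000 trees and
#' library defaults for every other hyperparameter (no tuning). On cohorts
#' of ~21 patients the forest overfits badly relative to the elastic net,
#' which is why it serves only as a comparator.
#'
#' @param n_trees number of trees (default 1000).
#' @param seed integer seed making the fit reproducible.
#' @return A list of class `expn_rf_config`.
#' @export
random_forest_config <- function(n_trees = 1000, seed = 1L) {
  stopifnot(n_trees >= 1)
  structure(list(n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "expn_rf_config")
}

#' Fit the random-forest comparator
#'
#' @param X preprocessed feature matrix (or `expn_features` without missing
#'   cells).
#' @param y numeric response.
#' @param config a [random_forest_config()].
#' @param preprocessor optional fitted `expn_preprocessor`, stored for
#'   prediction from raw features.
#' @return An object of class `expn_rf_fit` wrapping the fitted forest.
#' @export
fit_random_forest <- function(X, y, config = random_forest_config(),
                              preprocessor = NULL) {
  columns <- NULL
  if (inherits(X, "expn_features")) {
    columns <- X$columns
    X <- X$values
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (anyNA(X)) stop("X has missing cells; preprocess before fitting")
  if (nrow(X) < 2) stop("need at least 2 rows")
  stopifnot(inherits(config, "expn_rf_config"))
  forest <- with_seed(config$seed, {
    randomForest::randomForest(x = X, y = y, ntree = config$n_trees)
  })
  structure(list(forest = forest, config = config, columns = columns,
                 preprocessor = preprocessor),
            class = "expn_rf_fit")
}

#' @export
predict.expn_rf_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "expn_features")) {
    if (!is.null(object$preprocessor)) {
      newdata <- apply_preprocessor(object$preprocessor, newdata)
    }
    newdata <- newdata$values
  }
  as.numeric(predict(object$forest, as.matrix(newdata)))
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# deterministic 31-bit substream seed from a base seed and stream labels
substream_seed <- function(seed, ...) {
  labels <- c(seed, unlist(list(...)))
  h <- 0
  for (x in labels) {
    for (ch in utf8ToInt(as.character(x))) {
      h <- (h * 31 + ch) %% 2147483647
    }
    h <- (h * 131 + 7) %% 2147483647
  }
  as.integer(h)
}
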