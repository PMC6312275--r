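#' Encode cohort attributes into the model design matrix
#'
#' Binary attributes map to a single 0/1 column. Each continuous attribute
#' contributes a pair of columns — the raw value `x` and `log(1+x)` — so
#' mild nonlinear relationships between inputs and log clonal expansion can
#' be captured by a linear model. With the standard 19-attribute schema
#' (2 binary + 17 continuous) this yields the 36-column design. Missing
#' attribute values propagate to `NA` in both derived columns and are only
#' imputed later, inside each training fold.
#'
#' @param cohort an `expn_cohort`.
#' @param include_categories attribute categories to keep
#'   (default all three).
#' @return An object of class `expn_features`: a list with `values`
#'   (n x p numeric matrix, possibly with `NA`s) and `columns` (data frame
#'   with `name`, `source`, `transform` in `{identity, log1p}` and
#'   `category` per column).
#' @export
encode_features <- function(cohort,
                            include_categories = c("clinical", "tumor",
                                                   "circulating")) {
  stopifnot(inherits(cohort, "expn_cohort"))
  include_categories <- match.arg(include_categories,
                                  c("clinical", "tumor", "circulating"),
                                  several.ok = TRUE)
  s <- cohort$schema[cohort$schema$category %in% include_categories, ,
                     drop = FALSE]
  if (nrow(s) == 0) stop("no attributes in the requested categories")
  d <- cohort$data
  cols <- list()
  meta <- list()
  for (j in seq_len(nrow(s))) {
    nm <- s$name[j]
    v <- as.numeric(d[[nm]])
    if (any(!is.na(v) & v < 0)) {
      stop(sprintf("negative value in continuous attribute '%s'", nm))
    }
    if (s$kind[j] == "binary") {
      cols[[length(cols) + 1L]] <- v
      meta[[length(meta) + 1L]] <- c(nm, nm, "identity", s$category[j])
    } else {
      cols[[length(cols) + 1L]] <- v
      meta[[length(meta) + 1L]] <- c(nm, nm, "identity", s$category[j])
      cols[[length(cols) + 1L]] <- log1p(v)
      meta[[length(meta) + 1L]] <- c(paste0(nm, "_log1p"), nm, "log1p",
                                     s$category[j])
    }
  }
  values <- do.call(cbind, cols)
  columns <- as.data.frame(do.call(rbind, meta), stringsAsFactors = FALSE)
  names(columns) <- c("name", "source", "transform", "category")
  colnames(values) <- columns$name
  rownames(values) <- d$patient_id
  structure(list(values = values, columns = columns),
            class = "expn_features")
}

#' @export
print.expn_features <- function(x, ...) {
  cat(sprintf("<feature matrix: %d patients x %d columns (%d missing cells)>\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Fit a leakage-safe preprocessor on training rows
#'
#' Learns, per encoded column, the median of the non-missing training values
#' (for imputation) and then the mean and population standard deviation of
#' the imputed training column (for standardization). Both statistics come
#' from the training rows only, so applying the preprocessor to a held-out
#' row cannot leak information from that row into the model. A column that
#' is constant in training gets scale 1, which turns it into an all-zero
#' (uninformative) column after centering.
#'
#' @param train an `expn_features` of training rows; every column needs at
#'   least one non-missing value.
#' @return An object of class `expn_preprocessor` holding `medians`,
#'   `centers`, `scales` and the column metadata.
#' @export
fit_preprocessor <- function(train) {
  stopifnot(inherits(train, "expn_features"))
  X <- train$values
  p <- ncol(X)
  medians <- centers <- scales <- numeric(p)
  for (j in seq_len(p)) {
    v <- X[, j]
    obs <- v[!is.na(v)]
    if (length(obs) == 0) {
      stop(sprintf("column '%s' has no non-missing training values",
                   colnames(X)[j]))
    }
    medians[j] <- median(obs)
    v[is.na(v)] <- medians[j]
    centers[j] <- mean(v)
    s2 <- mean((v - centers[j])^2)          # denominator n
    scales[j] <- if (s2 > 0) sqrt(s2) else 1
  }
  structure(list(medians = medians, centers = centers, scales = scales,
                 columns = train$columns, fitted = TRUE),
            class = "expn_preprocessor")
}

#' Apply a fitted preprocessor
#'
#' Imputes missing cells with the stored training medians, then centers and
#' scales every column by the stored training statistics. The output has no
#' missing cells. The transformation of any row depends only on the training
#' rows the preprocessor was fitted on.
#'
#' @param pp a fitted `expn_preprocessor`.
#' @param m an `expn_features` whose columns match `pp`.
#' @return An `expn_features` with fully observed, standardized values.
#' @export
apply_preprocessor <- function(pp, m) {
  if (!inherits(pp, "expn_preprocessor") || !isTRUE(pp$fitted)) {
    stop("preprocessor is not fitted")
  }
  stopifnot(inherits(m, "expn_features"))
  if (!identical(pp$columns$name, m$columns$name)) {
    stop("column metadata does not match the preprocessor")
  }
  X <- m$values
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    v[is.na(v)] <- pp$medians[j]
    X[, j] <- (v - pp$centers[j]) / pp$scales[j]
  }
  structure(list(values = X, columns = m$columns), class = "expn_features")
}

#' Write a feature matrix to TSV with a JSON metadata sidecar
#'
#' @param m an `expn_features`.
#' @param path output TSV path; the column metadata is written next to it
#'   as `<path>.cols.json`.
#' @return `path`, invisibly.
#' @export
write_features <- function(m, path) {
  stopifnot(inherits(m, "expn_features"))
  d <- data.frame(patient_id = rownames(m$values), m$values,
                  check.names = FALSE, stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE,
              na = "NA")
  jsonlite::write_json(m$columns, paste0(path, ".cols.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

# rows -> expn_features subset (keeps metadata)
subset_features <- function(m, rows) {
  structure(list(values = m$values[rows, , drop = FALSE],
                 columns = m$columns),
            class = "expn_features")
}
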