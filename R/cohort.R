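#' Construct and validate a cohort table
#'
#' A cohort table pairs an attribute schema with one row per patient:
#' a unique `patient_id`, the schema'd pre-treatment attributes, the
#' post-treatment response `expanded_clone_count` (number of
#' tumor-infiltrating lymphocyte clones observed to expand in peripheral
#' blood after therapy), an optional durable-clinical-benefit label `dcb`
#' (1 = progression-free survival for at least six months) and optional
#' comparator biomarker columns such as `pd_l1_staining_pct`.
#'
#' @param data data frame with a `patient_id` column, one column per schema
#'   attribute, and optionally `expanded_clone_count`, `dcb`,
#'   `pd_l1_staining_pct`, `bajorin_score`.
#' @param schema an [attribute_schema()]; defaults to [default_schema()].
#' @return A validated object of class `expn_cohort`.
#' @export
cohort_table <- function(data, schema = default_schema()) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  obj <- structure(list(schema = schema, data = data),
                   class = "expn_cohort")
  validate_cohort(obj)
}

#' @export
print.expn_cohort <- function(x, ...) {
  n <- nrow(x$data)
  cat(sprintf("<cohort: %d patients, %d attributes>\n", n, nrow(x$schema)))
  if (n > 0) {
    has_y <- sum(!is.na(x$data$expanded_clone_count))
    has_dcb <- if ("dcb" %in% names(x$data)) sum(!is.na(x$data$dcb)) else 0
    cat(sprintf("  responses recorded: %d; DCB labels: %d\n", has_y, has_dcb))
  }
  invisible(x)
}

#' Validate a cohort table
#'
#' Checks patient-id uniqueness, that every attribute column appears in the
#' schema, value ranges (binary in \{0,1\}, continuous finite and >= 0,
#' counts non-negative integers, `dcb` in \{0,1\}) and missingness against
#' each attribute's `allow_missing` flag.
#'
#' @param cohort an `expn_cohort`.
#' @return The cohort, invisibly unchanged, or an error naming the offending
#'   row and column.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "expn_cohort"))
  d <- cohort$data
  s <- cohort$schema
  if (!"patient_id" %in% names(d)) stop("cohort data needs a patient_id column")
  if (anyDuplicated(d$patient_id)) {
    stop("duplicate patient_id: ",
         paste(unique(d$patient_id[duplicated(d$patient_id)]), collapse = ", "))
  }
  unknown <- setdiff(names(d), c(RESERVED_COLUMNS, s$name))
  if (length(unknown)) {
    stop("columns not in schema: ", paste(unknown, collapse = ", "))
  }
  missing_attrs <- setdiff(s$name, names(d))
  if (length(missing_attrs)) {
    stop("schema attributes absent from data: ",
         paste(missing_attrs, collapse = ", "))
  }
  for (j in seq_len(nrow(s))) {
    nm <- s$name[j]
    v <- d[[nm]]
    if (!is.numeric(v) && !is.logical(v)) {
      stop(sprintf("attribute '%s' is not numeric", nm))
    }
    v <- as.numeric(v)
    if (anyNA(v) && !s$allow_missing[j]) {
      stop(sprintf("attribute '%s' has missing values (rows %s) but does not allow them",
                   nm, paste(which(is.na(v)), collapse = ", ")))
    }
    obs <- which(!is.na(v))
    if (s$kind[j] == "binary") {
      bad <- obs[!(v[obs] %in% c(0, 1))]
      if (length(bad)) {
        stop(sprintf("binary attribute '%s' outside {0,1} at row %d (value %g)",
                     nm, bad[1], v[bad[1]]))
      }
    } else {
      bad <- obs[!is.finite(v[obs]) | v[obs] < 0]
      if (length(bad)) {
        stop(sprintf("continuous attribute '%s' negative or non-finite at row %d (value %g)",
                     nm, bad[1], v[bad[1]]))
      }
    }
    d[[nm]] <- v
  }
  if ("expanded_clone_count" %in% names(d)) {
    v <- d$expanded_clone_count
    obs <- which(!is.na(v))
    bad <- obs[!is.finite(v[obs]) | v[obs] < 0 | v[obs] != round(v[obs])]
    if (length(bad)) {
      stop(sprintf("expanded_clone_count must be a non-negative integer; row %d has %g",
                   bad[1], v[bad[1]]))
    }
  }
  if ("dcb" %in% names(d)) {
    v <- d$dcb
    obs <- which(!is.na(v))
    if (length(obs) && any(!(v[obs] %in% c(0, 1)))) {
      bad <- obs[!(v[obs] %in% c(0, 1))][1]
      stop(sprintf("dcb must be 0/1; row %d has %g", bad, v[bad]))
    }
  }
  if ("pd_l1_staining_pct" %in% names(d)) {
    v <- d$pd_l1_staining_pct
    obs <- which(!is.na(v))
    if (length(obs) && any(v[obs] < 0 | v[obs] > 100)) {
      stop("pd_l1_staining_pct must lie in [0, 100]")
    }
  }
  cohort$data <- d
  invisible(cohort)
}

#' Read a cohort table from CSV/TSV
#'
#' One row per patient; columns are `patient_id`, the schema attributes,
#' `expanded_clone_count`, and optionally `dcb`, `pd_l1_staining_pct` and
#' `bajorin_score`. Missing values are encoded by `na_token` (an empty cell
#' is always accepted as missing). The field separator is inferred from the
#' file extension (`.tsv`/`.txt` = tab, otherwise comma) unless given.
#'
#' @param path file path.
#' @param schema an [attribute_schema()].
#' @param sep field separator; `NULL` to infer from the extension.
#' @param na_token string encoding a missing value (default `"NA"`).
#' @return A validated `expn_cohort`; row order follows the file.
#' @export
load_cohort <- function(path, schema = default_schema(), sep = NULL,
                        na_token = "NA") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  d <- read.table(path, header = TRUE, sep = sep, quote = "\"",
                  na.strings = c(na_token, ""), check.names = FALSE,
                  stringsAsFactors = FALSE, colClasses = NA,
                  encoding = "UTF-8")
  # type check with row/column reporting before structural validation
  for (nm in intersect(names(d), c(schema$name, setdiff(RESERVED_COLUMNS,
                                                        "patient_id")))) {
    v <- d[[nm]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad)) {
        stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                     v[bad[1]], nm, bad[1]))
      }
      d[[nm]] <- num
    }
  }
  d$patient_id <- as.character(d$patient_id)
  tryCatch(cohort_table(d, schema), error = function(e) {
    stop(sprintf("invalid cohort file '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Write a cohort table to CSV/TSV
#'
#' Inverse of [load_cohort()]: writes `patient_id`, the attribute columns in
#' schema order, then the reserved columns present. Missing cells are written
#' as the `na_token`, so `load -> write -> load` round-trips exactly.
#'
#' @param cohort an `expn_cohort`.
#' @param path output path; separator inferred from the extension.
#' @param sep,na_token as in [load_cohort()].
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = NULL, na_token = "NA") {
  stopifnot(inherits(cohort, "expn_cohort"))
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  cols <- c("patient_id", cohort$schema$name,
            intersect(setdiff(RESERVED_COLUMNS, "patient_id"),
                      names(cohort$data)))
  write.table(cohort$data[, cols, drop = FALSE], path, sep = sep,
              row.names = FALSE, quote = FALSE, na = na_token,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Substitute a fallback score for a missing primary attribute
#'
#' Clinical risk scores are sometimes unavailable for individual patients
#' (e.g. a 5-factor prognostic score is undefined when therapy was given
#' first line); a closely related score recorded in a companion column can
#' stand in. For every patient whose `primary` attribute is missing, the
#' value of the `fallback` column is copied in; all other values are left
#' untouched, so the operation is idempotent.
#'
#' @param cohort an `expn_cohort`.
#' @param primary attribute name to repair (default `"five_factor_score"`).
#' @param fallback name of the column holding the substitute score
#'   (default `"bajorin_score"`).
#' @param strict if `TRUE`, a patient missing both values is an error;
#'   otherwise the value stays missing and is imputed downstream.
#' @return The repaired `expn_cohort`.
#' @export
apply_score_fallback <- function(cohort, primary = "five_factor_score",
                                 fallback = "bajorin_score",
                                 strict = FALSE) {
  stopifnot(inherits(cohort, "expn_cohort"))
  if (!primary %in% cohort$schema$name) {
    stop("primary attribute not in schema: ", primary)
  }
  d <- cohort$data
  miss <- is.na(d[[primary]])
  if (!any(miss)) return(cohort)
  if (!fallback %in% names(d)) {
    if (strict) stop("fallback column absent: ", fallback)
    return(cohort)
  }
  fb <- d[[fallback]]
  unresolved <- miss & is.na(fb)
  if (strict && any(unresolved)) {
    stop("missing both '", primary, "' and '", fallback, "' for patient(s): ",
         paste(d$patient_id[unresolved], collapse = ", "))
  }
  d[[primary]][miss & !is.na(fb)] <- fb[miss & !is.na(fb)]
  cohort$data <- d
  validate_cohort(cohort)
}

#' Derive the log clonal-expansion response
#'
#' The modelled response is the log number of tumor-infiltrating lymphocyte
#' clones that expanded in the blood after therapy. Because a patient can
#' have zero expanded clones, a pseudocount keeps the transform total:
#' `response = log(pseudocount + count)`, natural log by default. The
#' transform is strictly monotone in the count for any fixed pseudocount.
#'
#' @param cohort an `expn_cohort`; every patient must have
#'   `expanded_clone_count` recorded.
#' @param pseudocount non-negative offset added before the log (default 1).
#' @param log_base base of the logarithm: `exp(1)` (default) or `10`.
#' @return Numeric vector, one response per patient, named by `patient_id`.
#' @export
derive_response <- function(cohort, pseudocount = 1, log_base = exp(1)) {
  stopifnot(inherits(cohort, "expn_cohort"), pseudocount >= 0)
  counts <- cohort$data$expanded_clone_count
  if (is.null(counts) || anyNA(counts)) {
    bad <- if (is.null(counts)) cohort$data$patient_id
           else cohort$data$patient_id[is.na(counts)]
    stop("expanded_clone_count missing for patient(s): ",
         paste(bad, collapse = ", "))
  }
  y <- log(pseudocount + counts) / log(log_base)
  names(y) <- cohort$data$patient_id
  y
}

#' Number of patients in a cohort
#' @param cohort an `expn_cohort`.
#' @return Integer patient count.
#' @export
n_patients <- function(cohort) nrow(cohort$data)
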