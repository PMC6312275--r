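#' Attribute schema for a patient cohort
#'
#' An attribute schema describes the pre-treatment patient attributes a
#' cohort table may carry: each attribute has a unique name, a category
#' (`"clinical"`, `"tumor"` or `"circulating"`), a kind (`"binary"` or
#' `"continuous"`) and a flag saying whether missing values are allowed.
#' Binary attributes take values in \{0, 1\}; continuous attributes are
#' finite and non-negative.
#'
#' @param name character vector of unique attribute names.
#' @param category character vector, one of `"clinical"`, `"tumor"`,
#'   `"circulating"` per attribute.
#' @param kind character vector, `"binary"` or `"continuous"` per attribute.
#' @param allow_missing logical vector; whether `NA` values are tolerated
#'   for the attribute (they are later imputed inside each training fold).
#' @return A data frame of class `expn_schema` with one row per attribute.
#' @seealso [default_schema()] for the standard 19-attribute schema.
#' @export
attribute_schema <- function(name, category, kind,
                             allow_missing = kind == "continuous") {
  stopifnot(is.character(name), length(name) >= 1)
  if (anyDuplicated(name)) {
    stop("attribute names must be unique: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  category <- match_each(category, c("clinical", "tumor", "circulating"),
                         length(name), "category")
  kind <- match_each(kind, c("binary", "continuous"), length(name), "kind")
  allow_missing <- rep_len(as.logical(allow_missing), length(name))
  structure(
    data.frame(name = name, category = category, kind = kind,
               allow_missing = allow_missing, stringsAsFactors = FALSE),
    class = c("expn_schema", "data.frame")
  )
}

match_each <- function(x, choices, n, what) {
  x <- rep_len(as.character(x), n)
  bad <- !x %in% choices
  if (any(bad)) {
    stop("invalid ", what, ": ", paste(unique(x[bad]), collapse = ", "))
  }
  x
}

#' The standard pre-treatment attribute schema
#'
#' Nineteen attributes collected before anti-PD-L1 therapy: 7 clinical,
#' 7 tumor and 5 circulating. Exactly two (`prior_bcg`, `albumin_lt_4`) are
#' binary; the remaining 17 are non-negative continuous measurements, each of
#' which contributes a raw and a `log(1+x)` column to the encoded design, for
#' 2 + 17 x 2 = 36 model features. Continuous attributes may be missing
#' (occasional missingness is expected in clinical cohorts and is imputed
#' per training fold).
#'
#' @return An `expn_schema` data frame with 19 rows.
#' @export
default_schema <- function() {
  attribute_schema(
    name = c(
      # clinical
      "prior_bcg", "age", "albumin_lt_4", "neutrophil_lymphocyte_ratio",
      "days_since_last_chemo", "five_factor_score", "chemo_regimen_count",
      # tumor
      "missense_snv_count", "expressed_missense_snv_count",
      "neoantigen_count", "expressed_neoantigen_count",
      "tumor_clonality", "tumor_diversity", "tumor_t_cell_fraction",
      # circulating (peripheral blood TCR repertoire)
      "productive_tcr_count", "blood_clonality", "blood_diversity",
      "blood_t_cell_fraction", "top_clone_frequency"
    ),
    category = rep(c("clinical", "tumor", "circulating"), c(7, 7, 5)),
    kind = c("binary", "continuous", "binary", rep("continuous", 16))
  )
}

#' @export
print.expn_schema <- function(x, ...) {
  cat(sprintf("<attribute schema: %d attributes (%s)>\n", nrow(x),
              paste(sprintf("%d %s", table(x$category)[unique(x$category)],
                            unique(x$category)), collapse = ", ")))
  NextMethod()
}

# Reserved (non-attribute) cohort columns, in canonical order.
RESERVED_COLUMNS <- c("patient_id", "expanded_clone_count", "dcb",
                      "pd_l1_staining_pct", "bajorin_score")
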