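#' Triage fraction of a biomarker for durable clinical benefit
#'
#' Suppose patients are triaged by a single threshold on a biomarker score:
#' everyone at or above the threshold is treated (under
#' `direction = "higher"`). The triage statistic is the minimal fraction of
#' non-DCB patients that must be treated so that 100% of DCB patients are
#' treated. With `direction = "higher"` the optimal threshold is the
#' minimum score among DCB patients; non-DCB patients whose score ties the
#' threshold count as treated, which guarantees full DCB capture under any
#' tie structure. The statistic depends on scores only through their ranks,
#' so it is invariant to strictly monotone transformations.
#'
#' @param scores numeric biomarker values, one per patient (finite).
#' @param dcb 0/1 vector of durable-clinical-benefit labels (1 =
#'   progression-free survival >= 6 months).
#' @param direction `"higher"` if larger scores indicate benefit (default),
#'   `"lower"` for the mirrored rule.
#' @param biomarker label carried into the result.
#' @return An object of class `expn_triage`: `threshold`, `n_dcb`,
#'   `n_non_dcb`, `treated_non_dcb`, `fraction_non_dcb_treated` and
#'   `threshold_percentile_among_non_dcb` (percent of non-DCB patients
#'   strictly below the threshold).
#' @export
triage_fraction <- function(scores, dcb, direction = c("higher", "lower"),
                            biomarker = "score") {
  direction <- match.arg(direction)
  scores <- as.numeric(scores)
  keep <- !is.na(dcb)
  scores <- scores[keep]
  dcb <- as.numeric(dcb)[keep]
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop("scores must be finite for all labelled patients")
  }
  if (!all(dcb %in% c(0, 1))) stop("dcb must be 0/1")
  is_dcb <- dcb == 1
  if (!any(is_dcb) || all(is_dcb)) {
    stop("triage needs at least one DCB and one non-DCB patient")
  }
  if (direction == "lower") {
    mirrored <- triage_fraction(-scores, dcb, "higher", biomarker)
    mirrored$threshold <- -mirrored$threshold
    mirrored$direction <- "lower"
    return(mirrored)
  }
  threshold <- min(scores[is_dcb])
  non_dcb <- scores[!is_dcb]
  treated <- sum(non_dcb >= threshold)
  frac <- treated / length(non_dcb)
  structure(list(biomarker = biomarker, direction = direction,
                 threshold = threshold,
                 n_dcb = sum(is_dcb), n_non_dcb = length(non_dcb),
                 treated_non_dcb = treated,
                 fraction_non_dcb_treated = frac,
                 threshold_percentile_among_non_dcb = 100 * (1 - frac)),
            class = "expn_triage")
}

#' @export
print.expn_triage <- function(x, ...) {
  cat(sprintf(
    "<triage [%s]: treat %d/%d non-DCB (%.0f%%) to capture all %d DCB; threshold %.4g (%s)>\n",
    x$biomarker, x$treated_non_dcb, x$n_non_dcb,
    100 * x$fraction_non_dcb_treated, x$n_dcb, x$threshold, x$direction))
  invisible(x)
}

#' Compare triage performance of predicted expansion and single biomarkers
#'
#' Computes the triage fraction for the model's held-out expansion
#' predictions and for each requested comparator biomarker (by default the
#' mutation-load and neoantigen attributes plus PD-L1 staining, all
#' higher-is-better). Patients without a DCB label are excluded; a
#' requested biomarker absent from the cohort is skipped with a warning.
#'
#' @param cohort an `expn_cohort` with `dcb` labels.
#' @param held_out_predictions numeric vector of held-out predicted log
#'   expansions, one per patient (e.g. `run_loocv(...)$predictions`).
#' @param biomarkers named columns of the cohort data to compare against.
#' @return Data frame with one row per biomarker: threshold, counts,
#'   treated fraction (and percent) and threshold percentile.
#' @export
biomarker_comparison <- function(cohort, held_out_predictions,
                                 biomarkers = c("missense_snv_count",
                                                "expressed_neoantigen_count",
                                                "pd_l1_staining_pct")) {
  stopifnot(inherits(cohort, "expn_cohort"))
  d <- cohort$data
  if (!"dcb" %in% names(d) || all(is.na(d$dcb))) {
    stop("cohort has no DCB labels")
  }
  if (length(held_out_predictions) != nrow(d)) {
    stop("held_out_predictions must have one value per patient")
  }
  results <- list(triage_fraction(held_out_predictions, d$dcb,
                                  biomarker = "predicted_expansion"))
  for (bm in biomarkers) {
    if (!bm %in% names(d)) {
      warning("biomarker column absent, skipped: ", bm)
      next
    }
    v <- d[[bm]]
    lab <- !is.na(d$dcb) & !is.na(v)
    if (sum(lab & d$dcb == 1, na.rm = TRUE) == 0 ||
        sum(lab & d$dcb == 0, na.rm = TRUE) == 0) {
      warning("biomarker lacks both DCB groups, skipped: ", bm)
      next
    }
    results[[length(results) + 1L]] <-
      triage_fraction(v[lab], d$dcb[lab], biomarker = bm)
  }
  do.call(rbind, lapply(results, function(r) {
    data.frame(biomarker = r$biomarker, direction = r$direction,
               threshold = r$threshold, n_dcb = r$n_dcb,
               n_non_dcb = r$n_non_dcb,
               treated_non_dcb = r$treated_non_dcb,
               fraction_non_dcb_treated = r$fraction_non_dcb_treated,
               pct_non_dcb_treated = 100 * r$fraction_non_dcb_treated,
               threshold_percentile_among_non_dcb =
                 r$threshold_percentile_among_non_dcb,
               stringsAsFactors = FALSE)
  }))
}
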