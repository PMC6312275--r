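#' Held-out predictions versus observed log expansion
#'
#' Scatter of leave-one-out predictions against the observed log clonal
#' expansion, with the identity line in red (perfect predictions would lie
#' on it).
#'
#' @param loocv an `expn_loocv`.
#' @return A ggplot object.
#' @export
plot_loocv <- function(loocv) {
  stopifnot(inherits(loocv, "expn_loocv"))
  d <- data.frame(y = loocv$y, prediction = loocv$predictions)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$y, y = .data$prediction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red",
                         linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "observed log clonal expansion",
                  y = "held-out predicted log clonal expansion",
                  title = sprintf("LOOCV MSE %.3f, variance explained %.0f%%",
                                  loocv$mse,
                                  100 * loocv$variance_explained_nominal)) +
    ggplot2::theme_minimal()
}

#' Permutation null distribution with the observed statistic
#'
#' Histogram of the LOOCV errors obtained under permutation, with a dotted
#' vertical line at the error observed on the original cohort.
#'
#' @param test an `expn_permtest`.
#' @param bins histogram bin count.
#' @return A ggplot object.
#' @export
plot_permutation <- function(test, bins = 30) {
  stopifnot(inherits(test, "expn_permtest"))
  d <- data.frame(mse = test$null_draws)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mse)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70",
                            colour = "grey40") +
    ggplot2::geom_vline(xintercept = test$observed_stat,
                        linetype = "dotted", linewidth = 1) +
    ggplot2::labs(x = "LOOCV MSE under permutation", y = "count",
                  title = sprintf("Permuted %s (B = %d): p %s",
                                  test$permuted_target, test$B,
                                  format_p(test$p_value, test$B))) +
    ggplot2::theme_minimal()
}

#' Elastic-net coefficients by feature category
#'
#' Horizontal bar chart of the nonzero coefficients of a full-cohort fit,
#' coloured by the category of the source attribute.
#'
#' @param fit an `expn_enet_fit` carrying column metadata.
#' @return A ggplot object.
#' @export
plot_coefficients <- function(fit) {
  stopifnot(inherits(fit, "expn_enet_fit"))
  if (is.null(fit$columns)) stop("fit carries no column metadata")
  keep <- fit$coefficients != 0
  if (!any(keep)) stop("all coefficients are zero")
  d <- data.frame(feature = names(fit$coefficients)[keep],
                  coefficient = unname(fit$coefficients[keep]),
                  category = fit$columns$category[keep],
                  stringsAsFactors = FALSE)
  d <- d[order(d$coefficient), ]
  d$feature <- factor(d$feature, levels = d$feature)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$coefficient,
                                  y = .data$feature,
                                  fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "elastic-net coefficient (standardized features)",
                  y = NULL, fill = "category") +
    ggplot2::theme_minimal()
}

#' Biomarker distributions by durable clinical benefit, with triage
#'
#' Strip plot of each biomarker's values split by DCB status. Patients who
#' must be treated under the biomarker's single-threshold triage rule (all
#' DCB patients plus the non-DCB patients at or above the threshold) are
#' shown in red.
#'
#' @param cohort an `expn_cohort` with DCB labels.
#' @param held_out_predictions per-patient held-out predicted log
#'   expansions.
#' @param biomarkers comparator columns, as in [biomarker_comparison()].
#' @return A ggplot object (one facet per biomarker, free y scales).
#' @export
plot_triage <- function(cohort, held_out_predictions,
                        biomarkers = c("missense_snv_count",
                                       "expressed_neoantigen_count",
                                       "pd_l1_staining_pct")) {
  stopifnot(inherits(cohort, "expn_cohort"))
  d <- cohort$data
  scores <- c(list(predicted_expansion = held_out_predictions),
              stats::setNames(lapply(biomarkers, function(b) d[[b]]),
                              biomarkers))
  scores <- scores[!vapply(scores, is.null, logical(1))]
  rows <- list()
  for (nm in names(scores)) {
    v <- scores[[nm]]
    lab <- !is.na(d$dcb) & !is.na(v)
    if (!any(lab)) next
    thr <- tryCatch(triage_fraction(v[lab], d$dcb[lab])$threshold,
                    error = function(e) NA_real_)
    rows[[nm]] <- data.frame(
      biomarker = nm, value = v[lab],
      dcb = factor(ifelse(d$dcb[lab] == 1, "DCB", "no DCB"),
                   levels = c("no DCB", "DCB")),
      treated = !is.na(thr) & v[lab] >= thr,
      stringsAsFactors = FALSE)
  }
  d2 <- do.call(rbind, rows)
  ggplot2::ggplot(d2, ggplot2::aes(x = .data$dcb, y = .data$value,
                                   colour = .data$treated)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, size = 2) +
    ggplot2::facet_wrap(~biomarker, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = NULL, y = "biomarker value",
                  colour = "must treat") +
    ggplot2::theme_minimal()
}
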