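#' Normative reference for neuropsychological tests
#'
#' Healthy-control means and standard deviations for NCT-A (number connection
#' test A, seconds; longer is worse) and DST (digit symbol test, raw score;
#' lower is worse). A score is abnormal when it lies beyond
#' `sd_multiplier` control SDs in the impaired direction.
#'
#' @param nct_a_mean,nct_a_sd control NCT-A distribution (sd > 0).
#' @param dst_mean,dst_sd control DST distribution (sd > 0).
#' @param sd_multiplier abnormality multiplier (default 2).
#' @return An object of class `normative_reference`.
#' @export
normative_reference <- function(nct_a_mean, nct_a_sd, dst_mean, dst_sd,
                                sd_multiplier = 2) {
  dmn_assert(nct_a_sd > 0 && dst_sd > 0, "bad_params",
             "normative SDs must be positive")
  structure(list(nct_a_mean = nct_a_mean, nct_a_sd = nct_a_sd,
                 dst_mean = dst_mean, dst_sd = dst_sd,
                 sd_multiplier = sd_multiplier),
            class = "normative_reference")
}

#' @rdname normative_reference
#' @param hc_records data.frame of healthy-control manifest rows with
#'   `nct_a_seconds` and `dst_score` columns.
#' @export
norms_from_controls <- function(hc_records, sd_multiplier = 2) {
  dmn_assert(nrow(hc_records) >= 2, "bad_params",
             "need at least 2 controls to build norms")
  normative_reference(mean(hc_records$nct_a_seconds),
                      stats::sd(hc_records$nct_a_seconds),
                      mean(hc_records$dst_score),
                      stats::sd(hc_records$dst_score),
                      sd_multiplier = sd_multiplier)
}

#' Diagnose MHE from neuropsychological scores
#'
#' A cirrhotic patient is labelled MHE when at least one test is abnormal:
#' NCT-A time above the control mean plus k SD (slower), or DST score below
#' the control mean minus k SD (fewer symbols). Otherwise non-HE.
#'
#' @param record one-row data.frame (or list) with `nct_a_seconds` and
#'   `dst_score`.
#' @param norms a [normative_reference()].
#' @return `"MHE"` or `"nonHE"`.
#' @export
diagnose_mhe <- function(record, norms) {
  nct <- record$nct_a_seconds
  dst <- record$dst_score
  dmn_assert(!is.null(nct) && !is.null(dst) && !is.na(nct) && !is.na(dst),
             "missing_score", "both NCT-A and DST scores are required")
  k <- norms$sd_multiplier
  abnormal <- nct > norms$nct_a_mean + k * norms$nct_a_sd ||
    dst < norms$dst_mean - k * norms$dst_sd
  if (abnormal) "MHE" else "nonHE"
}

#' Pearson correlation of ROI connectivity with test scores
#'
#' Sample Pearson r with the two-sided p value from the exact t
#' transformation `t = r sqrt((n - 2) / (1 - r^2))` (as computed by
#' [stats::cor.test()]).
#'
#' @param roi_values numeric vector of per-patient ROI mean z values.
#' @param scores matching numeric vector of test scores.
#' @return A list with `r`, `p` and `n`.
#' @export
pearson_with_scores <- function(roi_values, scores) {
  dmn_assert(length(roi_values) == length(scores) && length(roi_values) >= 3,
             "bad_params", "need >= 3 paired observations")
  dmn_assert(stats::sd(roi_values) > 0 && stats::sd(scores) > 0,
             "constant_input", "inputs must not be constant")
  ct <- stats::cor.test(roi_values, scores, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(roi_values))
}

#' ROC curve for discriminating MHE from non-HE
#'
#' With the default orientation `"lower"` (reduced connectivity indicates
#' disease), every observed value is swept as a candidate threshold c:
#' sensitivity is the fraction of MHE patients strictly below c, specificity
#' the fraction of non-HE patients at or above c. AUC is the area under the
#' resulting curve by the trapezoidal rule, which equals the fraction of
#' concordant case-control pairs with ties counted one half.
#'
#' @param values numeric vector, one connectivity value per patient.
#' @param labels character vector of `"MHE"` / `"nonHE"`.
#' @param orientation `"lower"` if disease lowers the value, `"higher"` for
#'   the reverse.
#' @return An object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `orientation`, plus the Youden-optimal `cutoff`,
#'   `sens_at_cutoff`, `spec_at_cutoff`.
#' @export
roc_curve <- function(values, labels, orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  dmn_assert(length(values) == length(labels), "bad_params",
             "values and labels differ in length")
  dmn_assert(all(labels %in% c("MHE", "nonHE")), "bad_params",
             "labels must be MHE or nonHE")
  case <- values[labels == "MHE"]
  ctrl <- values[labels == "nonHE"]
  dmn_assert(length(case) > 0 && length(ctrl) > 0, "one_class_absent",
             "both classes must be present")
  x <- if (orientation == "lower") values else -values
  cs <- if (orientation == "lower") case else -case
  ct <- if (orientation == "lower") ctrl else -ctrl
  thr <- c(sort(unique(x)), Inf)
  sens <- vapply(thr, function(cc) mean(cs < cc), numeric(1))
  spec <- vapply(thr, function(cc) mean(ct >= cc), numeric(1))
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  # trapezoid over the full curve from (0,0) to (1,1)
  xs <- c(0, fpr[ord], 1); ys <- c(0, sens[ord], 1)
  auc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  youden <- sens + spec - 1
  best <- which(youden == max(youden))
  if (length(best) > 1) best <- best[which.max(spec[best])]
  cutoff <- thr[best]
  if (orientation == "higher" && is.finite(cutoff)) cutoff <- -cutoff
  res <- list(thresholds = if (orientation == "lower") thr else -thr,
              sensitivity = sens, specificity = spec, auc = auc,
              orientation = orientation, cutoff = cutoff,
              sens_at_cutoff = sens[best], spec_at_cutoff = spec[best],
              n_case = length(case), n_control = length(ctrl))
  class(res) <- "roc_result"
  res
}

#' Youden-optimal cutoff of an ROC result
#'
#' The threshold maximizing sensitivity + specificity - 1; ties are broken
#' toward higher specificity.
#'
#' @param roc a [roc_curve()] result.
#' @return A list with `cutoff`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(roc) {
  dmn_assert(inherits(roc, "roc_result"), "bad_params",
             "expected a roc_result")
  list(cutoff = roc$cutoff, sensitivity = roc$sens_at_cutoff,
       specificity = roc$spec_at_cutoff)
}

#' MHE prevalence among patients
#'
#' @param labels character vector of patient labels (`"MHE"` / `"nonHE"`).
#' @return A list with `count_mhe`, `count_total`, `percent` (one decimal).
#' @export
prevalence <- function(labels) {
  dmn_assert(length(labels) > 0, "bad_params", "no labels supplied")
  n_mhe <- sum(labels == "MHE")
  list(count_mhe = n_mhe, count_total = length(labels),
       percent = round(100 * n_mhe / length(labels), 1))
}
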