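#' Confusion counts for a binary response prediction
#'
#' @param tp,fp,fn,tn non-negative integer counts (positives = true
#'   responders; a "positive" prediction calls the lesion a responder).
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(v < 0) || any(v != round(v)))
    dce_validation_error("confusion counts must be non-negative integers")
  structure(as.list(v), class = "confusion_counts")
}

#' Mean-plus-two-SD response cutoff
#'
#' The cutoff rule used to call early response: a lesion is predicted to
#' respond if its DV lies at or below the mean plus two standard deviations
#' of the DV values of all lesions that responded.
#'
#' @param responder_values DV values (ml/100 ml) of responder lesions; at
#'   least two required.
#' @param sd_type SD convention, see [sd_conv()] (default population).
#' @return The cutoff (ml/100 ml).
#' @examples
#' cutoff_mean_plus_2sd(c(8, 12))  # mean 10, population SD 2 -> 14
#' @export
cutoff_mean_plus_2sd <- function(responder_values, sd_type = "population") {
  if (length(responder_values) < 2L)
    dce_validation_error("need at least two responder values for a cutoff")
  mean(responder_values) + 2 * sd_conv(responder_values, sd_type)
}

#' Predict response group from a DV value and a cutoff
#'
#' A lesion is predicted to respond if its DV is at or below the cutoff
#' (boundary inclusive: "cutoff or lower").
#'
#' @param dv DV value(s), ml/100 ml, >= 0.
#' @param cutoff cutoff in ml/100 ml.
#' @return Factor with levels `responder`, `non_responder`.
#' @export
predict_by_cutoff <- function(dv, cutoff) {
  if (any(dv < 0)) dce_validation_error("dv must be non-negative")
  factor(ifelse(dv <= cutoff, "responder", "non_responder"),
         levels = c("responder", "non_responder"))
}

#' Tally predictions against true response groups
#'
#' @param predicted,actual factors/characters with values `responder` /
#'   `non_responder` (responder = positive class).
#' @return A [confusion_counts()].
#' @export
tally_predictions <- function(predicted, actual) {
  predicted <- as.character(predicted); actual <- as.character(actual)
  stopifnot(length(predicted) == length(actual))
  confusion_counts(
    tp = sum(predicted == "responder" & actual == "responder"),
    fp = sum(predicted == "responder" & actual == "non_responder"),
    fn = sum(predicted == "non_responder" & actual == "responder"),
    tn = sum(predicted == "non_responder" & actual == "non_responder"))
}

#' Diagnostic performance metrics and clinical utility indexes
#'
#' Computes sensitivity = tp/(tp+fn), specificity = tn/(fp+tn),
#' PPV = tp/(tp+fp), NPV = tn/(tn+fn), and the clinical utility indexes
#' CUI+ = sensitivity x PPV (case-finding utility) and
#' CUI- = specificity x NPV (case-exclusion utility), all from exact
#' fractions. A metric whose denominator is zero is reported as `NA` and
#' listed in `undefined` (it is not silently propagated); a CUI whose factor
#' is undefined is itself undefined.
#'
#' @param counts a [confusion_counts()].
#' @param cutoff optional cutoff (ml/100 ml) recorded with the report.
#' @return An object of class `diagnostic_report` with fields `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `cui_positive`, `cui_negative` (fractions),
#'   `counts`, `cutoff`, `undefined`.
#' @examples
#' diagnostic_metrics(confusion_counts(tp = 7, fp = 3, fn = 1, tn = 10))
#' @export
diagnostic_metrics <- function(counts, cutoff = NA_real_) {
  stopifnot(inherits(counts, "confusion_counts"))
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- frac(counts$tp, counts$tp + counts$fn)
  spec <- frac(counts$tn, counts$fp + counts$tn)
  ppv <- frac(counts$tp, counts$tp + counts$fp)
  npv <- frac(counts$tn, counts$tn + counts$fn)
  cui_pos <- if (anyNA(c(sens, ppv))) NA_real_ else sens * ppv
  cui_neg <- if (anyNA(c(spec, npv))) NA_real_ else spec * npv
  out <- list(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
              cui_positive = cui_pos, cui_negative = cui_neg,
              counts = counts, cutoff = cutoff)
  out$undefined <- names(which(vapply(
    out[c("sensitivity", "specificity", "ppv", "npv",
          "cui_positive", "cui_negative")], is.na, logical(1))))
  structure(out, class = "diagnostic_report")
}

#' Format a diagnostic report as a summary-table row
#'
#' Percentages are rounded half-up to integers and the utility indexes to
#' three decimals, the conventional presentation of such tables.
#'
#' @param report a `diagnostic_report` from [diagnostic_metrics()].
#' @param label row label.
#' @return A one-row data.frame with percent columns (integer) and CUI
#'   columns (3 decimals).
#' @export
format_diagnostic_report <- function(report, label = "") {
  pct <- function(x) if (is.na(x)) NA_real_ else round_half_up(100 * x)
  data.frame(
    parameter = label,
    sensitivity_pct = pct(report$sensitivity),
    specificity_pct = pct(report$specificity),
    ppv_pct = pct(report$ppv),
    npv_pct = pct(report$npv),
    cui_positive = round_half_up(report$cui_positive, 3),
    cui_negative = round_half_up(report$cui_negative, 3))
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat("<diagnostic_report>",
      if (!is.na(x$cutoff)) sprintf(" cutoff %.4g ml/100ml;", x$cutoff) else "",
      "\n", sep = "")
  print(format_diagnostic_report(x), row.names = FALSE)
  if (length(x$undefined))
    cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}
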