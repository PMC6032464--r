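#' mRECIST response classification for viable (enhancing) tumor
#'
#' Applies the four modified-RECIST category definitions to a summed-diameter
#' assessment of viable (arterially enhancing) tumor:
#' * CR: disappearance of any intratumoral arterial enhancement;
#' * PD: increase of at least 20 percent in the sum of viable diameters,
#'   referenced to the smallest sum recorded since treatment start (nadir);
#' * PR: decrease of at least 30 percent in the sum of viable diameters,
#'   referenced to the baseline sum;
#' * SD: anything that qualifies for neither PR nor PD.
#'
#' Boundaries are inclusive ("at least"): exactly -30 percent is PR, exactly
#' +20 percent over the nadir is PD. PD is evaluated before PR. The rules
#' depend only on
#' diameter ratios, so they are invariant to uniform rescaling.
#'
#' @param baseline_sum_mm sum of viable-lesion diameters at baseline.
#' @param current_sum_mm current sum of viable diameters.
#' @param nadir_sum_mm smallest sum recorded since treatment start; must not
#'   exceed the baseline sum.
#' @param any_enhancement logical; is any intratumoral arterial enhancement
#'   present?
#' @return A factor with levels `CR`, `PR`, `SD`, `PD` (length 1).
#' @examples
#' mrecist_classify(50, 35, 50, TRUE)  # exactly -30%: PR
#' mrecist_classify(50, 24, 20, TRUE)  # exactly +20% over nadir: PD
#' @export
mrecist_classify <- function(baseline_sum_mm, current_sum_mm, nadir_sum_mm,
                             any_enhancement) {
  if (any(c(baseline_sum_mm, current_sum_mm, nadir_sum_mm) < 0))
    dce_validation_error("diameter sums must be non-negative")
  if (nadir_sum_mm > baseline_sum_mm)
    dce_validation_error("nadir sum cannot exceed baseline sum")
  value <-
    if (!any_enhancement) "CR"
    else if (current_sum_mm >= 1.2 * nadir_sum_mm) "PD"
    else if (current_sum_mm <= 0.7 * baseline_sum_mm) "PR"
    else "SD"
  factor(value, levels = MRECIST_LEVELS)
}

#' Responder / non-responder grouping of mRECIST categories
#'
#' Responders are lesions classified CR or PR; non-responders are SD or PD.
#'
#' @param categories character or factor vector of mRECIST categories.
#' @return A factor with levels `responder`, `non_responder`.
#' @export
responder_group <- function(categories) {
  categories <- as.character(categories)
  bad <- setdiff(stats::na.omit(unique(categories)), MRECIST_LEVELS)
  if (length(bad))
    dce_validation_error(paste("invalid mRECIST categories:",
                               paste(bad, collapse = ", ")))
  factor(ifelse(categories %in% c("CR", "PR"), "responder", "non_responder"),
         levels = c("responder", "non_responder"))
}

#' Tabulate mRECIST categories and responder groups
#'
#' @param categories character or factor vector of mRECIST categories.
#' @return A list with `by_category` (named CR/PR/SD/PD counts), `by_group`
#'   (responder / non_responder counts), and `n`.
#' @export
group_responders <- function(categories) {
  if (!length(categories)) dce_validation_error("no categories supplied")
  cats <- factor(as.character(categories), levels = MRECIST_LEVELS)
  if (anyNA(cats)) dce_validation_error("invalid mRECIST categories present")
  list(by_category = table(cats),
       by_group = table(responder_group(cats)),
       n = length(cats))
}

#' Patients with lesions in both response groups
#'
#' Identifies patients having at least one responder (CR/PR) and at least one
#' non-responder (SD/PD) lesion at final outcome.
#'
#' @param dataset a [study_dataset()] with `outcome_final` filled.
#' @return A list with `count` and `patient_ids`.
#' @export
mixed_outcome_patients <- function(dataset) {
  les <- dataset$lesions
  if (anyNA(les$outcome_final))
    dce_validation_error("final outcomes missing for some lesions")
  grp <- responder_group(les$outcome_final)
  mixed <- vapply(split(grp, les$patient_id),
                  function(g) length(unique(g)) == 2L, logical(1))
  ids <- names(mixed)[mixed]
  list(count = length(ids), patient_ids = ids)
}
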