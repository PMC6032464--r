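MRECIST_LEVELS <- c("CR", "PR", "SD", "PD")
TIMEPOINTS <- c("pre_tace", "day3", "day10")

#' Path to a packaged example data file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files. `"study_table1.csv"` is the packaged
#'   per-lesion demographics/outcome table of the 11-patient, 21-lesion HCC
#'   cohort used as a worked example throughout.
#' @return A file path (or a character vector of file names).
#' @export
dcekit_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "dcekit")))
  system.file("extdata", file, package = "dcekit", mustWork = TRUE)
}

#' Study dataset container
#'
#' Bundles the per-lesion table, per-patient metadata, per-lesion kinetic
#' parameter estimates (long format, filled by fitting or simulation), and
#' optional per-patient angiogenesis-factor trajectories.
#'
#' @param lesions data.frame, one row per lesion: `patient_id`, `lesion_id`,
#'   `segment`, `size_mm`, `outcome_3d`, `outcome_10d`, `outcome_final`.
#' @param patients data.frame, one row per patient: `patient_id`, `sex`,
#'   `age_years`, `interval_premri_tace_days`, `interval_tace_followup_days`,
#'   `followup_modality`.
#' @param kinetics optional data.frame, one row per lesion x timepoint:
#'   `patient_id`, `lesion_id`, `timepoint` (`pre_tace`/`day3`/`day10`),
#'   `ktrans` (ml/100 ml/min), `dv` (ml/100 ml).
#' @param angiogenesis optional data.frame, one row per patient x timepoint:
#'   `patient_id`, `timepoint`, `ang2_pg_ml`, `vegf_pg_ml`, `ckit_ng_ml`.
#'   Patient-level values are shared by all lesions of that patient.
#' @return An object of class `study_dataset`.
#' @export
study_dataset <- function(lesions, patients, kinetics = NULL, angiogenesis = NULL) {
  if (any(lesions$size_mm <= 0))
    dce_validation_error("lesion size_mm must be positive")
  tab <- table(lesions$patient_id)
  if (any(tab > 2L))
    dce_validation_error(sprintf(
      "patients with more than two lesions: %s",
      paste(names(tab)[tab > 2L], collapse = ", ")))
  if (!is.null(kinetics)) {
    if (any(!kinetics$timepoint %in% TIMEPOINTS))
      dce_validation_error("kinetics timepoint must be pre_tace/day3/day10")
    if (any(stats::na.omit(kinetics$ktrans) < 0) ||
        any(stats::na.omit(kinetics$dv) < 0 | stats::na.omit(kinetics$dv) > 100))
      dce_validation_error("kinetics: ktrans must be >= 0 and dv in [0, 100]")
  }
  structure(list(lesions = lesions, patients = patients,
                 kinetics = kinetics, angiogenesis = angiogenesis),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("<study_dataset> ", nrow(x$patients), " patients, ", nrow(x$lesions),
      " lesions", sep = "")
  if (!is.null(x$kinetics)) cat(";", nrow(x$kinetics), "kinetic records")
  if (!is.null(x$angiogenesis)) cat("; angiogenesis factors attached")
  cat("\n")
  invisible(x)
}

#' Load a per-lesion study table
#'
#' Reads a CSV with one row per lesion and the columns of the packaged
#' example (`patient_id`, `sex`, `age_years`, `segment`, `size_mm`,
#' `outcome_3d`, `outcome_10d`, `outcome_final`,
#' `interval_premri_tace_days`, `interval_tace_followup_days`,
#' `followup_modality`). Patient-level fields must be identical across a
#' patient's lesions; at most two lesions per patient are allowed.
#'
#' @param path CSV path; defaults to the packaged 21-lesion example table.
#' @return A [study_dataset()].
#' @examples
#' ds <- load_study_table()
#' nrow(ds$lesions)  # 21
#' @export
load_study_table <- function(path = dcekit_example("study_table1.csv")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "sex", "age_years", "segment", "size_mm",
            "outcome_3d", "outcome_10d", "outcome_final",
            "interval_premri_tace_days", "interval_tace_followup_days",
            "followup_modality")
  miss <- setdiff(need, names(d))
  if (length(miss))
    dce_format_error(paste0("study table is missing column(s): ",
                            paste(miss, collapse = ", ")))
  for (col in c("outcome_3d", "outcome_10d", "outcome_final")) {
    bad <- setdiff(stats::na.omit(unique(d[[col]])), MRECIST_LEVELS)
    if (length(bad))
      dce_validation_error(sprintf("column %s has invalid categories: %s",
                                   col, paste(bad, collapse = ", ")))
  }
  d$lesion_id <- stats::ave(seq_len(nrow(d)), d$patient_id, FUN = seq_along)
  lesions <- d[, c("patient_id", "lesion_id", "segment", "size_mm",
                   "outcome_3d", "outcome_10d", "outcome_final")]
  pat_cols <- c("patient_id", "sex", "age_years", "interval_premri_tace_days",
                "interval_tace_followup_days", "followup_modality")
  patients <- unique(d[, pat_cols])
  if (anyDuplicated(patients$patient_id))
    dce_validation_error("patient-level fields differ across a patient's lesions")
  rownames(lesions) <- rownames(patients) <- NULL
  study_dataset(lesions, patients)
}

#' Write a study dataset's lesion table back to CSV
#'
#' Inverse of [load_study_table()] (round-trip lossless).
#'
#' @param dataset a [study_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(dataset, path) {
  d <- merge(dataset$lesions, dataset$patients, by = "patient_id", sort = FALSE)
  d <- d[order(d$patient_id, d$lesion_id),
         c("patient_id", "sex", "age_years", "segment", "size_mm",
           "outcome_3d", "outcome_10d", "outcome_final",
           "interval_premri_tace_days", "interval_tace_followup_days",
           "followup_modality")]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Descriptive summary of a study dataset
#'
#' Counts and descriptive statistics: number of patients and lesions, mean
#' and SD of the largest lesion dimension, and mean/SD of the pre-treatment
#' MRI-to-TACE interval.
#'
#' @param dataset a [study_dataset()].
#' @param sd_type SD convention, see [sd_conv()].
#' @return A list of descriptive statistics.
#' @export
describe_study <- function(dataset, sd_type = "population") {
  list(
    n_patients = nrow(dataset$patients),
    n_lesions = nrow(dataset$lesions),
    size_mean_mm = mean(dataset$lesions$size_mm),
    size_sd_mm = sd_conv(dataset$lesions$size_mm, sd_type),
    interval_mean_days = mean(dataset$patients$interval_premri_tace_days),
    interval_sd_days = sd_conv(dataset$patients$interval_premri_tace_days, sd_type)
  )
}
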