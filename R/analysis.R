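#' Analysis configuration
#'
#' Central defaults for the pipeline, overridable from a YAML file: the
#' assumed hematocrit, the DV response cutoffs per timepoint (ml/100 ml; the
#' packaged defaults 40/30/17 are the worked-example values, while
#' [cutoff_mean_plus_2sd()] exposes the constructive rule), the descriptive
#' SD convention, the AIF peak-exclusion fraction, the S0 floor, exact-test
#' size limits, and the significance level.
#'
#' @param path optional YAML file whose top-level keys override the defaults.
#' @return A list of configuration values.
#' @export
dce_config <- function(path = NULL) {
  cfg <- list(
    hct = 0.45,
    cutoffs = list(pre_tace = 40, day3 = 30, day10 = 17),
    sd_type = "population",
    aif_peak_fraction = 0.5,
    s0_floor = 1e-6,
    deconv_reg = 0.15,
    exact_limit_friedman = 8L,
    exact_limit_mw = 25L,
    exact_limit_spearman = 9L,
    alpha = 0.05)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  cfg
}

#' Cutoff-based early-response prediction report
#'
#' For each timepoint, predicts each lesion's final response group from its
#' DV at that timepoint ("cutoff or lower" = responder), tallies the
#' predictions against the final mRECIST grouping, and computes the
#' diagnostic metrics and clinical utility indexes.
#'
#' @param dataset a [study_dataset()] with `kinetics` and final outcomes.
#' @param cutoffs named list/vector of DV cutoffs (ml/100 ml) per timepoint,
#'   names among `pre_tace`, `day3`, `day10`.
#' @return Named list of `diagnostic_report` objects, one per timepoint.
#' @export
response_prediction_report <- function(dataset,
                                       cutoffs = dce_config()$cutoffs) {
  if (is.null(dataset$kinetics))
    dce_validation_error("dataset has no kinetic records")
  kin <- merge(dataset$kinetics,
               dataset$lesions[, c("patient_id", "lesion_id", "outcome_final")],
               by = c("patient_id", "lesion_id"))
  kin$group <- responder_group(kin$outcome_final)
  out <- list()
  for (tp in intersect(TIMEPOINTS, names(cutoffs))) {
    sub <- kin[kin$timepoint == tp & !is.na(kin$dv), ]
    pred <- predict_by_cutoff(sub$dv, cutoffs[[tp]])
    out[[tp]] <- diagnostic_metrics(tally_predictions(pred, sub$group),
                                    cutoff = cutoffs[[tp]])
  }
  out
}

#' Full statistical analysis of a study dataset
#'
#' Reproduces the study's statistical layer on any dataset with fitted (or
#' simulated) kinetics: per-group/timepoint mean +/- SD summaries for DV and
#' Ktrans, within-group Friedman tests across the three timepoints,
#' between-group Mann-Whitney tests at each timepoint, Spearman correlations
#' of each parameter with the angiogenesis factors (patient-level values
#' duplicated across that patient's lesions, a deliberate pseudo-replication
#' matching how such data are analyzed), repeated-measures ANOVA of each
#' angiogenesis factor across time, and the cutoff-based prediction report.
#' No multiple-testing correction is applied by default.
#'
#' @param dataset a [study_dataset()] with `kinetics` filled.
#' @param config a [dce_config()] list.
#' @return A list with elements `summaries`, `friedman`, `mann_whitney`,
#'   `correlations`, `anova`, `prediction`.
#' @export
analyze_study <- function(dataset, config = dce_config()) {
  out <- list(summaries = list(), friedman = list(), mann_whitney = list(),
              correlations = list(), anova = list())
  kin <- merge(dataset$kinetics,
               dataset$lesions[, c("patient_id", "lesion_id", "outcome_final")],
               by = c("patient_id", "lesion_id"))
  kin$group <- responder_group(kin$outcome_final)
  for (par in c("dv", "ktrans")) {
    out$summaries[[par]] <- summarize_groups(dataset, par, config$sd_type)
    for (grp in c("responder", "non_responder")) {
      wide <- tryCatch(kinetics_wide(dataset, par, grp), dce_error = function(e) NULL)
      if (!is.null(wide) && nrow(wide) >= 2L)
        out$friedman[[paste(par, grp, sep = "_")]] <-
          friedman_exact(wide, config$exact_limit_friedman)
    }
    for (tp in TIMEPOINTS) {
      x <- kin[[par]][kin$timepoint == tp & kin$group == "responder"]
      y <- kin[[par]][kin$timepoint == tp & kin$group == "non_responder"]
      if (length(x) && length(y))
        out$mann_whitney[[paste(par, tp, sep = "_")]] <-
          mann_whitney_u(x, y, config$exact_limit_mw)
    }
  }
  if (!is.null(dataset$angiogenesis)) {
    ang <- merge(kin, dataset$angiogenesis, by = c("patient_id", "timepoint"))
    for (par in c("dv", "ktrans")) {
      for (fac in c("ang2_pg_ml", "vegf_pg_ml", "ckit_ng_ml")) {
        ok <- stats::complete.cases(ang[[par]], ang[[fac]])
        if (sum(ok) >= 3L)
          out$correlations[[paste(par, fac, sep = "_x_")]] <-
            spearman_rank(ang[[par]][ok], ang[[fac]][ok],
                          config$exact_limit_spearman)
      }
    }
    for (fac in c("ang2_pg_ml", "vegf_pg_ml", "ckit_ng_ml")) {
      w <- stats::reshape(
        dataset$angiogenesis[, c("patient_id", "timepoint", fac)],
        direction = "wide", idvar = "patient_id", timevar = "timepoint")
      m <- as.matrix(w[, paste(fac, TIMEPOINTS, sep = ".")])
      pat_grp <- vapply(split(kin$group, kin$patient_id),
                        function(g) names(which.max(table(g))), character(1))
      grp <- pat_grp[as.character(w$patient_id)]
      res <- tryCatch(anova_across_time(m, grp), dce_error = function(e) NULL)
      if (!is.null(res)) out$anova[[fac]] <- res
    }
  }
  out$prediction <- response_prediction_report(dataset, config$cutoffs)
  out
}

#' Write analysis results to disk
#'
#' Emits `stats.json` (all test results), `summary_dv.csv` /
#' `summary_ktrans.csv` (group summaries) and `prediction_report.csv` (the
#' diagnostic table, one row per timepoint) into a directory.
#'
#' @param results output of [analyze_study()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  as_plain <- function(x) {
    if (inherits(x, "stat_result"))
      return(x[c("statistic", "p_value", "method", "exact")])
    if (inherits(x, "diagnostic_report"))
      return(x[c("sensitivity", "specificity", "ppv", "npv",
                 "cui_positive", "cui_negative", "cutoff")])
    if (is.list(x)) return(lapply(x, as_plain))
    x
  }
  stats_out <- as_plain(results[c("friedman", "mann_whitney",
                                  "correlations", "prediction")])
  jsonlite::write_json(stats_out, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (par in names(results$summaries))
    utils::write.csv(results$summaries[[par]],
                     file.path(dir, paste0("summary_", par, ".csv")),
                     row.names = FALSE)
  pred <- do.call(rbind, lapply(names(results$prediction), function(tp)
    format_diagnostic_report(results$prediction[[tp]], tp)))
  utils::write.csv(pred, file.path(dir, "prediction_report.csv"),
                   row.names = FALSE)
  invisible(dir)
}
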