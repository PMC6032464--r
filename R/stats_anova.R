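#' Repeated-measures ANOVA across timepoints with a grouping factor
#'
#' Mixed two-way ANOVA with one within-subject factor (time, the matrix
#' columns) and one between-subject factor (`groups`): used to evaluate
#' changes in angiogenesis factors across time. Sums of squares are the
#' sequential decomposition of `value ~ subject + time + group:time` (the
#' subject term absorbs the group main effect, which is not a test of
#' interest here); F statistics for the time main effect and the group x time
#' interaction use the within-subject residual mean square.
#'
#' Degenerate inputs are reported rather than propagated as NaN: with zero
#' residual variance an effect with zero sum of squares gives F = 0, p = 1,
#' and a nonzero effect gives F = Inf, p = 0.
#'
#' @param values numeric matrix, rows = subjects (patients), columns =
#'   timepoints; complete (no NA).
#' @param groups group label per row.
#' @return A list with `time` and `interaction`, each a [stat_result()], and
#'   the ANOVA `table` (data.frame of SS/df/MS).
#' @export
anova_across_time <- function(values, groups) {
  values <- as.matrix(values)
  if (anyNA(values)) dce_validation_error("missing cells are not allowed")
  N <- nrow(values); k <- ncol(values)
  groups <- factor(groups)
  if (length(groups) != N)
    dce_validation_error("groups must have one label per row")
  g <- nlevels(groups)
  if (N < 2L || k < 2L || g < 1L || any(table(groups) < 1L))
    dce_validation_error("need >= 2 subjects and >= 2 timepoints")
  if (g >= N)
    dce_stop("singular design: as many groups as subjects", "dce_design_error")
  d <- data.frame(
    value = as.vector(values),
    subject = factor(rep(seq_len(N), times = k)),
    time = factor(rep(seq_len(k), each = N)),
    group = rep(groups, times = k))
  m <- stats::lm(value ~ subject + time + group:time, data = d)
  a <- suppressWarnings(stats::anova(m))  # perfect fits handled explicitly below
  ss <- a[["Sum Sq"]]; df <- a[["Df"]]
  rn <- rownames(a)
  i_time <- which(rn == "time")
  i_int <- grep("group", rn)
  i_res <- which(rn == "Residuals")
  ms_res <- ss[i_res] / max(df[i_res], 1L)
  fp <- function(ss_eff, df_eff) {
    ms_eff <- ss_eff / df_eff
    if (ms_res <= 1e-12) {
      if (ss_eff <= 1e-12) return(c(0, 1))
      return(c(Inf, 0))
    }
    f <- ms_eff / ms_res
    c(f, stats::pf(f, df_eff, df[i_res], lower.tail = FALSE))
  }
  tm <- fp(ss[i_time], df[i_time])
  it <- fp(sum(ss[i_int]), sum(df[i_int]))
  list(
    time = stat_result(tm[1], tm[2], "repeated-measures ANOVA: time", FALSE),
    interaction = stat_result(it[1], it[2],
                              "repeated-measures ANOVA: group x time", FALSE),
    table = data.frame(term = rn, ss = ss, df = df, row.names = NULL))
}

#' Per-group, per-timepoint summary of a kinetic parameter
#'
#' Produces the mean +/- SD layout of a group-results table: one row per
#' (response group, timepoint) with n, mean and SD of the chosen parameter.
#' Lesions are grouped by their final mRECIST outcome. Empty groups are
#' omitted with a warning.
#'
#' @param dataset a [study_dataset()] with `kinetics` filled and
#'   `outcome_final` present in the lesion table.
#' @param parameter `"dv"` or `"ktrans"`.
#' @param sd_type SD convention, see [sd_conv()] (default population).
#' @return data.frame with columns `group`, `timepoint`, `n`, `mean`, `sd`.
#' @export
summarize_groups <- function(dataset, parameter = c("dv", "ktrans"),
                             sd_type = "population") {
  parameter <- match.arg(parameter)
  if (is.null(dataset$kinetics))
    dce_validation_error("dataset has no kinetic records")
  kin <- merge(dataset$kinetics,
               dataset$lesions[, c("patient_id", "lesion_id", "outcome_final")],
               by = c("patient_id", "lesion_id"))
  kin$group <- responder_group(kin$outcome_final)
  out <- expand.grid(group = levels(kin$group), timepoint = TIMEPOINTS,
                     stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(out)), function(i) {
    v <- kin[[parameter]][kin$group == out$group[i] &
                            kin$timepoint == out$timepoint[i]]
    v <- v[!is.na(v)]
    data.frame(group = out$group[i], timepoint = out$timepoint[i],
               n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v)) sd_conv(v, sd_type) else NA_real_)
  })
  res <- do.call(rbind, res)
  empty <- res$n == 0L
  if (any(empty)) {
    warning(sprintf("omitting empty group cells: %s",
                    paste(res$group[empty], res$timepoint[empty],
                          sep = "/", collapse = ", ")))
    res <- res[!empty, , drop = FALSE]
  }
  res$timepoint <- factor(res$timepoint, levels = TIMEPOINTS)
  res[order(res$group, res$timepoint), , drop = FALSE]
}

#' Kinetics in wide (lesion x timepoint) layout
#'
#' Convenience pivot for [friedman_exact()]: rows are lesions, columns the
#' three timepoints.
#'
#' @param dataset a [study_dataset()] with `kinetics` filled.
#' @param parameter `"dv"` or `"ktrans"`.
#' @param group optional `"responder"` / `"non_responder"` filter (by final
#'   outcome).
#' @return Numeric matrix with one row per lesion with complete records.
#' @export
kinetics_wide <- function(dataset, parameter = c("dv", "ktrans"), group = NULL) {
  parameter <- match.arg(parameter)
  kin <- merge(dataset$kinetics,
               dataset$lesions[, c("patient_id", "lesion_id", "outcome_final")],
               by = c("patient_id", "lesion_id"))
  if (!is.null(group))
    kin <- kin[responder_group(kin$outcome_final) == group, , drop = FALSE]
  key <- interaction(kin$patient_id, kin$lesion_id, drop = TRUE)
  rows <- lapply(split(kin, key), function(gk) {
    v <- gk[[parameter]][match(TIMEPOINTS, gk$timepoint)]
    if (anyNA(v)) NULL else v
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) dce_validation_error("no lesions with complete records")
  m <- do.call(rbind, rows)
  colnames(m) <- TIMEPOINTS
  m
}
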