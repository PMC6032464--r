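#' Default per-group, per-timepoint kinetic parameter distributions
#'
#' Mean and SD of DV (ml/100 ml) and Ktrans (ml/100 ml/min) for responder and
#' non-responder lesions at the three study timepoints. The defaults are the
#' group statistics of the 21-lesion TACE + sorafenib cohort this package's
#' worked examples reproduce: responder DV falls 28.4 -> 14.2 -> 8.6 while
#' non-responder DV recovers by day 10.
#'
#' @return data.frame with columns `parameter`, `group`, `timepoint`, `mean`,
#'   `sd`.
#' @export
default_param_dists <- function() {
  data.frame(
    parameter = rep(c("dv", "ktrans"), each = 6L),
    group = rep(rep(c("responder", "non_responder"), each = 3L), 2L),
    timepoint = rep(TIMEPOINTS, 4L),
    mean = c(28.4, 14.2, 8.6,   32.3, 24.5, 27.0,
             145.2, 15.9, 8.7,  67.5, 105.4, 97.0),
    sd = c(12.4, 7.0, 4.7,      11.6, 12.1, 9.5,
           151.3, 15.3, 9.5,    66.5, 197.3, 166.0))
}

#' Specification of a synthetic DCE-MRI cohort
#'
#' Defines the study conditions the generator emulates: cohort size and
#' lesion multiplicity, the responder fraction, per-group/timepoint kinetic
#' parameter distributions (drawn as truncated normals at the physical
#' bounds), the acquisition schedule, bolus arrival, baseline signal and
#' noise level, within-patient correlation of lesion parameters, and the
#' Ang2-DV correlation.
#'
#' @param n_patients number of patients.
#' @param lesions_per_patient lesions per patient (at most 2).
#' @param max_lesions cap on the total number of lesions (the last patient
#'   may contribute a single lesion); `NA` = no cap.
#' @param p_responder per-lesion probability of the responder group.
#' @param param_dists distribution table as from [default_param_dists()].
#' @param noise_snr baseline signal-to-noise ratio: Gaussian noise with
#'   SD = s0 / noise_snr is added to every simulated signal sample
#'   (`Inf` = noiseless).
#' @param s0 baseline (pre-contrast) signal level, arbitrary units.
#' @param schedule an [acq_schedule()].
#' @param bolus_arrival_s bolus arrival time (s after injection).
#' @param hct assumed [hematocrit()] fraction.
#' @param within_patient_rho Gaussian-copula correlation between the two
#'   lesions of one patient for each kinetic parameter (shared physiology).
#' @param ang2_rho target Spearman correlation between patient-level DV and
#'   the simulated Ang2 level.
#' @param seed RNG seed used by [generate_cohort()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 11L,
                        lesions_per_patient = 2L,
                        max_lesions = 21L,
                        p_responder = 8 / 21,
                        param_dists = default_param_dists(),
                        noise_snr = 40,
                        s0 = 100,
                        schedule = acq_schedule(),
                        bolus_arrival_s = 20,
                        hct = 0.45,
                        within_patient_rho = 0.3,
                        ang2_rho = 0.6,
                        seed = 1L) {
  if (lesions_per_patient > 2L)
    dce_validation_error("at most two lesions per patient")
  if (p_responder < 0 || p_responder > 1)
    dce_validation_error("p_responder must be a probability")
  if (any(param_dists$sd < 0))
    dce_validation_error("parameter SDs must be non-negative")
  if (noise_snr <= 0) dce_validation_error("noise_snr must be positive")
  if (bolus_arrival_s >= max(schedule$frame_times))
    dce_validation_error("bolus arrival lies after the last frame")
  structure(list(n_patients = as.integer(n_patients),
                 lesions_per_patient = as.integer(lesions_per_patient),
                 max_lesions = max_lesions,
                 p_responder = p_responder,
                 param_dists = param_dists,
                 noise_snr = noise_snr, s0 = s0,
                 schedule = schedule, bolus_arrival_s = bolus_arrival_s,
                 hct = hct,
                 within_patient_rho = within_patient_rho,
                 ang2_rho = ang2_rho,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Deterministic population arterial input function
#'
#' A gamma-variate first pass (mode ~10 s after bolus arrival, peak relative
#' enhancement 3.0 in whole blood) plus a slower recirculation/washout term,
#' sampled at the schedule's frame times; identically zero before bolus
#' arrival. The curve is deterministic — the `seed` argument is accepted for
#' interface symmetry with the stochastic generators and does not change the
#' output.
#'
#' @param schedule an [acq_schedule()].
#' @param bolus_arrival_s arrival time (s after injection), within the
#'   schedule span.
#' @param seed ignored (deterministic curve).
#' @return A [conc_curve()] of kind `"arterial_blood"`.
#' @export
generate_aif <- function(schedule, bolus_arrival_s = 20, seed = NULL) {
  tt <- schedule$frame_times
  if (bolus_arrival_s >= max(tt))
    dce_validation_error("bolus arrival lies after the last frame")
  ts <- pmax(tt - bolus_arrival_s, 0)
  alpha <- 2.5; beta <- 4
  peak_g <- (alpha * beta)^alpha * exp(-alpha)  # gamma-variate mode value
  firstpass <- 3.0 * ts^alpha * exp(-ts / beta) / peak_g
  tail <- 0.8 * (1 - exp(-ts / 30)) * exp(-ts / 300)
  v <- ifelse(tt <= bolus_arrival_s, 0, firstpass + tail)
  conc_curve("aif", tt, v, kind = "arterial_blood")
}

## correlated standard normals per lesion within a patient (Gaussian copula)
.copula_z <- function(n_lesions_per_patient, n_patients, rho) {
  zp <- stats::rnorm(n_patients)
  zl <- matrix(stats::rnorm(n_patients * n_lesions_per_patient),
               n_patients, n_lesions_per_patient)
  sqrt(rho) * zp + sqrt(1 - rho) * zl
}

#' Generate a complete synthetic study
#'
#' Draws per-lesion ground-truth kinetic parameters from truncated normal
#' distributions (DV truncated to (0, 100], Ktrans to [0, 1000]; truncation
#' at physical bounds shifts the realized moments away from the nominal
#' mean/SD — see [truncnorm_moments()]), with a Gaussian-copula correlation
#' between lesions of the same patient. Tissue concentration curves are
#' synthesized with [tofts_forward()] driven by the hematocrit-corrected
#' population AIF, converted back to signal as S = s0 (1 + C), and degraded
#' with Gaussian noise of SD s0/noise_snr. Final mRECIST categories are
#' assigned consistently with the group label (responders CR:PR as 5:3,
#' non-responders SD:PD as 11:2). Patient-level Ang2 is generated
#' rank-correlated with the patient's DV; VEGF and c-KIT are independent of
#' the kinetic parameters.
#'
#' Fully deterministic for a fixed `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `dce_cohort`: `dataset` (a [study_dataset()]
#'   without kinetics), `truth` (data.frame of true parameters and group per
#'   lesion x timepoint), `curves` (long data.frame
#'   `roi_id,time_s,signal,is_baseline` holding lesion and aortic signal
#'   curves), `meta` (roi_id -> patient/lesion/timepoint/type map), `aif`
#'   (the noiseless blood AIF), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  np <- spec$n_patients
  pid <- rep(seq_len(np), each = spec$lesions_per_patient)
  if (is.finite(spec$max_lesions))
    pid <- pid[seq_len(min(length(pid), spec$max_lesions))]
  lid <- stats::ave(pid, pid, FUN = seq_along)
  np_eff <- length(unique(pid))
  lesions_per <- as.vector(table(pid))
  n_les <- length(pid)

  # group labels and final categories
  group <- ifelse(stats::runif(n_les) < spec$p_responder,
                  "responder", "non_responder")
  final <- character(n_les)
  is_r <- group == "responder"
  final[is_r] <- sample(c("CR", "PR"), sum(is_r), TRUE, prob = c(5, 3) / 8)
  final[!is_r] <- sample(c("SD", "PD"), sum(!is_r), TRUE, prob = c(11, 2) / 13)

  # ground-truth kinetic parameters: copula draw per parameter x timepoint
  bounds <- list(dv = c(0, 100), ktrans = c(0, 1000))
  truth <- expand.grid(lesion_row = seq_len(n_les), timepoint = TIMEPOINTS,
                       stringsAsFactors = FALSE)
  truth <- truth[order(truth$lesion_row), ]
  truth$patient_id <- pid[truth$lesion_row]
  truth$lesion_id <- lid[truth$lesion_row]
  truth$group <- group[truth$lesion_row]
  for (par in c("dv", "ktrans")) {
    vals <- matrix(NA_real_, n_les, length(TIMEPOINTS))
    for (j in seq_along(TIMEPOINTS)) {
      z <- .copula_z(max(lesions_per), np_eff, spec$within_patient_rho)
      zl <- z[cbind(match(pid, seq_len(np_eff)), lid)]
      u <- stats::pnorm(zl)
      dist <- spec$param_dists
      for (gname in c("responder", "non_responder")) {
        row <- dist[dist$parameter == par & dist$group == gname &
                      dist$timepoint == TIMEPOINTS[j], ]
        sel <- group == gname
        vals[sel, j] <- qtruncnorm(u[sel], row$mean, row$sd,
                                   bounds[[par]][1], bounds[[par]][2])
      }
    }
    truth[[par]] <- vals[cbind(truth$lesion_row,
                               match(truth$timepoint, TIMEPOINTS))]
  }
  truth$dv <- pmax(truth$dv, 1e-3)  # open lower bound of the DV domain
  truth <- truth[, c("patient_id", "lesion_id", "timepoint", "group",
                     "ktrans", "dv")]
  rownames(truth) <- NULL

  # study table: sizes lognormal (moment-matched to 22.6 +/- 17.9 mm)
  size <- pmax(round(stats::rlnorm(n_les, meanlog = 2.875, sdlog = 0.698)), 5)
  lesions <- data.frame(
    patient_id = pid, lesion_id = lid,
    segment = sample(1:8, n_les, TRUE),
    size_mm = size,
    outcome_3d = final, outcome_10d = final, outcome_final = final)
  patients <- data.frame(
    patient_id = seq_len(np_eff),
    sex = sample(c("m", "f"), np_eff, TRUE, prob = c(8, 3) / 11),
    age_years = round(rtruncnorm(np_eff, 65, 10, 30, 90)),
    interval_premri_tace_days = sample(1:8, np_eff, TRUE),
    interval_tace_followup_days = sample(40:114, np_eff, TRUE),
    followup_modality = sample(c("CT", "MRI", "CTHA"), np_eff, TRUE,
                               prob = c(8, 1, 2) / 11))

  # angiogenesis factors, patient x timepoint; Ang2 rank-correlated with DV
  pat_dv <- do.call(rbind, lapply(split(truth, truth$patient_id), function(g) {
    data.frame(patient_id = g$patient_id[1],
               dv_mean = vapply(TIMEPOINTS,
                                function(tp) mean(g$dv[g$timepoint == tp]),
                                numeric(1)))
  }))
  rho_g <- 2 * sin(pi * spec$ang2_rho / 6)  # copula rho for target Spearman
  ang <- do.call(rbind, lapply(seq_along(TIMEPOINTS), function(j) {
    dvj <- pat_dv$dv_mean[seq(j, nrow(pat_dv), by = length(TIMEPOINTS))]
    zdv <- stats::qnorm((rank(dvj) - 0.5) / np_eff)
    zang <- rho_g * zdv + sqrt(1 - rho_g^2) * stats::rnorm(np_eff)
    data.frame(patient_id = seq_len(np_eff), timepoint = TIMEPOINTS[j],
               ang2_pg_ml = round(3500 + 800 * zang),
               vegf_pg_ml = round(stats::rlnorm(np_eff, log(100), 0.6)),
               ckit_ng_ml = round(rtruncnorm(np_eff, 8.5, 2, 0.5, 30), 1))
  }))
  ang <- ang[order(ang$patient_id, match(ang$timepoint, TIMEPOINTS)), ]
  rownames(ang) <- NULL

  # signal curves
  aif <- generate_aif(spec$schedule, spec$bolus_arrival_s)
  cp <- blood_to_plasma(aif, hematocrit(spec$hct))
  tt <- spec$schedule$frame_times
  nb <- n_baseline_frames(spec$schedule)
  noise_sd <- if (is.finite(spec$noise_snr)) spec$s0 / spec$noise_snr else 0
  meta <- list(); sig <- list()
  mk_signal <- function(conc) {
    s <- spec$s0 * (1 + conc)
    if (noise_sd > 0) s <- s + stats::rnorm(length(s), 0, noise_sd)
    pmax(s, 0)
  }
  for (p in seq_len(np_eff)) {
    for (tp in TIMEPOINTS) {
      rid <- sprintf("P%03d_aorta_%s", p, tp)
      sig[[rid]] <- mk_signal(aif$values)
      meta[[rid]] <- data.frame(roi_id = rid, patient_id = p, lesion_id = NA,
                                timepoint = tp, type = "aorta")
    }
  }
  for (i in seq_len(n_les)) {
    for (tp in TIMEPOINTS) {
      tr <- truth[truth$patient_id == pid[i] & truth$lesion_id == lid[i] &
                    truth$timepoint == tp, ]
      ct <- tofts_forward(kinetic_params(tr$ktrans, tr$dv), cp, tt)
      rid <- sprintf("P%03d_L%d_%s", pid[i], lid[i], tp)
      sig[[rid]] <- mk_signal(ct$values)
      meta[[rid]] <- data.frame(roi_id = rid, patient_id = pid[i],
                                lesion_id = lid[i], timepoint = tp,
                                type = "lesion")
    }
  }
  curves <- do.call(rbind, lapply(names(sig), function(rid) {
    data.frame(roi_id = rid, time_s = tt, signal = sig[[rid]],
               is_baseline = seq_along(tt) <= nb)
  }))
  dataset <- study_dataset(lesions, patients, kinetics = NULL,
                           angiogenesis = ang)
  structure(list(dataset = dataset, truth = truth, curves = curves,
                 meta = do.call(rbind, meta), aif = aif, spec = spec),
            class = "dce_cohort")
}

#' @export
print.dce_cohort <- function(x, ...) {
  cat("<dce_cohort> ", nrow(x$dataset$patients), " patients, ",
      nrow(x$dataset$lesions), " lesions, ",
      length(unique(x$curves$roi_id)), " signal curves (seed ",
      x$spec$seed, ")\n", sep = "")
  invisible(x)
}

#' Fit the kinetic model to every lesion of a cohort
#'
#' Runs the full measurement pipeline on simulated (or imported) signal
#' curves: per patient and timepoint the aortic curve is converted to
#' relative enhancement, hematocrit-corrected to plasma, and used as the AIF
#' to fit [fit_tofts()] to each lesion curve of that session.
#'
#' A quality gate withholds DV where the acquisition does not measure it:
#' when a lesion's tracer influx is so low that the tissue curve never
#' approaches saturation within the 10-minute window, the distribution
#' volume is unidentifiable (the fit escapes along a flat ridge) and its
#' asymptotic standard error explodes. Such DV estimates are reported as
#' `NA` rather than as arbitrary numbers.
#'
#' @param cohort a `dce_cohort` from [generate_cohort()], or a list with
#'   `curves` and `meta` in the same layout.
#' @param hct hematocrit fraction for the blood-to-plasma conversion.
#' @param max_dv_rel_se relative standard-error threshold above which DV is
#'   reported as `NA` (default 0.5, i.e. DV must be determined to better
#'   than about 50 percent); `Inf` disables the gate.
#' @return data.frame `patient_id, lesion_id, timepoint, ktrans, dv, dv_se,
#'   rss, converged` suitable as the `kinetics` slot of a [study_dataset()].
#' @export
fit_cohort <- function(cohort, hct = 0.45, max_dv_rel_se = 0.5) {
  curves <- split(cohort$curves, cohort$curves$roi_id)
  meta <- cohort$meta
  as_curve <- function(g) {
    g <- g[order(g$time_s), ]
    signal_curve(g$roi_id[1], g$time_s, g$signal, sum(g$is_baseline))
  }
  out <- list()
  sessions <- unique(meta[meta$type == "lesion", c("patient_id", "timepoint")])
  for (i in seq_len(nrow(sessions))) {
    p <- sessions$patient_id[i]; tp <- sessions$timepoint[i]
    aid <- meta$roi_id[meta$type == "aorta" & meta$patient_id == p &
                         meta$timepoint == tp]
    if (length(aid) != 1L)
      dce_validation_error(sprintf("no aortic curve for patient %s at %s", p, tp))
    cb <- signal_to_concentration(as_curve(curves[[aid]]),
                                  kind = "arterial_blood")
    cp <- blood_to_plasma(cb, hematocrit(hct))
    lids <- meta[meta$type == "lesion" & meta$patient_id == p &
                   meta$timepoint == tp, ]
    for (j in seq_len(nrow(lids))) {
      ct <- signal_to_concentration(as_curve(curves[[lids$roi_id[j]]]))
      fit <- fit_tofts(ct, cp)
      dv <- fit$params$dv
      if (!is.na(dv) &&
          (!fit$converged || !is.finite(fit$se[["dv"]]) ||
             fit$se[["dv"]] > max_dv_rel_se * dv))
        dv <- NA_real_
      out[[length(out) + 1L]] <- data.frame(
        patient_id = p, lesion_id = lids$lesion_id[j], timepoint = tp,
        ktrans = fit$params$ktrans, dv = dv, dv_se = fit$se[["dv"]],
        rss = fit$rss, converged = fit$converged)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a cohort to CSV files
#'
#' Writes `curves.csv` (signal curves), `meta.csv` (ROI map), `study.csv`
#' (per-lesion study table) and `truth.csv` (ground-truth parameters) into a
#' directory.
#'
#' @param cohort a `dce_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$curves, file.path(dir, "curves.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$meta, file.path(dir, "meta.csv"),
                   row.names = FALSE, quote = FALSE)
  write_study_table(cohort$dataset, file.path(dir, "study.csv"))
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
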