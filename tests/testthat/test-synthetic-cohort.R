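test_that("population AIF is causal, deterministic, and peaks in the arterial phase", {
  s <- acq_schedule()
  aif <- generate_aif(s, bolus_arrival_s = 20)
  expect_true(all(aif$values[aif$times <= 20] == 0))
  expect_identical(aif$values, generate_aif(s, 20)$values)
  tpk <- aif$times[which.max(aif$values)]
  expect_gte(tpk, 20); expect_lte(tpk, 50)
  expect_error(generate_aif(s, bolus_arrival_s = 1e4),
               class = "dce_validation_error")
})

test_that("cohort generation respects structure and is byte-deterministic", {
  co <- generate_cohort(cohort_spec(seed = 5))
  expect_identical(nrow(co$dataset$lesions), 21L)
  expect_true(all(table(co$dataset$lesions$patient_id) <= 2))
  expect_identical(nrow(co$truth), 63L)  # 21 lesions x 3 timepoints
  # group label constant across a lesion's timepoints, consistent with mRECIST
  per_lesion <- split(co$truth$group,
                      paste(co$truth$patient_id, co$truth$lesion_id))
  expect_true(all(vapply(per_lesion, function(g) length(unique(g)) == 1L,
                         logical(1))))
  expect_identical(
    as.character(responder_group(co$dataset$lesions$outcome_final)),
    co$truth$group[co$truth$timepoint == "pre_tace"])
  co2 <- generate_cohort(cohort_spec(seed = 5))
  expect_identical(co, co2)
  expect_false(identical(co$curves$signal,
                         generate_cohort(cohort_spec(seed = 6))$curves$signal))
  expect_error(cohort_spec(lesions_per_patient = 3),
               class = "dce_validation_error")
})

test_that("noiseless simulation round-trips through the fitting pipeline", {
  co <- generate_cohort(cohort_spec(n_patients = 3L, max_lesions = 5L,
                                    noise_snr = Inf, seed = 9))
  fits <- fit_cohort(co)
  m <- merge(fits, co$truth, by = c("patient_id", "lesion_id", "timepoint"),
             suffixes = c("_hat", "_true"))
  expect_identical(nrow(m), 15L)
  expect_true(all(abs(m$ktrans_hat / m$ktrans_true - 1) < 0.01))
  expect_true(all(abs(m$dv_hat / m$dv_true - 1) < 0.01))
})

test_that("generated moments converge to the truncated-normal law", {
  co <- generate_cohort(cohort_spec(n_patients = 250L, max_lesions = 500L,
                                    seed = 31))
  dists <- default_param_dists()
  bounds <- list(dv = c(0, 100), ktrans = c(0, 1000))
  for (i in seq_len(nrow(dists))) {
    row <- dists[i, ]
    v <- co$truth[co$truth$group == row$group &
                    co$truth$timepoint == row$timepoint, ][[row$parameter]]
    mom <- truncnorm_moments(row$mean, row$sd,
                             bounds[[row$parameter]][1],
                             bounds[[row$parameter]][2])
    # within 3 standard errors of the analytic truncated mean
    expect_lt(abs(mean(v) - mom$mean), 3 * mom$sd / sqrt(length(v)) + 1e-9,
              label = sprintf("%s/%s/%s mean", row$parameter, row$group,
                              row$timepoint))
    expect_lt(abs(sd(v) / mom$sd - 1), 0.25)
  }
})

test_that("default-spec responder day-10 DV matches the configured 8.6", {
  co <- generate_cohort(cohort_spec(seed = 1))
  v <- co$truth$dv[co$truth$group == "responder" &
                     co$truth$timepoint == "day10"]
  expect_gte(length(v), 2L)
  expect_lt(abs(mean(v) - 8.6), 2 * 4.7 / sqrt(length(v)))
})

test_that("the simulated effect direction survives the full pipeline", {
  # responder DV must fall monotonically across timepoints after
  # simulate -> convert -> fit -> summarize, for every seed tried
  for (seed in 1:8) {
    co <- generate_cohort(cohort_spec(seed = seed))
    co$dataset$kinetics <- fit_cohort(co)
    s <- summarize_groups(co$dataset, "dv")
    resp <- s$mean[s$group == "responder"][order(match(
      s$timepoint[s$group == "responder"], c("pre_tace", "day3", "day10")))]
    expect_true(all(diff(resp) < 0), label = paste("seed", seed))
  }
})

test_that("angiogenesis covariates carry the configured DV association", {
  co <- generate_cohort(cohort_spec(n_patients = 120L, max_lesions = 240L,
                                    seed = 17))
  pat_dv <- aggregate(dv ~ patient_id + timepoint, co$truth, mean)
  m <- merge(pat_dv, co$dataset$angiogenesis, by = c("patient_id", "timepoint"))
  r_ang2 <- cor(m$dv, m$ang2_pg_ml, method = "spearman")
  r_vegf <- cor(m$dv, m$vegf_pg_ml, method = "spearman")
  expect_gt(r_ang2, 0.4); expect_lt(r_ang2, 0.8)
  expect_lt(abs(r_vegf), 0.2)
})
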