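# Synthetic per-lesion DV values matched to the worked example's printed
# confusion structure: with cutoffs 40/30/17 the three timepoints produce
# (tp,fp,fn,tn) = (7,12,1,1), (8,10,0,3), (7,3,1,10).
table3_kinetics <- function(dataset, seed = 1) {
  set.seed(seed)
  les <- dataset$lesions
  grp <- responder_group(les$outcome_final)
  resp <- which(grp == "responder")     # 8 lesions
  nonr <- which(grp == "non_responder") # 13 lesions
  dv <- matrix(NA_real_, nrow(les), 3,
               dimnames = list(NULL, c("pre_tace", "day3", "day10")))
  below <- function(idx, k) sample(idx, k)  # which lesions sit below cutoff
  # pre-TACE, cutoff 40: 7/8 responders and 12/13 non-responders below
  i <- below(resp, 7); dv[i, 1] <- 30; dv[setdiff(resp, i), 1] <- 50
  i <- below(nonr, 12); dv[i, 1] <- 35; dv[setdiff(nonr, i), 1] <- 45
  # day 3, cutoff 30: all 8 responders and 10/13 non-responders below
  dv[resp, 2] <- 20
  i <- below(nonr, 10); dv[i, 2] <- 25; dv[setdiff(nonr, i), 2] <- 35
  # day 10, cutoff 17: 7/8 responders and 3/13 non-responders below
  i <- below(resp, 7); dv[i, 3] <- 10; dv[setdiff(resp, i), 3] <- 20
  i <- below(nonr, 3); dv[i, 3] <- 15; dv[setdiff(nonr, i), 3] <- 25
  data.frame(patient_id = rep(les$patient_id, 3),
             lesion_id = rep(les$lesion_id, 3),
             timepoint = rep(colnames(dv), each = nrow(les)),
             ktrans = 10,
             dv = as.vector(dv))
}

test_that("the cutoff report reproduces the worked-example diagnostic table", {
  ds <- load_study_table()
  ds$kinetics <- table3_kinetics(ds)
  rep3 <- response_prediction_report(ds)
  rows <- do.call(rbind, Map(format_diagnostic_report, rep3, names(rep3)))
  expect_identical(rows$parameter, c("pre_tace", "day3", "day10"))
  expect_equal(rows$sensitivity_pct, c(88, 100, 88))
  expect_equal(rows$specificity_pct, c(8, 23, 77))
  expect_equal(rows$ppv_pct, c(37, 44, 70))
  expect_equal(rows$npv_pct, c(50, 100, 91))
  expect_equal(rows$cui_positive, c(0.322, 0.444, 0.613))
  expect_equal(rows$cui_negative, c(0.038, 0.231, 0.699))
})

test_that("analyze_study assembles every layer and writes its outputs", {
  co <- tiny_cohort(seed = 23)
  co$dataset$kinetics <- fit_cohort(co)
  res <- analyze_study(co$dataset)
  expect_named(res, c("summaries", "friedman", "mann_whitney",
                      "correlations", "anova", "prediction"))
  expect_s3_class(res$summaries$dv, "data.frame")
  expect_true(length(res$friedman) >= 1)
  for (f in res$friedman) expect_s3_class(f, "stat_result")
  expect_length(res$mann_whitney, 6)
  expect_length(res$correlations, 6)
  expect_length(res$anova, 3)
  expect_named(res$prediction, c("pre_tace", "day3", "day10"))
  dir <- withr::local_tempdir()
  write_analysis(res, dir)
  expect_true(all(file.exists(file.path(
    dir, c("stats.json", "summary_dv.csv", "summary_ktrans.csv",
           "prediction_report.csv")))))
  js <- jsonlite::read_json(file.path(dir, "stats.json"))
  expect_true(all(c("friedman", "mann_whitney", "prediction") %in% names(js)))
})

test_that("YAML configuration overrides the packaged defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("hct: 0.40", "cutoffs:", "  pre_tace: 35", "  day3: 30",
               "  day10: 15"), path)
  cfg <- dce_config(path)
  expect_equal(cfg$hct, 0.40)
  expect_equal(cfg$cutoffs$day10, 15)
  expect_equal(cfg$sd_type, "population")  # untouched default survives
})
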