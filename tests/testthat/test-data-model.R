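test_that("acquisition schedule derives strictly increasing frame midpoints", {
  s <- acq_schedule()
  expect_length(s$frame_times, length(s$phase_starts) * s$frames_per_phase)
  expect_true(all(diff(s$frame_times) > 0))
  # pre-contrast burst lies entirely before injection
  expect_identical(n_baseline_frames(s), 5L)
  expect_true(all(s$frame_times[1:5] < 0))
  # frame midpoints: first frame of a 30-s, 5-frame burst sits 3 s in
  expect_equal(s$frame_times[6:10], 20 + c(3, 9, 15, 21, 27))
  expect_error(acq_schedule(phase_starts = c(0, 10), phase_duration = 30),
               class = "dce_validation_error")
})

test_that("curve tables round-trip and validate", {
  s <- acq_schedule()
  tt <- s$frame_times
  set.seed(1)
  curves <- list(
    signal_curve("lesion_a", tt, 100 + runif(50, 0, 50), 5),
    signal_curve("lesion_b", tt, 80 + runif(50, 0, 40), 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve_table(curves, path)
  back <- read_curve_table(path)
  expect_named(back, c("lesion_a", "lesion_b"))
  for (i in 1:2) {
    expect_equal(back[[i]]$times, curves[[i]]$times, tolerance = 1e-12)
    expect_equal(back[[i]]$values, curves[[i]]$values, tolerance = 1e-12)
    expect_identical(back[[i]]$n_baseline, curves[[i]]$n_baseline)
  }
  # missing column is a format error; all-FALSE baseline a validation error
  d <- utils::read.csv(path)
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d[, -4], path2, row.names = FALSE)
  expect_error(read_curve_table(path2), class = "dce_format_error")
  d$is_baseline <- FALSE
  utils::write.csv(d, path2, row.names = FALSE)
  expect_error(read_curve_table(path2), class = "dce_validation_error")
})

test_that("signal curves reject non-monotone times and bad baselines", {
  expect_error(signal_curve("x", c(1, 3, 2), c(1, 1, 1), 1),
               class = "dce_validation_error")
  expect_error(signal_curve("x", 1:3, c(1, -1, 1), 1),
               class = "dce_validation_error")
  expect_error(signal_curve("x", 1:3, c(1, 1, 1), 0),
               class = "dce_validation_error")
})

test_that("ROI extraction averages voxels per label and recovers known curves", {
  s <- acq_schedule()
  tt <- s$frame_times
  const <- signal_curve("c", tt, rep(100, 50), 5)
  ramp <- signal_curve("r", tt, 100 + pmax(tt, 0) / 10, 5)
  ph <- phantom_image(list(const, ramp), dims = c(6L, 6L, 3L))
  got <- extract_roi_curves(ph$image, ph$mask, s)
  expect_length(got, 2L)
  expect_equal(got[["roi_1"]]$values, rep(100, 50))
  expect_equal(got[["roi_2"]]$values, ramp$values, tolerance = 1e-12)
  expect_identical(got[["roi_1"]]$n_baseline, 5L)
  # dimension mismatch and missing labels are rejected
  expect_error(extract_roi_curves(ph$image, ph$mask[-1, , ], s),
               class = "dce_validation_error")
  expect_error(extract_roi_curves(ph$image, array(0L, dim(ph$mask)), s),
               class = "dce_validation_error")
})

test_that("NIfTI file input reaches the same curves as in-memory arrays", {
  skip_if_not_installed("RNifti")
  s <- acq_schedule()
  curve <- signal_curve("c", s$frame_times, 100 + pmax(s$frame_times, 0), 5)
  ph <- phantom_image(list(curve), dims = c(4L, 4L, 2L))
  img_path <- withr::local_tempfile(fileext = ".nii.gz")
  mask_path <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(ph$image), img_path)
  RNifti::writeNifti(RNifti::asNifti(ph$mask + 0), mask_path)
  got <- extract_roi_curves(img_path, mask_path, s)
  expect_equal(got[["roi_1"]]$values, curve$values, tolerance = 1e-6)
})

test_that("the packaged study table reproduces the cohort's descriptives", {
  ds <- load_study_table()
  d <- describe_study(ds)
  expect_identical(d$n_patients, 11L)
  expect_identical(d$n_lesions, 21L)
  expect_equal(round(d$size_mean_mm, 1), 22.6)
  expect_equal(round(d$size_sd_mm, 1), 17.9)
  expect_equal(round(d$interval_mean_days, 1), 2.7)
  expect_equal(round(d$interval_sd_days, 1), 2.0)
  # the population-vs-sample SD convention matters at this cohort size
  expect_equal(round(describe_study(ds, "sample")$interval_sd_days, 1), 2.1)
})

test_that("study tables round-trip and reject more than two lesions per patient", {
  ds <- load_study_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_study_table(ds, path)
  back <- load_study_table(path)
  expect_equal(back$lesions, ds$lesions)
  expect_equal(back$patients, ds$patients)
  d <- utils::read.csv(dcekit_example("study_table1.csv"))
  d <- rbind(d, transform(d[d$patient_id == 1, ][1, ], size_mm = 12))
  utils::write.csv(d, path, row.names = FALSE)
  expect_error(load_study_table(path), class = "dce_validation_error")
})
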