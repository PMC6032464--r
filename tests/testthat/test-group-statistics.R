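test_that("Friedman statistic and exact p behave on canonical inputs", {
  m <- t(sapply(1:8, function(i) c(30, 20, 10) + i))  # every row decreasing
  f <- friedman_exact(m)
  expect_true(f$exact)
  expect_equal(f$statistic, 16)
  expect_equal(f$p_value, 6 / 6^8)   # only fully concordant orderings
  expect_lt(f$p_value, 0.001)
  const <- matrix(5, 4, 3)
  fc <- friedman_exact(const)
  expect_equal(fc$statistic, 0); expect_equal(fc$p_value, 1)
  # exchangeability: permuting columns leaves the p unchanged
  set.seed(2); x <- matrix(rnorm(15), 5, 3)
  expect_equal(friedman_exact(x)$p_value,
               friedman_exact(x[, c(3, 1, 2)])$p_value)
  expect_error(friedman_exact(matrix(c(1, NA, 2, 3, 4, 5), 2, 3)),
               class = "dce_validation_error")
})

test_that("Friedman agrees with full enumeration and the base-R statistic", {
  set.seed(8)
  for (i in 1:6) {
    n <- sample(2:4, 1)
    x <- matrix(rnorm(3 * n), n, 3)
    if (i %% 2 == 0) x[1, 1] <- x[1, 2]  # inject a tie
    f <- friedman_exact(x)
    expect_equal(f$p_value, friedman_enum_p(x), tolerance = 1e-12)
  }
  y <- matrix(rnorm(30), 10, 3)
  expect_equal(friedman_exact(y, exact_limit = 2)$statistic,
               unname(stats::friedman.test(y)$statistic))
  expect_equal(friedman_exact(y, exact_limit = 2)$p_value,
               stats::friedman.test(y)$p.value)
})

test_that("Mann-Whitney exact p matches enumeration and known cases", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_true(r$exact)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)
  # identical multisets: p = 1 by symmetry
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # label symmetry
  set.seed(5); x <- rnorm(5); y <- rnorm(7)
  expect_equal(mann_whitney_u(x, y)$p_value, mann_whitney_u(y, x)$p_value)
  # agreement with enumeration oracle and with base R for all small sizes
  for (m in 1:3) for (n in m:(6 - m)) {
    xx <- rnorm(m); yy <- rnorm(n)
    mine <- mann_whitney_u(xx, yy)
    expect_equal(mine$p_value, mw_enum_p(xx, yy), tolerance = 1e-12,
                 label = sprintf("m=%d n=%d", m, n))
    expect_equal(mine$p_value,
                 stats::wilcox.test(xx, yy, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1), class = "dce_validation_error")
})

test_that("Spearman correlation handles ranks, exactness and degeneracy", {
  expect_equal(spearman_rank(1:5, c(2, 4, 6, 8, 10))$estimate, 1)
  expect_equal(spearman_rank(1:5, 5:1)$estimate, -1)
  r <- spearman_rank(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$estimate, 0.6)
  expect_equal(r$p_value, spearman_enum_p(c(1, 2, 3, 4), c(2, 1, 4, 3)))
  set.seed(6)
  for (i in 1:4) {
    x <- rnorm(5); y <- rnorm(5)
    expect_equal(spearman_rank(x, y)$p_value, spearman_enum_p(x, y),
                 tolerance = 1e-12)
  }
  # large-n path matches the t-approximation used by base R
  x <- rnorm(20); y <- x + rnorm(20)
  expect_equal(spearman_rank(x, y)$p_value,
               stats::cor.test(x, y, method = "spearman",
                               exact = FALSE)$p.value,
               tolerance = 1e-10)
  cz <- spearman_rank(rep(1, 4), rnorm(4))
  expect_true(is.na(cz$estimate)); expect_true(is.na(cz$p_value))
})

test_that("repeated-measures ANOVA matches aov and handles degeneracy", {
  set.seed(4)
  N <- 10; vals <- matrix(rnorm(N * 3), N, 3)
  grp <- rep(c("a", "b"), each = 5)
  r <- anova_across_time(vals, grp)
  d <- data.frame(y = as.vector(vals), s = factor(rep(1:N, 3)),
                  t = factor(rep(1:3, each = N)), g = rep(grp, 3))
  a <- summary(stats::aov(y ~ g * t + Error(s), data = d))[["Error: Within"]][[1]]
  expect_equal(r$time$statistic, a["t", "F value"], tolerance = 1e-10)
  expect_equal(r$interaction$statistic, a["g:t", "F value"], tolerance = 1e-10)
  expect_equal(r$time$p_value, a["t", "Pr(>F)"], tolerance = 1e-10)
  # additive time effect, zero noise: interaction F = 0, time F unbounded
  v2 <- matrix(rep(c(1, 2, 3), each = 6), 6, 3) + 5
  r2 <- anova_across_time(v2, rep(c("a", "b"), 3))
  expect_identical(r2$interaction$statistic, 0)
  expect_identical(r2$interaction$p_value, 1)
  expect_identical(r2$time$statistic, Inf)
  expect_identical(r2$time$p_value, 0)
  # all-equal data: F = 0
  r3 <- anova_across_time(matrix(7, 6, 3), rep(c("a", "b"), 3))
  expect_identical(r3$time$statistic, 0)
  expect_error(anova_across_time(vals, rep("a", 9)),
               class = "dce_validation_error")
})

test_that("group summaries follow the mean +/- SD layout", {
  co <- tiny_cohort(seed = 12)
  co$dataset$kinetics <- co$truth[, c("patient_id", "lesion_id", "timepoint",
                                      "ktrans", "dv")]
  s <- summarize_groups(co$dataset, "dv")
  expect_named(s, c("group", "timepoint", "n", "mean", "sd"))
  expect_identical(sum(s$n), nrow(co$truth))
  # duplicating every kinetic record leaves the means unchanged
  s2 <- summarize_groups(
    study_dataset(co$dataset$lesions, co$dataset$patients,
                  kinetics = rbind(co$dataset$kinetics, co$dataset$kinetics)),
    "dv")
  expect_equal(s2$mean, s$mean)
  # a single-lesion group has SD 0 under the population convention
  one <- study_dataset(
    data.frame(patient_id = 1, lesion_id = 1, segment = 1, size_mm = 10,
               outcome_3d = "CR", outcome_10d = "CR", outcome_final = "CR"),
    data.frame(patient_id = 1),
    kinetics = data.frame(patient_id = 1, lesion_id = 1,
                          timepoint = c("pre_tace", "day3", "day10"),
                          ktrans = c(50, 10, 5), dv = c(30, 15, 9)))
  s1 <- suppressWarnings(summarize_groups(one, "dv"))
  expect_true(all(s1$sd == 0))
})

test_that("null-calibration: exact Mann-Whitney keeps its size near 5%", {
  set.seed(99)
  rejections <- mean(replicate(400, {
    mann_whitney_u(rnorm(8), rnorm(13))$p_value <= 0.05
  }))
  expect_gte(rejections, 0.02); expect_lte(rejections, 0.08)
})
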