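test_that("ROC curve places thresholds at midpoints and includes endpoints", {
  r <- roc_curve(c(TRUE, TRUE, FALSE, FALSE), c(3, 4, 0, 1))
  # perfect separation: an operating point with sens = spec = 1 exists
  expect_true(any(r$points$sensitivity == 1 & r$points$specificity == 1))
  # degenerate endpoints present
  expect_true(any(r$points$sensitivity == 1 & r$points$specificity == 0))
  expect_true(any(r$points$sensitivity == 0 & r$points$specificity == 1))
  # thresholds strictly ordered; sens non-increasing, spec non-decreasing
  expect_true(all(diff(r$points$threshold) > 0))
  expect_true(all(diff(r$points$sensitivity) <= 0))
  expect_true(all(diff(r$points$specificity) >= 0))

  # overlapping classes: no perfect operating point
  r2 <- roc_curve(c(TRUE, TRUE, FALSE, FALSE), c(2, 1, 2, 0))
  expect_false(any(r2$points$sensitivity == 1 & r2$points$specificity == 1))

  expect_error(roc_curve(c(TRUE, TRUE), c(1, 2)), "ROC undefined")
})

test_that("optimal cut point minimises distance to the top-left corner", {
  r <- roc_curve(c(TRUE, TRUE, FALSE, FALSE), c(3, 4, 0, 1))
  cp <- optimal_cutpoint(r)
  expect_equal(cp$threshold, 2.0)
  expect_equal(cp$sensitivity, 1)
  expect_equal(cp$specificity, 1)
  expect_equal(cp$distance_to_corner, 0)
})

test_that("cut point ties break toward higher sensitivity then smaller |threshold|", {
  fake <- structure(list(points = data.frame(
    threshold = c(1, 2, 3),
    sensitivity = c(0.9, 0.8, 0.5),
    specificity = c(0.8, 0.9, 0.5))), class = "prom_roc")
  cp <- optimal_cutpoint(fake)
  expect_equal(cp$sensitivity, 0.9)
  expect_equal(cp$threshold, 1)
  # exact duplicate points: smaller |threshold| wins
  fake2 <- structure(list(points = data.frame(
    threshold = c(-3, 2), sensitivity = c(0.9, 0.9),
    specificity = c(0.9, 0.9))), class = "prom_roc")
  expect_equal(optimal_cutpoint(fake2)$threshold, 2)
})

test_that("AUC equals the Mann-Whitney probability, ties counted half", {
  expect_equal(auc(c(TRUE, TRUE, FALSE, FALSE), c(4, 3, 2, 1)), 1.0)
  # enumerated by hand over the 4 positive-negative pairs: (2,2)=.5,
  # (2,0)=1, (1,2)=0, (1,0)=1 -> 2.5/4
  expect_equal(auc(c(TRUE, TRUE, FALSE, FALSE), c(2, 1, 2, 0)), 0.625)
  expect_error(auc(c(TRUE, TRUE), c(1, 2)), "both classes")

  # labels independent of scores: AUC near 1/2 (Monte Carlo, n = 10000)
  set.seed(7)
  lab <- sample(c(TRUE, FALSE), 10000, replace = TRUE)
  sc <- sample(0:10, 10000, replace = TRUE)
  expect_lt(abs(auc(lab, sc) - 0.5), 0.02)
})

test_that("pair-counting AUC equals trapezoidal area and flips under relabeling", {
  set.seed(11)
  for (i in 1:50) {
    inst <- random_roc_instance()
    a <- auc(inst$labels, inst$scores)
    expect_equal(a, trapezoid_auc(roc_curve(inst$labels, inst$scores)),
                 tolerance = 1e-12)
    expect_equal(auc(!inst$labels, inst$scores), 1 - a, tolerance = 1e-12)
    expect_equal(auc(inst$labels, inst$scores, "lower_score_positive"), 1 - a,
                 tolerance = 1e-12)
  }
})

test_that("AUC and DeLong interval agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  for (i in 1:10) {
    inst <- random_roc_instance()
    if (sum(inst$labels) < 2 || sum(!inst$labels) < 2) next
    ours <- auc_ci_delong(inst$labels, inst$scores)
    ref <- suppressWarnings(suppressMessages(
      pROC::ci.auc(pROC::roc(inst$labels, inst$scores, direction = "<",
                             quiet = TRUE), method = "delong")))
    expect_equal(ours$auc, as.numeric(ref[2]), tolerance = 1e-10)
    expect_equal(ours$ci_low, max(0, as.numeric(ref[1])), tolerance = 1e-10)
    expect_equal(ours$ci_high, min(1, as.numeric(ref[3])), tolerance = 1e-10)
  }
})

test_that("DeLong interval behaves at the edges and is monotone in alpha", {
  lab <- rep(c(TRUE, FALSE), each = 20)
  sc <- c(rnorm(20, 5), rnorm(20, 0))
  expect_warning(res <- auc_ci_delong(lab, sc), "perfect separation")
  expect_equal(res$ci_low, 1)
  expect_equal(res$ci_high, 1)

  set.seed(21)
  lab <- rep(c(TRUE, FALSE), each = 100)
  sc <- c(rnorm(100, 0.8), rnorm(100))
  ci95 <- auc_ci_delong(lab, sc, alpha = 0.05)
  ci90 <- auc_ci_delong(lab, sc, alpha = 0.10)
  expect_gt(ci90$ci_low, ci95$ci_low)
  expect_lt(ci90$ci_high, ci95$ci_high)
  expect_error(auc_ci_delong(c(TRUE, FALSE, FALSE), c(1, 2, 3)), "at least 2")
})

test_that("discrimination labels follow the conventional AUC bands", {
  set.seed(3)
  lab <- rep(c(TRUE, FALSE), each = 50)
  weak <- c(rnorm(50, 0.2), rnorm(50))
  strong <- c(rnorm(50, 3), rnorm(50))
  expect_equal(auc_ci_delong(lab, weak)$discrimination_label, "poor")
  expect_equal(suppressWarnings(auc_ci_delong(lab, strong))$discrimination_label,
               "excellent")
})

test_that("bootstrap percentile intervals are seeded, nested and calibrated", {
  x <- rnorm(250)
  ci_a <- bootstrap_ci(mean, x, n_reps = 400, seed = 99)
  ci_b <- bootstrap_ci(mean, x, n_reps = 400, seed = 99)
  expect_identical(ci_a, ci_b)                      # determinism
  ci_90 <- bootstrap_ci(mean, x, n_reps = 400, alpha = 0.10, seed = 99)
  expect_gte(ci_90[1], ci_a[1])                     # nesting
  expect_lte(ci_90[2], ci_a[2])

  # constant statistic: degenerate interval
  expect_equal(unclass(bootstrap_ci(function(d) 1.5, x, n_reps = 50,
                                    seed = 1))[1:2], c(1.5, 1.5))

  # width close to the closed-form normal interval 2 * 1.96 / sqrt(250)
  set.seed(5)
  x <- rnorm(250)
  ci <- bootstrap_ci(mean, x, n_reps = 2000, seed = 17)
  expect_lt(abs((ci[2] - ci[1]) - 2 * 1.96 / sqrt(250)) /
              (2 * 1.96 / sqrt(250)), 0.2)
})

test_that("bootstrap redraws undefined resamples and fails above 20%", {
  # statistic undefined unless the resample contains both classes
  d <- data.frame(g = rep(c(TRUE, FALSE), c(39, 1)), y = rnorm(40))
  stat <- function(r) {
    if (!any(r$g) || all(r$g)) stop("one class")
    mean(r$y[r$g]) - mean(r$y[!r$g])
  }
  ci <- bootstrap_ci(stat, d, n_reps = 100, seed = 2)
  expect_true(is.finite(ci[1]) && is.finite(ci[2]))

  # always-undefined statistic errors with the failure rate
  expect_error(bootstrap_ci(function(r) NA_real_, d, n_reps = 20, seed = 2),
               "undefined on 100%")
})

test_that("cluster bootstrap resamples whole patients", {
  d <- data.frame(pid = rep(1:10, each = 5), y = rnorm(50))
  # statistic = number of distinct patients; under cluster resampling the
  # rows of each drawn patient always appear as a block of 5
  stat <- function(r) {
    counts <- table(r$pid)
    if (all(counts %% 5 == 0)) 1 else 0
  }
  ci <- bootstrap_ci(stat, d, n_reps = 50, seed = 3, cluster = d$pid)
  expect_equal(unclass(ci)[1:2], c(1, 1))
})
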