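test_that("mean change method averages the 'somewhat better' pairs only", {
  p <- make_pairs(change = c(2, 3, 4, 9, -1),
                  grc_label = c("somewhat_better", "somewhat_better",
                                "somewhat_better", "much_better", "unchanged"))
  fit <- mid(p, "mc", n_boot = 0)
  expect_equal(fit$mid, 3.0)
  expect_equal(fit$n_improved, 3L)

  # single pair: estimate passes through, bootstrap CI degenerates
  p1 <- make_pairs(2.5, "somewhat_better")
  expect_warning(fit1 <- mid(p1, "mc", n_boot = 50, seed = 1), "degenerate")
  expect_equal(fit1$mid, 2.5)
  expect_equal(fit1$ci_low, fit1$ci_high)

  expect_error(mid(make_pairs(1, "much_better"), "mc", n_boot = 0),
               "somewhat_better")
})

test_that("mean difference of change subtracts the unchanged group mean", {
  p <- make_pairs(change = c(3, 4, 1),
                  grc_label = c("somewhat_better", "somewhat_better",
                                "unchanged"))
  expect_equal(mid(p, "mdc", n_boot = 0)$mid, 2.5)

  # identical group means -> zero
  p0 <- make_pairs(c(2, 2), c("somewhat_better", "unchanged"))
  expect_equal(mid(p0, "mdc", n_boot = 0)$mid, 0)

  expect_error(mid(make_pairs(1, "somewhat_better"), "mdc", n_boot = 0),
               "unchanged")
})

test_that("mdc identity: mid_mdc = mid_mc - mean(unchanged changes)", {
  set.seed(43)
  for (i in 1:20) {
    n_sb <- sample(2:20, 1); n_un <- sample(2:20, 1); n_mb <- sample(0:10, 1)
    p <- make_pairs(
      change = c(rnorm(n_sb, 3), rnorm(n_un, 0.5), rnorm(n_mb, 5)),
      grc_label = rep(c("somewhat_better", "unchanged", "much_better"),
                      c(n_sb, n_un, n_mb)))
    mdc <- mid(p, "mdc", n_boot = 0)$mid
    mc <- mid(p, "mc", n_boot = 0)$mid
    expect_equal(mdc, mc - mean(p$change[p$grc_label == "unchanged"]))
  }
})

test_that("ROC MID finds the separating midpoint with its operating stats", {
  p <- make_pairs(change = c(3, 4, 0, 1),
                  grc_label = rep(c("somewhat_better", "unchanged"), each = 2))
  fit <- suppressWarnings(mid(p, "roc", n_boot = 0))
  expect_equal(fit$mid, 2.0)
  expect_equal(fit$sensitivity, 1)
  expect_equal(fit$specificity, 1)
  expect_equal(fit$auc$auc, 1)
  expect_error(mid(make_pairs(c(1, 2), c("somewhat_better", "unchanged")),
                   "roc", n_boot = 0), ">= 2")
})

test_that("ROC MID equals brute-force search over all midpoint thresholds", {
  set.seed(47)
  for (i in 1:30) {
    n <- sample(8:50, 1)
    lab <- c("somewhat_better", "unchanged")[
      sample(1:2, n, replace = TRUE, prob = c(0.6, 0.4))]
    if (sum(lab == "somewhat_better") < 2 || sum(lab == "unchanged") < 2) next
    change <- sample(seq(-3, 8, by = 0.5), n, replace = TRUE) +
      (lab == "somewhat_better") * sample(0:3, n, replace = TRUE)
    p <- make_pairs(change, lab)
    fit <- suppressWarnings(mid(p, "roc", n_boot = 0))
    oracle <- brute_force_cutpoint(lab == "somewhat_better", change)
    expect_equal(fit$mid, oracle$threshold)
    expect_equal(fit$sensitivity, oracle$sensitivity)
    expect_equal(fit$specificity, oracle$specificity)
  }
})

test_that("predictive MID follows the likelihood-ratio-1 closed form", {
  set.seed(53)
  n <- 200
  change <- runif(n, -2, 7)
  prob <- plogis(-3 + 1.5 * change)
  lab <- ifelse(runif(n) < prob, "somewhat_better", "unchanged")
  p <- make_pairs(change, lab)
  fit <- mid(p, "predictive", n_boot = 0)
  # prevalence-adjusted estimate vs its own coefficients, exactly
  expect_equal(fit$mid, (log(fit$pre_odds) - fit$C) / fit$B)
  expect_equal(fit$mid_unadjusted, -fit$C / fit$B)
  expect_equal(fit$pre_odds, fit$n_improved / fit$n_reference)

  # coefficients agree with a direct likelihood maximisation oracle
  ml <- logistic_ml_oracle(as.numeric(lab == "somewhat_better"), change)
  expect_equal(unname(fit$C), ml[1], tolerance = 1e-4)
  expect_equal(unname(fit$B), ml[2], tolerance = 1e-4)

  # worked closed forms: C = -5, B = 2 give 2.5 at even odds, 3.0 at odds e
  expect_equal((log(1) - (-5)) / 2, 2.5)
  expect_equal((log(exp(1)) - (-5)) / 2, 3.0)
})

test_that("predictive MID rejects separation and inverse relationships", {
  p_sep <- make_pairs(c(5, 6, 7, 0, 1, 2),
                      rep(c("somewhat_better", "unchanged"), each = 3))
  expect_error(mid(p_sep, "predictive", n_boot = 0), "ROC")
  set.seed(59)
  change <- rnorm(60)
  lab <- ifelse(change < rnorm(60, 0.3), "somewhat_better", "unchanged")
  p_inv <- make_pairs(change, lab)
  expect_error(mid(p_inv, "predictive", n_boot = 0), "inversely related")
})

test_that("shifting all change scores by delta translates the MID estimates", {
  set.seed(61)
  n <- 120
  change <- round(rnorm(n, 2, 2) * 2) / 2
  lab <- ifelse(plogis(-2 + 1.2 * change) > runif(n),
                sample(c("somewhat_better", "much_better"), n, replace = TRUE),
                "unchanged")
  p <- make_pairs(change, lab)
  delta <- 1.5
  p_shift <- p
  p_shift$change <- p$change + delta
  for (m in c("mc", "roc", "predictive")) {
    a <- suppressWarnings(mid(p, m, n_boot = 0)$mid)
    b <- suppressWarnings(mid(p_shift, m, n_boot = 0)$mid)
    expect_equal(b, a + delta, tolerance = 1e-6)
  }
  # the mean difference of change is a contrast, so it is shift-invariant
  expect_equal(mid(p_shift, "mdc", n_boot = 0)$mid,
               mid(p, "mdc", n_boot = 0)$mid)
})

test_that("improved set for ROC/predictive includes 'much better'", {
  p <- make_pairs(change = c(3, 4, 5, 6, 0, 1),
                  grc_label = c("somewhat_better", "somewhat_better",
                                "much_better", "much_better",
                                "unchanged", "unchanged"))
  fit <- suppressWarnings(mid(p, "roc", n_boot = 0))
  expect_equal(fit$n_improved, 4L)
  expect_equal(fit$n_reference, 2L)
  # deteriorated levels are excluded, not counted in either group
  p2 <- make_pairs(change = c(3, 4, 5, 6, 0, 1, -2, -4),
                   grc_label = c("somewhat_better", "somewhat_better",
                                 "much_better", "much_better",
                                 "unchanged", "unchanged",
                                 "somewhat_worse", "much_worse"))
  fit2 <- suppressWarnings(mid(p2, "roc", n_boot = 0))
  expect_equal(fit2$n_improved + fit2$n_reference, 6L)

  expect_error(grc_dichotomization(improved = "much_better",
                                   reference = "unchanged",
                                   excluded = c("somewhat_worse", "much_worse")),
               "partition")
})

test_that("bootstrap CIs bracket the estimate and respect the resampling unit", {
  coh <- generate_cohort(synthetic_config(seed = 29))
  p <- build_pairs(coh, "nrs")
  fit <- mid(p, "roc", n_boot = 200, seed = 7)
  expect_true(fit$ci_low <= fit$mid && fit$mid <= fit$ci_high)
  fit_cl <- mid(p, "roc", n_boot = 200, seed = 7, boot_unit = "patient")
  expect_true(fit_cl$ci_low <= fit_cl$mid && fit_cl$mid <= fit_cl$ci_high)
  # same seed, same unit: identical interval
  fit2 <- mid(p, "roc", n_boot = 200, seed = 7)
  expect_identical(c(fit$ci_low, fit$ci_high), c(fit2$ci_low, fit2$ci_high))
})

test_that("mid_all assembles 4 methods x 4 instruments with per-cell failures", {
  coh <- generate_cohort(synthetic_config(seed = 37))
  mt <- suppressWarnings(mid_all(coh, n_boot = 0))
  expect_equal(nrow(mt), 16L)
  expect_true(all(is.na(mt$error)))
  expect_true(all(is.finite(mt$mid)))

  # remove every unchanged rating: mc still works, the rest fail per cell
  coh2 <- coh
  coh2$grc[!is.na(coh2$grc) & coh2$grc == 3L] <- 2L
  mt2 <- suppressWarnings(mid_all(coh2, instruments = "nrs", n_boot = 0))
  expect_true(is.na(mt2$error[mt2$method == "mc"]))
  expect_true(all(!is.na(mt2$error[mt2$method != "mc"])))
})

test_that("on the calibrated regime MID estimates sit in plausible bands", {
  coh <- generate_cohort(synthetic_config(seed = 67))
  mt <- suppressWarnings(mid_all(coh, n_boot = 0))
  nrs <- mt[mt$instrument == "nrs", ]
  expect_true(all(nrs$mid >= 1 & nrs$mid <= 4))
  tot <- mt[mt$instrument == "prwhe_total", ]
  expect_true(all(tot$mid[tot$method != "mc"] >= 8 &
                    tot$mid[tot$method != "mc"] <= 30))
  # the mean-change cell tracks the generator's own conditional mean
  p <- build_pairs(generate_cohort(synthetic_config(n_patients = 2000,
                                                    seed = 71)),
                   "prwhe_total")
  truth <- mean(p$change[p$grc_label == "somewhat_better"])
  expect_lt(abs(tot$mid[tot$method == "mc"] - truth) / truth, 0.25)
})
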