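test_that("default configuration draws the study-shaped cohort", {
  coh <- generate_cohort(synthetic_config())
  expect_equal(length(unique(coh$patient_id)), 50L)
  expect_equal(nrow(coh), 300L)
  fu <- coh[coh$timepoint != "baseline", ]
  expect_equal(nrow(fu), 250L)
  expect_true(all(!is.na(fu$grc)))
  expect_true(all(!is.na(fu$pass_satisfied)))
  expect_true(all(is.na(coh$grc[coh$timepoint == "baseline"])))
  # instrument ranges and integer NRS
  expect_true(all(coh$nrs >= 0 & coh$nrs <= 10 & coh$nrs == round(coh$nrs)))
  expect_true(all(coh$prwhe_total >= 0 & coh$prwhe_total <= 100))
  expect_equal(coh$prwhe_total, coh$prwhe_pain + coh$prwhe_function)
})

test_that("identical configurations reproduce identical cohorts", {
  a <- generate_cohort(synthetic_config(seed = 123))
  b <- generate_cohort(synthetic_config(seed = 123))
  expect_identical(a, b)
  c <- generate_cohort(synthetic_config(seed = 124))
  expect_false(identical(a, c))
  # the caller's RNG stream is untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_cohort(synthetic_config(seed = 9)))
  expect_identical(rnorm(1), before)
})

test_that("noiseless anchors make the GRC a step function of improvement", {
  cfg <- synthetic_config(n_patients = 150, seed = 17,
                          noise_sd = c(nrs = 0, prwhe_pain = 0,
                                       prwhe_function = 0),
                          anchor_noise_sd = 0)
  coh <- generate_cohort(cfg)
  p <- build_pairs(coh, "nrs")
  fit <- suppressWarnings(mid(p, "roc", n_boot = 0))
  # recovery up to the score granularity (integer NRS, half-point cuts)
  expect_lte(abs(fit$mid - true_parameters(cfg)$true_mid[1]), 0.5)
  expect_gt(fit$auc$auc, 0.97)
})

test_that("larger improvement couples monotonically to better GRC", {
  coh <- generate_cohort(synthetic_config(n_patients = 400, seed = 19))
  p <- build_pairs(coh, "nrs")
  # better GRC = smaller code, so the rank correlation with change is negative
  expect_lt(spearman_rho(p$grc, p$change), -0.5)
})

test_that("ground-truth readback maps the latent thresholds to score scales", {
  cfg <- synthetic_config()
  tp <- true_parameters(cfg)
  expect_equal(tp$true_mid[tp$instrument == "nrs"], 2.5)
  expect_equal(tp$true_mid[tp$instrument == "prwhe_total"], 25)
  expect_equal(tp$true_pass[tp$instrument == "nrs"], 2.5)
  expect_equal(tp$true_pass[tp$instrument == "prwhe_pain"], 12.5)
  # truth is independent of measurement noise
  cfg0 <- synthetic_config(noise_sd = c(nrs = 0, prwhe_pain = 0,
                                        prwhe_function = 0))
  expect_equal(true_parameters(cfg0), tp)
})

test_that("configuration validation rejects impossible settings", {
  expect_error(synthetic_config(grc_thresholds = c(1, 2, 2, 3)),
               "strictly increasing")
  expect_error(synthetic_config(missing_rate = 1.2), "missing_rate")
  expect_error(synthetic_config(pass_scale = 0), "pass_scale")
  expect_error(synthetic_config(n_patients = 0), "n_patients")
})

test_that("item-level synthesis is consistent with the subscale scores", {
  coh <- generate_cohort(synthetic_config(n_patients = 8, seed = 3,
                                          items = TRUE))
  items <- as.matrix(coh[sprintf("prwhe_item_%02d", 1:15)])
  for (i in seq_len(nrow(coh))) {
    sc <- score_prwhe(items[i, ])
    expect_equal(sc[["pain"]], coh$prwhe_pain[i])
    expect_equal(sc[["fn"]], coh$prwhe_function[i])
  }
})

test_that("missingness is applied at random and surfaces in exclusion logs", {
  coh <- generate_cohort(synthetic_config(n_patients = 40, seed = 7,
                                          missing_rate = 0.15))
  fu <- coh[coh$timepoint != "baseline", ]
  expect_gt(sum(is.na(fu$grc)), 0)
  p <- build_pairs(coh, "nrs")
  expect_gt(attr(p, "exclusions")[["missing_anchor"]], 0)
  expect_equal(nrow(p),
               sum(!is.na(fu$grc) & !is.na(fu$nrs) &
                     fu$patient_id %in%
                       coh$patient_id[coh$timepoint == "baseline"]))
})

test_that("generator config files round-trip through the flat key-value format", {
  cfg <- synthetic_config(n_patients = 21, seed = 77, missing_rate = 0.05,
                          items = TRUE)
  path <- tempfile(fileext = ".txt")
  write_synthetic_config(cfg, path)
  cfg2 <- read_synthetic_config(path)
  expect_equal(cfg2, cfg)
  expect_identical(generate_cohort(cfg2), generate_cohort(cfg))
})

test_that("the bundled paper-regime configuration loads and reproduces", {
  path <- system.file("extdata", "paper_regime_config.txt",
                      package = "midpass")
  expect_true(nzchar(path))
  cfg <- read_synthetic_config(path)
  expect_equal(cfg$n_patients, 50L)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh), 300L)
})
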