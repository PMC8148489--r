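test_that("a perfect predictor reproduces the hand-counted accuracy", {
  sim <- tiny_sim(n = 80, d = 10, k = 2, noise_sd = 0.3, seed = 22,
                  censor_fraction = 0.5)
  fup <- sim$followup
  truth <- sim$truth$true_survival_living
  oracle_model <- function(cohort) truth  # knows true survival exactly

  report <- validate_on_followup(oracle_model, fup)
  hand_count <- sum(truth > fup$followup_years)
  expect_equal(report$n_estimate_exceeds_followup, hand_count)
  expect_equal(report$classification_accuracy,
               hand_count / report$n_patients)
  expect_equal(nrow(report$per_patient), report$n_patients)
  # the cohort construction exercises both outcomes
  expect_gt(hand_count, 0)
  expect_lt(hand_count, report$n_patients)

  # accuracy + remaining fraction is exactly 1
  n_rem <- sum(!report$per_patient$exceeds)
  expect_equal(report$classification_accuracy + n_rem / report$n_patients,
               1, tolerance = 1e-15)
})

test_that("accuracy responds monotonically to censoring severity", {
  sim <- tiny_sim(n = 40, d = 8, k = 2, noise_sd = 0.2, seed = 23,
                  censor_fraction = 0.4)
  fup <- sim$followup
  est <- sim$truth$true_survival_living
  model <- function(cohort) est

  # follow-ups all below every estimate -> accuracy 1, MAE absent
  low <- fup; low$followup_years <- rep(min(est) / 2, length(est))
  r_low <- validate_on_followup(model, low)
  expect_equal(r_low$classification_accuracy, 1)
  expect_true(is.na(r_low$mae_remaining_years))

  # follow-ups all above -> accuracy 0, MAE over everyone
  high <- fup; high$followup_years <- rep(max(est) + 1, length(est))
  r_high <- validate_on_followup(model, high)
  expect_equal(r_high$classification_accuracy, 0)
  expect_equal(r_high$mae_remaining_years,
               mean(abs(high$followup_years - est)))

  # ties count as not-exceeding (strict inequality)
  tie <- fup; tie$followup_years <- est
  expect_equal(validate_on_followup(model, tie)$classification_accuracy, 0)
})

test_that("summary statistics match a two-pass oracle in years and months", {
  sim <- tiny_sim(n = 30, d = 8, k = 2, noise_sd = 0.2, seed = 24,
                  censor_fraction = 0.5)
  est <- sim$truth$true_survival_living + 0.3
  report <- validate_on_followup(function(cohort) est, sim$followup)
  s <- summarize_estimates(report)
  # two-pass SD oracle (n - 1 denominator)
  two_pass_sd <- function(v) sqrt(sum((v - mean(v))^2) / (length(v) - 1))
  expect_equal(s$mean_estimate_years, mean(est), tolerance = 1e-12)
  expect_equal(s$sd_estimate_years, two_pass_sd(est), tolerance = 1e-12)
  expect_equal(s$mean_followup_years, mean(sim$followup$followup_years))
  expect_equal(s$mean_estimate_months, 12 * mean(est))
  expect_equal(s$sd_followup_months, 12 * two_pass_sd(sim$followup$followup_years))
  expect_false(s$degenerate_sd)

  # trivial arithmetic: estimates of 1 and 3 years average 24 months
  fup2 <- sim$followup
  fup2$cohort <- expression_cohort(fup2$cohort$values[1:2, ],
                                   fup2$cohort$sample_ids[1:2],
                                   fup2$cohort$feature_names)
  fup2$followup_years <- fup2$followup_years[1:2]
  r2 <- validate_on_followup(function(cohort) c(1, 3), fup2)
  expect_equal(summarize_estimates(r2)$mean_estimate_months, 24)

  # single-patient boundary: SD reported as 0 with a flag
  fup1 <- fup2
  fup1$cohort <- expression_cohort(fup1$cohort$values[1, , drop = FALSE],
                                   fup1$cohort$sample_ids[1],
                                   fup1$cohort$feature_names)
  fup1$followup_years <- fup1$followup_years[1]
  s1 <- summarize_estimates(validate_on_followup(function(cohort) 2, fup1))
  expect_equal(s1$sd_estimate_years, 0)
  expect_true(s1$degenerate_sd)
})

test_that("a trained SVR model validates through the full protocol", {
  sim <- tiny_sim(n = 100, d = 15, k = 3, noise_sd = 0.2, seed = 25,
                  censor_fraction = 0.35)
  ds <- sim$dataset
  feats <- sim$truth$signal_features
  model <- fit_svr(ds$cohort$values[, feats], ds$survival_years,
                   default_svr(), feature_names = feats)
  report <- validate_on_followup(model, sim$followup)
  expect_equal(nrow(report$per_patient), length(sim$followup$followup_years))
  expect_true(report$classification_accuracy >= 0 &&
                report$classification_accuracy <= 1)

  # missing features in the validation cohort are reported by name
  small <- sim$followup
  keep <- setdiff(small$cohort$feature_names, feats[1])
  small$cohort <- expression_cohort(
    small$cohort$values[, keep], small$cohort$sample_ids, keep)
  expect_error(validate_on_followup(model, small), feats[1])

  # TSV + JSON writers round-trip the headline numbers
  dir <- local_tempdir()
  write_validation_report(report, file.path(dir, "v.tsv"),
                          file.path(dir, "v.json"))
  js <- jsonlite::read_json(file.path(dir, "v.json"), simplifyVector = TRUE)
  expect_equal(js$classification_accuracy, report$classification_accuracy)
  tab <- read.delim(file.path(dir, "v.tsv"))
  expect_equal(nrow(tab), report$n_patients)
})
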