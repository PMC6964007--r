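test_that("generation is seed-deterministic and respects invariants", {
  cfg <- cohort_config(n = 400, seed = 15)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$observed, b$observed)
  expect_identical(a$complete, b$complete)

  d <- a$complete
  expect_true(all(d$pga >= 0 & d$pga <= 10))
  expect_true(all(d$pain >= 0 & d$pain <= 10))
  expect_true(all(d$esr >= 0))
  expect_true(all(d$active_joint_count >= 1))     # zero-truncated
  expect_true(all(d$non_remission %in% 0:1))
  expect_true(all(levels(d$jia_category) %in%
                    c("oligoarthritis", "rf_neg_poly", "rf_pos_poly",
                      "systemic", "enthesitis_related", "psoriatic",
                      "undifferentiated")))
  # outcomes are never masked
  expect_false(anyNA(a$observed$non_remission))
  expect_false(anyNA(a$observed$severe_course))

  expect_error(cohort_config(n = 10, seed = 1), "n >= 20")
  expect_error(cohort_config(n = 100, seed = 1, missing_rate = 0.7),
               "missing_rate")
})

test_that("the masked-cell fraction matches the configured rate", {
  co <- generate_cohort(cohort_config(n = 5000, seed = 16,
                                      missing_rate = 0.10))
  pred_cols <- setdiff(names(co$observed),
                       c("non_remission", "severe_course",
                         "disability_chaq_gt0"))
  frac <- mean(is.na(as.matrix(co$observed[pred_cols])))
  expect_lt(abs(frac - 0.10), 0.01)
})

test_that("MCAR masking is independent of the outcome; MAR tracks low PGA", {
  co <- generate_cohort(cohort_config(n = 10000, seed = 17,
                                      missing_rate = 0.10))
  tab <- table(miss = is.na(co$observed$esr),
               y = co$observed$non_remission)
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.001)

  mar <- generate_cohort(cohort_config(n = 10000, seed = 18,
                                       missing_rate = 0.10,
                                       missing_mechanism = "MAR_on_pga"))
  low_pga <- mar$complete$pga < median(mar$complete$pga)
  rate_low <- mean(is.na(mar$observed$esr[low_pga]))
  rate_high <- mean(is.na(mar$observed$esr[!low_pga]))
  expect_gt(rate_low, rate_high)
  # the overall rate is preserved by the weight normalisation
  expect_lt(abs(mean(is.na(mar$observed$esr)) - 0.10), 0.02)
})

test_that("target prevalence is reached by intercept calibration", {
  co <- generate_cohort(cohort_config(
    n = 5000, seed = 19,
    target_prevalence = c(non_remission = 81, severe_course = 15)))
  expect_lt(abs(mean(co$complete$non_remission) - 0.81), 0.02)
  expect_lt(abs(mean(co$complete$severe_course) - 0.15), 0.02)
  expect_error(cohort_config(n = 100, seed = 1,
                             target_prevalence = c(non_remission = 100)),
               "strictly between")
})

test_that("intercept_for_prevalence solves the closed intercept-only cases", {
  flat <- risk_model("flat", 5, c(esr = 0), "fitted")
  expect_equal(intercept_for_prevalence(flat, target = 50), 0,
               tolerance = 0.02)
  expect_equal(intercept_for_prevalence(flat, target = 81), qlogis(0.81),
               tolerance = 0.02)
  lo <- intercept_for_prevalence(flat, target = 30)
  hi <- intercept_for_prevalence(flat, target = 70)
  expect_gt(hi, lo)
})

test_that("the true linear predictor's discrimination is stable across seeds", {
  model <- get_model("nordic_nonremission")
  cs <- vapply(31:34, function(s) {
    co <- generate_cohort(cohort_config(n = 10000, seed = s,
                                        missing_rate = 0))
    c_index(predict_risk(model, co$complete, "probability"),
            co$complete$non_remission)
  }, 0)
  expect_lt(sd(cs), 0.01)
})

test_that("cohort CSV round-trips through the loader with joint-count mapping", {
  co <- generate_cohort(cohort_config(n = 60, seed = 20))
  path <- withr::local_tempfile(fileext = ".csv")
  obs <- co$observed
  obs$joint_count_for_nordic <- NULL       # user supplies the raw column
  write_cohort(obs, path)
  expect_message(reloaded <- load_cohort(path), "active_joint_count")
  expect_equal(reloaded$joint_count_for_nordic, obs$active_joint_count)
  expect_equal(reloaded$esr, obs$esr)
  expect_s3_class(reloaded$jia_category, "factor")
})
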