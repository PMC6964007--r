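test_that("built-in specs reproduce the printed coefficient tables", {
  m <- builtin_models()
  expect_gte(length(m), 7)

  expect_equal(m$canadian_severe$intercept, -2.92)
  expect_equal(m$nordic_nonremission$intercept, -1.58)
  expect_equal(m$nordic_disability$intercept, -1.68)
  expect_equal(m$finetuned_nonremission_labs$intercept, 0.24)
  expect_equal(m$finetuned_nonremission_nolabs$intercept, 0.17)
  expect_equal(m$finetuned_severe_labs$intercept, -2.9)
  expect_equal(m$finetuned_severe_nolabs$intercept, -2.8)

  expect_equal(m$nordic_nonremission$coefficients[["b27_positive"]], 1.37)
  expect_equal(m$nordic_nonremission$coefficients[["ankle_arthritis"]], 1.10)
  expect_equal(m$finetuned_nonremission_labs$coefficients[["ankle_arthritis"]],
               0.52)
  expect_equal(m$canadian_severe$coefficients[["tmj_arthritis"]], 1.50)
  expect_equal(m$canadian_severe$coefficients[["jia_oligoarthritis"]], -1.14)
  expect_equal(m$nordic_disability$coefficients[["pain"]], 0.77)

  expect_true(all(vapply(m, function(x)
    x$provenance %in% c("published", "fine_tuned_reference"), TRUE)))
})

test_that("linear predictor returns the printed intercept on an all-zero record", {
  zero <- zero_record()
  for (m in builtin_models())
    expect_equal(linear_predictor(m, zero), m$intercept, info = m$name)
})

test_that("linear predictor arithmetic and JIA-category dummy expansion", {
  nordic <- get_model("nordic_nonremission")
  d <- zero_record()
  d$joint_count_for_nordic <- 1L
  expect_equal(linear_predictor(nordic, d), -1.54)

  canadian <- get_model("canadian_severe")
  oligo <- zero_record(); oligo$jia_category <- "oligoarthritis"
  expect_equal(linear_predictor(canadian, oligo), -2.92 - 1.14)
  # reference categories contribute nothing
  era <- zero_record(); era$jia_category <- "enthesitis_related"
  expect_equal(linear_predictor(canadian, era), -2.92)

  # a zero coefficient never moves A
  padded <- risk_model("padded", nordic$intercept,
                       c(nordic$coefficients, pain = 0), "fitted")
  d2 <- zero_record(); d2$pain <- 7.3
  expect_equal(linear_predictor(padded, d2), linear_predictor(nordic, d2))
})

test_that("predicted probability is the logistic transform on the percent scale", {
  flat <- risk_model("flat", 0, c(esr = 0), "fitted")
  d <- zero_record()
  expect_equal(predict_risk(flat, d), 50)

  nordic <- get_model("nordic_nonremission")
  expect_equal(predict_risk(nordic, d), 17.07, tolerance = 1e-3)
  expect_equal(predict_risk(nordic, d, scale = "probability"),
               plogis(-1.58))

  steep <- risk_model("steep", 50, c(esr = 0), "fitted")
  expect_gt(predict_risk(steep, d), 100 - 1e-10)
  expect_lte(predict_risk(steep, d), 100)

  # round trip: A recoverable from the probability by the logit
  a <- linear_predictor(nordic, d)
  expect_equal(qlogis(predict_risk(nordic, d, "probability")), a)
})

test_that("probability is strictly monotone in positive-coefficient predictors", {
  nordic <- get_model("nordic_nonremission")
  pos <- names(which(nordic$coefficients > 0))
  base <- zero_record()
  for (col in pos) {
    bumped <- base
    bumped[[col]] <- if (col %in% c("joint_count_for_nordic", "esr")) 2 else 1
    expect_gt(predict_risk(nordic, bumped), predict_risk(nordic, base),
              label = col)
  }
})

test_that("missing or unknown predictors raise informative errors", {
  nordic <- get_model("nordic_nonremission")
  d <- zero_record(); d$esr <- NA_real_
  expect_error(linear_predictor(nordic, d), "esr")

  d2 <- zero_record(); d2$esr <- NULL
  expect_error(linear_predictor(nordic, d2), "absent")

  expect_error(risk_model("bogus", 0, c(shoe_size = 1), "published"),
               "unknown predictor")
})

test_that("risk stratification follows the 20/60 percent cuts", {
  expect_equal(as.character(classify_risk(10)), "low")
  expect_equal(as.character(classify_risk(70)), "high")
  expect_equal(as.character(classify_risk(40)), "intermediate")
  # cut values themselves are not beyond the cuts
  expect_equal(as.character(classify_risk(c(20, 60))),
               c("intermediate", "intermediate"))
  expect_error(classify_risk(140), "percent")
  expect_error(classify_risk(50, low_cut = 60, high_cut = 20))
})
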