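make_masked_cohort <- function(n = 250, seed = 101, rate = 0.1) {
  generate_cohort(cohort_config(n = n, seed = seed, missing_rate = rate))
}

test_that("a complete input yields M identical copies", {
  co <- generate_cohort(cohort_config(n = 60, seed = 5, missing_rate = 0))
  imps <- mice_impute(co$observed, M = 3, n_iter = 2, seed = 9)
  expect_length(imps$imputations, 3)
  for (k in 1:3) expect_identical(get_imputation(imps, k), co$observed)
})

test_that("observed cells are preserved and missing cells filled to type", {
  co <- make_masked_cohort()
  obs <- co$observed
  imps <- mice_impute(obs, M = 3, n_iter = 3, seed = 21)
  outcome_cols <- c("non_remission", "severe_course", "disability_chaq_gt0")
  for (k in 1:3) {
    d <- get_imputation(imps, k)
    for (col in setdiff(names(obs), outcome_cols)) {
      seen <- !is.na(obs[[col]])
      expect_identical(d[[col]][seen], obs[[col]][seen],
                       info = paste("observed cells of", col))
      expect_false(anyNA(d[[col]]), info = paste("no NA left in", col))
    }
    for (col in c("ana_positive", "crp_gt_10", "ankle_arthritis"))
      expect_true(all(d[[col]] %in% 0:1), info = col)
    jc <- d$active_joint_count
    expect_true(all(jc >= 0 & jc == round(jc)))
    expect_true(all(as.character(d$jia_category) %in%
                      levels(obs$jia_category)))
    # outcomes untouched
    for (col in outcome_cols)
      expect_identical(d[[col]], obs[[col]])
  }
})

test_that("imputation is deterministic in the seed", {
  obs <- make_masked_cohort(n = 120, seed = 33)$observed
  a <- mice_impute(obs, M = 2, n_iter = 2, seed = 50)
  b <- mice_impute(obs, M = 2, n_iter = 2, seed = 50)
  expect_identical(a$imputations, b$imputations)
  c <- mice_impute(obs, M = 2, n_iter = 2, seed = 51)
  expect_false(identical(a$imputations, c$imputations))
})

test_that("imputation guardrails reject unusable requests", {
  obs <- make_masked_cohort(n = 80, seed = 34)$observed
  expect_error(mice_impute(obs, M = 1, seed = 1), "M must be")
  expect_error(mice_impute(obs, M = 2, seed = 1,
                           columns = c("esr", "non_remission")),
               "outcome")
  bad <- obs; bad$esr <- NA_real_
  expect_error(mice_impute(bad, M = 2, seed = 1), "no observed values")
  expect_error(mice_impute(obs, M = 2), "seed")
})

test_that("imputed continuous values track the generator truth", {
  co <- make_masked_cohort(n = 600, seed = 77)
  obs <- co$observed
  mis <- is.na(obs$esr)
  imps <- mice_impute(obs, M = 20, n_iter = 5, seed = 7)
  imputed_means <- vapply(imps$imputations,
                          function(d) mean(d$esr[mis]), 0)
  truth_mean <- mean(co$complete$esr[mis])
  tol <- 3 * sd(co$complete$esr) / sqrt(sum(mis))
  expect_lt(abs(mean(imputed_means) - truth_mean), tol)
})
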