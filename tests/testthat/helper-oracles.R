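# Independent oracles and small fixtures shared across test files.

# O(n^2) pair-counting C-index: concordant + 0.5 * tied over all
# case-control pairs.  Deliberately naive; the reference for c_index().
brute_cindex <- function(scores, outcomes) {
  cases <- scores[outcomes == 1]
  controls <- scores[outcomes == 0]
  total <- 0
  for (a in cases) for (b in controls)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(cases) * length(controls))
}

trapezoid_area <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# A patient record with every model predictor at zero; systemic JIA is
# the reference category for the Canadian model's dummies (no indicator),
# so it contributes nothing to any built-in linear predictor.
zero_record <- function() {
  d <- data.frame(jia_category = "systemic")
  for (col in c("active_joint_count", "joint_count_for_nordic"))
    d[[col]] <- 0L
  for (col in c("esr", "pga", "pain")) d[[col]] <- 0
  for (col in c("crp_gt_10", "morning_stiffness_gt_15",
                "morning_stiffness_present", "ana_positive",
                "b27_positive", "rf_positive", "ankle_arthritis",
                "finger_arthritis", "subtalar_arthritis",
                "cervical_arthritis", "hip_arthritis", "tmj_arthritis",
                "midfoot_arthritis", "upper_limb_involvement",
                "symmetric_involvement", "enthesitis_present"))
    d[[col]] <- 0L
  d
}

# Small simulated design for logistic-fit tests: p standard-normal
# predictors named x1..xp, outcome from known beta (intercept first).
sim_logistic <- function(n, beta, seed) {
  p <- length(beta) - 1L
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  lp <- beta[1] + drop(X %*% beta[-1])
  d <- as.data.frame(X)
  d$y <- rbinom(n, 1, plogis(lp))
  d
}

nordic_predictors <- function() names(get_model("nordic_nonremission")$coefficients)
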