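# Synthetic JIA inception cohorts.  Baseline predictors are drawn from
# marginal families chosen to match the published medians/IQRs/prevalences
# of such cohorts; a single weak latent severity factor correlates the
# joint count with the joint-site indicators and stiffness.  Outcomes are
# drawn from known logistic truth models, so generator truth is available
# as an oracle for every downstream stage.

default_marginals <- function() {
  list(
    jia_category = c(oligoarthritis = 0.38, rf_neg_poly = 0.23,
                     rf_pos_poly = 0.03, systemic = 0.08,
                     enthesitis_related = 0.11, psoriatic = 0.06,
                     undifferentiated = 0.11),
    joint_count = list(mu = 3.5, size = 1.5, severity_loading = 0.35),
    site_prevalence = c(ankle_arthritis = 0.40, finger_arthritis = 0.38,
                        hip_arthritis = 0.13, cervical_arthritis = 0.06,
                        subtalar_arthritis = 0.05, tmj_arthritis = 0.05,
                        midfoot_arthritis = 0.08,
                        upper_limb_involvement = 0.30,
                        symmetric_involvement = 0.35),
    site_severity_loading = 0.5,
    binary_prevalence = c(morning_stiffness_gt_15 = 0.60,
                          morning_stiffness_present = 0.70,
                          ana_positive = 0.50, b27_positive = 0.09,
                          rf_positive = 0.06, crp_gt_10 = 0.30,
                          enthesitis_present = 0.12),
    stiffness_severity_loading = 0.3,
    esr = list(meanlog = log(20), sdlog = 0.8, severity_loading = 0.2),
    pga = list(shape1 = 2, shape2 = 3.2),
    pain = list(shape1 = 2, shape2 = 3.2))
}

#' Configuration for a synthetic inception cohort
#'
#' @param n cohort size (>= 20).
#' @param seed integer seed.
#' @param truth `jia_model` generating the `non_remission` outcome
#'   (default: the published Nordic non-remission model).
#' @param severe_truth `jia_model` generating `severe_course` (default:
#'   the fine-tuned severe-course reference coefficients).
#' @param disability_truth `jia_model` generating `disability_chaq_gt0`
#'   (default: the published Nordic disability model).
#' @param marginals per-predictor distribution parameters; see
#'   `default_marginals()` in the sources.  Entries you supply override
#'   the defaults.
#' @param target_prevalence optional named numeric vector of target
#'   outcome prevalences in percent (names among the outcome columns);
#'   each named truth model's intercept is shifted so the mean generated
#'   probability matches the target.
#' @param missing_rate fraction of predictor cells masked (0 to 0.5).
#' @param missing_mechanism `"MCAR"` (all predictor cells, uniform) or
#'   `"MAR_on_pga"` (laboratory values go missing more often when the
#'   physician global assessment is low, mimicking testing only when
#'   clinically indicated; overall rate preserved).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n, seed, truth = NULL, severe_truth = NULL,
                          disability_truth = NULL, marginals = list(),
                          target_prevalence = NULL, missing_rate = 0.10,
                          missing_mechanism = c("MCAR", "MAR_on_pga")) {
  stopifnot(n >= 20)
  if (missing(seed)) stop("seed is required")
  if (missing_rate < 0 || missing_rate > 0.5)
    stop("missing_rate must lie in [0, 0.5]")
  missing_mechanism <- match.arg(missing_mechanism)
  builtin <- builtin_models()
  if (is.null(truth)) truth <- builtin$nordic_nonremission
  if (is.null(severe_truth)) severe_truth <- builtin$finetuned_severe_labs
  if (is.null(disability_truth)) disability_truth <- builtin$nordic_disability
  marg <- utils::modifyList(default_marginals(), marginals)
  if (!is.null(target_prevalence)) {
    bad <- setdiff(names(target_prevalence), outcome_columns)
    if (length(bad) || is.null(names(target_prevalence)))
      stop("target_prevalence must be named by outcome column")
    if (any(target_prevalence <= 0 | target_prevalence >= 100))
      stop("target prevalence must lie strictly between 0 and 100 percent")
  }
  truths <- list(non_remission = truth, severe_course = severe_truth,
                 disability_chaq_gt0 = disability_truth)
  gen <- all_predictors()
  for (tm in truths) {
    extra <- setdiff(names(tm$coefficients),
                     c(gen, paste0("jia_", jia_categories)))
    if (length(extra))
      stop("truth model '", tm$name, "' uses ungenerated predictor(s): ",
           paste(extra, collapse = ", "))
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 truths = truths, marginals = marg,
                 target_prevalence = target_prevalence,
                 missing_rate = missing_rate,
                 missing_mechanism = missing_mechanism),
            class = "cohort_config")
}

# Draw the complete (pre-masking) predictor table.
draw_predictors <- function(n, marg) {
  z <- stats::rnorm(n)                    # latent severity factor
  jc <- marg$joint_count
  mu <- exp(log(jc$mu) + jc$severity_loading * z)
  count <- stats::qnbinom(
    stats::runif(n, stats::pnbinom(0, mu = mu, size = jc$size), 1),
    mu = mu, size = jc$size)              # zero-truncated
  d <- data.frame(active_joint_count = count,
                  joint_count_for_nordic = count)
  for (site in names(marg$site_prevalence)) {
    p <- stats::plogis(stats::qlogis(marg$site_prevalence[[site]]) +
                         marg$site_severity_loading * z)
    d[[site]] <- stats::rbinom(n, 1, p)
  }
  for (col in names(marg$binary_prevalence)) {
    load <- if (startsWith(col, "morning_stiffness"))
      marg$stiffness_severity_loading else 0
    p <- stats::plogis(stats::qlogis(marg$binary_prevalence[[col]]) +
                         load * z)
    d[[col]] <- stats::rbinom(n, 1, p)
  }
  esr <- marg$esr
  d$esr <- stats::rlnorm(n, esr$meanlog + esr$severity_loading * z,
                         esr$sdlog)
  d$pga <- 10 * stats::rbeta(n, marg$pga$shape1, marg$pga$shape2)
  d$pain <- 10 * stats::rbeta(n, marg$pain$shape1, marg$pain$shape2)
  d$jia_category <- factor(
    sample(names(marg$jia_category), n, replace = TRUE,
           prob = marg$jia_category),
    levels = jia_categories)
  d
}

#' Intercept shift achieving a target outcome prevalence
#'
#' Bisects on the model intercept until the Monte-Carlo mean predicted
#' probability over `n_mc` predictor draws from the marginals matches the
#' target within 0.2 percentage points.
#'
#' @param truth a `jia_model`.
#' @param marginals marginal parameters as in [cohort_config()].
#' @param target target prevalence in percent, strictly in (0, 100).
#' @param n_mc Monte-Carlo draws used to evaluate the mean probability.
#' @param seed seed for the Monte-Carlo draw.
#' @return the calibrated intercept (a real number).
#' @export
intercept_for_prevalence <- function(truth, marginals = default_marginals(),
                                     target, n_mc = 1e5, seed = 20201) {
  if (target <= 0 || target >= 100)
    stop("target prevalence must lie strictly between 0 and 100 percent")
  marg <- utils::modifyList(default_marginals(), marginals)
  lp <- with_seed(seed, {
    d <- draw_predictors(n_mc, marg)
    linear_predictor(truth, d)
  })
  f <- function(delta) mean(stats::plogis(lp + delta)) - target / 100
  lo <- -10; hi <- 10
  while (f(lo) > 0 || f(hi) < 0) {
    lo <- lo * 2; hi <- hi * 2
    if (hi > 80) stop("target prevalence unreachable from this model")
  }
  repeat {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < 0.002 || (hi - lo) < 1e-10) break
    if (fm > 0) hi <- mid else lo <- mid
  }
  truth$intercept + mid
}

#' Generate a synthetic inception cohort
#'
#' Draws baseline predictors from the configured marginals, generates each
#' outcome from its logistic truth model (intercepts shifted first if
#' target prevalences were requested), then masks predictor cells at the
#' configured missing rate under the chosen mechanism.  Outcomes are never
#' masked.  The complete pre-masking table is returned alongside the
#' observed one so generator truth can serve as an oracle.
#'
#' @param config a [cohort_config()].
#' @return object of class `synth_cohort`: list with `observed` (masked
#'   table), `complete` (pre-masking table), `truths` (the truth models
#'   actually used, after any intercept calibration), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  truths <- config$truths
  if (!is.null(config$target_prevalence)) {
    for (oc in names(config$target_prevalence)) {
      truths[[oc]]$intercept <- intercept_for_prevalence(
        truths[[oc]], config$marginals, config$target_prevalence[[oc]],
        seed = config$seed + 10007L)
    }
  }
  res <- with_seed(config$seed, {
    d <- draw_predictors(config$n, config$marginals)
    for (oc in names(truths)) {
      p <- stats::plogis(linear_predictor(truths[[oc]], d))
      d[[oc]] <- stats::rbinom(config$n, 1, p)
    }
    observed <- mask_cells(d, config)
    list(observed = observed, complete = d)
  })
  structure(list(observed = res$observed, complete = res$complete,
                 truths = truths, config = config),
            class = "synth_cohort")
}

# Mask predictor cells under MCAR or MAR-on-PGA; outcomes untouched.
mask_cells <- function(d, config) {
  rate <- config$missing_rate
  if (rate == 0) return(d)
  pred_cols <- setdiff(names(d), outcome_columns)
  if (config$missing_mechanism == "MCAR") {
    for (col in pred_cols)
      d[[col]][stats::runif(config$n) < rate] <- NA
  } else {
    # labs missing more often when PGA is low ("tested when indicated");
    # weights normalised so the expected overall rate stays `rate`
    lab_cols <- intersect(c("esr", "crp_gt_10", "ana_positive",
                            "b27_positive", "rf_positive"), pred_cols)
    w <- (12 - d$pga); w <- w / mean(w)
    for (col in pred_cols) {
      p <- if (col %in% lab_cols) pmin(rate * w, 0.95) else rate
      d[[col]][stats::runif(config$n) < p] <- NA
    }
  }
  d
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("<synth_cohort> n =", x$config$n, " seed =", x$config$seed, "\n")
  cat("  missing:", format(x$config$missing_rate), "(",
      x$config$missing_mechanism, ")\n")
  for (oc in names(x$truths))
    cat(sprintf("  %s: prevalence %.3f (truth: %s)\n", oc,
                mean(x$complete[[oc]]), x$truths[[oc]]$name))
  invisible(x)
}
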