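#' Construct a logistic risk model specification
#'
#' A risk model is a logistic calculator: a linear predictor
#' \eqn{A = \alpha + \sum_j \beta_j x_j} over named baseline predictors,
#' mapped to a chance of the outcome \eqn{100\, e^A / (1 + e^A)} percent.
#' Coefficient names must match cohort columns, except JIA-category
#' dummies, written `jia_<level>` (e.g. `jia_oligoarthritis`), which are
#' derived 0/1 indicators of `jia_category`; omitted categories form the
#' reference and contribute 0.
#'
#' @param name identifier for the model.
#' @param intercept the constant term of the linear predictor.
#' @param coefficients named numeric vector of slopes.
#' @param provenance one of `"published"`, `"fine_tuned_reference"`,
#'   `"fitted"`.
#' @param outcome optional name of the outcome the model predicts.
#' @return an object of class `jia_model`.
#' @export
risk_model <- function(name, intercept, coefficients,
                       provenance = c("published", "fine_tuned_reference",
                                      "fitted"),
                       outcome = NULL) {
  provenance <- match.arg(provenance)
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(coefficients), !is.null(names(coefficients)),
            all(nzchar(names(coefficients))))
  # the shipped calculators must stay on the roster; fitted models may
  # carry any column names their data supplied
  if (provenance != "fitted") {
    known <- c(all_predictors(), paste0("jia_", jia_categories))
    bad <- setdiff(names(coefficients), known)
    if (length(bad))
      stop("unknown predictor key(s) in model '", name, "': ",
           paste(bad, collapse = ", "))
  }
  structure(list(name = name, intercept = unname(intercept),
                 coefficients = coefficients, provenance = provenance,
                 outcome = outcome),
            class = "jia_model")
}

#' @export
print.jia_model <- function(x, ...) {
  cat("<jia_model> ", x$name, "  [", x$provenance, "]\n", sep = "")
  if (!is.null(x$outcome)) cat("  outcome: ", x$outcome, "\n", sep = "")
  cat("  A = ", format(x$intercept), " + ...  (",
      length(x$coefficients), " terms)\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Built-in published and fine-tuned reference models
#'
#' Returns the three published calculators — the Canadian severe-disease-
#' course model and the Nordic models for non-achievement of remission and
#' for functional disability (CHAQ > 0) — plus the four fine-tuned Nordic
#' coefficient sets re-estimated on the Canadian cohort (non-remission and
#' severe course, each with and without laboratory variables).  Fine-tuned
#' sets are shipped as reference constants (`provenance =
#' "fine_tuned_reference"`); they are data-derived, not re-estimated here.
#'
#' @return named list of [risk_model()] objects.
#' @export
builtin_models <- function() {
  m <- list(
    risk_model(
      "canadian_severe", -2.92,
      c(active_joint_count    =  0.18,
        jia_psoriatic         = -1.23,
        jia_oligoarthritis    = -1.14,
        jia_rf_neg_poly       = -0.49,
        upper_limb_involvement =  0.75,
        symmetric_involvement = -0.88,
        rf_positive           =  1.31,
        subtalar_arthritis    = -1.42,
        finger_arthritis      = -0.31,
        cervical_arthritis    =  0.84,
        ankle_arthritis       =  0.48,
        morning_stiffness_present = 0.56,
        hip_arthritis         =  0.06,
        tmj_arthritis         =  1.50,
        midfoot_arthritis     =  0.54,
        enthesitis_present    =  0.86),
      "published", outcome = "severe_course"),
    risk_model(
      "nordic_nonremission", -1.58,
      c(joint_count_for_nordic  = 0.04,
        esr                     = 0.03,
        crp_gt_10               = -0.07,
        morning_stiffness_gt_15 = 1.16,
        pga                     = 0.16,
        ana_positive            = 1.25,
        b27_positive            = 1.37,
        ankle_arthritis         = 1.10),
      "published", outcome = "non_remission"),
    risk_model(
      "nordic_disability", -1.68,
      c(joint_count_for_nordic  = -0.02,
        esr                     =  0.01,
        crp_gt_10               = -0.20,
        morning_stiffness_gt_15 =  1.03,
        pga                     = -0.40,
        finger_arthritis        =  1.21,
        pain                    =  0.77),
      "published", outcome = "disability_chaq_gt0"),
    risk_model(
      "finetuned_nonremission_labs", 0.24,
      c(joint_count_for_nordic  =  0.16,
        esr                     = -0.01,
        crp_gt_10               =  0.12,
        morning_stiffness_gt_15 =  0.42,
        pga                     =  0.15,
        ana_positive            =  0.03,
        b27_positive            =  1.07,
        ankle_arthritis         =  0.52),
      "fine_tuned_reference", outcome = "non_remission"),
    risk_model(
      "finetuned_nonremission_nolabs", 0.17,
      c(joint_count_for_nordic  = 0.15,
        morning_stiffness_gt_15 = 0.38,
        pga                     = 0.14,
        ankle_arthritis         = 0.53),
      "fine_tuned_reference", outcome = "non_remission"),
    risk_model(
      "finetuned_severe_labs", -2.9,
      c(joint_count_for_nordic  =  0.22,
        esr                     = -0.01,
        crp_gt_10               =  0.08,
        morning_stiffness_gt_15 =  0.23,
        pga                     = -0.05,
        ana_positive            = -0.56,
        b27_positive            =  0.85,
        ankle_arthritis         = -0.70),
      "fine_tuned_reference", outcome = "severe_course"),
    risk_model(
      "finetuned_severe_nolabs", -2.8,
      c(joint_count_for_nordic  =  0.21,
        morning_stiffness_gt_15 = -0.03,
        pga                     = -0.06,
        ankle_arthritis         = -0.70),
      "fine_tuned_reference", outcome = "severe_course"))
  stats::setNames(m, vapply(m, `[[`, "", "name"))
}

#' Look up a built-in model by name
#'
#' @param name model identifier (see [builtin_models()]).
#' @return a `jia_model`.
#' @export
get_model <- function(name) {
  m <- builtin_models()
  if (!name %in% names(m))
    stop("unknown model '", name, "'; available: ",
         paste(names(m), collapse = ", "))
  m[[name]]
}

#' Design matrix for a model's coefficient terms
#'
#' Builds the n x p matrix of predictor values matching
#' `names(model$coefficients)` (no intercept column).  `jia_*` dummy terms
#' are expanded from `jia_category`.
#'
#' @param terms character vector of coefficient names, or a `jia_model`.
#' @param data cohort data.frame.
#' @param allow_missing if `FALSE` (default) any `NA` in a required
#'   predictor is an error naming the predictor.
#' @return numeric matrix with one column per term.
#' @export
model_design <- function(terms, data, allow_missing = FALSE) {
  if (inherits(terms, "jia_model")) terms <- names(terms$coefficients)
  X <- matrix(NA_real_, nrow(data), length(terms),
              dimnames = list(NULL, terms))
  for (term in terms) {
    if (startsWith(term, "jia_")) {
      level <- sub("^jia_", "", term)
      if (!level %in% jia_categories)
        stop("unknown JIA category dummy '", term, "'")
      if (!"jia_category" %in% names(data))
        stop("model requires predictor 'jia_category', absent from data")
      X[, term] <- as.numeric(as.character(data$jia_category) == level)
      if (!allow_missing && anyNA(X[, term]))
        stop("missing values in required predictor 'jia_category'; ",
             "impute before scoring")
    } else {
      if (!term %in% names(data))
        stop("model requires predictor '", term, "', absent from data")
      X[, term] <- as.numeric(data[[term]])
      if (!allow_missing && anyNA(X[, term]))
        stop("missing values in required predictor '", term, "'; ",
             "impute before scoring")
    }
  }
  X
}

#' Linear predictor A of a risk model
#'
#' \eqn{A = \alpha + \sum_j \beta_j x_j} for every patient row.  Binary
#' predictors contribute their coefficient or 0; JIA-category dummies are
#' expanded as in [model_design()].
#'
#' @param model a `jia_model`.
#' @param data cohort data.frame with all required predictors non-missing.
#' @return numeric vector, one value per row.
#' @export
linear_predictor <- function(model, data) {
  stopifnot(inherits(model, "jia_model"))
  X <- model_design(model, data)
  drop(model$intercept + X %*% model$coefficients)
}

#' Predicted chance of the outcome
#'
#' Maps the linear predictor through the logistic function.  Reported on
#' the percent scale by default (as the calculators print it); use
#' `scale = "probability"` for the 0-1 scale used internally.
#'
#' @inheritParams linear_predictor
#' @param scale `"percent"` (0-100, default) or `"probability"` (0-1).
#' @return numeric vector of predicted chances.
#' @export
predict_risk <- function(model, data, scale = c("percent", "probability")) {
  scale <- match.arg(scale)
  p <- stats::plogis(linear_predictor(model, data))
  if (scale == "percent") 100 * p else p
}

#' Risk stratum from a predicted chance
#'
#' Low risk below `low_cut` percent, high risk above `high_cut` percent,
#' intermediate otherwise (cut values themselves are intermediate).
#'
#' @param probability predicted chance(s) in percent, 0-100.
#' @param low_cut,high_cut stratum cut-points in percent; `low_cut <
#'   high_cut`.
#' @return factor with levels `low`, `intermediate`, `high`.
#' @export
classify_risk <- function(probability, low_cut = 20, high_cut = 60) {
  stopifnot(low_cut < high_cut)
  if (any(probability < 0 | probability > 100, na.rm = TRUE))
    stop("probability must be on the percent scale, within [0, 100]")
  out <- ifelse(probability < low_cut, "low",
                ifelse(probability > high_cut, "high", "intermediate"))
  factor(out, levels = c("low", "intermediate", "high"))
}
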