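# The external-validation procedure: per-imputation statistics pooled by
# Rubin's rules; un-tuned scoring with the published coefficients;
# fine-tuning via full refits with LOOCV C-indices, BCCV within-dataset
# SDs, and bootstrap coefficient SEs.

#' Pool estimates across imputed datasets by Rubin's rules
#'
#' Point estimate is the unweighted mean of the per-dataset estimates;
#' the total variance is \eqn{\bar W + (1 + 1/M) B}, where \eqn{\bar W}
#' is the mean within-dataset variance and \eqn{B} the sample variance of
#' the per-dataset estimates.  The 95% CI is estimate +/- 1.96 total SE.
#'
#' @param estimates numeric vector of M per-dataset estimates (M >= 2).
#' @param within_vars numeric vector of M within-dataset variances
#'   (squared SEs), all >= 0.
#' @return object of class `pooled_estimate`: list with `estimate`,
#'   `within_var`, `between_var`, `total_se`, `ci95`, `M`.
#' @export
rubin_pool <- function(estimates, within_vars) {
  M <- length(estimates)
  if (M < 2) stop("Rubin's rules require M >= 2 datasets")
  stopifnot(length(within_vars) == M, all(within_vars >= 0),
            !anyNA(estimates), !anyNA(within_vars))
  est <- mean(estimates)
  W <- mean(within_vars)
  B <- stats::var(estimates)
  total_se <- sqrt(W + (1 + 1 / M) * B)
  structure(list(estimate = est, within_var = W, between_var = B,
                 total_se = total_se,
                 ci95 = c(est - 1.96 * total_se, est + 1.96 * total_se),
                 M = M),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, digits = 3, ...) {
  cat(format(round(x$estimate, digits)), " (95% CI ",
      format(round(x$ci95[1], digits)), ", ",
      format(round(x$ci95[2], digits)), "; SE ",
      format(round(x$total_se, digits)), "; M = ", x$M, ")\n", sep = "")
  invisible(x)
}

#' Evaluate a model as published (no refitting)
#'
#' Scores every patient of every imputed dataset with the model's printed
#' intercept and coefficients, computes the C-index and its DeLong SE per
#' dataset, and pools across datasets by Rubin's rules.  The model is
#' never modified.
#'
#' @param model a `jia_model`.
#' @param imps an `imputation_set`.
#' @param outcome name of the binary outcome column.
#' @return a `pooled_estimate` of the C-index, with per-dataset C-indices
#'   in attribute `per_dataset`.
#' @export
evaluate_untuned <- function(model, imps, outcome) {
  stopifnot(inherits(model, "jia_model"), inherits(imps, "imputation_set"))
  cs <- ses <- numeric(imps$M)
  for (k in seq_len(imps$M)) {
    d <- imps$imputations[[k]]
    if (!outcome %in% names(d))
      stop("outcome column '", outcome, "' absent from imputed data")
    p <- predict_risk(model, d, scale = "probability")
    cs[k] <- c_index(p, d[[outcome]])
    ses[k] <- c_index_se(p, d[[outcome]])
  }
  out <- rubin_pool(cs, ses^2)
  attr(out, "per_dataset") <- cs
  out
}

#' Leave-one-out cross-validated C-index
#'
#' For each observation the model is refit on the remaining n - 1 rows
#' and the held-out observation predicted; the C-index is computed over
#' the n out-of-sample predictions.  Deterministic (no RNG).
#'
#' @inheritParams fit_logistic
#' @return the LOOCV C-index; out-of-sample probabilities in attribute
#'   `predictions`, the apparent (full-fit, in-sample) C-index in
#'   attribute `apparent`.
#' @export
loocv_cindex <- function(data, predictors, outcome) {
  y <- data[[outcome]]
  check_scored(rep(0, length(y)), y)
  n <- length(y)
  if (n < 20) stop("LOOCV C-index requires n >= 20")
  X <- cbind(`(Intercept)` = 1, model_design(predictors, data))
  full <- logistic_fit_core(X, y)
  preds <- numeric(n)
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (length(unique(yi)) < 2)
      stop("LOOCV fold ", i, " lost an outcome class")
    fit <- logistic_fit_core(X[-i, , drop = FALSE], yi, start = full$beta)
    preds[i] <- stats::plogis(drop(X[i, ] %*% fit$beta))
  }
  out <- c_index(preds, y)
  attr(out, "predictions") <- preds
  attr(out, "apparent") <- c_index(stats::plogis(drop(X %*% full$beta)), y)
  out
}

#' BCCV within-dataset SD of the C-index
#'
#' Bootstrap-nested cross-validation: for each of B bootstrap resamples
#' of the dataset, every original observation appearing in the resample
#' is predicted out-of-sample by a model fit on the resample with all
#' copies of that observation removed; a C-index is then computed over
#' the resample's predicted values (originals entering with their
#' bootstrap multiplicity), so each resample C-index mimics a
#' leave-one-original-out cross-validation of that bootstrap sample.  The
#' SD of the B resample C-indices estimates the within-dataset SD of the
#' LOOCV C-index.  A resample missing an outcome class (before or after
#' a deletion) is redrawn, up to 100 times.
#'
#' @inheritParams fit_logistic
#' @param B number of bootstrap resamples.
#' @param seed integer seed; mandatory.
#' @return the SD of the B bootstrap C-indices; the C-indices themselves
#'   in attribute `cindices` and the number of redraws in `redraws`.
#' @export
bccv_se <- function(data, predictors, outcome, B = 25, seed) {
  if (missing(seed)) stop("seed is required for BCCV")
  y <- data[[outcome]]
  check_scored(rep(0, length(y)), y)
  n <- length(y)
  X <- cbind(`(Intercept)` = 1, model_design(predictors, data))
  full <- logistic_fit_core(X, y)
  redraws <- 0L
  cs <- with_seed(seed, vapply(seq_len(B), function(b) {
    for (attempt in seq_len(100)) {
      idx <- sample.int(n, n, replace = TRUE)
      ok <- length(unique(y[idx])) == 2
      if (ok) {
        preds <- rep(NA_real_, n)
        for (i in unique(idx)) {          # delete ALL copies of original i
          keep <- idx[idx != i]
          if (length(unique(y[keep])) < 2) { ok <- FALSE; break }
          fit <- logistic_fit_core(X[keep, , drop = FALSE], y[keep],
                                   start = full$beta)
          preds[i] <- stats::plogis(drop(X[i, ] %*% fit$beta))
        }
      }
      if (ok) return(c_index(preds[idx], y[idx]))
      redraws <<- redraws + 1L
    }
    stop("BCCV: could not draw a two-class bootstrap resample ",
         "in 100 attempts")
  }, 0))
  out <- stats::sd(cs)
  attr(out, "cindices") <- cs
  attr(out, "redraws") <- redraws
  out
}

#' Fine-tune a model on imputed data and validate it honestly
#'
#' Re-estimates a template model's intercept and coefficients on each
#' imputed dataset (same predictors, same logistic form).  Per dataset it
#' computes the LOOCV C-index with its BCCV within-dataset SD, and the
#' within-dataset coefficient SEs as the SD of coefficient estimates over
#' B bootstrap refits; everything is pooled across the M datasets by
#' Rubin's rules.  Calibration deciles and risk-stratum proportions are
#' computed on the out-of-sample (LOOCV) predicted probabilities averaged
#' over datasets.
#'
#' @param template a `jia_model` supplying the predictor set.
#' @param imps an `imputation_set`.
#' @param outcome name of the binary outcome column.
#' @param B bootstrap resamples per dataset (C-index SD and coefficient
#'   SEs).
#' @param seed integer seed; per-dataset streams are `seed + dataset
#'   index` offsets so M and B can change without correlating streams.
#' @param compute_cindex also run the LOOCV/BCCV C-index machinery (and
#'   the calibration/stratum summaries that depend on it); coefficient
#'   pooling alone is much cheaper.
#' @param low_cut,high_cut risk-stratum cut-points in percent.
#' @return object of class `validation_report` with elements `model`,
#'   `outcome`, `finetuned` (pooled LOOCV C-index or NULL), `coefficients`
#'   (list of `pooled_estimate`, intercept first), `calibration`,
#'   `strata`, `loocv_predictions`, `events` (log of redraw/separation
#'   events), `M`, `B`, `seed`.
#' @export
finetune_and_validate <- function(template, imps, outcome, B = 25, seed,
                                  compute_cindex = TRUE,
                                  low_cut = 20, high_cut = 60) {
  stopifnot(inherits(template, "jia_model"),
            inherits(imps, "imputation_set"))
  if (missing(seed)) stop("seed is required")
  predictors <- names(template$coefficients)
  M <- imps$M
  terms <- c("(Intercept)", predictors)
  events <- character()

  coef_est <- matrix(NA_real_, M, length(terms),
                     dimnames = list(NULL, terms))
  coef_wvar <- coef_est
  cs <- wvars <- numeric(M)
  pred_mat <- NULL

  for (m in seq_len(M)) {
    d <- imps$imputations[[m]]
    y <- d[[outcome]]
    fit <- fit_logistic(d, predictors, outcome)
    if (attr(fit, "separated"))
      events <- c(events,
                  sprintf("dataset %d: full fit used ridge fallback", m))
    coef_est[m, ] <- c(fit$intercept, fit$coefficients)

    # bootstrap coefficient SEs within this dataset
    boot <- with_seed(seed + m, {
      out <- matrix(NA_real_, B, length(terms))
      n <- nrow(d)
      for (b in seq_len(B)) {
        for (attempt in seq_len(100)) {
          idx <- sample.int(n, n, replace = TRUE)
          if (length(unique(y[idx])) == 2) break
          if (attempt == 100)
            stop("bootstrap: single-class resamples persist")
        }
        bf <- fit_logistic(d[idx, , drop = FALSE], predictors, outcome)
        out[b, ] <- c(bf$intercept, bf$coefficients)
      }
      out
    })
    coef_wvar[m, ] <- apply(boot, 2, stats::var)

    if (compute_cindex) {
      cv <- loocv_cindex(d, predictors, outcome)
      cs[m] <- as.numeric(cv)
      if (is.null(pred_mat)) pred_mat <- matrix(NA_real_, nrow(d), M)
      pred_mat[, m] <- attr(cv, "predictions")
      sd_m <- bccv_se(d, predictors, outcome, B = B, seed = seed + m)
      if (attr(sd_m, "redraws") > 0)
        events <- c(events, sprintf(
          "dataset %d: %d BCCV resample(s) redrawn", m,
          attr(sd_m, "redraws")))
      wvars[m] <- as.numeric(sd_m)^2
    }
  }

  coefficients <- lapply(terms, function(tm)
    rubin_pool(coef_est[, tm], coef_wvar[, tm]))
  names(coefficients) <- terms

  finetuned <- calibration <- strata <- loocv_predictions <- NULL
  if (compute_cindex) {
    finetuned <- rubin_pool(cs, wvars)
    attr(finetuned, "per_dataset") <- cs
    loocv_predictions <- rowMeans(pred_mat)
    y <- imps$imputations[[1]][[outcome]]
    calibration <- calibration_deciles(loocv_predictions, y)
    strata <- prop.table(table(classify_risk(100 * loocv_predictions,
                                             low_cut, high_cut)))
  }

  structure(list(model = template$name, outcome = outcome,
                 finetuned = finetuned, coefficients = coefficients,
                 calibration = calibration, strata = strata,
                 loocv_predictions = loocv_predictions,
                 events = events, M = M, B = B, seed = seed),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> model:", x$model, " outcome:", x$outcome, "\n")
  if (!is.null(x$untuned)) {
    cat("  un-tuned C-index: "); print(x$untuned)
  }
  if (!is.null(x$finetuned)) {
    cat("  fine-tuned LOOCV C-index: "); print(x$finetuned)
  }
  if (!is.null(x$coefficients)) {
    cat("  pooled coefficients:\n")
    for (nm in names(x$coefficients)) {
      est <- x$coefficients[[nm]]
      cat(sprintf("    %-26s %7.3f (SE %.3f)\n", nm, est$estimate,
                  est$total_se))
    }
  }
  if (!is.null(x$strata)) {
    cat("  risk strata (LOOCV):",
        paste(sprintf("%s %.1f%%", names(x$strata), 100 * x$strata),
              collapse = ", "), "\n")
  }
  if (length(x$events)) cat("  events:", length(x$events), "logged\n")
  invisible(x)
}
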