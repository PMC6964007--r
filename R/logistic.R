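# Internal logistic fitting on a pre-built design matrix (intercept column
# included).  glm.fit does the work; perfect separation or non-convergence
# falls back to a ridge-penalised IRLS with a small L2 penalty on the
# slopes (never the intercept), so leave-one-out subsets of small cohorts
# cannot derail a whole pipeline run.

ridge_irls <- function(X, y, ridge = 1e-4, maxit = 100, tol = 1e-9) {
  p <- ncol(X)
  pen <- diag(c(0, rep(ridge, p - 1L)), p)
  beta <- numeric(p)
  beta[1] <- stats::qlogis(min(max(mean(y), 1e-3), 1 - 1e-3))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(drop(solve(XtW %*% X + pen, XtW %*% z)),
                         error = function(e) NULL)
    if (is.null(beta_new)) return(NULL)
    done <- max(abs(beta_new - beta)) < tol
    beta <- beta_new
    if (done) break
  }
  beta
}

separated <- function(beta, converged) {
  !isTRUE(converged) || any(!is.finite(beta)) || max(abs(beta)) > 15
}

# Returns list(beta, separated, converged); beta named after colnames(X).
logistic_fit_core <- function(X, y, start = NULL) {
  fit <- suppressWarnings(tryCatch(
    stats::glm.fit(X, y, family = stats::binomial(), start = start,
                   control = stats::glm.control(maxit = 30)),
    error = function(e) NULL))
  if (!is.null(fit) && !separated(stats::coef(fit), fit$converged))
    return(list(beta = stats::coef(fit), separated = FALSE,
                converged = TRUE))
  beta <- ridge_irls(X, y)
  if (is.null(beta))
    stop("logistic fit failed even with ridge fallback")
  names(beta) <- colnames(X)
  list(beta = beta, separated = TRUE, converged = TRUE)
}

#' Fit a logistic regression with a fixed predictor set
#'
#' Maximum-likelihood logistic regression of a binary outcome on the named
#' predictors (the "fine-tuning" refit: same predictors, same model form,
#' new intercept and coefficients).  Perfect separation or non-convergence
#' is retried with a small L2 penalty (1e-4) on the slopes and flagged via
#' the `separated` attribute.
#'
#' @param data cohort data.frame containing the predictors and outcome,
#'   with no missing values among them.
#' @param predictors character vector of coefficient names (may include
#'   `jia_*` dummies).
#' @param outcome name of the binary outcome column.
#' @return a `jia_model` with `provenance = "fitted"`; attributes
#'   `separated` (logical) and `converged` (logical).
#' @export
fit_logistic <- function(data, predictors, outcome) {
  y <- data[[outcome]]
  if (is.null(y)) stop("outcome column '", outcome, "' absent from data")
  check_scored(rep(0, length(y)), y)      # both classes, no NA, 0/1
  if (nrow(data) <= length(predictors) + 1L)
    stop("need n > number of predictors + 1")
  X <- cbind(`(Intercept)` = 1, model_design(predictors, data))
  fit <- logistic_fit_core(X, y)
  model <- risk_model(paste0("fitted_", outcome), fit$beta[1],
                      fit$beta[-1], provenance = "fitted",
                      outcome = outcome)
  attr(model, "separated") <- fit$separated
  attr(model, "converged") <- fit$converged
  model
}
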