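# Multiple imputation by chained equations, written for the mixed
# predictor roster of a baseline JIA table: Bayesian-draw linear models
# for continuous variables, posterior-draw logistic models for binaries,
# a multinomial model (nnet) for the JIA category, and rounded draws
# floored at zero for joint counts.  Outcomes are never imputed.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

impute_method_for <- function(col, values) {
  if (col == "jia_category" || is.factor(values) || is.character(values))
    return("multinomial")
  if (col %in% count_predictors) return("count")
  if (col %in% binary_predictors ||
      all(values %in% c(0, 1, NA))) return("logistic")
  "normal"
}

# Design matrix (with intercept) from the completed working copy,
# excluding the target column.
impute_design <- function(work, target, predictor_cols) {
  cols <- setdiff(predictor_cols, target)
  if (!length(cols)) return(matrix(1, nrow(work), 1))
  df <- work[cols]
  stats::model.matrix(~ ., df)
}

# Bayesian linear-regression draw for the missing cells of one column.
draw_normal <- function(X, y, obs, mis) {
  Xo <- X[obs, , drop = FALSE]; yo <- y[obs]
  p <- ncol(Xo); n <- length(yo)
  XtX <- crossprod(Xo)
  eps <- 1e-6 * mean(diag(XtX))
  XtXr <- XtX + diag(eps, p)
  beta_hat <- solve(XtXr, crossprod(Xo, yo))
  resid <- yo - drop(Xo %*% beta_hat)
  df <- max(n - p, 1)
  sigma2 <- sum(resid^2) / stats::rchisq(1, df)
  V <- sigma2 * solve(XtXr)
  beta_star <- drop(beta_hat) +
    drop(t(chol(V + diag(1e-12, p))) %*% stats::rnorm(p))
  drop(X[mis, , drop = FALSE] %*% beta_star) +
    stats::rnorm(length(mis), 0, sqrt(sigma2))
}

# Posterior-draw logistic imputation for a binary column; falls back to a
# marginal Bernoulli draw if the fit degenerates.
draw_logistic <- function(X, y, obs, mis) {
  Xo <- X[obs, , drop = FALSE]; yo <- y[obs]
  fallback <- function()
    stats::rbinom(length(mis), 1, mean(yo))
  if (length(unique(yo)) < 2) return(fallback())
  fit <- tryCatch(logistic_fit_core(Xo, yo), error = function(e) NULL)
  if (is.null(fit)) return(fallback())
  beta <- fit$beta
  mu <- stats::plogis(drop(Xo %*% beta))
  w <- pmax(mu * (1 - mu), 1e-10)
  H <- crossprod(Xo * sqrt(w)) + diag(1e-6, ncol(Xo))
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V)) return(fallback())
  beta_star <- beta + drop(t(chol((V + t(V)) / 2 + diag(1e-12, ncol(Xo)))) %*%
                             stats::rnorm(ncol(Xo)))
  p <- stats::plogis(drop(X[mis, , drop = FALSE] %*% beta_star))
  stats::rbinom(length(mis), 1, p)
}

# Multinomial draw for the JIA category column.
draw_multinomial <- function(X, y, obs, mis) {
  yo <- droplevels(factor(y[obs]))
  if (nlevels(yo) < 2)
    return(rep(levels(yo), length(mis)))
  dfo <- data.frame(.y = yo, X[obs, -1, drop = FALSE])
  dfm <- data.frame(X[mis, -1, drop = FALSE])
  fit <- tryCatch(
    nnet::multinom(.y ~ ., data = dfo, trace = FALSE, maxit = 60,
                   MaxNWts = 10000),
    error = function(e) NULL)
  if (is.null(fit)) {
    pr <- matrix(rep(prop.table(table(yo)), each = length(mis)),
                 nrow = length(mis))
    colnames(pr) <- levels(yo)
  } else {
    pr <- stats::predict(fit, newdata = dfm, type = "probs")
    if (nlevels(yo) == 2L) {               # vector of P(second level)
      pr <- cbind(1 - pr, pr)
    } else if (length(mis) == 1L) {        # single row comes back as vector
      pr <- matrix(pr, nrow = 1)
    }
    colnames(pr) <- levels(yo)
  }
  apply(pr, 1, function(p) sample(levels(yo), 1, prob = pmax(p, 0)))
}

#' Multiple imputation by chained equations
#'
#' Produces `M` completed copies of a cohort table.  Each incomplete
#' predictor is regressed on all other predictors (linear model for
#' continuous variables, logistic for binaries, multinomial for
#' `jia_category`; joint counts are drawn as continuous then rounded and
#' floored at 0) and its missing cells are drawn from the fitted
#' predictive distribution, sweeping over columns in order of ascending
#' missingness for `n_iter` iterations.  Outcome columns are never
#' imputed and never used as imputation predictors unless
#' `impute_with_outcome = TRUE` (in which case complete outcome columns
#' join the predictor set).
#'
#' The M streams are seeded independently (`seed + m` for dataset m), so
#' results are bit-reproducible for a given `(data, M, n_iter, seed)` and
#' unchanged datasets keep their stream when `M` changes.
#'
#' @param data cohort data.frame; missing predictor cells as `NA`.
#' @param M number of imputed datasets (>= 2).
#' @param n_iter chained-equation sweeps per dataset.
#' @param seed integer seed; mandatory.
#' @param columns columns to impute; default: every non-outcome column
#'   containing `NA`.  Naming an outcome column here is an error.
#' @param impute_with_outcome also condition imputation models on complete
#'   outcome columns (off by default).
#' @return an object of class `imputation_set`: list with elements
#'   `imputations` (list of M data.frames), `M`, `n_iter`, `seed`,
#'   `columns`, `methods`.
#' @export
mice_impute <- function(data, M = 20, n_iter = 10, seed,
                        columns = NULL, impute_with_outcome = FALSE) {
  stopifnot(is.data.frame(data))
  if (missing(seed)) stop("seed is required for reproducible imputation")
  if (!is.numeric(M) || M < 2) stop("M must be an integer >= 2")
  M <- as.integer(M)
  outcomes <- intersect(outcome_columns, names(data))
  if (is.character(data$jia_category))
    data$jia_category <- factor(data$jia_category, levels = jia_categories)

  if (is.null(columns)) {
    columns <- names(data)[vapply(data, anyNA, TRUE)]
    columns <- setdiff(columns, outcomes)
  } else {
    hit <- intersect(columns, outcomes)
    if (length(hit))
      stop("outcome column(s) may not be imputed: ",
           paste(hit, collapse = ", "))
    columns <- intersect(columns, names(data))
  }
  for (col in columns)
    if (all(is.na(data[[col]])))
      stop("column '", col, "' has no observed values; cannot impute")

  predictor_cols <- setdiff(names(data), outcomes)
  if (impute_with_outcome)
    predictor_cols <- c(predictor_cols,
                        outcomes[!vapply(data[outcomes], anyNA, TRUE)])

  methods <- vapply(columns, function(col)
    impute_method_for(col, data[[col]]), "")
  # visit sequence: ascending missingness
  n_mis <- vapply(columns, function(col) sum(is.na(data[[col]])), 0L)
  columns <- columns[order(n_mis)]
  miss_idx <- lapply(data[columns], function(x) which(is.na(x)))
  names(miss_idx) <- columns

  one_dataset <- function(m) {
    with_seed(seed + m, {
      work <- data
      for (col in columns) {              # initial fill: observed draws
        mis <- miss_idx[[col]]
        if (!length(mis)) next
        obs_vals <- work[[col]][!is.na(work[[col]])]
        work[[col]][mis] <- sample(obs_vals, length(mis), replace = TRUE)
      }
      if (any(lengths(miss_idx) > 0)) {
        for (it in seq_len(n_iter)) {
          for (col in columns) {
            mis <- miss_idx[[col]]
            if (!length(mis)) next
            obs <- setdiff(seq_len(nrow(work)), mis)
            X <- impute_design(work, col, predictor_cols)
            y <- work[[col]]
            work[[col]][mis] <- switch(
              methods[[col]],
              normal = draw_normal(X, as.numeric(y), obs, mis),
              count = pmax(0, round(draw_normal(X, as.numeric(y),
                                                obs, mis))),
              logistic = draw_logistic(X, as.numeric(y), obs, mis),
              multinomial = {
                lev <- draw_multinomial(X, as.character(y), obs, mis)
                if (is.factor(y)) factor(lev, levels = levels(y)) else lev
              })
          }
        }
      }
      work
    })
  }

  imputations <- lapply(seq_len(M), one_dataset)
  structure(list(imputations = imputations, M = M, n_iter = n_iter,
                 seed = seed, columns = columns, methods = methods),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("<imputation_set> M =", x$M, "datasets,", x$n_iter,
      "sweeps, seed", x$seed, "\n")
  if (length(x$columns))
    cat("  imputed:", paste(x$columns, collapse = ", "), "\n")
  else cat("  nothing to impute (input was complete)\n")
  invisible(x)
}

#' Extract one completed dataset
#'
#' @param imps an `imputation_set`.
#' @param k dataset index in 1..M.
#' @return data.frame.
#' @export
get_imputation <- function(imps, k) {
  stopifnot(inherits(imps, "imputation_set"), k >= 1, k <= imps$M)
  imps$imputations[[k]]
}

#' Write completed datasets to CSV
#'
#' Files are named `<stem>.imp<k>.csv` for k = 1..M.
#'
#' @param imps an `imputation_set`.
#' @param stem path prefix.
#' @return character vector of paths, invisibly.
#' @export
write_imputations <- function(imps, stem) {
  stopifnot(inherits(imps, "imputation_set"))
  paths <- sprintf("%s.imp%d.csv", stem, seq_len(imps$M))
  for (k in seq_len(imps$M)) write_cohort(imps$imputations[[k]], paths[k])
  invisible(paths)
}
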