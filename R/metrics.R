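check_scored <- function(scores, outcomes, min_per_class = 1L) {
  stopifnot(is.numeric(scores), length(scores) == length(outcomes))
  if (anyNA(scores) || anyNA(outcomes))
    stop("scores and outcomes must not contain missing values")
  if (!all(outcomes %in% c(0, 1)))
    stop("outcomes must be binary 0/1")
  n1 <- sum(outcomes == 1); n0 <- sum(outcomes == 0)
  if (n1 < min_per_class || n0 < min_per_class)
    stop("undefined statistic: outcomes must contain both classes")
  invisible(c(n1 = n1, n0 = n0))
}

#' Concordance index (tie-aware AUC)
#'
#' Probability that a randomly chosen case scores above a randomly chosen
#' control, with tied score pairs counted 1/2: over all case-control
#' pairs, (concordant + 0.5 tied) / total.  Equals the area under the ROC
#' curve; 1.0 is perfect discrimination, 0.5 is chance.  Computed via
#' midranks (the Wilcoxon-Mann-Whitney identity), O(n log n).
#'
#' @param scores numeric risk scores or probabilities.
#' @param outcomes binary 0/1 vector, same length; both classes required.
#' @return C-index in \[0, 1\].
#' @export
c_index <- function(scores, outcomes) {
  n <- check_scored(scores, outcomes)
  r <- rank(scores)                       # midranks handle ties
  (sum(r[outcomes == 1]) - n[["n1"]] * (n[["n1"]] + 1) / 2) /
    (as.numeric(n[["n1"]]) * n[["n0"]])
}

# DeLong structural components: for each case, the fraction of controls it
# beats (ties 1/2); and symmetrically for controls.
delong_components <- function(scores, outcomes) {
  cases <- scores[outcomes == 1]; controls <- scores[outcomes == 0]
  m <- length(cases); n0 <- length(controls)
  r_all <- rank(c(cases, controls))
  v10 <- (r_all[seq_len(m)] - rank(cases)) / n0
  v01 <- 1 - (r_all[m + seq_len(n0)] - rank(controls)) / m
  list(v10 = v10, v01 = v01)
}

#' Analytic standard error of the C-index
#'
#' DeLong's structural-components variance:
#' \eqn{\widehat{var} = S_{10}/m + S_{01}/n_0}, where \eqn{S_{10}} is the
#' sample variance over cases of the per-case placement values and
#' \eqn{S_{01}} the analogue over controls.  Degenerate score vectors
#' (all tied) have SE 0.
#'
#' @inheritParams c_index
#' @return non-negative standard error.
#' @export
c_index_se <- function(scores, outcomes) {
  check_scored(scores, outcomes, min_per_class = 2L)
  v <- delong_components(scores, outcomes)
  sqrt(stats::var(v$v10) / length(v$v10) +
       stats::var(v$v01) / length(v$v01))
}

#' ROC curve points
#'
#' One point per distinct score threshold (predicate: score >= threshold),
#' plus the (0, 0) and (1, 1) endpoints.  Tied scores collapse into a
#' single threshold, so the trapezoidal area under the returned polyline
#' equals [c_index()] exactly.
#'
#' @inheritParams c_index
#' @return data.frame with columns `fpr`, `tpr`, ordered from (0,0) to
#'   (1,1).
#' @export
roc_points <- function(scores, outcomes) {
  n <- check_scored(scores, outcomes)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- outcomes[ord]
  # index of the last element of each tied block, descending scores
  block_end <- which(!duplicated(s, fromLast = TRUE))
  tpr <- cumsum(y)[block_end] / n[["n1"]]
  fpr <- cumsum(1 - y)[block_end] / n[["n0"]]
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Decile calibration table
#'
#' Patients are sorted by predicted probability (stable sort) and split
#' into 10 near-equal bins, lowest predictions first; when n is not a
#' multiple of 10 the remainder is distributed one per bin starting from
#' the lowest bin.  Each bin reports the mean predicted probability, the
#' observed outcome rate, and its count.
#'
#' @param predicted predicted probabilities on the 0-1 scale.
#' @param outcomes binary 0/1 vector, same length, n >= 10.
#' @return data.frame with columns `bin`, `mean_pred`, `obs_rate`,
#'   `count`; counts sum to n.
#' @export
calibration_deciles <- function(predicted, outcomes) {
  stopifnot(is.numeric(predicted), length(predicted) == length(outcomes))
  n <- length(predicted)
  if (n < 10) stop("calibration deciles require n >= 10")
  if (anyNA(predicted) || anyNA(outcomes))
    stop("predicted and outcomes must not contain missing values")
  ord <- order(predicted)                 # radix: stable
  sizes <- rep(n %/% 10, 10)
  rem <- n %% 10
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
  bin <- rep(seq_len(10), times = sizes)
  p <- predicted[ord]; y <- outcomes[ord]
  data.frame(
    bin = seq_len(10),
    mean_pred = as.numeric(tapply(p, bin, mean)),
    obs_rate = as.numeric(tapply(y, bin, mean)),
    count = as.integer(sizes))
}
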