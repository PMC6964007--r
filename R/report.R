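# End-to-end validation run: cohort in, imputation, un-tuned evaluation,
# fine-tuning, and deterministic report files out.

pooled_to_list <- function(x) {
  if (is.null(x)) return(NULL)
  list(estimate = x$estimate, within_var = x$within_var,
       between_var = x$between_var, total_se = x$total_se,
       ci95_low = x$ci95[1], ci95_high = x$ci95[2], M = x$M)
}

#' Run the full external-validation pipeline
#'
#' Loads (or accepts) a patient-level cohort, restricts it to rows with an
#' evaluable (non-missing) outcome, imputes missing predictors in `M`
#' datasets, evaluates the model exactly as published, fine-tunes it with
#' LOOCV C-indices and BCCV/bootstrap SEs, and (optionally) writes
#' `report.json`, `roc.csv`, `calibration.csv`, `coefficients.csv` and
#' `events.log` to a directory.  All randomness derives from `seed`, so a
#' rerun with identical input, configuration and seed reproduces every
#' output byte for byte.
#'
#' @param input cohort data.frame or path to a cohort CSV.
#' @param model a `jia_model` or the name of a built-in model.
#' @param outcome outcome column name (default: the model's outcome).
#' @param M number of imputations.
#' @param n_iter chained-equation sweeps.
#' @param B bootstrap resamples.
#' @param seed integer seed.
#' @param no_labs drop the laboratory predictors (ESR, CRP > 10, ANA,
#'   HLA-B27) from the model before evaluation and fine-tuning.
#' @param finetune run the fine-tuning stage.
#' @param compute_cindex run the LOOCV/BCCV machinery within fine-tuning.
#' @param out_dir optional output directory (created if needed).
#' @param low_cut,high_cut risk-stratum cut-points in percent.
#' @return a `validation_report` (invisibly if `out_dir` is given) with
#'   the un-tuned pooled C-index in `$untuned` and ROC tables in `$roc`.
#' @export
run_validation <- function(input, model, outcome = NULL, M = 20,
                           n_iter = 10, B = 25, seed, no_labs = FALSE,
                           finetune = TRUE, compute_cindex = TRUE,
                           out_dir = NULL, low_cut = 20, high_cut = 60) {
  if (missing(seed)) stop("seed is required")
  data <- if (is.character(input)) load_cohort(input, quiet = TRUE)
          else validate_cohort(map_joint_count(input, quiet = TRUE))
  if (is.character(model)) model <- get_model(model)
  if (is.null(outcome)) outcome <- model$outcome
  if (is.null(outcome) || !outcome %in% names(data))
    stop("outcome column '", outcome, "' not found in the input data")
  if (no_labs) {
    labs <- c("esr", "crp_gt_10", "ana_positive", "b27_positive")
    keep <- setdiff(names(model$coefficients), labs)
    model <- risk_model(paste0(model$name, "_nolabs"), model$intercept,
                        model$coefficients[keep], model$provenance,
                        outcome = model$outcome)
  }

  # evaluable patients only; keep just what the pipeline consumes
  data <- data[!is.na(data[[outcome]]), , drop = FALSE]
  need <- names(model$coefficients)
  jia_terms <- startsWith(need, "jia_")
  cols <- unique(c(need[!jia_terms],
                   if (any(jia_terms)) "jia_category", outcome))
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("input lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  data <- data[cols]

  imps <- mice_impute(data, M = M, n_iter = n_iter, seed = seed)
  untuned <- evaluate_untuned(model, imps, outcome)

  report <- NULL
  if (finetune) {
    report <- finetune_and_validate(model, imps, outcome, B = B,
                                    seed = seed,
                                    compute_cindex = compute_cindex,
                                    low_cut = low_cut,
                                    high_cut = high_cut)
  } else {
    report <- structure(list(model = model$name, outcome = outcome,
                             finetuned = NULL, coefficients = NULL,
                             calibration = NULL, strata = NULL,
                             loocv_predictions = NULL,
                             events = character(), M = M, B = B,
                             seed = seed),
                        class = "validation_report")
  }
  report$untuned <- untuned

  # ROC tables on predictions averaged across imputed datasets
  y <- imps$imputations[[1]][[outcome]]
  p_untuned <- rowMeans(vapply(imps$imputations, function(d)
    predict_risk(model, d, scale = "probability"), numeric(nrow(data))))
  roc <- cbind(which = "untuned", roc_points(p_untuned, y))
  if (!is.null(report$loocv_predictions))
    roc <- rbind(roc, cbind(which = "finetuned",
                            roc_points(report$loocv_predictions, y)))
  report$roc <- roc

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    json <- list(
      model = report$model, outcome = outcome, n = nrow(data),
      M = M, n_iter = n_iter, B = B, seed = seed, no_labs = no_labs,
      untuned_cindex = pooled_to_list(report$untuned),
      finetuned_cindex = pooled_to_list(report$finetuned),
      coefficients = lapply(report$coefficients, pooled_to_list),
      risk_strata = if (!is.null(report$strata))
        as.list(stats::setNames(as.numeric(report$strata),
                                names(report$strata))))
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    utils::write.csv(report$roc, file.path(out_dir, "roc.csv"),
                     row.names = FALSE)
    if (!is.null(report$calibration))
      utils::write.csv(report$calibration,
                       file.path(out_dir, "calibration.csv"),
                       row.names = FALSE)
    if (!is.null(report$coefficients)) {
      ct <- do.call(rbind, lapply(names(report$coefficients), function(nm) {
        e <- report$coefficients[[nm]]
        data.frame(term = nm, estimate = e$estimate, total_se = e$total_se,
                   ci95_low = e$ci95[1], ci95_high = e$ci95[2])
      }))
      utils::write.csv(ct, file.path(out_dir, "coefficients.csv"),
                       row.names = FALSE)
    }
    writeLines(report$events, file.path(out_dir, "events.log"))
    return(invisible(report))
  }
  report
}
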