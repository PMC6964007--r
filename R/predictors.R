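#' @title Baseline predictor roster
#' @description
#' Column names and types for a patient-level baseline table ("cohort").
#' One row per patient; predictors may be missing (`NA`), outcomes may not
#' be missing among evaluable patients.
#'
#' Numeric predictors are the joint counts (non-negative integers), ESR in
#' mm/h, and the 0-10 visual-analogue scales (physician global assessment
#' and pain).  All remaining predictors are 0/1 indicators, plus the
#' seven-level JIA category.
#' @name predictor_roster
NULL

# Seven ILAR-style JIA onset categories used by the Canadian model's dummies.
jia_categories <- c("oligoarthritis", "rf_neg_poly", "rf_pos_poly",
                    "systemic", "enthesitis_related", "psoriatic",
                    "undifferentiated")

# Count-valued predictors (non-negative integers).
count_predictors <- c("active_joint_count", "joint_count_for_nordic")

# Continuous predictors with their valid ranges.
continuous_predictors <- c(esr = Inf, pga = 10, pain = 10)

binary_predictors <- c(
  "crp_gt_10", "morning_stiffness_gt_15", "morning_stiffness_present",
  "ana_positive", "b27_positive", "rf_positive",
  "ankle_arthritis", "finger_arthritis", "subtalar_arthritis",
  "cervical_arthritis", "hip_arthritis", "tmj_arthritis",
  "midfoot_arthritis", "upper_limb_involvement", "symmetric_involvement",
  "enthesitis_present")

outcome_columns <- c("non_remission", "severe_course", "disability_chaq_gt0")

all_predictors <- function() {
  c(count_predictors, names(continuous_predictors), binary_predictors,
    "jia_category")
}

#' Validate a cohort table
#'
#' Checks the structural invariants of a patient-level baseline table:
#' VAS fields in \[0, 10\], counts and ESR non-negative, binary columns in
#' \{0, 1\}, `jia_category` restricted to its seven levels, and outcome
#' columns (where present and non-missing) in \{0, 1\}.  Missing predictor
#' cells (`NA`) are allowed; unknown columns are ignored.
#'
#' @param data data.frame with one row per patient.
#' @return `data` invisibly, with `jia_category` coerced to a factor on the
#'   canonical seven levels if the column is present.
#' @export
validate_cohort <- function(data) {
  stopifnot(is.data.frame(data))
  for (col in intersect(count_predictors, names(data))) {
    x <- data[[col]]
    if (!is.numeric(x) || any(x < 0 | x != round(x), na.rm = TRUE))
      stop("column '", col, "' must hold non-negative integer joint counts")
  }
  for (col in intersect(names(continuous_predictors), names(data))) {
    x <- data[[col]]
    hi <- continuous_predictors[[col]]
    if (!is.numeric(x) || any(x < 0 | x > hi, na.rm = TRUE))
      stop("column '", col, "' out of range [0, ", hi, "]")
  }
  for (col in intersect(c(binary_predictors, outcome_columns), names(data))) {
    x <- data[[col]]
    if (!all(x %in% c(0, 1, NA)))
      stop("column '", col, "' must be binary 0/1")
  }
  if ("jia_category" %in% names(data)) {
    x <- as.character(data$jia_category)
    bad <- setdiff(unique(x[!is.na(x)]), jia_categories)
    if (length(bad))
      stop("unknown jia_category level(s): ", paste(bad, collapse = ", "))
    data$jia_category <- factor(x, levels = jia_categories)
  }
  invisible(data)
}

#' Read a cohort CSV
#'
#' Reads a patient-level baseline table (one header row, empty cells or
#' "NA" for missing values) and validates it.  The Nordic models score a
#' single joint-count predictor, `joint_count_for_nordic`; if that column
#' is absent it is created from `cumulative_joint_count` when available
#' (the count the Nordic models were built on) and otherwise from
#' `active_joint_count` (the baseline substitute), with a message stating
#' which column was mapped.
#'
#' @param path path to a CSV file.
#' @param quiet suppress the joint-count mapping message.
#' @return validated data.frame.
#' @export
load_cohort <- function(path, quiet = FALSE) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  data <- map_joint_count(data, quiet = quiet)
  data <- validate_cohort(data)
  data
}

#' Map a joint-count column onto the Nordic models' predictor
#'
#' @param data cohort data.frame.
#' @param quiet suppress the mapping message.
#' @return `data` with a `joint_count_for_nordic` column.
#' @export
map_joint_count <- function(data, quiet = FALSE) {
  if ("joint_count_for_nordic" %in% names(data)) return(data)
  src <- if ("cumulative_joint_count" %in% names(data))
    "cumulative_joint_count" else if ("active_joint_count" %in% names(data))
    "active_joint_count" else return(data)
  data$joint_count_for_nordic <- data[[src]]
  if (!quiet)
    message("joint_count_for_nordic mapped from column '", src, "'")
  data
}

#' Write a cohort CSV
#'
#' Inverse of [load_cohort()]: missing cells are written as "NA".
#'
#' @param data cohort data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "NA")
  invisible(path)
}
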