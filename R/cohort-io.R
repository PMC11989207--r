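cohort_columns <- c("patient_id", "ct_stage", "cn_stage", "ypt_stage",
                    "ypn_stage", "rt_post_stage", "rn_post_stage",
                    "mrtrg", "ptrg", "cd3_ct", "cd3_im", "cd8_ct", "cd8_im",
                    "grade", "dfs_months", "dfs_event", "os_months",
                    "os_event")

score_columns <- c("is_mean_percentile", "is_class", "nar_path",
                   "nar_path_cat", "nar_rad", "nar_rad_cat", "pcr",
                   "near_pcr", "combined_stratum")

add_finding <- function(findings, row, column, value, message) {
  rbind(findings, data.frame(row = row, column = column,
                             value = as.character(value),
                             message = message, stringsAsFactors = FALSE))
}

check_nonneg_number <- function(x, what) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v) || !is.finite(v) || v < 0) {
    stop(what, " must be a non-negative number: ", x, call. = FALSE)
  }
}

empty_findings <- function() {
  data.frame(row = integer(), column = character(), value = character(),
             message = character(), stringsAsFactors = FALSE)
}

# validate one column cell-wise with an encoder/checker; invalid cells are
# blanked to NA and reported as findings rather than aborting the read
validate_cells <- function(df, findings, column, check) {
  if (!column %in% names(df)) return(list(df = df, findings = findings))
  x <- df[[column]]
  for (i in seq_along(x)) {
    if (is.na(x[i]) || identical(as.character(x[i]), "")) next
    ok <- tryCatch({ check(x[i]); TRUE }, error = function(e) e)
    if (!isTRUE(ok)) {
      findings <- add_finding(findings, i, column, x[i],
                              conditionMessage(ok))
      df[[column]][i] <- NA
    }
  }
  list(df = df, findings = findings)
}

#' Read a patient-level cohort table
#'
#' Reads a comma-delimited UTF-8 cohort file with a header row of canonical
#' column names (`patient_id`, `ct_stage`, `cn_stage`, `ypt_stage`,
#' `ypn_stage`, `rt_post_stage`, `rn_post_stage`, `mrtrg`, `ptrg`,
#' `cd3_ct`, `cd3_im`, `cd8_ct`, `cd8_im`, `grade`, `dfs_months`,
#' `dfs_event`, `os_months`, `os_event`). Empty cells are missing; unknown
#' columns are preserved but ignored by the pipeline. Stage labels are
#' validated with the staging encoders; an invalid cell does not abort the
#' read — the field is set missing and a structured finding (row, column,
#' offending value, message) is recorded. Absence of `patient_id` or
#' `ct_stage`, or a duplicated `patient_id`, is a hard error.
#'
#' @param path path to the CSV file.
#' @return list with `records` (data frame, one row per patient, all
#'   canonical columns present) and `findings` (data frame of row-level
#'   validation findings).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), fileEncoding = "UTF-8")
  for (col in c("patient_id", "ct_stage")) {
    if (!col %in% names(df)) {
      stop("mandatory column missing: ", col, call. = FALSE)
    }
  }
  if (anyDuplicated(df$patient_id)) {
    stop("duplicated patient_id: ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]),
               collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(cohort_columns, names(df))) {
    df[[col]] <- rep(NA, nrow(df))
  }
  findings <- empty_findings()
  for (col in c("ct_stage", "ypt_stage", "rt_post_stage")) {
    r <- validate_cells(df, findings, col, encode_t_stage)
    df <- r$df; findings <- r$findings
  }
  for (col in c("cn_stage", "ypn_stage", "rn_post_stage")) {
    r <- validate_cells(df, findings, col, encode_n_stage)
    df <- r$df; findings <- r$findings
  }
  checks <- list(
    mrtrg = check_mrtrg,
    ptrg = check_ptrg,
    grade = function(x) {
      if (!x %in% 1:3) stop("tumor grade out of range 1-3: ", x, call. = FALSE)
    },
    dfs_event = function(x) {
      if (!x %in% c(0, 1)) stop("event indicator must be 0/1: ", x, call. = FALSE)
    },
    os_event = function(x) {
      if (!x %in% c(0, 1)) stop("event indicator must be 0/1: ", x, call. = FALSE)
    },
    dfs_months = function(x) check_nonneg_number(x, "time"),
    os_months = function(x) check_nonneg_number(x, "time")
  )
  for (col in c("cd3_ct", "cd3_im", "cd8_ct", "cd8_im")) {
    checks[[col]] <- function(x) check_nonneg_number(x, "density")
  }
  for (col in names(checks)) {
    r <- validate_cells(df, findings, col, checks[[col]])
    df <- r$df; findings <- r$findings
  }
  for (col in c("mrtrg", "ptrg", "grade", "dfs_event", "os_event")) {
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  }
  for (col in c("cd3_ct", "cd3_im", "cd8_ct", "cd8_im",
                "dfs_months", "os_months")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  list(records = df, findings = findings)
}

#' Write a scored cohort table
#'
#' Writes the cohort with its appended score columns
#' (`is_mean_percentile`, `is_class`, `nar_path`, `nar_path_cat`,
#' `nar_rad`, `nar_rad_cat`, `pcr`, `near_pcr`, `combined_stratum`) as a
#' comma-delimited UTF-8 file. Numeric score values are written with three
#' decimal places; endpoints as 0/1; missing values as empty cells.
#'
#' @param records scored cohort data frame (see [score_cohort()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_scored_cohort <- function(records, path) {
  df <- records
  fmt3 <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.3f", x))
  for (col in c("is_mean_percentile", "nar_path", "nar_rad")) {
    if (col %in% names(df)) df[[col]] <- fmt3(df[[col]])
  }
  for (col in c("pcr", "near_pcr")) {
    if (col %in% names(df)) df[[col]] <- ifelse(is.na(df[[col]]), NA_integer_,
                                                as.integer(df[[col]]))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   na = "", fileEncoding = "UTF-8")
  invisible(path)
}
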