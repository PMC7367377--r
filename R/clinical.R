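#' Clinical covariate table
#'
#' Per-patient overall-survival outcome plus the confounders used in
#' multivariate Cox adjustment: sex, pathologic stage, retrospective
#' collection indicator, race, year of initial diagnosis, age at initial
#' diagnosis and microsatellite status. Missing values are preserved as `NA`
#' and handled downstream by complete-case analysis; nothing is imputed.
#'
#' @format A data.frame of class `clinical_table` with columns `patient_id`,
#'   `survival_time` (days), `event` (1 = death, 0 = censored), `sex`,
#'   `pathologic_stage`, `retrospective`, `race`, `year_of_diagnosis`,
#'   `age_at_diagnosis`, `microsatellite_status` (`mss`/`msi-l`/`msi-h`).
#' @name clinical_table
NULL

CLINICAL_COLUMNS <- c("patient_id", "survival_time", "event", "sex",
                      "pathologic_stage", "retrospective", "race",
                      "year_of_diagnosis", "age_at_diagnosis",
                      "microsatellite_status")

CONFOUNDER_COLUMNS <- c("sex", "pathologic_stage", "retrospective", "race",
                        "year_of_diagnosis", "age_at_diagnosis",
                        "microsatellite_status")

validate_clinical <- function(df) {
  missing_cols <- setdiff(c("patient_id", "survival_time", "event"), names(df))
  if (length(missing_cols)) {
    ssnet_error(paste0("clinical table missing column(s): ",
                       paste(missing_cols, collapse = ", ")),
                "ssnet_format_error")
  }
  for (col in setdiff(CLINICAL_COLUMNS, names(df))) df[[col]] <- NA
  df <- df[, CLINICAL_COLUMNS]
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id)) {
    ssnet_error("duplicate patient ids", "ssnet_validation_error")
  }
  df$survival_time <- as.numeric(df$survival_time)
  df$event <- as.integer(df$event)
  if (any(df$survival_time < 0, na.rm = TRUE)) {
    ssnet_error("negative survival time", "ssnet_validation_error")
  }
  if (!all(df$event %in% c(0L, 1L) | is.na(df$event))) {
    ssnet_error("event must be 0 or 1", "ssnet_validation_error")
  }
  ms <- df$microsatellite_status
  if (!all(is.na(ms) | ms %in% c("mss", "msi-l", "msi-h"))) {
    ssnet_error("microsatellite_status must be mss/msi-l/msi-h", "ssnet_validation_error")
  }
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read a clinical covariate table from TSV
#'
#' Requires `patient_id`, `survival_time` and `event` columns; the confounder
#' columns are optional and filled with `NA` when absent. Empty strings and
#' literal `NA` are read as missing.
#'
#' @param path tab-separated file with a header of named columns.
#' @return A [clinical_table].
#' @export
read_clinical_table <- function(path) {
  df <- read_tsv_plain(path, na.strings = c("NA", ""))
  validate_clinical(df)
}

#' Write a clinical covariate table to TSV
#'
#' @param clinical a [clinical_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Restrict a clinical table to complete cases on the confounders
#'
#' Mirrors the complete-case behaviour of multivariate Cox adjustment:
#' patients missing any confounder (or the outcome) are dropped.
#'
#' @param clinical a [clinical_table].
#' @param confounders columns that must be observed; defaults to the full
#'   confounder list.
#' @return The complete-case subset, still a `clinical_table`.
#' @export
complete_case_clinical <- function(clinical, confounders = CONFOUNDER_COLUMNS) {
  need <- c("survival_time", "event", confounders)
  keep <- stats::complete.cases(clinical[, need, drop = FALSE])
  out <- clinical[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("clinical_table", "data.frame")
  out
}
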