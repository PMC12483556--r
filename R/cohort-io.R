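cohort_required_cols <- c("patient_id", "rsi", "n_fractions",
                          "dose_per_fraction", "time_months", "event")
cohort_covariate_cols <- c("t4_flag", "n23_flag", "smoking_gt10py", "ecog_gt0")

#' Validate a cohort table
#'
#' Checks the standard cohort schema: required columns present, RSI in
#' (0, 1], valid fractionation, non-negative follow-up, 0/1 event flags,
#' and 0/1/NA covariate flags. All violations are collected and reported
#' together.
#'
#' @param cohort Data frame.
#' @return Invisibly `TRUE`; errors with an itemized message otherwise.
#' @export
validate_cohort <- function(cohort) {
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)
  if (!is.data.frame(cohort)) {
    stop("cohort must be a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(cohort_required_cols, names(cohort))
  if (length(missing_cols)) {
    add(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  } else {
    bad_rows <- function(cond) paste(utils::head(which(cond), 5), collapse = ", ")
    if (anyNA(cohort$rsi) || any(cohort$rsi <= 0 | cohort$rsi > 1, na.rm = TRUE)) {
      add(paste0("rsi outside (0, 1] in row(s): ",
                 bad_rows(is.na(cohort$rsi) | cohort$rsi <= 0 | cohort$rsi > 1)))
    }
    if (anyNA(cohort$n_fractions) ||
        any(cohort$n_fractions < 1 | cohort$n_fractions != round(cohort$n_fractions),
            na.rm = TRUE)) {
      add(paste0("invalid n_fractions in row(s): ",
                 bad_rows(is.na(cohort$n_fractions) | cohort$n_fractions < 1 |
                          cohort$n_fractions != round(cohort$n_fractions))))
    }
    if (anyNA(cohort$dose_per_fraction) ||
        any(cohort$dose_per_fraction <= 0, na.rm = TRUE)) {
      add(paste0("non-positive dose_per_fraction in row(s): ",
                 bad_rows(is.na(cohort$dose_per_fraction) |
                          cohort$dose_per_fraction <= 0)))
    }
    if (anyNA(cohort$time_months) || any(cohort$time_months < 0, na.rm = TRUE)) {
      add(paste0("negative or missing time_months in row(s): ",
                 bad_rows(is.na(cohort$time_months) | cohort$time_months < 0)))
    }
    if (anyNA(cohort$event) || !all(cohort$event %in% c(0, 1))) {
      add("event must be 0/1 with no missing values")
    }
    for (cv in intersect(cohort_covariate_cols, names(cohort))) {
      if (!all(cohort[[cv]] %in% c(0, 1, NA))) {
        add(paste0(cv, " must be 0/1 (missing tolerated)"))
      }
    }
  }
  if (length(issues)) {
    stop("cohort validation failed:\n",
         paste0("  - ", issues, collapse = "\n"), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a cohort table from delimited text
#'
#' @param path CSV or TSV file with the standard cohort schema; separator
#'   sniffed from the header line. Missing covariate columns are tolerated.
#' @param validate Run [validate_cohort()] on the result (default TRUE).
#' @return A data frame of class `gard_cohort`.
#' @export
read_cohort <- function(path, validate = TRUE) {
  cohort <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                              stringsAsFactors = FALSE, check.names = FALSE)
  if (validate) validate_cohort(cohort)
  class(cohort) <- c("gard_cohort", "data.frame")
  cohort
}

#' Write a cohort table to delimited text
#'
#' @param cohort Cohort data frame.
#' @param path Output path; `.tsv` extension writes tab-separated,
#'   otherwise comma-separated.
#' @return Invisibly `path`.
#' @export
write_cohort <- function(cohort, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(cohort, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
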