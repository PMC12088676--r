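#' @name critical_trial_records
#' @title Critical-trial record schema
#' @description
#' A critical-trial dataset has one row per subject (each subject contributes
#' exactly one critical trial) with the columns:
#'
#' `subject_id, experiment_id, condition, stim_color, stim_shape, stim_side,
#' attended_color, noticed, notice_confidence, color_response, shape_response,
#' side_response, excluded, exclusion_reason`
#'
#' `condition` is `present` or `absent`; `noticed` is `yes` or `no`;
#' `notice_confidence` is an integer 0-3 (designs that collect it) or empty;
#' `stim_side` is `left`/`right`. The empty string means "not applicable":
#' absent-condition rows carry no stimulus features, and responses are empty
#' for questions a design does not ask. `excluded` is `TRUE`/`FALSE` (empty
#' means `FALSE`) and excluded rows must carry an `exclusion_reason`.
NULL

record_columns <- c(
  "subject_id", "experiment_id", "condition", "stim_color", "stim_shape",
  "stim_side", "attended_color", "noticed", "notice_confidence",
  "color_response", "shape_response", "side_response", "excluded",
  "exclusion_reason")

#' Read and validate critical-trial records from CSV
#'
#' @param path Path to a CSV file with the header documented in
#'   [critical_trial_records].
#' @return A data frame of validated records (`excluded` parsed to logical,
#'   `notice_confidence` to integer with `NA` for empty).
#' @seealso [write_records()], [validate_records()]
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = character(0))
  missing_cols <- setdiff(record_columns, names(df))
  if (length(missing_cols)) {
    stop("records file is missing mandatory columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[record_columns]
  if (nrow(df) == 0L) stop("records file contains no rows")
  df$excluded <- parse_flag(df$excluded)
  df$notice_confidence <- suppressWarnings(
    ifelse(df$notice_confidence == "", NA_integer_,
           as.integer(df$notice_confidence)))
  validate_records(df)
}

parse_flag <- function(x) {
  x <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no", "")] <- FALSE
  out
}

#' Validate a critical-trial record data frame
#'
#' Checks the per-row invariants: `condition` in present/absent, `noticed`
#' in yes/no, absent rows carrying no stimulus features, confidence in 0-3
#' when given, and an exclusion reason on every excluded row. All violations
#' are reported together with their row numbers.
#'
#' @param records A data frame with the columns of [critical_trial_records].
#' @return The validated data frame, invisibly unchanged.
#' @export
validate_records <- function(records) {
  missing_cols <- setdiff(record_columns, names(records))
  if (length(missing_cols)) {
    stop("records are missing mandatory columns: ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- list()
  flag_rows <- function(cond, msg) {
    rows <- which(cond)
    if (length(rows)) bad[[length(bad) + 1L]] <<-
        sprintf("%s (rows %s)", msg,
                paste(utils::head(rows, 10L), collapse = ", "))
  }
  flag_rows(!(records$condition %in% c("present", "absent")),
            "condition must be 'present' or 'absent'")
  flag_rows(!(records$noticed %in% c("yes", "no")),
            "noticed must be 'yes' or 'no'")
  absent <- records$condition == "absent"
  flag_rows(absent & (records$stim_color != "" | records$stim_shape != "" |
                        records$stim_side != ""),
            "absent-condition rows must not carry stimulus features")
  flag_rows(records$condition == "present" & records$stim_side != "" &
              !(records$stim_side %in% c("left", "right")),
            "stim_side must be 'left' or 'right'")
  conf <- records$notice_confidence
  flag_rows(!is.na(conf) & (conf < 0L | conf > 3L),
            "notice_confidence must be an integer 0-3")
  flag_rows(is.na(records$excluded),
            "excluded must be TRUE or FALSE")
  flag_rows(!is.na(records$excluded) & records$excluded &
              records$exclusion_reason == "",
            "excluded rows must carry an exclusion_reason")
  if (length(bad)) {
    stop("invalid records:\n  ", paste(unlist(bad), collapse = "\n  "))
  }
  invisible(records)
}

#' Write critical-trial records to CSV
#'
#' Emits exactly the schema of [critical_trial_records] so that files
#' round-trip through [read_records()].
#'
#' @param records A validated record data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  validate_records(records)
  out <- records[record_columns]
  out$excluded <- ifelse(out$excluded, "TRUE", "FALSE")
  out$notice_confidence <- ifelse(is.na(out$notice_confidence), "",
                                  as.character(out$notice_confidence))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Non-excluded records of one experiment; the unit every matrix builder
# works on.
included_records <- function(records) {
  validate_records(records)
  records[!records$excluded, , drop = FALSE]
}
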