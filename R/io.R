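# CSV contracts: one row per round / per subject, UTF-8, header required.

stop_rows <- function(msg, rows) {
  # rows are data rows; +1 converts to file line numbers under the header
  stop(msg, " (line", if (length(rows) > 1) "s", " ",
       paste(utils::head(rows + 1L, 20L), collapse = ", "),
       if (length(rows) > 20) ", ...", ")", call. = FALSE)
}

#' Read a round-level measurement CSV
#'
#' Expected columns: `subject_id, site, population, sex, age, round_index,
#' n1_sbp, n1_dbp, n2_sbp, n2_dbp, dev_status, dev_sbp, dev_dbp` (`site`,
#' `population`, `sex`, `age` optional). Device values may be empty only
#' when `dev_status` is not `"ok"`. Readings are checked against
#' physiological sanity bounds (40 <= DBP < SBP <= 300); violations are
#' reported with their line numbers.
#'
#' @param path CSV file path.
#' @return Data frame of rounds.
#' @export
read_rounds_csv <- function(path) {
  if (!file.exists(path)) stop("rounds file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("rounds file is empty: ", path, call. = FALSE)
  miss <- setdiff(ROUND_COLUMNS, names(df))
  if (length(miss)) {
    stop("rounds file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  num <- c("round_index", "n1_sbp", "n1_dbp", "n2_sbp", "n2_dbp",
           "dev_sbp", "dev_dbp")
  for (col in num) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & df[[col]] != "" & is.na(v))
    if (length(bad)) stop_rows(paste0("non-numeric ", col), bad)
    df[[col]] <- v
  }
  bad_status <- which(!df$dev_status %in% DEVICE_STATUSES)
  if (length(bad_status)) stop_rows("unknown dev_status", bad_status)
  nurse_na <- which(!stats::complete.cases(
    df[c("n1_sbp", "n1_dbp", "n2_sbp", "n2_dbp")]))
  if (length(nurse_na)) stop_rows("missing nurse reading", nurse_na)
  dev_na <- is.na(df$dev_sbp) | is.na(df$dev_dbp)
  bad_dev <- which(df$dev_status == "ok" & dev_na)
  if (length(bad_dev)) {
    stop_rows("dev_status is 'ok' but device values are missing", bad_dev)
  }
  bad_dev2 <- which(df$dev_status != "ok" & !dev_na)
  if (length(bad_dev2)) {
    stop_rows("device values present despite failure status", bad_dev2)
  }
  sane <- function(sbp, dbp) !is.na(sbp) & !is.na(dbp) &
    dbp >= 40 & dbp < sbp & sbp <= 300
  bad_n1 <- which(!sane(df$n1_sbp, df$n1_dbp))
  if (length(bad_n1)) stop_rows("nurse-1 reading outside sanity bounds", bad_n1)
  bad_n2 <- which(!sane(df$n2_sbp, df$n2_dbp))
  if (length(bad_n2)) stop_rows("nurse-2 reading outside sanity bounds", bad_n2)
  bad_ri <- which(is.na(df$round_index) | df$round_index < 1 |
                    df$round_index > 8)
  if (length(bad_ri)) stop_rows("round_index outside 1-8", bad_ri)
  df
}

#' Read a subject-level screening CSV
#'
#' Expected columns: `subject_id`, screening fields (`age`, `arm_diff_sbp`,
#' `arm_diff_dbp`, `resting_sbp`, `resting_dbp`) plus `proteinuria_flag`
#' and `gestational_weeks` for pregnant cohorts.
#'
#' @param path CSV file path.
#' @return Data frame of subject records.
#' @export
read_subjects_csv <- function(path) {
  if (!file.exists(path)) stop("subjects file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("subjects file is empty: ", path, call. = FALSE)
  if (!"subject_id" %in% names(df)) {
    stop("subjects file lacks subject_id", call. = FALSE)
  }
  dup <- which(duplicated(df$subject_id))
  if (length(dup)) stop_rows("duplicated subject_id", dup)
  if ("proteinuria_flag" %in% names(df) &&
      !is.logical(df$proteinuria_flag)) {
    df$proteinuria_flag <- as.logical(df$proteinuria_flag)
  }
  df
}
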