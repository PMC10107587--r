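# End-to-end evaluation and report generation.

#' Evaluate a validation study end to end
#'
#' Runs the full pipeline on round-level (and optionally subject-level)
#' records: eligibility screening, the ordered exclusion cascade, ISO
#' criteria 1 and 2 for SBP and DBP, the sampling audit, and Bland-Altman
#' agreement. Error sign convention throughout is device minus reference.
#'
#' @param rounds Round-level data frame (see [read_rounds_csv()]) or a
#'   `synthetic_study`.
#' @param subjects Optional subject-level data frame; enables screening
#'   and the sex / pregnant-group parts of the audit.
#' @param population `"general"` or `"pregnant"`.
#' @param tolerance,probability Criterion-2 constants.
#' @param table_mode Use the published lookup table for the criterion-2
#'   threshold (see [max_permissible_sd()]).
#' @param min_pairs,max_nurse_diff,sbp_dev_limit,dbp_dev_limit Cascade
#'   parameters, see [run_cascade()].
#' @return Object of class `study_report`: `criterion1` / `criterion2`
#'   (each a list with `sbp` and `dbp` entries), `bland_altman` (idem),
#'   `ledger`, `audit`, `screening`, `metadata` (`n_subjects`,
#'   `n_measurements`, `population`, `status`). When the cascade retains
#'   too little data for the criteria, `metadata$status` is
#'   `"not_evaluable"` and the criterion slots are `NULL`.
#' @examples
#' st <- generate_study(scenario("TZ_general", seed = 11))
#' rep <- evaluate_study(st)
#' rep$criterion1$sbp
#' @export
evaluate_study <- function(rounds, subjects = NULL,
                           population = c("general", "pregnant"),
                           tolerance = 10, probability = 0.85,
                           table_mode = FALSE,
                           min_pairs = 3L, max_nurse_diff = 4,
                           sbp_dev_limit = 12, dbp_dev_limit = 8) {
  if (inherits(rounds, "synthetic_study")) {
    if (is.null(subjects)) subjects <- rounds$subjects
    population <- rounds$config$population
    rounds <- rounds$rounds
  }
  population <- match.arg(population)
  if (is.null(rounds) || !nrow(rounds)) {
    stop("no measurement rounds supplied", call. = FALSE)
  }

  screening <- NULL
  if (!is.null(subjects)) {
    screening <- screen_subject(subjects, population)
    ineligible <- screening$subject_id[!screening$eligible]
    rounds <- rounds[!rounds$subject_id %in% ineligible, , drop = FALSE]
    subjects <- subjects[!subjects$subject_id %in% ineligible, , drop = FALSE]
  }
  if (!nrow(rounds)) {
    stop("no rounds left after eligibility screening", call. = FALSE)
  }

  cc <- run_cascade(rounds, max_nurse_diff = max_nurse_diff,
                    min_pairs = min_pairs, sbp_dev_limit = sbp_dev_limit,
                    dbp_dev_limit = dbp_dev_limit)
  pairs <- cc$pairs

  evaluable <- nrow(pairs) >= 2L && length(unique(pairs$subject_id)) >= 2L
  crit1 <- crit2 <- ba <- NULL
  audit <- NULL
  if (evaluable) {
    err_s <- pairs$device_sbp - pairs$reference_sbp
    err_d <- pairs$device_dbp - pairs$reference_dbp
    crit1 <- list(sbp = criterion1(err_s), dbp = criterion1(err_d))
    crit2 <- list(
      sbp = criterion2(err_s, pairs$subject_id, tolerance = tolerance,
                       probability = probability, table_mode = table_mode,
                       min_pairs = min_pairs),
      dbp = criterion2(err_d, pairs$subject_id, tolerance = tolerance,
                       probability = probability, table_mode = table_mode,
                       min_pairs = min_pairs))
    ba <- list(
      sbp = bland_altman(pairs$device_sbp, pairs$reference_sbp,
                         subject = pairs$subject_id),
      dbp = bland_altman(pairs$device_dbp, pairs$reference_dbp,
                         subject = pairs$subject_id))
    audit <- tryCatch(
      audit_sampling(pairs, subjects, population),
      error = function(e) NULL)
  }

  structure(list(
    criterion1 = crit1, criterion2 = crit2, bland_altman = ba,
    ledger = cc$ledger, audit = audit, screening = screening,
    pairs = pairs,
    metadata = list(population = population,
                    n_subjects = length(unique(pairs$subject_id)),
                    n_measurements = nrow(pairs),
                    status = if (evaluable) "evaluated" else "not_evaluable")),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  md <- x$metadata
  cat("Validation study report (", md$population, " population): N = ",
      md$n_subjects, " subjects, M = ", md$n_measurements,
      " measurements\n", sep = "")
  if (md$status != "evaluated") {
    cat("  status: NOT EVALUABLE (insufficient retained data)\n")
    return(invisible(x))
  }
  fmt_verdict <- function(v) if (v) "(passed)" else "(did not pass)"
  for (arm in c("sbp", "dbp")) {
    c1 <- x$criterion1[[arm]]; c2 <- x$criterion2[[arm]]
    cat(sprintf("  %s criterion 1: mean %.1f %s  SD %.1f %s\n",
                toupper(arm), c1$mean_error,
                fmt_verdict(abs(c1$mean_error) <= c1$mean_limit),
                c1$sd_error, fmt_verdict(c1$sd_error <= c1$sd_limit)))
    cat(sprintf("  %s criterion 2: SD of subject means %.1f <= %.2f  %s\n",
                toupper(arm), c2$sd_between_subjects, c2$permissible_sd,
                fmt_verdict(c2$passed)))
  }
  invisible(x)
}

report_to_list <- function(report) {
  strip <- function(x) {
    if (is.null(x)) return(NULL)
    x <- unclass(x)
    if (is.list(x) && !is.data.frame(x)) lapply(x, strip) else x
  }
  list(
    metadata = report$metadata,
    criterion1 = strip(report$criterion1),
    criterion2 = lapply(report$criterion2, function(c2) {
      if (is.null(c2)) return(NULL)
      c2 <- unclass(c2)
      c2$per_subject_mean_errors <- as.list(c2$per_subject_mean_errors)
      c2
    }),
    bland_altman = lapply(report$bland_altman, function(b) {
      if (is.null(b)) return(NULL)
      b <- unclass(b); b$points <- NULL; b
    }),
    ledger = {
      l <- unclass(report$ledger); l$records <- NULL; l
    },
    audit = if (is.null(report$audit)) NULL else as.data.frame(report$audit))
}

#' Write a study report to disk
#'
#' Emits `report.json` (machine-readable summary), `ledger.json` (full
#' per-record exclusion reasons), `criteria.txt` (human-readable criterion
#' tables in the conventional layout), and Bland-Altman point CSVs per arm.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return Named vector of the files written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(report = file.path(dir, "report.json"),
             ledger = file.path(dir, "ledger.json"),
             criteria = file.path(dir, "criteria.txt"))
  jsonlite::write_json(report_to_list(report), paths[["report"]],
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  jsonlite::write_json(
    c(unclass(report$ledger)["records"],
      list(screening = report$screening)),
    paths[["ledger"]], auto_unbox = TRUE, digits = NA, na = "null",
    pretty = TRUE)
  sink(paths[["criteria"]]); on.exit(sink(), add = TRUE)
  print(report)
  print(report$ledger)
  if (!is.null(report$audit)) print(report$audit)
  sink(); on.exit()
  if (!is.null(report$bland_altman)) {
    for (arm in names(report$bland_altman)) {
      p <- file.path(dir, paste0("bland_altman_", arm, ".csv"))
      write_bland_altman(report$bland_altman[[arm]], p, arm = toupper(arm))
      paths[[paste0("bland_altman_", arm)]] <- p
    }
  }
  invisible(paths)
}

#' Read back a written report
#'
#' Parses `report.json` as written by [write_report()]; numeric content
#' round-trips exactly.
#'
#' @param path Path to `report.json`.
#' @return Nested list mirroring [report_to_list] output.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
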