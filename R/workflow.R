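# Session workflow: reference derivation, round validity, exclusion cascade.

DEVICE_STATUSES <- c("ok", "signal_not_captured", "poor_quality",
                     "irregular_heart_rate", "outlier", "missing")

ROUND_COLUMNS <- c("subject_id", "round_index", "n1_sbp", "n1_dbp",
                   "n2_sbp", "n2_dbp", "dev_status", "dev_sbp", "dev_dbp")

# ---- eligibility screening -----------------------------------------------

#' Default screening caps per population
#'
#' Age range, between-arm difference limits, and resting-BP ceilings used
#' at enrollment: general population 18-80 years and resting BP capped at
#' 180/120 mmHg; pregnant population 18-50 years, capped at 160/110 mmHg;
#' both populations excluded for between-arm differences >15 mmHg systolic
#' or >10 mmHg diastolic.
#'
#' @param population `"general"` or `"pregnant"`.
#' @return List with `age_range`, `arm_diff_limit` (sbp, dbp) and
#'   `resting_cap` (sbp, dbp).
#' @export
screening_caps <- function(population = c("general", "pregnant")) {
  population <- match.arg(population)
  if (population == "pregnant") {
    list(age_range = c(18, 50), arm_diff_limit = c(sbp = 15, dbp = 10),
         resting_cap = c(sbp = 160, dbp = 110))
  } else {
    list(age_range = c(18, 80), arm_diff_limit = c(sbp = 15, dbp = 10),
         resting_cap = c(sbp = 180, dbp = 120))
  }
}

#' Screen subjects for enrollment eligibility
#'
#' Applies the enrollment rules in a fixed order per subject - age range,
#' between-arm BP difference, resting-BP ceiling - and reports the first
#' rule failed. Resting BP exceeds the cap when either arm's reading is
#' strictly above its ceiling.
#'
#' @param subjects Data frame with columns `subject_id`, `age`,
#'   `arm_diff_sbp`, `arm_diff_dbp`, `resting_sbp`, `resting_dbp`.
#' @param population `"general"` or `"pregnant"` (sets the default caps).
#' @param caps Screening caps, see [screening_caps()].
#' @return `subjects` with logical `eligible` and character `reason`
#'   (`NA` when eligible) columns appended.
#' @examples
#' screen_subject(data.frame(subject_id = "s1", age = 40, arm_diff_sbp = 16,
#'                           arm_diff_dbp = 4, resting_sbp = 120,
#'                           resting_dbp = 80))
#' @export
screen_subject <- function(subjects, population = c("general", "pregnant"),
                           caps = screening_caps(population)) {
  population <- match.arg(population)
  need <- c("age", "arm_diff_sbp", "arm_diff_dbp", "resting_sbp", "resting_dbp")
  miss <- setdiff(need, names(subjects))
  if (length(miss)) {
    stop("screening fields missing from subject records: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  incomplete <- !stats::complete.cases(subjects[need])
  if (any(incomplete)) {
    stop("incomplete screening fields for subject(s): ",
         paste(subjects$subject_id[incomplete], collapse = ", "),
         call. = FALSE)
  }
  reason <- rep(NA_character_, nrow(subjects))
  bad_age <- subjects$age < caps$age_range[1] | subjects$age > caps$age_range[2]
  bad_arm <- abs(subjects$arm_diff_sbp) > caps$arm_diff_limit[["sbp"]] |
    abs(subjects$arm_diff_dbp) > caps$arm_diff_limit[["dbp"]]
  bad_rest <- subjects$resting_sbp > caps$resting_cap[["sbp"]] |
    subjects$resting_dbp > caps$resting_cap[["dbp"]]
  reason[is.na(reason) & bad_age] <- "age_range"
  reason[is.na(reason) & bad_arm] <- "arm_difference"
  reason[is.na(reason) & bad_rest] <- "resting_bp_cap"
  subjects$eligible <- is.na(reason)
  subjects$reason <- reason
  subjects
}

# ---- round validation ----------------------------------------------------

#' Validate measurement rounds and derive the auscultatory reference
#'
#' A round yields a valid paired measurement when the device produced a
#' reading (`dev_status == "ok"`) and the two nurses' simultaneous readings
#' agree within `max_nurse_diff` mmHg on both arms; the reference is then
#' the arithmetic mean of the two nurses per arm. Device failure takes
#' precedence in the recorded reason (mirroring the cascade order);
#' `inter_nurse_fail` additionally flags disagreement so that overlap
#' between the two failure modes can be reported.
#'
#' @param rounds Data frame of rounds, one row each, with columns
#'   `subject_id`, `round_index`, `n1_sbp`, `n1_dbp`, `n2_sbp`, `n2_dbp`,
#'   `dev_status`, `dev_sbp`, `dev_dbp`.
#' @param max_nurse_diff Inter-observer agreement limit, mmHg (default 4;
#'   a round with a difference strictly greater is discarded).
#' @return `rounds` with `reference_sbp`, `reference_dbp`, `valid`,
#'   `reason` (`NA` when valid, else `"device_<status>"` or
#'   `"inter_nurse"`) and logical `inter_nurse_fail` appended.
#' @export
validate_round <- function(rounds, max_nurse_diff = 4) {
  miss <- setdiff(ROUND_COLUMNS, names(rounds))
  if (length(miss)) {
    stop("round records lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  nurse_cols <- c("n1_sbp", "n1_dbp", "n2_sbp", "n2_dbp")
  if (anyNA(rounds[nurse_cols])) {
    stop("nurse readings must be present for every round", call. = FALSE)
  }
  bad_status <- !rounds$dev_status %in% DEVICE_STATUSES
  if (any(bad_status)) {
    stop("unknown device status: ",
         paste(unique(rounds$dev_status[bad_status]), collapse = ", "),
         call. = FALSE)
  }
  inter_nurse_fail <- abs(rounds$n1_sbp - rounds$n2_sbp) > max_nurse_diff |
    abs(rounds$n1_dbp - rounds$n2_dbp) > max_nurse_diff
  device_fail <- rounds$dev_status != "ok"
  rounds$reference_sbp <- (rounds$n1_sbp + rounds$n2_sbp) / 2
  rounds$reference_dbp <- (rounds$n1_dbp + rounds$n2_dbp) / 2
  rounds$valid <- !device_fail & !inter_nurse_fail
  reason <- rep(NA_character_, nrow(rounds))
  reason[inter_nurse_fail] <- "inter_nurse"
  reason[device_fail] <- paste0("device_", rounds$dev_status[device_fail])
  rounds$reason <- reason
  rounds$inter_nurse_fail <- inter_nurse_fail
  rounds
}

# ---- stage-4 variability predicate ---------------------------------------

# A subject is flagged when >= min_deviant of their rounds have a reference
# value deviating from the subject median by more than the limit on either
# arm. Isolated here so the interpretation of the protocol's wording can be
# swapped without touching the cascade.
reference_variability_flag <- function(ref_sbp, ref_dbp,
                                       sbp_limit = 12, dbp_limit = 8,
                                       min_deviant = 2L) {
  dev_sbp <- abs(ref_sbp - stats::median(ref_sbp)) > sbp_limit
  dev_dbp <- abs(ref_dbp - stats::median(ref_dbp)) > dbp_limit
  sum(dev_sbp | dev_dbp) >= min_deviant
}

# ---- exclusion cascade ---------------------------------------------------

#' Apply the ordered exclusion cascade
#'
#' Removes measurements and subjects in the fixed protocol order:
#' \enumerate{
#'   \item device failure (any status other than `"ok"`), measurement level;
#'   \item inter-nurse disagreement (difference strictly above
#'     `max_nurse_diff` mmHg on either arm), measurement level;
#'   \item subjects left with fewer than `min_pairs` valid paired
#'     measurements, subject level;
#'   \item subjects whose per-round reference values are excessively
#'     variable: at least two rounds deviating from the subject median by
#'     more than `sbp_dev_limit` mmHg systolic or `dbp_dev_limit` mmHg
#'     diastolic, subject level.
#' }
#' Each removed record carries exactly the first reason that struck it;
#' rounds that fail both the device and the inter-nurse rule are counted
#' under stage 1 and reported separately as overlap.
#'
#' @inheritParams validate_round
#' @param min_pairs Stage-3 minimum valid pairs per subject.
#' @param sbp_dev_limit,dbp_dev_limit Stage-4 deviation limits, mmHg.
#' @return A list of class `cascade_result` with `pairs` (data frame of
#'   retained paired measurements: `subject_id`, `round_index`,
#'   `reference_sbp/dbp`, `device_sbp/dbp`) and `ledger` (class
#'   `exclusion_ledger`; see [print.exclusion_ledger()]).
#' @examples
#' st <- generate_study(generator_config(n_subjects = 12, seed = 1))
#' run_cascade(st$rounds)$ledger
#' @export
run_cascade <- function(rounds, max_nurse_diff = 4, min_pairs = 3L,
                        sbp_dev_limit = 12, dbp_dev_limit = 8) {
  rounds <- validate_round(rounds, max_nurse_diff = max_nurse_diff)
  n_input <- nrow(rounds)
  subjects_in <- unique(rounds$subject_id)
  reason <- rounds$reason                      # stages 1-2 already coded
  overlap <- sum(rounds$dev_status != "ok" & rounds$inter_nurse_fail)

  surv <- is.na(reason)
  # stage 3: whole subjects with < min_pairs surviving pairs
  n_pairs <- table(rounds$subject_id[surv])
  kept_counts <- n_pairs[match(rounds$subject_id, names(n_pairs))]
  kept_counts[is.na(kept_counts)] <- 0L
  few <- surv & kept_counts < min_pairs
  subj_stage3 <- setdiff(subjects_in, rounds$subject_id[surv & !few])
  reason[few] <- "insufficient_pairs"
  surv <- is.na(reason)

  # stage 4: reference-variability rule, whole subjects
  subj_stage4 <- character(0)
  for (sid in unique(rounds$subject_id[surv])) {
    idx <- which(surv & rounds$subject_id == sid)
    if (reference_variability_flag(rounds$reference_sbp[idx],
                                   rounds$reference_dbp[idx],
                                   sbp_limit = sbp_dev_limit,
                                   dbp_limit = dbp_dev_limit)) {
      reason[idx] <- "reference_variability"
      subj_stage4 <- c(subj_stage4, sid)
    }
  }
  surv <- is.na(reason)

  pairs <- rounds[surv, c("subject_id", "round_index",
                          "reference_sbp", "reference_dbp",
                          "dev_sbp", "dev_dbp")]
  names(pairs)[names(pairs) == "dev_sbp"] <- "device_sbp"
  names(pairs)[names(pairs) == "dev_dbp"] <- "device_dbp"
  rownames(pairs) <- NULL

  stage_of <- function(r) {
    ifelse(startsWith(r, "device_"), "device_failure",
           ifelse(r == "inter_nurse", "inter_nurse", r))
  }
  excluded <- !surv
  m_stages <- c(device_failure = sum(excluded & startsWith(reason, "device_")),
                inter_nurse = sum(excluded & reason == "inter_nurse"),
                insufficient_pairs = sum(excluded & reason == "insufficient_pairs"),
                reference_variability = sum(excluded & reason == "reference_variability"))
  retained_subjects <- unique(pairs$subject_id)
  ledger <- structure(
    list(measurement = data.frame(
           stage = names(m_stages), n_excluded = as.integer(m_stages),
           row.names = NULL),
         subject = data.frame(
           stage = c("insufficient_pairs", "reference_variability"),
           n_excluded = c(length(subj_stage3), length(subj_stage4)),
           row.names = NULL),
         n_input_measurements = n_input,
         n_retained_measurements = nrow(pairs),
         n_input_subjects = length(subjects_in),
         n_retained_subjects = length(retained_subjects),
         device_inter_nurse_overlap = overlap,
         records = data.frame(subject_id = rounds$subject_id,
                              round_index = rounds$round_index,
                              reason = reason, row.names = NULL)),
    class = "exclusion_ledger")
  structure(list(pairs = pairs, ledger = ledger), class = "cascade_result")
}

#' Percentage share of an exclusion tally
#'
#' The convention used in study reports: `100 * count / total`, rounded to
#' one decimal (466 of 1144 excluded measurements is 40.7).
#'
#' @param count,total Non-negative counts; `total > 0`.
#' @return Percentage rounded to 1 decimal.
#' @examples
#' exclusion_share(466, 1144)
#' @export
exclusion_share <- function(count, total) {
  stopifnot(is.numeric(count), is.numeric(total), all(total > 0),
            all(count >= 0))
  round(100 * count / total, 1)
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat("Exclusion cascade:", x$n_input_measurements, "measurements from",
      x$n_input_subjects, "subjects\n")
  tot_excl <- x$n_input_measurements - x$n_retained_measurements
  for (i in seq_len(nrow(x$measurement))) {
    n <- x$measurement$n_excluded[i]
    pct <- if (tot_excl > 0) sprintf(" (%.1f%% of excluded)",
                                     exclusion_share(n, tot_excl)) else ""
    cat(sprintf("  %-22s %5d%s\n", x$measurement$stage[i], n, pct))
  }
  cat("  retained:", x$n_retained_measurements, "measurements,",
      x$n_retained_subjects, "subjects\n")
  if (x$device_inter_nurse_overlap > 0) {
    cat("  device-failure rounds also failing inter-nurse agreement:",
        x$device_inter_nurse_overlap, "\n")
  }
  invisible(x)
}
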