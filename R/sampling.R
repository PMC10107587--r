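# Sampling-distribution requirements of the consensus protocol.

#' Sampling requirements for a validation study
#'
#' The analytical-sample composition the consensus protocol demands.
#' General population: at least 85 subjects; at least 30% of each sex;
#' reference systolic distribution with >=5% of measurements <=100 mmHg,
#' >=5% >=160 mmHg and >=20% >=140 mmHg; diastolic with >=5% <=60 mmHg,
#' >=5% >=100 mmHg and >=20% >=85 mmHg. Pregnant population: at least 45
#' subjects, and at least 20 subjects in each of the normotensive,
#' hypertensive-without-proteinuria and pre-eclampsia groups.
#'
#' @param population `"general"` or `"pregnant"`.
#' @return A list describing each requirement (used by [audit_sampling()]).
#' @export
sampling_requirements <- function(population = c("general", "pregnant")) {
  population <- match.arg(population)
  if (population == "general") {
    list(population = "general",
         min_subjects = 85,
         min_sex_fraction = 0.30,
         sbp_bands = list(
           list(name = "sbp_le_100", op = "<=", cut = 100, min_fraction = 0.05),
           list(name = "sbp_ge_160", op = ">=", cut = 160, min_fraction = 0.05),
           list(name = "sbp_ge_140", op = ">=", cut = 140, min_fraction = 0.20)),
         dbp_bands = list(
           list(name = "dbp_le_60", op = "<=", cut = 60, min_fraction = 0.05),
           list(name = "dbp_ge_100", op = ">=", cut = 100, min_fraction = 0.05),
           list(name = "dbp_ge_85", op = ">=", cut = 85, min_fraction = 0.20)))
  } else {
    list(population = "pregnant",
         min_subjects = 45,
         min_group_n = 20,
         groups = c("normotensive", "hypertensive_no_proteinuria",
                    "pre_eclampsia"))
  }
}

#' Classify pregnant subjects by hypertensive status at enrollment
#'
#' Normotensive when SBP < 140 and DBP < 90 mmHg; otherwise pre-eclampsia
#' when the proteinuria flag is set (proteinuria > 300 mg/24 h), else
#' hypertensive without proteinuria.
#'
#' @param sbp,dbp Enrollment BP, mmHg (vectorized).
#' @param proteinuria Logical flag, same length.
#' @return Factor with levels `normotensive`,
#'   `hypertensive_no_proteinuria`, `pre_eclampsia`.
#' @examples
#' classify_pregnant(c(139, 150, 140), c(89, 95, 85), c(FALSE, TRUE, FALSE))
#' @export
classify_pregnant <- function(sbp, dbp, proteinuria) {
  if (anyNA(sbp) || anyNA(dbp)) {
    stop("enrollment BP required to classify pregnant subjects", call. = FALSE)
  }
  if (anyNA(proteinuria)) {
    stop("proteinuria flag required to classify pregnant subjects",
         call. = FALSE)
  }
  hyper <- sbp >= 140 | dbp >= 90
  out <- ifelse(!hyper, "normotensive",
                ifelse(proteinuria, "pre_eclampsia",
                       "hypertensive_no_proteinuria"))
  factor(out, levels = c("normotensive", "hypertensive_no_proteinuria",
                         "pre_eclampsia"))
}

#' Audit a dataset against the sampling requirements
#'
#' For general populations, band fractions are computed over the reference
#' values of the retained paired measurements and sex fractions over the
#' retained subjects. For pregnant populations, subjects are classified at
#' enrollment (resting BP + proteinuria flag) and group minima are checked.
#'
#' @param pairs Retained paired measurements (from [run_cascade()]); needs
#'   `subject_id`, `reference_sbp`, `reference_dbp`. May be `NULL` for
#'   pregnant audits.
#' @param subjects Subject records; general audits use `sex` (`"male"` /
#'   `"female"`, `NA` allowed), pregnant audits use `resting_sbp`,
#'   `resting_dbp`, `proteinuria_flag`.
#' @param population `"general"` or `"pregnant"`.
#' @param requirements Requirement set, see [sampling_requirements()].
#' @return Data frame of class `sampling_audit`: one row per requirement
#'   with `requirement`, `observed` (count or fraction), `observed_percent`
#'   (1 decimal, `NA` for count requirements), `bound`, `unit`, `passed`.
#' @examples
#' st <- generate_study(scenario("TZ_general", seed = 1))
#' cc <- run_cascade(st$rounds)
#' audit_sampling(cc$pairs, st$subjects, "general")
#' @export
audit_sampling <- function(pairs, subjects = NULL,
                           population = c("general", "pregnant"),
                           requirements = sampling_requirements(population)) {
  population <- match.arg(population)
  rows <- list()
  add <- function(name, observed, bound, unit, passed, percent = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      requirement = name, observed = observed, observed_percent = percent,
      bound = bound, unit = unit, passed = passed, row.names = NULL)
  }
  if (population == "general") {
    if (is.null(pairs) || !nrow(pairs)) {
      stop("general-population audit needs retained paired measurements",
           call. = FALSE)
    }
    n_subj <- length(unique(pairs$subject_id))
    add("min_subjects", n_subj, requirements$min_subjects, "count",
        n_subj >= requirements$min_subjects)
    if (!is.null(subjects) && "sex" %in% names(subjects)) {
      retained <- subjects[subjects$subject_id %in% pairs$subject_id, ]
      sex <- retained$sex[!is.na(retained$sex)]
      for (s in c("male", "female")) {
        frac <- if (length(sex)) mean(sex == s) else NA_real_
        add(paste0("sex_", s), frac, requirements$min_sex_fraction,
            "fraction", isTRUE(frac >= requirements$min_sex_fraction),
            percent = round(100 * frac, 1))
      }
    }
    band_rows <- function(values, bands) {
      for (b in bands) {
        inside <- if (b$op == "<=") values <= b$cut else values >= b$cut
        frac <- mean(inside)
        add(b$name, frac, b$min_fraction, "fraction of measurements",
            frac >= b$min_fraction, percent = exclusion_share(sum(inside),
                                                              length(values)))
      }
    }
    band_rows(pairs$reference_sbp, requirements$sbp_bands)
    band_rows(pairs$reference_dbp, requirements$dbp_bands)
  } else {
    if (is.null(subjects) || !nrow(subjects)) {
      stop("pregnant-population audit needs subject records", call. = FALSE)
    }
    if (!"proteinuria_flag" %in% names(subjects) ||
        anyNA(subjects$proteinuria_flag)) {
      stop("pregnant-population audit needs proteinuria flags for every subject",
           call. = FALSE)
    }
    if (!is.null(pairs) && nrow(pairs)) {
      subjects <- subjects[subjects$subject_id %in% pairs$subject_id, ]
    }
    add("min_subjects", nrow(subjects), requirements$min_subjects, "count",
        nrow(subjects) >= requirements$min_subjects)
    grp <- classify_pregnant(subjects$resting_sbp, subjects$resting_dbp,
                             subjects$proteinuria_flag)
    counts <- table(grp)
    for (g in requirements$groups) {
      n <- as.integer(counts[[g]])
      add(paste0("group_", g), n, requirements$min_group_n, "count",
          n >= requirements$min_group_n,
          percent = exclusion_share(n, nrow(subjects)))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sampling_audit", class(out))
  out
}

#' @export
print.sampling_audit <- function(x, ...) {
  cat("Sampling audit\n")
  for (i in seq_len(nrow(x))) {
    obs <- if (!is.na(x$observed_percent[i]) && x$unit[i] != "count") {
      sprintf("%.1f%%", x$observed_percent[i])
    } else sprintf("%g", x$observed[i])
    bound <- if (x$unit[i] == "count") sprintf(">= %g", x$bound[i])
      else sprintf(">= %.0f%%", 100 * x$bound[i])
    cat(sprintf("  %-22s observed %-8s required %-8s %s\n", x$requirement[i],
                obs, bound, if (x$passed[i]) "passed" else "FAILED"))
  }
  invisible(x)
}
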