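# Bland-Altman agreement and observer qualification.

#' Bland-Altman agreement analysis
#'
#' Computes per-pair means and differences (device minus reference), the
#' bias (mean difference) and the 95% limits of agreement
#' `bias +/- 1.96 * SD(differences)` (sample SD, n-1 denominator). The
#' bias is by construction identical to the criterion-1 mean error on the
#' same pairs. Repeated measurements per subject are pooled as the study
#' reports do; set `per_subject = TRUE` to average within subject first.
#'
#' @param device,reference Numeric vectors of paired readings, mmHg.
#' @param subject Optional subject identifiers (required for
#'   `per_subject = TRUE`; otherwise carried into the point export).
#' @param per_subject Average each subject's pairs before the analysis.
#' @return Object of class `bland_altman_result`: `points` (data frame
#'   with `pair_mean`, `pair_diff`, `subject_id`), `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`.
#' @examples
#' ba <- bland_altman(device = c(118, 124, 122), reference = c(120, 124, 120))
#' ba$bias
#' @export
bland_altman <- function(device, reference, subject = NULL,
                         per_subject = FALSE) {
  stopifnot(is.numeric(device), is.numeric(reference),
            length(device) == length(reference))
  if (length(device) < 2L) {
    stop("Bland-Altman analysis needs at least 2 pairs", call. = FALSE)
  }
  if (anyNA(device) || anyNA(reference)) {
    stop("paired readings must be complete", call. = FALSE)
  }
  if (is.null(subject)) {
    if (per_subject) stop("per_subject = TRUE requires subject identifiers",
                          call. = FALSE)
    subject <- rep(NA_character_, length(device))
  }
  if (per_subject) {
    device <- tapply(device, subject, mean)
    reference <- tapply(reference, subject, mean)
    subject <- names(device)
    device <- as.numeric(device); reference <- as.numeric(reference)
  }
  diffs <- device - reference
  means <- (device + reference) / 2
  bias <- mean(diffs)
  s <- stats::sd(diffs)
  structure(
    list(points = data.frame(pair_mean = means, pair_diff = diffs,
                             subject_id = as.character(subject),
                             row.names = NULL),
         bias = bias, sd_diff = s,
         loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
         n = length(diffs)),
    class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.2f mmHg, LoA [%.2f, %.2f]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Export Bland-Altman points for plotting
#'
#' Writes the (mean, difference) scatter underlying a Bland-Altman plot as
#' CSV with columns `pair_mean`, `pair_diff`, `subject_id`, `arm`.
#'
#' @param x A `bland_altman_result`.
#' @param path Output CSV path.
#' @param arm Label (`"SBP"` or `"DBP"`) recorded with every point.
#' @return `path`, invisibly.
#' @export
write_bland_altman <- function(x, path, arm = "SBP") {
  stopifnot(inherits(x, "bland_altman_result"))
  pts <- x$points
  pts$arm <- arm
  utils::write.csv(pts, path, row.names = FALSE)
  invisible(path)
}

#' Observer qualification from practice measurements
#'
#' Before data collection each nurse pair must demonstrate inter-rater
#' reliability on exactly 50 practice measurements: SBP and DBP differences
#' both within 5 mmHg on at least 45, and both within 10 mmHg on at least
#' 48. Tolerances are inclusive.
#'
#' @param n1_sbp,n1_dbp,n2_sbp,n2_dbp Numeric vectors of length 50: the two
#'   observers' simultaneous practice readings.
#' @return Object of class `observer_qualification`: `n_practice`,
#'   `n_within_5`, `n_within_10`, `passed`.
#' @examples
#' qualify_observers(rep(120, 50), rep(80, 50), rep(120, 50), rep(80, 50))
#' @export
qualify_observers <- function(n1_sbp, n1_dbp, n2_sbp, n2_dbp) {
  n <- length(n1_sbp)
  if (n != 50L || length(n1_dbp) != 50L || length(n2_sbp) != 50L ||
      length(n2_dbp) != 50L) {
    stop("observer qualification requires exactly 50 practice measurements",
         call. = FALSE)
  }
  ds <- abs(n1_sbp - n2_sbp)
  dd <- abs(n1_dbp - n2_dbp)
  w5 <- sum(ds <= 5 & dd <= 5)
  w10 <- sum(ds <= 10 & dd <= 10)
  structure(
    list(n_practice = n, n_within_5 = w5, n_within_10 = w10,
         passed = (w5 >= 45L && w10 >= 48L)),
    class = "observer_qualification")
}

#' @export
print.observer_qualification <- function(x, ...) {
  cat(sprintf("Observer qualification: %d/50 within 5 mmHg (need 45), %d/50 within 10 mmHg (need 48): %s\n",
              x$n_within_5, x$n_within_10,
              if (x$passed) "qualified" else "not qualified"))
  invisible(x)
}
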