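# Synthetic validation studies with the error structure the analysis
# assumes: per-subject true BP from a mixture, a shared auscultatory signal
# per round, independent quantized observer errors, and a device model with
# calibration anchoring, per-subject bias and within-subject noise.

quantize <- function(x, gradation) {
  if (is.null(gradation) || gradation <= 0) return(x)
  round(x / gradation) * gradation
}

#' Bivariate blood-pressure mixture specification
#'
#' Each component is a bivariate normal over (SBP, DBP) with a common
#' within-component correlation; components carry an optional probability
#' of proteinuria (pregnant populations).
#'
#' @param weights Component weights (must sum to 1; at least one positive).
#' @param sbp_mean,sbp_sd,dbp_mean,dbp_sd Component parameters, mmHg.
#' @param correlation Within-component SBP-DBP correlation.
#' @param proteinuria_prob Per-component probability of proteinuria.
#' @return Object of class `bp_mixture`.
#' @export
bp_mixture <- function(weights, sbp_mean, sbp_sd, dbp_mean, dbp_sd,
                       correlation = 0.6, proteinuria_prob = 0) {
  k <- length(weights)
  stopifnot(k >= 1L, length(sbp_mean) == k, length(sbp_sd) == k,
            length(dbp_mean) == k, length(dbp_sd) == k,
            all(sbp_sd >= 0), all(dbp_sd >= 0),
            correlation > -1, correlation < 1)
  if (length(proteinuria_prob) == 1L) proteinuria_prob <- rep(proteinuria_prob, k)
  stopifnot(length(proteinuria_prob) == k,
            all(proteinuria_prob >= 0), all(proteinuria_prob <= 1))
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("mixture weights must be non-negative with positive total",
         call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("mixture weights must sum to 1", call. = FALSE)
  }
  structure(list(weights = weights, sbp_mean = sbp_mean, sbp_sd = sbp_sd,
                 dbp_mean = dbp_mean, dbp_sd = dbp_sd,
                 correlation = correlation,
                 proteinuria_prob = proteinuria_prob),
            class = "bp_mixture")
}

draw_mixture <- function(mix, n) {
  comp <- sample.int(length(mix$weights), n, replace = TRUE,
                     prob = mix$weights)
  z1 <- stats::rnorm(n)
  z2 <- mix$correlation * z1 +
    sqrt(1 - mix$correlation^2) * stats::rnorm(n)
  data.frame(
    sbp = mix$sbp_mean[comp] + mix$sbp_sd[comp] * z1,
    dbp = mix$dbp_mean[comp] + mix$dbp_sd[comp] * z2,
    component = comp,
    proteinuria = stats::runif(n) < mix$proteinuria_prob[comp])
}

default_failure_mixture <- function() {
  # reported shares of unsuccessful readings; they total 99.3% as printed,
  # so they are renormalized to a proper mixture
  x <- c(signal_not_captured = 0.638, poor_quality = 0.190,
         irregular_heart_rate = 0.103, outlier = 0.021, missing = 0.041)
  x / sum(x)
}

as_arm_pair <- function(x, name) {
  if (length(x) == 1L) x <- c(sbp = unname(x), dbp = unname(x))
  if (is.null(names(x))) names(x) <- c("sbp", "dbp")
  stopifnot(length(x) == 2L, all(c("sbp", "dbp") %in% names(x)))
  if (!is.finite(x[["sbp"]]) || !is.finite(x[["dbp"]])) {
    stop(name, " must be finite", call. = FALSE)
  }
  x[c("sbp", "dbp")]
}

#' Configuration for a synthetic validation study
#'
#' Parameterizes every source of structure and noise the simulator knows
#' about. The measurement model per round is: latent auscultatory signal =
#' subject truth + N(0, `round_bp_sd`^2) shared by both observers and the
#' device; each nurse reads signal + N(0, `observer_error_sd`^2 +
#' `inter_nurse_extra_sd`^2) quantized to `reading_gradation`; the device,
#' when it produces a reading, reports
#' `calibration_anchor_weight * calibration_reference +
#' (1 - weight) * signal + subject_bias + N(0, device_within_subject_sd^2)`
#' with `subject_bias ~ N(device_bias, device_between_subject_sd^2)`.
#' Device failures occur independently per round with probability
#' `failure_probability * cold_weather_multiplier` (capped at 1) and draw
#' their status from `failure_mixture`.
#'
#' @param n_subjects Number of enrolled subjects.
#' @param population `"general"` or `"pregnant"`.
#' @param site_label Free-text site tag carried into the CSVs.
#' @param mixture A [bp_mixture()] for the true (SBP, DBP) distribution.
#' @param observer_error_sd,inter_nurse_extra_sd Independent per-nurse
#'   reading error components, mmHg.
#' @param round_bp_sd Round-to-round fluctuation of the latent signal, mmHg.
#' @param reading_gradation Cuff scale gradation for nurse readings, mmHg
#'   (0 disables quantization).
#' @param device_bias,device_between_subject_sd,device_within_subject_sd
#'   Device error decomposition, mmHg; scalars or named
#'   `c(sbp=, dbp=)` pairs.
#' @param calibration_anchor_weight Weight of the one-time cuff calibration
#'   value in the device output, in \[0, 1\].
#' @param failure_probability Per-round device failure probability.
#' @param failure_mixture Named fractions over the failure statuses
#'   (defaults to the pooled shares reported across the study sites).
#' @param cold_weather_multiplier Scalar inflation of the failure
#'   probability (cold-finger effect).
#' @param female_fraction Fraction of female subjects (pregnant
#'   populations are all female).
#' @param min_valid_rounds,max_rounds Session workflow bounds: rounds are
#'   repeated until `min_valid_rounds` valid paired readings or
#'   `max_rounds` attempts.
#' @param seed Integer RNG seed; required by [generate_study()].
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 100,
                             population = c("general", "pregnant"),
                             site_label = "SIM",
                             mixture = NULL,
                             observer_error_sd = 1.5,
                             inter_nurse_extra_sd = 0.8,
                             round_bp_sd = 2,
                             reading_gradation = 2,
                             device_bias = 0,
                             device_between_subject_sd = 3,
                             device_within_subject_sd = 4,
                             calibration_anchor_weight = 0.5,
                             failure_probability = 0.15,
                             failure_mixture = default_failure_mixture(),
                             cold_weather_multiplier = 1,
                             female_fraction = 0.55,
                             min_valid_rounds = 4L,
                             max_rounds = 8L,
                             seed = NULL) {
  population <- match.arg(population)
  if (is.null(mixture)) {
    mixture <- bp_mixture(weights = c(0.10, 0.65, 0.25),
                          sbp_mean = c(94, 119, 150), sbp_sd = c(7, 11, 13),
                          dbp_mean = c(58, 76, 95), dbp_sd = c(6, 8, 9))
  }
  stopifnot(inherits(mixture, "bp_mixture"),
            n_subjects >= 1, observer_error_sd >= 0,
            inter_nurse_extra_sd >= 0, round_bp_sd >= 0,
            reading_gradation >= 0,
            calibration_anchor_weight >= 0, calibration_anchor_weight <= 1,
            failure_probability >= 0, failure_probability <= 1,
            cold_weather_multiplier >= 0,
            female_fraction >= 0, female_fraction <= 1,
            min_valid_rounds >= 1, max_rounds >= min_valid_rounds)
  if (any(failure_mixture < 0) || abs(sum(failure_mixture) - 1) > 1e-8) {
    stop("failure_mixture must be non-negative fractions summing to 1",
         call. = FALSE)
  }
  if (!all(names(failure_mixture) %in% setdiff(DEVICE_STATUSES, "ok"))) {
    stop("failure_mixture names must be device failure statuses",
         call. = FALSE)
  }
  structure(list(
    n_subjects = as.integer(n_subjects), population = population,
    site_label = site_label, mixture = mixture,
    observer_error_sd = observer_error_sd,
    inter_nurse_extra_sd = inter_nurse_extra_sd,
    round_bp_sd = round_bp_sd, reading_gradation = reading_gradation,
    device_bias = as_arm_pair(device_bias, "device_bias"),
    device_between_subject_sd = as_arm_pair(device_between_subject_sd,
                                            "device_between_subject_sd"),
    device_within_subject_sd = as_arm_pair(device_within_subject_sd,
                                           "device_within_subject_sd"),
    calibration_anchor_weight = calibration_anchor_weight,
    failure_probability = failure_probability,
    failure_mixture = failure_mixture,
    cold_weather_multiplier = cold_weather_multiplier,
    female_fraction = if (population == "pregnant") 1 else female_fraction,
    min_valid_rounds = as.integer(min_valid_rounds),
    max_rounds = as.integer(max_rounds),
    seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "generator_config")
}

#' Generate a synthetic validation study
#'
#' Draws a full study - subject records, calibration attempts, and up to
#' `max_rounds` validation rounds per subject - under the measurement model
#' described in [generator_config()]. Calibration follows the session
#' workflow: up to 6 device attempts for 2 valid readings; a subject whose
#' calibration never succeeds yields no device readings in the validation
#' rounds (all statuses `signal_not_captured`). Rounds stop as soon as
#' `min_valid_rounds` valid paired readings are collected. Output is
#' bit-identical for a given seed.
#'
#' @param config A [generator_config()] with a non-`NULL` `seed`.
#' @return Object of class `synthetic_study`: `subjects`, `rounds` (in the
#'   round-level CSV layout), `calibration` (per-subject attempts and
#'   anchor values) and `ground_truth` (true BP and realized device bias
#'   per subject).
#' @examples
#' st <- generate_study(generator_config(n_subjects = 5, seed = 42))
#' head(st$rounds)
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(config$seed)) {
    stop("generator_config must carry an integer seed for reproducibility",
         call. = FALSE)
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  n <- config$n_subjects
  g <- config$reading_gradation
  nurse_sd <- sqrt(config$observer_error_sd^2 + config$inter_nurse_extra_sd^2)
  p_fail <- min(1, config$failure_probability * config$cold_weather_multiplier)
  w <- config$calibration_anchor_weight
  kmax <- config$max_rounds

  truth <- draw_mixture(config$mixture, n)
  truth$sbp <- quantize(truth$sbp, g)
  truth$dbp <- quantize(truth$dbp, g)

  subject_id <- sprintf("%s-%04d", config$site_label, seq_len(n))
  sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
  age <- if (config$population == "pregnant") {
    round(stats::runif(n, 19, 45))
  } else round(stats::runif(n, 20, 79))
  subjects <- data.frame(
    subject_id = subject_id, site = config$site_label,
    population = config$population, sex = sex, age = age,
    arm_diff_sbp = round(abs(stats::rnorm(n, 0, 5))),
    arm_diff_dbp = round(abs(stats::rnorm(n, 0, 3))),
    resting_sbp = quantize(truth$sbp + stats::rnorm(n, 0, 2), 2),
    resting_dbp = quantize(truth$dbp + stats::rnorm(n, 0, 2), 2),
    proteinuria_flag = if (config$population == "pregnant") truth$proteinuria
      else NA,
    gestational_weeks = if (config$population == "pregnant")
      round(stats::runif(n, 13, 40)) else NA_real_,
    row.names = NULL)

  bias_sbp <- stats::rnorm(n, config$device_bias[["sbp"]],
                           config$device_between_subject_sd[["sbp"]])
  bias_dbp <- stats::rnorm(n, config$device_bias[["dbp"]],
                           config$device_between_subject_sd[["dbp"]])

  # calibration round: nurse cuff value anchors the device; up to 6 device
  # attempts for 2 valid readings
  cal_signal_sbp <- truth$sbp + stats::rnorm(n, 0, config$round_bp_sd)
  cal_signal_dbp <- truth$dbp + stats::rnorm(n, 0, config$round_bp_sd)
  cal_n1s <- quantize(cal_signal_sbp + stats::rnorm(n, 0, nurse_sd), g)
  cal_n2s <- quantize(cal_signal_sbp + stats::rnorm(n, 0, nurse_sd), g)
  cal_n1d <- quantize(cal_signal_dbp + stats::rnorm(n, 0, nurse_sd), g)
  cal_n2d <- quantize(cal_signal_dbp + stats::rnorm(n, 0, nurse_sd), g)
  calib_sbp <- (cal_n1s + cal_n2s) / 2
  calib_dbp <- (cal_n1d + cal_n2d) / 2
  cal_ok <- matrix(stats::runif(n * 6L) >= p_fail, n, 6L)
  cal_successes <- rowSums(cal_ok)
  cal_attempts <- apply(cal_ok, 1L, function(r) {
    pos <- which(cumsum(r) == 2L)
    if (length(pos)) pos[1L] else 6L
  })
  calibrated <- cal_successes >= 2L

  # validation rounds, generated for all kmax attempts then truncated at
  # the attempt where min_valid_rounds valid pairs have been collected
  m <- n * kmax
  sig_s <- truth$sbp + stats::rnorm(m, 0, config$round_bp_sd)
  sig_d <- truth$dbp + stats::rnorm(m, 0, config$round_bp_sd)
  n1s <- quantize(sig_s + stats::rnorm(m, 0, nurse_sd), g)
  n2s <- quantize(sig_s + stats::rnorm(m, 0, nurse_sd), g)
  n1d <- quantize(sig_d + stats::rnorm(m, 0, nurse_sd), g)
  n2d <- quantize(sig_d + stats::rnorm(m, 0, nurse_sd), g)
  fail <- stats::runif(m) < p_fail
  fail <- fail | rep(!calibrated, times = kmax)
  status <- rep("ok", m)
  if (any(fail)) {
    pool <- names(config$failure_mixture)[config$failure_mixture > 0]
    probs <- config$failure_mixture[config$failure_mixture > 0]
    drawn <- pool[sample.int(length(pool), sum(fail), replace = TRUE,
                             prob = probs)]
    # a never-calibrated device cannot even start a capture
    drawn[rep(!calibrated, times = kmax)[fail]] <- "signal_not_captured"
    status[fail] <- drawn
  }
  dev_s <- round(w * rep(calib_sbp, times = kmax) + (1 - w) * sig_s +
                   rep(bias_sbp, times = kmax) +
                   stats::rnorm(m, 0, config$device_within_subject_sd[["sbp"]]), 1)
  dev_d <- round(w * rep(calib_dbp, times = kmax) + (1 - w) * sig_d +
                   rep(bias_dbp, times = kmax) +
                   stats::rnorm(m, 0, config$device_within_subject_sd[["dbp"]]), 1)
  dev_s[fail] <- NA_real_
  dev_d[fail] <- NA_real_

  valid <- matrix(!fail &
                    abs(n1s - n2s) <= 4 & abs(n1d - n2d) <= 4, n, kmax)
  cum_valid <- t(apply(valid, 1L, cumsum))
  attempted <- apply(cum_valid, 1L, function(cv) {
    pos <- which(cv >= config$min_valid_rounds)
    if (length(pos)) pos[1L] else kmax
  })
  attempted <- pmax(attempted, min(config$min_valid_rounds, kmax))

  keep <- as.vector(vapply(seq_len(kmax), function(j) attempted >= j,
                           logical(n)))
  ridx <- rep(seq_len(kmax), each = n)
  rounds <- data.frame(
    subject_id = rep(subject_id, times = kmax)[keep],
    site = config$site_label, population = config$population,
    sex = rep(sex, times = kmax)[keep], age = rep(age, times = kmax)[keep],
    round_index = ridx[keep],
    n1_sbp = n1s[keep], n1_dbp = n1d[keep],
    n2_sbp = n2s[keep], n2_dbp = n2d[keep],
    dev_status = status[keep], dev_sbp = dev_s[keep], dev_dbp = dev_d[keep],
    row.names = NULL)
  rounds <- rounds[order(rounds$subject_id, rounds$round_index), ]
  rownames(rounds) <- NULL

  structure(list(
    subjects = subjects,
    rounds = rounds,
    calibration = data.frame(subject_id = subject_id,
                             calib_sbp = calib_sbp, calib_dbp = calib_dbp,
                             attempts = cal_attempts, calibrated = calibrated,
                             row.names = NULL),
    ground_truth = data.frame(subject_id = subject_id,
                              true_sbp = truth$sbp, true_dbp = truth$dbp,
                              device_bias_sbp = bias_sbp,
                              device_bias_dbp = bias_dbp,
                              row.names = NULL),
    config = config), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic validation study:", x$config$n_subjects, "subjects,",
      nrow(x$rounds), "rounds (", x$config$population, "population, site",
      x$config$site_label, ")\n")
  invisible(x)
}

#' Write a synthetic study to CSV files
#'
#' Emits `rounds.csv` and `subjects.csv` in the layout the evaluation
#' pipeline reads, plus `ground_truth.csv` for test harnesses.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(rounds = file.path(dir, "rounds.csv"),
             subjects = file.path(dir, "subjects.csv"),
             ground_truth = file.path(dir, "ground_truth.csv"))
  utils::write.csv(study$rounds, paths[["rounds"]], row.names = FALSE)
  utils::write.csv(study$subjects, paths[["subjects"]], row.names = FALSE)
  utils::write.csv(study$ground_truth, paths[["ground_truth"]],
                   row.names = FALSE)
  invisible(paths)
}
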