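test_that("the generator is reproducible and seed-sensitive", {
  cfg <- generator_config(n_subjects = 10, seed = 123)
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a$rounds, b$rounds)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- generate_study(generator_config(n_subjects = 10, seed = 124))
  expect_false(identical(a$rounds, c$rounds))
  expect_error(generate_study(generator_config(n_subjects = 10)), "seed")
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(77)
  x1 <- rnorm(3)
  set.seed(77)
  invisible(generate_study(generator_config(n_subjects = 5, seed = 1)))
  x2 <- rnorm(3)
  expect_identical(x1, x2)
})

test_that("with all noise off the device, reference and truth coincide", {
  cfg <- generator_config(n_subjects = 20, observer_error_sd = 0,
                          inter_nurse_extra_sd = 0, round_bp_sd = 0,
                          device_bias = 0, device_between_subject_sd = 0,
                          device_within_subject_sd = 0,
                          failure_probability = 0, seed = 5)
  st <- generate_study(cfg)
  cc <- run_cascade(st$rounds)
  expect_equal(sum(cc$ledger$measurement$n_excluded), 0L)
  truth <- st$ground_truth$true_sbp[match(cc$pairs$subject_id,
                                          st$ground_truth$subject_id)]
  expect_equal(cc$pairs$reference_sbp, truth)
  expect_equal(cc$pairs$device_sbp, truth)
  rep <- evaluate_study(st)
  expect_equal(rep$criterion1$sbp$mean_error, 0)
  expect_true(rep$criterion1$sbp$passed)
  expect_true(rep$criterion2$dbp$passed)
})

test_that("zero observer noise produces no inter-nurse exclusions", {
  cfg <- generator_config(n_subjects = 30, observer_error_sd = 0,
                          inter_nurse_extra_sd = 0, seed = 9)
  cc <- run_cascade(generate_study(cfg)$rounds)
  m <- cc$ledger$measurement
  expect_equal(m$n_excluded[m$stage == "inter_nurse"], 0L)
})

test_that("total device failure yields a gracefully non-evaluable study", {
  cfg <- generator_config(n_subjects = 10, failure_probability = 1, seed = 2)
  st <- generate_study(cfg)
  expect_true(all(st$rounds$dev_status != "ok"))
  rep <- evaluate_study(st)
  expect_equal(rep$metadata$status, "not_evaluable")
  expect_null(rep$criterion1)
  expect_equal(rep$metadata$n_measurements, 0L)
})

test_that("inter-nurse exclusions grow with the extra observer noise", {
  counts <- vapply(c(0, 2, 4), function(extra) {
    total <- 0L
    for (s in 1:4) {
      cfg <- generator_config(n_subjects = 40, inter_nurse_extra_sd = extra,
                              failure_probability = 0, seed = 300 + s)
      m <- run_cascade(generate_study(cfg)$rounds)$ledger$measurement
      total <- total + m$n_excluded[m$stage == "inter_nurse"]
    }
    total
  }, integer(1))
  expect_true(all(diff(counts) > 0))
})

test_that("configuration invariants are enforced", {
  expect_error(bp_mixture(c(0.5, 0.4), c(120, 140), c(10, 10),
                          c(80, 90), c(8, 8)), "sum to 1")
  expect_error(bp_mixture(c(0, 0), c(120, 140), c(10, 10),
                          c(80, 90), c(8, 8)), "positive total")
  expect_error(generator_config(failure_mixture = c(signal_not_captured = 1,
                                                    poor_quality = 0.2)),
               "summing to 1")
  expect_error(generator_config(failure_probability = 1.2))
  expect_error(generator_config(calibration_anchor_weight = -0.1))
})

test_that("scenarios exist for the four study settings and differ as documented", {
  expect_error(scenario("XX_nowhere"), "arg")
  cold <- scenario("BN_cold", seed = 1)
  warm <- scenario("BN_general", seed = 1)
  expect_gt(cold$cold_weather_multiplier, 1)
  # cold weather inflates the device-failure exclusion share
  share <- function(cfg) {
    l <- run_cascade(generate_study(cfg)$rounds)$ledger
    l$measurement$n_excluded[l$measurement$stage == "device_failure"] /
      l$n_input_measurements
  }
  expect_gt(share(cold), share(warm))
})

test_that("the pregnant scenario meets the group minima", {
  st <- generate_study(scenario("SA_pregnant", seed = 21))
  grp <- classify_pregnant(st$subjects$resting_sbp, st$subjects$resting_dbp,
                           st$subjects$proteinuria_flag)
  expect_true(all(table(grp) >= 20))
  expect_true(all(st$subjects$sex == "female"))
  expect_true(all(!is.na(st$subjects$gestational_weeks)))
})

test_that("simulated site scenarios center on their target mean errors", {
  reps <- 20
  m_tz <- vapply(seq_len(reps), function(r) {
    cc <- run_cascade(generate_study(scenario("TZ_general",
                                              seed = 4000 + r))$rounds)
    mean(cc$pairs$device_sbp - cc$pairs$reference_sbp)
  }, numeric(1))
  expect_lt(abs(mean(m_tz) - 0.8), 0.45)
})

test_that("study CSVs round-trip through the readers", {
  st <- generate_study(scenario("TZ_general", seed = 13, n_subjects = 20))
  dir <- tempfile("study")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  write_study(st, dir)
  rounds <- read_rounds_csv(file.path(dir, "rounds.csv"))
  subjects <- read_subjects_csv(file.path(dir, "subjects.csv"))
  expect_equal(nrow(rounds), nrow(st$rounds))
  expect_equal(rounds$n1_sbp, st$rounds$n1_sbp)
  expect_equal(subjects$subject_id, st$subjects$subject_id)
  direct <- evaluate_study(st)
  via_csv <- evaluate_study(rounds, subjects, population = "general")
  expect_equal(via_csv$criterion1$sbp$mean_error,
               direct$criterion1$sbp$mean_error)
  expect_equal(via_csv$criterion2$sbp$sd_between_subjects,
               direct$criterion2$sbp$sd_between_subjects)
})
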