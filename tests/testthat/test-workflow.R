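test_that("screening applies the rules in order and reports the first failure", {
  subj <- data.frame(
    subject_id = c("ok", "arm", "rest", "age", "preg_ok"),
    age = c(40, 40, 40, 17, 40),
    arm_diff_sbp = c(4, 16, 4, 16, 4),
    arm_diff_dbp = c(2, 2, 2, 2, 2),
    resting_sbp = c(120, 120, 181, 120, 158),
    resting_dbp = c(80, 80, 100, 80, 100))
  r <- screen_subject(subj, "general")
  expect_equal(r$eligible, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(r$reason, c(NA, "arm_difference", "resting_bp_cap",
                           "age_range", NA))

  # pregnant caps are tighter: 158/100 is still eligible, 161 systolic is not
  p <- screen_subject(data.frame(subject_id = c("a", "b"), age = c(30, 30),
                                 arm_diff_sbp = 2, arm_diff_dbp = 2,
                                 resting_sbp = c(158, 161),
                                 resting_dbp = c(100, 100)), "pregnant")
  expect_equal(p$eligible, c(TRUE, FALSE))
  expect_equal(p$reason[2], "resting_bp_cap")

  subj$resting_sbp[1] <- NA
  expect_error(screen_subject(subj, "general"), "incomplete")
  expect_error(screen_subject(subj[, -which(names(subj) == "age")],
                              "general"), "missing")
})

test_that("round validation averages agreeing nurses into the reference", {
  r <- validate_round(make_rounds("s1", 1, n1_sbp = 120, n1_dbp = 80,
                                  n2_sbp = 124, n2_dbp = 82,
                                  dev_sbp = 118, dev_dbp = 79))
  expect_true(r$valid)
  expect_equal(r$reference_sbp, 122)
  expect_equal(r$reference_dbp, 81)

  # 5 mmHg systolic disagreement invalidates the round
  r2 <- validate_round(make_rounds("s1", 1, 120, 80, 125, 80))
  expect_false(r2$valid)
  expect_equal(r2$reason, "inter_nurse")

  # 4 mmHg is still acceptable (strictly-greater-than rule)
  expect_true(validate_round(make_rounds("s1", 1, 120, 80, 124, 80))$valid)

  # identical readings reproduce themselves exactly
  r3 <- validate_round(make_rounds("s1", 1, 117, 79, 117, 79))
  expect_equal(r3$reference_sbp, 117)
  expect_equal(r3$reference_dbp, 79)

  r4 <- validate_round(make_rounds("s1", 1, 120, 80, 120, 80,
                                   dev_status = "poor_quality"))
  expect_false(r4$valid)
  expect_equal(r4$reason, "device_poor_quality")

  expect_error(validate_round(make_rounds("s1", 1, NA, 80, 120, 80)),
               "nurse readings")
  bad <- make_rounds("s1", 1, 120, 80, 120, 80)
  bad$dev_status <- "exploded"
  bad$dev_sbp <- NA; bad$dev_dbp <- NA
  expect_error(validate_round(bad), "unknown device status")
})

test_that("round validation is symmetric in the nurse labels", {
  rounds <- make_rounds(rep("s", 3), 1:3,
                        n1_sbp = c(120, 130, 110), n1_dbp = c(80, 85, 70),
                        n2_sbp = c(123, 135, 112), n2_dbp = c(82, 85, 74))
  swapped <- rounds
  swapped[c("n1_sbp", "n1_dbp", "n2_sbp", "n2_dbp")] <-
    rounds[c("n2_sbp", "n2_dbp", "n1_sbp", "n1_dbp")]
  a <- validate_round(rounds)
  b <- validate_round(swapped)
  expect_equal(a$valid, b$valid)
  expect_equal(a$reference_sbp, b$reference_sbp)
  expect_equal(a$reference_dbp, b$reference_dbp)
})

test_that("the cascade removes subjects left with too few pairs", {
  rounds <- rbind(
    make_rounds(rep("few", 4), 1:4,
                n1_sbp = c(120, 120, 120, 120), n1_dbp = 80,
                n2_sbp = c(120, 127, 126, 120), n2_dbp = 80),
    stable_subject("keep1"), stable_subject("keep2"))
  cc <- run_cascade(rounds)
  expect_false("few" %in% cc$pairs$subject_id)
  m <- cc$ledger$measurement
  expect_equal(m$n_excluded[m$stage == "inter_nurse"], 2L)
  expect_equal(m$n_excluded[m$stage == "insufficient_pairs"], 2L)
  s <- cc$ledger$subject
  expect_equal(s$n_excluded[s$stage == "insufficient_pairs"], 1L)
  expect_equal(cc$ledger$n_retained_subjects, 2L)
  reasons <- cc$ledger$records
  expect_equal(sort(reasons$reason[reasons$subject_id == "few"]),
               c("insufficient_pairs", "insufficient_pairs",
                 "inter_nurse", "inter_nurse"))
})

test_that("a fully valid, stable dataset passes the cascade untouched", {
  rounds <- rbind(stable_subject("a"), stable_subject("b", sbp = 140, dbp = 90))
  cc <- run_cascade(rounds)
  expect_equal(nrow(cc$pairs), nrow(rounds))
  expect_equal(sum(cc$ledger$measurement$n_excluded), 0L)
  expect_equal(cc$ledger$n_retained_subjects, 2L)
})

test_that("the variability rule drops subjects with two deviant rounds", {
  # two of five rounds sit >12 mmHg systolic from the subject median
  wobble <- make_rounds(rep("w", 5), 1:5,
                        n1_sbp = c(120, 120, 140, 140, 120), n1_dbp = 80,
                        n2_sbp = c(120, 120, 140, 140, 120), n2_dbp = 80)
  cc <- run_cascade(rbind(wobble, stable_subject("a"), stable_subject("b")))
  expect_false("w" %in% cc$pairs$subject_id)
  s <- cc$ledger$subject
  expect_equal(s$n_excluded[s$stage == "reference_variability"], 1L)
  m <- cc$ledger$measurement
  expect_equal(m$n_excluded[m$stage == "reference_variability"], 5L)

  # a single deviant round is tolerated
  one <- make_rounds(rep("o", 4), 1:4,
                     n1_sbp = c(120, 120, 140, 120), n1_dbp = 80,
                     n2_sbp = c(120, 120, 140, 120), n2_dbp = 80)
  cc2 <- run_cascade(rbind(one, stable_subject("a")))
  expect_true("o" %in% cc2$pairs$subject_id)

  # the diastolic limit is tighter (8 mmHg)
  dw <- make_rounds(rep("d", 5), 1:5,
                    n1_sbp = 120, n1_dbp = c(80, 80, 80, 92, 92),
                    n2_sbp = 120, n2_dbp = c(80, 80, 80, 92, 92))
  cc3 <- run_cascade(rbind(dw, stable_subject("a")))
  expect_false("d" %in% cc3$pairs$subject_id)
})

test_that("device failure takes precedence and overlap is reported", {
  rounds <- make_rounds(rep("s", 5), 1:5,
                        n1_sbp = c(120, 120, 120, 120, 120), n1_dbp = 80,
                        n2_sbp = c(120, 120, 120, 127, 120), n2_dbp = 80,
                        dev_status = c("ok", "signal_not_captured", "ok",
                                       "missing", "ok"))
  rounds$dev_sbp[c(2, 4)] <- NA; rounds$dev_dbp[c(2, 4)] <- NA
  cc <- run_cascade(rbind(rounds, stable_subject("a")))
  m <- cc$ledger$measurement
  expect_equal(m$n_excluded[m$stage == "device_failure"], 2L)
  expect_equal(m$n_excluded[m$stage == "inter_nurse"], 0L)
  expect_equal(cc$ledger$device_inter_nurse_overlap, 1L)
  rec <- cc$ledger$records
  expect_equal(rec$reason[rec$subject_id == "s" & rec$round_index == 4],
               "device_missing")
})

test_that("reordering rounds does not change which subjects are retained", {
  set.seed(7)
  st <- generate_study(generator_config(n_subjects = 15, seed = 99))
  shuffled <- st$rounds[sample.int(nrow(st$rounds)), ]
  a <- run_cascade(st$rounds)
  b <- run_cascade(shuffled)
  expect_setequal(unique(a$pairs$subject_id), unique(b$pairs$subject_id))
  expect_equal(a$ledger$n_retained_measurements,
               b$ledger$n_retained_measurements)
})

test_that("pregnant subjects are classified by BP and proteinuria", {
  expect_equal(as.character(classify_pregnant(139, 89, FALSE)),
               "normotensive")
  expect_equal(as.character(classify_pregnant(150, 95, TRUE)),
               "pre_eclampsia")
  # the hypertension definition is a disjunction: either arm suffices
  expect_equal(as.character(classify_pregnant(140, 85, FALSE)),
               "hypertensive_no_proteinuria")
  expect_equal(as.character(classify_pregnant(120, 90, FALSE)),
               "hypertensive_no_proteinuria")
  expect_error(classify_pregnant(NA, 80, TRUE), "enrollment BP")
  expect_error(classify_pregnant(120, 80, NA), "proteinuria")
})

test_that("the sampling audit flags unmet band and group requirements", {
  # no measurements at or above 160 systolic: that band must fail
  pairs <- data.frame(subject_id = rep(sprintf("s%03d", 1:90), each = 4),
                      reference_sbp = rep(c(95, 120, 125, 145), 90),
                      reference_dbp = rep(c(55, 75, 88, 102), 90))
  a <- audit_sampling(pairs, subjects = NULL, population = "general")
  expect_false(a$passed[a$requirement == "sbp_ge_160"])
  expect_true(a$passed[a$requirement == "sbp_le_100"])
  expect_true(a$passed[a$requirement == "min_subjects"])

  subj <- data.frame(subject_id = sprintf("p%02d", 1:60),
                     resting_sbp = rep(c(120, 150, 150), each = 20),
                     resting_dbp = rep(c(75, 95, 96), each = 20),
                     proteinuria_flag = rep(c(FALSE, FALSE, TRUE), each = 20))
  b <- audit_sampling(NULL, subj, population = "pregnant")
  expect_true(all(b$passed))
  subj$proteinuria_flag[1] <- NA
  expect_error(audit_sampling(NULL, subj, population = "pregnant"),
               "proteinuria")
})
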