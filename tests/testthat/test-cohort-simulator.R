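test_that("simulation_params validates its inputs", {
  expect_error(simulation_params(n_patients = 5), "rng_seed")
  expect_error(simulation_params(rng_seed = 1,
                                 p_lab_out_of_range = 1.2), "\\[0, 1\\]")
  gd <- default_grade_distributions()
  gd$fatigue <- c(0.5, 0.5, 0.5, 0, 0)
  expect_error(simulation_params(rng_seed = 1, grade_distributions = gd),
               "summing to 1")
  gd$fatigue <- NULL
  expect_error(simulation_params(rng_seed = 1, grade_distributions = gd),
               "fatigue")
})

test_that("degenerate parameters pin every cycle to one tier", {
  all_zero <- lapply(default_grade_distributions(),
                     function(d) c(1, 0, 0, 0, 0))

  log <- simulate_cohort(simulation_params(
    n_patients = 6, cycles_per_patient = 4L,
    p_questionnaire_completed = 1, p_lab_out_of_range = 0,
    grade_distributions = all_zero, rng_seed = 11))
  tiers <- vapply(log$decisions, effective_tier, integer(1))
  expect_true(all(tiers == 1L))

  log <- simulate_cohort(simulation_params(
    n_patients = 6, cycles_per_patient = 4L,
    p_questionnaire_completed = 1, p_lab_out_of_range = 1,
    grade_distributions = all_zero, rng_seed = 11))
  tiers <- vapply(log$decisions, effective_tier, integer(1))
  expect_true(all(tiers == 3L))
})

test_that("the same seed reproduces the cohort exactly", {
  p <- simulation_params(n_patients = 8, rng_seed = 202)
  log1 <- simulate_cohort(p)
  log2 <- simulate_cohort(p)
  expect_identical(log1, log2)
  log3 <- simulate_cohort(simulation_params(n_patients = 8,
                                            rng_seed = 203))
  expect_false(identical(log1, log3))
})

test_that("simulate_cohort restores the caller's RNG state", {
  set.seed(77)
  before <- .Random.seed
  invisible(simulate_cohort(simulation_params(n_patients = 3,
                                              rng_seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("empirical rates recover the configured probabilities", {
  # 150 patients x 8 cycles = 1200; binomial 3-standard-error bands
  p <- simulation_params(n_patients = 150, cycles_per_patient = 8L,
                         p_questionnaire_completed = 0.77,
                         p_lab_out_of_range = 0.33, rng_seed = 5)
  log <- simulate_cohort(p)
  n <- length(log$records)
  expect_identical(n, 1200L)

  has_q <- vapply(log$records, function(r) !is.null(r$questionnaire),
                  logical(1))
  se_q <- sqrt(0.77 * 0.23 / n)
  expect_lt(abs(mean(has_q) - 0.77), 3 * se_q)

  lab_out <- vapply(log$records, function(r)
    evaluate_panel(r$panel)$overall == "OUT_OF_RANGE", logical(1))
  se_l <- sqrt(0.33 * 0.67 / n)
  expect_lt(abs(mean(lab_out) - 0.33), 3 * se_l)

  # per-grade frequency recovery for one symptom
  grades <- unlist(lapply(log$records, function(r) {
    if (is.null(r$questionnaire)) return(NULL)
    q_grade <- r$questionnaire$reports
    q_grade$grade[q_grade$symptom == "fatigue"]
  }))
  target <- default_grade_distributions()$fatigue
  for (g in 0:2) {
    phat <- mean(grades == g)
    se <- sqrt(target[g + 1] * (1 - target[g + 1]) / length(grades))
    expect_lt(abs(phat - target[g + 1]), 3 * se)
  }
})

test_that("staleness back-dates questionnaires beyond the window", {
  log <- simulate_cohort(simulation_params(
    n_patients = 10, cycles_per_patient = 5L,
    p_questionnaire_completed = 1, p_stale_given_completed = 1,
    p_lab_out_of_range = 0, rng_seed = 9))
  fresh <- vapply(log$records, function(r)
    is_fresh(r$questionnaire$completed_on,
             r$plan$planned_infusion_date, 3L), logical(1))
  expect_false(any(fresh))
  tiers <- vapply(log$decisions, effective_tier, integer(1))
  expect_true(all(tiers == 2L))
  expect_true(all(vapply(log$decisions, function(d)
    "EPRO_STALE" %in% d$rationale, logical(1))))
})

test_that("the trial fixture reproduces every printed marginal", {
  log <- build_echo_fixture()
  expect_length(log$records, 339L)
  expect_length(log$questionnaires, 843L)
  expect_length(unique(vapply(log$records, function(r)
    r$plan$patient_id, character(1))), 43L)

  fresh <- vapply(log$records, function(r) {
    !is.null(r$questionnaire) &&
      is_fresh(r$questionnaire$completed_on,
               r$plan$planned_infusion_date, 3L)
  }, logical(1))
  expect_identical(sum(fresh), 262L)

  acceptable <- vapply(log$records, function(r) {
    !is.null(r$questionnaire) && max_grade(r$questionnaire) <= 1L
  }, logical(1))
  expect_identical(sum(fresh & acceptable), 221L)

  labs_ok <- vapply(log$records, function(r)
    evaluate_panel(r$panel)$overall == "IN_RANGE", logical(1))
  expect_identical(sum(labs_ok), 228L)

  # grade-3/4 records: 137 total, diarrhea 5, neuropathy 4
  sev <- table(unlist(lapply(log$questionnaires, function(q)
    q$reports$symptom[q$reports$grade >= 3L])))
  expect_identical(sum(sev), 137L)
  expect_identical(unname(sev["diarrhea"]), 5L)
  expect_identical(unname(sev["peripheral_sensory_neuropathy"]), 4L)
})

test_that("fixture tier counts are invariant to the admissible joint split", {
  # the printed marginals fix tier counts under lab-first precedence no
  # matter how questionnaire problems co-occur with lab failures
  for (b in c(6L, 20L, 41L)) {
    log <- decide_cohort(build_echo_fixture(n_flagged_lab_in = b))
    tiers <- vapply(log$decisions, effective_tier, integer(1))
    expect_identical(as.integer(table(factor(tiers, 1:3))),
                     c(145L, 83L, 111L), label = paste("split", b))
  }
  expect_error(build_echo_fixture(5L), "6..41")
  expect_error(build_echo_fixture(42L), "6..41")
})
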