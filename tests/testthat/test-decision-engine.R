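mk_lab <- function(state, infusion = as.Date("2020-05-15")) {
  v <- in_range_panel_values()
  switch(state,
    in_range = test_panel(infusion - 1L),
    out_of_range = test_panel(infusion - 1L,
                              overrides = c(thrombocytes = 80)),
    incomplete = lab_panel("p01", infusion - 1L,
                           v[names(v) != "creatinine"]),
    absent = NULL,
    stale = test_panel(infusion - 5L))
}

mk_epro <- function(state, infusion = as.Date("2020-05-15")) {
  # returns list(questionnaire, baseline)
  switch(state,
    fresh_ok = list(q = test_q(c(fatigue = 1, nausea = 0),
                               infusion - 1L), b = NULL),
    fresh_flagged = list(q = test_q(c(nausea = 2), infusion - 1L),
                         b = NULL),
    fresh_at_baseline = list(
      q = test_q(c(peripheral_sensory_neuropathy = 2), infusion - 1L),
      b = test_q(c(peripheral_sensory_neuropathy = 2), infusion - 30L)),
    absent = list(q = NULL, b = NULL),
    stale = list(q = test_q(c(fatigue = 1), infusion - 5L), b = NULL))
}

test_that("decide matches the 25-row lab-state x ePRO-state truth table", {
  # hand-derived oracle: labs out of range (fresh) always postpones;
  # any missing/stale data evaluates manually; symptoms >= 2 above
  # baseline evaluate; otherwise go
  lab_states <- c("in_range", "out_of_range", "incomplete", "absent",
                  "stale")
  epro_states <- c("fresh_ok", "fresh_flagged", "fresh_at_baseline",
                   "absent", "stale")
  expected_tier <- function(lab, epro) {
    if (lab == "out_of_range") return(3L)
    if (lab %in% c("incomplete", "absent", "stale")) return(2L)
    if (epro %in% c("absent", "stale", "fresh_flagged")) return(2L)
    1L
  }
  primary_code <- function(lab, epro) {
    switch(lab,
      out_of_range = "LABS_OUT_OF_RANGE",
      incomplete = "LABS_MISSING",
      absent = "LABS_MISSING",
      stale = "LABS_STALE",
      in_range = switch(epro,
        absent = "EPRO_MISSING",
        stale = "EPRO_STALE",
        fresh_flagged = "SYMPTOM_GE2_ABOVE_BASELINE",
        "ALL_CLEAR"))
  }
  cfg <- engine_config(baseline_policy = "explicit")
  n_checked <- 0L
  for (lab in lab_states) {
    for (epro in epro_states) {
      ep <- mk_epro(epro)
      rec <- cycle_record(test_plan(), ep$q, mk_lab(lab), ep$b)
      d <- decide(rec, cfg)
      expect_identical(d$tier, expected_tier(lab, epro),
                       label = paste(lab, "x", epro))
      expect_true(primary_code(lab, epro) %in% d$rationale,
                  label = paste(lab, "x", epro, "rationale"))
      n_checked <- n_checked + 1L
    }
  }
  expect_identical(n_checked, 25L)
})

test_that("rationale collects every contributing code", {
  rec <- cycle_record(test_plan(), NULL,
                      mk_lab("out_of_range"))
  d <- decide(rec)
  expect_identical(d$tier, 3L)
  expect_setequal(d$rationale, c("LABS_OUT_OF_RANGE", "EPRO_MISSING"))

  rec <- cycle_record(test_plan(), NULL, NULL)
  d <- decide(rec)
  expect_identical(d$tier, 2L)
  expect_setequal(d$rationale, c("LABS_MISSING", "EPRO_MISSING"))
})

test_that("tier 1 carries exactly ALL_CLEAR and flagged symptoms are named", {
  d <- decide(test_record())
  expect_identical(d$tier, 1L)
  expect_identical(d$rationale, "ALL_CLEAR")

  d <- decide(test_record(questionnaire = test_q(c(nausea = 2))),
              engine_config(baseline_policy = "explicit"))
  expect_identical(d$tier, 2L)
  expect_identical(attr(d, "flagged_symptoms"), "nausea")
})

test_that("decide rejects invalid records with findings", {
  bad_q <- test_q(c(diarrhea = 4))
  bad_q$reports$grade <- 5L
  expect_error(decide(test_record(questionnaire = bad_q)),
               "grade out of 0-4")
})

test_that("decide is pure: repeated calls are identical, inputs untouched", {
  rec <- test_record(questionnaire = test_q(c(nausea = 2)))
  cfg <- engine_config(baseline_policy = "explicit")
  snapshot <- unserialize(serialize(rec, NULL))
  d1 <- decide(rec, cfg)
  d2 <- decide(rec, cfg)
  expect_identical(d1, d2)
  expect_identical(rec, snapshot)
})

test_that("increasing a symptom grade never decreases the tier", {
  cfg <- engine_config(baseline_policy = "explicit")
  tiers <- vapply(0:4, function(g) {
    decide(test_record(questionnaire = test_q(c(nausea = g))), cfg)$tier
  }, integer(1))
  expect_true(all(diff(tiers) >= 0))
})

test_that("overrides preserve the engine decision as an audit trail", {
  d <- decide(test_record(questionnaire = NULL))
  expect_identical(d$tier, 2L)

  o <- apply_override(d, 1L, "nurse reviewed by phone")
  expect_identical(o$tier, 2L)                 # engine tier unchanged
  expect_identical(o$rationale, d$rationale)   # rationale unchanged
  expect_identical(o$overridden_tier, 1L)
  expect_identical(effective_tier(o), 1L)
  expect_identical(effective_tier(d), 2L)

  # no-op override is still recorded
  o2 <- apply_override(tier_recommendation(3, "LABS_OUT_OF_RANGE"), 3,
                       "confirmed after repeat labs")
  expect_identical(o2$overridden_tier, 3L)
  expect_identical(effective_tier(o2), 3L)

  expect_error(apply_override(d, 1L, ""), "attributable")
  expect_error(apply_override(d, 5L, "note"), "1, 2 or 3")
})

test_that("first_questionnaire policy resolves baselines per patient", {
  infusion <- as.Date("2020-05-15")
  baseline <- test_q(c(nausea = 2), "2020-01-02")
  current <- test_q(c(nausea = 2), infusion - 1L)
  rec <- cycle_record(test_plan(), current, test_panel(infusion - 1L))
  log <- cohort_log(list(rec), questionnaires = list(baseline, current))

  # nausea 2 already at baseline: no flag, tier 1
  decided <- decide_cohort(log, engine_config())
  expect_identical(decided$decisions[[1]]$tier, 1L)

  # under the explicit policy the unattached baseline is ignored
  decided <- decide_cohort(log, engine_config(baseline_policy = "explicit"))
  expect_identical(decided$decisions[[1]]$tier, 2L)
})
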