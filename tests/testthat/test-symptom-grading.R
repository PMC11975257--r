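test_that("grade_questionnaire applies first-match rubric semantics", {
  # identity rubric passes already-graded answers through
  q <- grade_questionnaire("p01", "2020-05-14", list(diarrhea = 3))
  expect_identical(q$reports$symptom, "diarrhea")
  expect_identical(q$reports$grade, 3L)

  # answer-pattern rubric: all "none" answers grade to 0
  catalog <- default_symptom_catalog()
  rules <- stats::setNames(lapply(as.character(catalog), function(s)
    list(list(answer = "none", grade = 0))), as.character(catalog))
  rub <- grading_rubric(rules)
  answers <- stats::setNames(as.list(rep("none", 16L)),
                             as.character(catalog))
  q <- grade_questionnaire("p01", "2020-05-14", answers, rub)
  expect_true(all(q$reports$grade == 0L))
  expect_identical(nrow(q$reports), 16L)

  # ordered rules: the first matching rule wins
  rub <- grading_rubric(list(fatigue = list(
    list(answer = "a", grade = 1),
    list(answer = "b", grade = 2),
    list(answer = "b", grade = 4))))
  q <- grade_questionnaire("p01", "2020-05-14", list(fatigue = "b"), rub)
  expect_identical(q$reports$grade, 2L)

  # unanswered symptoms are absent, not grade 0
  q <- grade_questionnaire("p01", "2020-05-14", list(pain = 1))
  expect_false("fatigue" %in% q$reports$symptom)

  # rejections name the symptom
  expect_error(grade_questionnaire("p01", "2020-05-14", list(hiccups = 1)),
               "hiccups")
  expect_error(
    grade_questionnaire("p01", "2020-05-14", list(fatigue = "b"),
                        grading_rubric(list(fatigue = list(
                          list(answer = "a", grade = 1))),
                          identity = FALSE)),
    "fatigue")
  expect_error(grading_rubric(list(pain = list(list(answer = "x",
                                                    grade = 7)))),
               "outside 0-4")
})

test_that("max_grade is the maximum over reports", {
  expect_identical(max_grade(test_q(c(pain = 0, nausea = 0))), 0L)
  expect_identical(max_grade(test_q(c(pain = 1, fatigue = 1,
                                      nausea = 2))), 2L)
  expect_identical(max_grade(test_q(c(pain = 4, nausea = 1))), 4L)
})

test_that("flags_above_baseline matches brute force over all grade pairs", {
  # independent oracle: flag iff current >= 2 and current > baseline
  for (cur in 0:4) {
    for (base in 0:4) {
      q <- test_q(c(peripheral_sensory_neuropathy = cur))
      bl <- test_q(c(peripheral_sensory_neuropathy = base))
      got <- flags_above_baseline(q, bl)
      want <- if (cur >= 2 && cur > base) {
        "peripheral_sensory_neuropathy"
      } else character(0)
      expect_identical(got, want)
    }
  }
})

test_that("flags_above_baseline handles absent baselines and mixed reports", {
  # absent baseline counts as grade 0
  expect_identical(
    flags_above_baseline(test_q(c(peripheral_sensory_neuropathy = 2))),
    "peripheral_sensory_neuropathy")
  # symptom absent from baseline counts as baseline 0
  got <- flags_above_baseline(test_q(c(pain = 1, nausea = 3)),
                              test_q(c(nausea = 2)))
  expect_identical(got, "nausea")
  # a questionnaire is never above its own baseline
  q <- test_q(c(pain = 3, nausea = 2, fatigue = 0))
  expect_identical(flags_above_baseline(q, q), character(0))
})

test_that("absolute baseline exemption never re-flags a baseline-2 symptom", {
  q4 <- test_q(c(nausea = 4))
  b2 <- test_q(c(nausea = 2))
  expect_identical(flags_above_baseline(q4, b2, "grade_exceeds"), "nausea")
  expect_identical(flags_above_baseline(q4, b2, "absolute"), character(0))
})

test_that("detect_alerts matches the exhaustive grade-pair truth table", {
  # oracle: GRADE_GE3 iff current >= 3; RISE_FROM_0 iff previous == 0 and
  # current == 2 (>= 3 already alerted; no duplicate per symptom)
  for (prev in 0:4) {
    for (cur in 0:4) {
      alerts <- detect_alerts(test_q(c(diarrhea = cur)),
                              test_q(c(diarrhea = prev)))
      triggers <- vapply(alerts, `[[`, character(1), "trigger")
      want <- if (cur >= 3) "GRADE_GE3" else
        if (prev == 0 && cur == 2) "RISE_FROM_0" else character(0)
      expect_identical(triggers, want,
                       label = sprintf("prev=%d cur=%d", prev, cur))
      expect_lte(length(alerts), 1L)
    }
  }
})

test_that("without a previous questionnaire only GRADE_GE3 can fire", {
  expect_length(detect_alerts(test_q(c(fatigue = 2))), 0L)
  alerts <- detect_alerts(test_q(c(diarrhea = 3)))
  expect_identical(alerts[[1]]$trigger, "GRADE_GE3")
  expect_identical(alerts[[1]]$grade, 3L)
})

test_that("alert presence is monotone in the current grade", {
  for (prev in 0:4) {
    fired <- vapply(0:4, function(cur) {
      length(detect_alerts(test_q(c(vomiting = cur)),
                           test_q(c(vomiting = prev)))) > 0
    }, logical(1))
    # once an alert fires at some grade, it fires at every higher grade
    expect_true(all(diff(fired) >= 0))
  }
})

test_that("alerts follow catalog order and fire once per symptom", {
  q <- test_q(c(vomiting = 3, blood_in_urine = 4, nausea = 2))
  alerts <- detect_alerts(q, test_q(c(nausea = 0)))
  syms <- vapply(alerts, `[[`, character(1), "symptom")
  expect_identical(syms, c("blood_in_urine", "nausea", "vomiting"))
  expect_identical(anyDuplicated(syms), 0L)
})

test_that("any_rise_ge2 rule alerts on a two-grade jump from any level", {
  prev <- test_q(c(pain = 1))
  cur <- test_q(c(pain = 2))
  expect_length(detect_alerts(cur, prev, rise_rule = "from_zero"), 0L)
  # 1 -> 2 is a one-grade rise: still silent under any_rise_ge2
  expect_length(detect_alerts(cur, prev, rise_rule = "any_rise_ge2"), 0L)
  # 0 -> 2 fires under both rules
  expect_length(detect_alerts(cur, test_q(c(pain = 0)),
                              rise_rule = "any_rise_ge2"), 1L)
})
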