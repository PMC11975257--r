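# CTCAE-style grading of questionnaire answers, baseline-adjusted symptom
# flags, and the urgency-alert algorithm.

#' Grading rubric: answer patterns to CTCAE grades
#'
#' A rubric maps raw questionnaire answers to CTCAE grades 0-4, one ordered
#' rule list per symptom; the first matching rule wins. The production
#' answer-to-grade mapping is configuration data, not code: the default
#' rubric is the identity on already-graded input (answers 0-4 pass
#' through).
#'
#' @param rules Named list: per symptom, a list of `list(answer=, grade=)`
#'   rules tried in order, answers compared as strings.
#' @param identity If `TRUE`, numeric answers 0-4 map to themselves for any
#'   symptom without explicit rules.
#' @return An object of class `grading_rubric`.
#' @export
grading_rubric <- function(rules = list(), identity = length(rules) == 0) {
  for (s in names(rules)) {
    for (r in rules[[s]]) {
      g <- as.integer(r$grade)
      if (is.na(g) || g < 0L || g > 4L) {
        stop("rubric rule for ", s, " maps to a grade outside 0-4",
             call. = FALSE)
      }
    }
  }
  structure(list(rules = rules, identity = isTRUE(identity)),
            class = "grading_rubric")
}

#' @rdname grading_rubric
#' @export
identity_rubric <- function() grading_rubric()

#' Grade raw questionnaire answers
#'
#' Applies the rubric to a set of raw per-symptom answers and returns a
#' [questionnaire()]. Unanswered symptoms are absent from the result (not
#' grade 0). Unknown symptoms or answers matched by no rule are rejected,
#' naming the symptom.
#'
#' @param patient_id,completed_on Passed to [questionnaire()].
#' @param raw_answers Named list/vector of raw answer values per symptom.
#' @param rubric A [grading_rubric()].
#' @param catalog A [symptom_catalog()]; answers outside it are rejected.
#' @return A [questionnaire()].
#' @examples
#' q <- grade_questionnaire("p01", "2020-05-14", list(diarrhea = 3))
#' q$reports
#' @export
grade_questionnaire <- function(patient_id, completed_on, raw_answers,
                                rubric = identity_rubric(),
                                catalog = default_symptom_catalog()) {
  syms <- names(raw_answers)
  if (is.null(syms) || any(!nzchar(syms))) {
    stop("raw_answers must be named by symptom", call. = FALSE)
  }
  unknown <- setdiff(syms, catalog)
  if (length(unknown)) {
    stop("unknown symptom(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  grades <- vapply(syms, function(s) {
    ans <- raw_answers[[s]]
    for (r in rubric$rules[[s]]) {
      if (identical(as.character(r$answer), as.character(ans))) {
        return(as.integer(r$grade))
      }
    }
    if (rubric$identity) {
      g <- suppressWarnings(as.integer(ans))
      if (!is.na(g) && g >= 0L && g <= 4L) return(g)
    }
    stop("no rubric rule matches answer for symptom ", s, call. = FALSE)
  }, integer(1))
  questionnaire(patient_id, completed_on, grades)
}

#' Maximum CTCAE grade in a questionnaire
#'
#' @param q A [questionnaire()].
#' @return Integer: the maximum grade over all reports (0 when every
#'   report is grade 0).
#' @export
max_grade <- function(q) {
  stopifnot(inherits(q, "questionnaire"))
  max(q$reports$grade)
}

q_grade_of <- function(q, symptom) {
  # grade of a symptom in a questionnaire; 0 when the questionnaire is
  # absent or does not report the symptom
  if (is.null(q)) return(0L)
  i <- match(symptom, q$reports$symptom)
  if (is.na(i)) 0L else q$reports$grade[i]
}

#' Symptoms at grade >= 2 above baseline
#'
#' The tier-2 symptom trigger: a symptom counts only if its current grade
#' is >= 2 and it is not "already at baseline". Two readings of that
#' exemption are supported: under `"grade_exceeds"` (default) the symptom
#' flags iff its current grade strictly exceeds its baseline grade, so a
#' baseline grade-2 neuropathy that worsens to 4 still flags; under
#' `"absolute"` any symptom already at grade >= 2 at baseline is exempt
#' regardless of worsening. A symptom absent from the baseline (or an
#' absent baseline) counts as baseline grade 0.
#'
#' @param current A [questionnaire()].
#' @param baseline A [questionnaire()] or `NULL`.
#' @param exemption `"grade_exceeds"` or `"absolute"`.
#' @return Character vector of flagged symptoms, in `current` report order.
#' @export
flags_above_baseline <- function(current, baseline = NULL,
                                 exemption = c("grade_exceeds", "absolute")) {
  stopifnot(inherits(current, "questionnaire"))
  exemption <- match.arg(exemption)
  r <- current$reports
  base <- vapply(r$symptom, q_grade_of, integer(1), q = baseline)
  flagged <- if (exemption == "grade_exceeds") {
    r$grade >= 2L & r$grade > base
  } else {
    r$grade >= 2L & base < 2L
  }
  r$symptom[flagged]
}

#' Urgency-alert detection
#'
#' Implements the alert rule of the symptom urgency algorithm: an alert is
#' raised for every symptom at grade 3 or higher (`GRADE_GE3`), and for
#' every symptom that rose from grade 0 in the previous questionnaire to
#' grade 2 now (`RISE_FROM_0`). At most one alert fires per symptom per
#' questionnaire: a symptom at grade >= 3 alerts as `GRADE_GE3` only.
#' When no previous questionnaire exists there is no basis for a "rise",
#' so only `GRADE_GE3` can fire. Under `rise_rule = "any_rise_ge2"` the
#' rise trigger generalizes to any increase of at least two grades.
#'
#' @param current A [questionnaire()].
#' @param previous The previous [questionnaire()] or `NULL`.
#' @param catalog A [symptom_catalog()]; alerts are emitted in catalog
#'   order.
#' @param rise_rule `"from_zero"` (default) or `"any_rise_ge2"`.
#' @return List of [alert_event()] objects (possibly empty).
#' @examples
#' q <- questionnaire("p01", "2020-05-14", c(diarrhea = 3))
#' detect_alerts(q)  # one GRADE_GE3 alert
#' @export
detect_alerts <- function(current, previous = NULL,
                          catalog = default_symptom_catalog(),
                          rise_rule = c("from_zero", "any_rise_ge2")) {
  stopifnot(inherits(current, "questionnaire"))
  rise_rule <- match.arg(rise_rule)
  alerts <- list()
  reported <- intersect(catalog, current$reports$symptom)
  for (s in reported) {
    cur <- q_grade_of(current, s)
    if (cur >= 3L) {
      alerts[[length(alerts) + 1L]] <- alert_event(
        current$patient_id, s, cur, "GRADE_GE3", current$completed_on)
    } else if (cur >= 2L && !is.null(previous)) {
      prev <- q_grade_of(previous, s)
      rose <- if (rise_rule == "from_zero") prev == 0L else cur - prev >= 2L
      if (rose) {
        alerts[[length(alerts) + 1L]] <- alert_event(
          current$patient_id, s, cur, "RISE_FROM_0", current$completed_on)
      }
    }
  }
  alerts
}
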