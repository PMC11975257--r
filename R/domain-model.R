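# Domain types shared by every module: symptom catalog, questionnaires,
# laboratory panels, reference ranges, cycle plans/records, recommendations.

#' Laboratory analytes screened before each chemotherapy cycle
#'
#' The seven analytes used to judge bone-marrow, liver and kidney function
#' before a new cycle: red and white blood cell counts, thrombocytes,
#' alanine and aspartate aminotransferases, bilirubin and creatinine.
#'
#' @return Character vector of the seven analyte identifiers.
#' @export
lab_analytes <- function() {
  c("rbc", "wbc", "thrombocytes", "alt", "ast", "bilirubin", "creatinine")
}

.default_symptoms <- c(
  "blood_in_urine", "dysuria", "eye_symptoms",
  "peripheral_sensory_neuropathy", "pain", "constipation", "cough",
  "decreased_appetite", "diarrhea", "fatigue", "fever", "mouth_sores",
  "nausea", "rash_or_skin_changes", "shortness_of_breath", "vomiting"
)

#' Symptom catalog
#'
#' An ordered set of symptom identifiers (lowercase snake-case slugs) that a
#' questionnaire may grade. The default catalog holds the 16 core
#' chemotherapy side-effect symptoms monitored by the ePRO questionnaire.
#'
#' @param symptoms Character vector of unique, non-empty symptom slugs.
#' @return An object of class `symptom_catalog` (a character vector).
#' @examples
#' cat <- default_symptom_catalog()
#' length(cat)  # 16
#' @export
symptom_catalog <- function(symptoms = .default_symptoms) {
  if (!is.character(symptoms) || length(symptoms) == 0) {
    stop("catalog must be a non-empty character vector", call. = FALSE)
  }
  if (anyDuplicated(symptoms)) {
    stop("catalog symptoms must be unique", call. = FALSE)
  }
  if (any(!nzchar(symptoms))) {
    stop("catalog symptoms must be non-empty strings", call. = FALSE)
  }
  structure(symptoms, class = c("symptom_catalog", "character"))
}

#' @rdname symptom_catalog
#' @export
default_symptom_catalog <- function() symptom_catalog()

as_date_scalar <- function(x, what) {
  d <- tryCatch(as.Date(x), error = function(e) as.Date(NA))
  if (length(d) != 1L || is.na(d)) {
    stop(what, " must be a single valid ISO 8601 date", call. = FALSE)
  }
  d
}

#' Symptom questionnaire
#'
#' One completed ePRO questionnaire: per-symptom NCI-CTCAE grades (0-4) with
#' a completion date. Unanswered symptoms are simply absent, not grade 0.
#'
#' @param patient_id Opaque patient identifier (single string).
#' @param completed_on Completion date (`Date` or ISO 8601 string).
#' @param grades Named integer vector or two-column data frame
#'   (`symptom`, `grade`) mapping symptom slugs to grades 0-4.
#' @return An object of class `questionnaire` with fields `patient_id`,
#'   `completed_on` and `reports` (data frame `symptom`, `grade`).
#' @examples
#' questionnaire("p01", "2020-05-14", c(diarrhea = 3, fatigue = 1))
#' @export
questionnaire <- function(patient_id, completed_on, grades) {
  if (is.data.frame(grades)) {
    reports <- data.frame(symptom = as.character(grades$symptom),
                          grade = as.integer(grades$grade),
                          stringsAsFactors = FALSE)
  } else {
    if (is.null(names(grades)) || any(!nzchar(names(grades)))) {
      stop("grades must be a named vector or a symptom/grade data frame",
           call. = FALSE)
    }
    reports <- data.frame(symptom = names(grades),
                          grade = as.integer(grades),
                          stringsAsFactors = FALSE)
  }
  if (nrow(reports) == 0L) {
    stop("a questionnaire with zero symptom reports is invalid", call. = FALSE)
  }
  if (anyDuplicated(reports$symptom)) {
    stop("at most one report per symptom", call. = FALSE)
  }
  if (anyNA(reports$grade) || any(reports$grade < 0L | reports$grade > 4L)) {
    stop("grades must be integers in 0-4", call. = FALSE)
  }
  structure(
    list(patient_id = as.character(patient_id)[1L],
         completed_on = as_date_scalar(completed_on, "completed_on"),
         reports = reports),
    class = "questionnaire"
  )
}

#' @export
print.questionnaire <- function(x, ...) {
  cat("ePRO questionnaire: patient", x$patient_id,
      "completed", format(x$completed_on), "\n")
  nz <- x$reports[x$reports$grade > 0L, , drop = FALSE]
  if (nrow(nz)) {
    cat(paste0("  ", nz$symptom, ": grade ", nz$grade, collapse = "\n"), "\n")
  } else {
    cat("  all reported symptoms at grade 0\n")
  }
  invisible(x)
}

#' Laboratory panel
#'
#' Results of one pre-infusion peripheral blood sample for up to seven
#' analytes (see [lab_analytes()]), in the units declared by the reference
#' ranges in use.
#'
#' @param patient_id Opaque patient identifier.
#' @param sampled_on Sampling date (`Date` or ISO 8601 string).
#' @param values Named numeric vector, names from [lab_analytes()].
#' @return An object of class `lab_panel` with fields `patient_id`,
#'   `sampled_on` and `results` (data frame `analyte`, `value`).
#' @examples
#' lab_panel("p01", "2020-05-14",
#'           c(rbc = 4.5, wbc = 6, thrombocytes = 250, alt = 20,
#'             ast = 22, bilirubin = 8, creatinine = 70))
#' @export
lab_panel <- function(patient_id, sampled_on, values) {
  if (is.data.frame(values)) {
    results <- data.frame(analyte = as.character(values$analyte),
                          value = as.numeric(values$value),
                          stringsAsFactors = FALSE)
  } else {
    results <- data.frame(analyte = names(values),
                          value = as.numeric(values),
                          stringsAsFactors = FALSE)
  }
  if (anyDuplicated(results$analyte)) {
    stop("at most one result per analyte", call. = FALSE)
  }
  unknown <- setdiff(results$analyte, lab_analytes())
  if (length(unknown)) {
    stop("unknown analyte(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(results$value) || any(!is.finite(results$value)) ||
      any(results$value < 0)) {
    stop("analyte values must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(patient_id = as.character(patient_id)[1L],
         sampled_on = as_date_scalar(sampled_on, "sampled_on"),
         results = results),
    class = "lab_panel"
  )
}

#' Reference-range set for laboratory screening
#'
#' Inclusive `[low, high]` bounds per analyte within which a new cycle is
#' considered safe to prescribe. Use `-Inf`/`Inf` for unbounded sides.
#' All seven analytes must be present.
#'
#' The shipped defaults ([default_reference_ranges()]) are illustrative
#' standard adult ranges with a chemotherapy-style thrombocyte floor; real
#' deployments must configure the bounds mandated by the regimen's summary
#' of product characteristics and local practice.
#'
#' @param ranges Data frame with columns `analyte`, `low`, `high`, `unit`,
#'   or a named list of `list(low=, high=, unit=)` entries.
#' @return An object of class `reference_ranges` (a data frame).
#' @export
reference_ranges <- function(ranges) {
  if (!is.data.frame(ranges)) {
    ranges <- do.call(rbind, lapply(names(ranges), function(a) {
      r <- ranges[[a]]
      data.frame(analyte = a,
                 low = as.numeric(if (is.null(r$low)) -Inf else r$low),
                 high = as.numeric(if (is.null(r$high)) Inf else r$high),
                 unit = as.character(if (is.null(r$unit)) "" else r$unit),
                 stringsAsFactors = FALSE)
    }))
  }
  missing <- setdiff(lab_analytes(), ranges$analyte)
  if (length(missing)) {
    stop("reference ranges missing analyte(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- ranges$analyte[ranges$low > ranges$high]
  if (length(bad)) {
    stop("malformed range (low > high) for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ranges <- ranges[match(lab_analytes(), ranges$analyte), , drop = FALSE]
  rownames(ranges) <- NULL
  structure(ranges, class = c("reference_ranges", "data.frame"))
}

#' @rdname reference_ranges
#' @export
default_reference_ranges <- function() {
  reference_ranges(data.frame(
    analyte = lab_analytes(),
    low  = c(3.5,  3.0, 100,   0,   0,  0,  40),
    high = c(6.1, 11.0, 400,  50,  50, 21, 120),
    unit = c("10^12/L", "10^9/L", "10^9/L", "U/L", "U/L",
             "umol/L", "umol/L"),
    stringsAsFactors = FALSE
  ))
}

#' Planned chemotherapy cycle
#'
#' @param patient_id Opaque patient identifier.
#' @param cycle_number Positive integer cycle index within the regimen.
#' @param planned_infusion_date Planned infusion date.
#' @param regimen_label Free-text regimen description.
#' @return An object of class `cycle_plan`.
#' @export
cycle_plan <- function(patient_id, cycle_number, planned_infusion_date,
                       regimen_label = "") {
  cycle_number <- as.integer(cycle_number)
  if (is.na(cycle_number) || cycle_number < 1L) {
    stop("cycle_number must be a positive integer", call. = FALSE)
  }
  structure(
    list(patient_id = as.character(patient_id)[1L],
         cycle_number = cycle_number,
         planned_infusion_date = as_date_scalar(planned_infusion_date,
                                                "planned_infusion_date"),
         regimen_label = as.character(regimen_label)[1L]),
    class = "cycle_plan"
  )
}

#' Cycle record: the join consumed by the decision engine
#'
#' Binds one planned cycle to its latest questionnaire, latest laboratory
#' panel and baseline questionnaire, any of which may be absent.
#'
#' @param plan A [cycle_plan()].
#' @param questionnaire Latest [questionnaire()] or `NULL`.
#' @param panel Latest [lab_panel()] or `NULL`.
#' @param baseline Baseline [questionnaire()] or `NULL`.
#' @return An object of class `cycle_record`.
#' @export
cycle_record <- function(plan, questionnaire = NULL, panel = NULL,
                         baseline = NULL) {
  stopifnot(inherits(plan, "cycle_plan"))
  structure(
    list(plan = plan, questionnaire = questionnaire, panel = panel,
         baseline = baseline),
    class = "cycle_record"
  )
}

#' Three-tier recommendation
#'
#' The engine's output for one cycle: tier 1 (green, "go"), tier 2 (yellow,
#' "evaluate") or tier 3 (red, "postpone"), with machine-readable rationale
#' codes and an optional care-team override that preserves the original
#' engine decision as an audit trail.
#'
#' @param tier Integer 1, 2 or 3.
#' @param rationale Non-empty character vector of reason codes
#'   (`ALL_CLEAR`, `LABS_OUT_OF_RANGE`, `LABS_MISSING`, `LABS_STALE`,
#'   `EPRO_MISSING`, `EPRO_STALE`, `SYMPTOM_GE2_ABOVE_BASELINE`).
#' @param overridden_tier Optional integer 1-3 set by [apply_override()].
#' @param override_note Optional attribution note for the override.
#' @return An object of class `tier_recommendation`.
#' @export
tier_recommendation <- function(tier, rationale, overridden_tier = NULL,
                                override_note = NULL) {
  tier <- as.integer(tier)
  if (!tier %in% 1:3) stop("tier must be 1, 2 or 3", call. = FALSE)
  if (!is.character(rationale) || length(rationale) == 0) {
    stop("rationale must be a non-empty character vector", call. = FALSE)
  }
  if (tier == 1L && !identical(unname(rationale), "ALL_CLEAR")) {
    stop("tier 1 requires rationale ALL_CLEAR and nothing else",
         call. = FALSE)
  }
  if (!is.null(overridden_tier)) {
    overridden_tier <- as.integer(overridden_tier)
    if (!overridden_tier %in% 1:3) {
      stop("overridden_tier must be 1, 2 or 3", call. = FALSE)
    }
  }
  structure(
    list(tier = tier, rationale = rationale,
         overridden_tier = overridden_tier, override_note = override_note),
    class = "tier_recommendation"
  )
}

.tier_labels <- c("1" = "green/go", "2" = "yellow/evaluate",
                  "3" = "red/postpone")

#' @export
print.tier_recommendation <- function(x, ...) {
  cat("Tier", x$tier, paste0("(", .tier_labels[as.character(x$tier)], ")"),
      "-", paste(x$rationale, collapse = ", "), "\n")
  if (!is.null(x$overridden_tier)) {
    cat("  overridden to tier", x$overridden_tier, ":",
        x$override_note, "\n")
  }
  invisible(x)
}

#' Alert raised by the symptom urgency algorithm
#'
#' @param patient_id Opaque patient identifier.
#' @param symptom Symptom slug.
#' @param grade Current CTCAE grade.
#' @param trigger `"GRADE_GE3"` (severe symptom) or `"RISE_FROM_0"`
#'   (new moderate symptom).
#' @param raised_on Date of the questionnaire that triggered the alert.
#' @return An object of class `alert_event`.
#' @export
alert_event <- function(patient_id, symptom, grade, trigger, raised_on) {
  grade <- as.integer(grade)
  trigger <- match.arg(trigger, c("GRADE_GE3", "RISE_FROM_0"))
  if (trigger == "GRADE_GE3" && grade < 3L) {
    stop("GRADE_GE3 alerts require grade >= 3", call. = FALSE)
  }
  if (trigger == "RISE_FROM_0" && grade < 2L) {
    stop("RISE_FROM_0 alerts require grade >= 2", call. = FALSE)
  }
  structure(
    list(patient_id = as.character(patient_id)[1L], symptom = symptom,
         grade = grade, trigger = trigger,
         raised_on = as_date_scalar(raised_on, "raised_on")),
    class = "alert_event"
  )
}

#' Cohort log
#'
#' A list of cycle records plus (optionally) the parallel list of tier
#' recommendations, and the full pool of completed questionnaires for
#' prevalence reporting (a superset of the questionnaires attached to
#' records: patients also complete questionnaires between cycles).
#'
#' @param records List of [cycle_record()] objects.
#' @param decisions Parallel list of [tier_recommendation()] or `NULL`.
#' @param questionnaires List of all completed [questionnaire()] objects;
#'   defaults to those attached to the records.
#' @return An object of class `cohort_log`.
#' @export
cohort_log <- function(records, decisions = NULL, questionnaires = NULL) {
  if (!is.null(decisions) && length(decisions) != length(records)) {
    stop("decisions must parallel records (equal lengths)", call. = FALSE)
  }
  if (is.null(questionnaires)) {
    questionnaires <- Filter(Negate(is.null),
                             lapply(records, `[[`, "questionnaire"))
  }
  structure(
    list(records = records, decisions = decisions,
         questionnaires = questionnaires),
    class = "cohort_log"
  )
}

#' @export
print.cohort_log <- function(x, ...) {
  cat("Cohort log:", length(x$records), "cycle records,",
      length(x$questionnaires), "completed questionnaires,",
      if (is.null(x$decisions)) "no decisions yet" else
        paste(length(x$decisions), "decisions"), "\n")
  invisible(x)
}

#' Validate a cycle record
#'
#' Checks every structural invariant of a cycle record and returns the
#' violations as findings rather than raising: patient identifiers of the
#' questionnaire and panel must match the plan, grades must lie in 0-4,
#' symptoms must belong to the catalog, analytes must be unique and known,
#' values finite and non-negative. Pure and total: never raises, never
#' mutates.
#'
#' @param record A [cycle_record()] (possibly hand-built or deserialized).
#' @param catalog A [symptom_catalog()].
#' @param ranges A [reference_ranges()] set (reserved for unit checks).
#' @return Character vector of findings, each naming the field and the
#'   violated rule; `character(0)` iff the record is valid.
#' @export
validate_record <- function(record, catalog = default_symptom_catalog(),
                            ranges = default_reference_ranges()) {
  findings <- character(0)
  add <- function(msg) findings <<- c(findings, msg)

  plan <- record$plan
  if (is.null(plan)) {
    return("plan: missing")
  }
  if (!is.character(plan$patient_id) || !nzchar(plan$patient_id)) {
    add("plan.patient_id: must be a non-empty string")
  }
  if (!is.numeric(plan$cycle_number) || is.na(plan$cycle_number) ||
      plan$cycle_number < 1) {
    add("plan.cycle_number: must be a positive integer")
  }
  if (!inherits(plan$planned_infusion_date, "Date") ||
      is.na(plan$planned_infusion_date)) {
    add("plan.planned_infusion_date: must be a valid date")
  }

  check_q <- function(q, field) {
    if (is.null(q)) return(invisible())
    if (!identical(q$patient_id, plan$patient_id)) {
      add(paste0(field, ".patient_id: does not match plan.patient_id"))
    }
    if (!inherits(q$completed_on, "Date") || is.na(q$completed_on)) {
      add(paste0(field, ".completed_on: must be a valid date"))
    }
    r <- q$reports
    if (is.null(r) || nrow(r) == 0L) {
      add(paste0(field, ".reports: questionnaire with zero reports"))
      return(invisible())
    }
    dup <- unique(r$symptom[duplicated(r$symptom)])
    for (s in dup) add(paste0(field, ".reports: duplicate symptom ", s))
    unknown <- setdiff(unique(r$symptom), catalog)
    for (s in unknown) {
      add(paste0(field, ".reports: symptom ", s, " not in catalog"))
    }
    bad <- r$symptom[is.na(r$grade) | r$grade < 0 | r$grade > 4]
    for (s in bad) {
      add(paste0(field, ".reports.", s, ": grade out of 0-4"))
    }
  }
  check_q(record$questionnaire, "questionnaire")
  check_q(record$baseline, "baseline")

  p <- record$panel
  if (!is.null(p)) {
    if (!identical(p$patient_id, plan$patient_id)) {
      add("panel.patient_id: does not match plan.patient_id")
    }
    if (!inherits(p$sampled_on, "Date") || is.na(p$sampled_on)) {
      add("panel.sampled_on: must be a valid date")
    }
    r <- p$results
    dup <- unique(r$analyte[duplicated(r$analyte)])
    for (a in dup) add(paste0("panel.results: duplicate analyte ", a))
    unknown <- setdiff(unique(r$analyte), lab_analytes())
    for (a in unknown) {
      add(paste0("panel.results: unknown analyte ", a))
    }
    bad <- r$analyte[is.na(r$value) | !is.finite(r$value) | r$value < 0]
    for (a in bad) {
      add(paste0("panel.results.", a,
                 ": value must be finite and non-negative"))
    }
  }
  findings
}
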