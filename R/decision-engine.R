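# The three-tier recommendation engine: one pure decision per planned
# cycle from its labs, questionnaire, baseline and data freshness.

#' Decision-engine configuration
#'
#' @param max_age_days Maximum data age in whole days relative to the
#'   planned infusion date (default 3).
#' @param ranges A [reference_ranges()] set.
#' @param catalog A [symptom_catalog()].
#' @param baseline_policy `"first_questionnaire"`: when a record carries no
#'   explicit baseline, [decide_cohort()] uses the patient's earliest
#'   completed questionnaire on record; `"explicit"`: only a baseline
#'   attached to the record is used.
#' @param baseline_exemption Passed to [flags_above_baseline()].
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(max_age_days = 3L,
                          ranges = default_reference_ranges(),
                          catalog = default_symptom_catalog(),
                          baseline_policy = c("first_questionnaire",
                                              "explicit"),
                          baseline_exemption = c("grade_exceeds",
                                                 "absolute")) {
  max_age_days <- as.integer(max_age_days)
  if (is.na(max_age_days) || max_age_days < 0L) {
    stop("max_age_days must be a non-negative integer", call. = FALSE)
  }
  structure(
    list(max_age_days = max_age_days,
         ranges = if (inherits(ranges, "reference_ranges")) ranges else
           reference_ranges(ranges),
         catalog = if (inherits(catalog, "symptom_catalog")) catalog else
           symptom_catalog(catalog),
         baseline_policy = match.arg(baseline_policy),
         baseline_exemption = match.arg(baseline_exemption)),
    class = "engine_config"
  )
}

#' Decide the tier recommendation for one planned cycle
#'
#' Applies the engine's rules in precedence order, first match setting the
#' tier while the rationale collects every contributing code:
#'
#' 1. laboratory panel present, fresh and `OUT_OF_RANGE` -> tier 3
#'    (`LABS_OUT_OF_RANGE`): postpone;
#' 2. panel absent, stale, or `INCOMPLETE` -> tier 2 (`LABS_MISSING` /
#'    `LABS_STALE`): manual evaluation;
#' 3. questionnaire absent or older than `max_age_days` relative to the
#'    planned infusion date -> tier 2 (`EPRO_MISSING` / `EPRO_STALE`);
#' 4. any symptom at grade >= 2 above baseline
#'    ([flags_above_baseline()]) -> tier 2
#'    (`SYMPTOM_GE2_ABOVE_BASELINE`);
#' 5. otherwise tier 1 (`ALL_CLEAR`): go.
#'
#' Lab-out-of-range takes precedence over missing data, so the tier-3
#' count over a cohort equals the count of cycles with a fresh
#' out-of-range panel regardless of questionnaire availability. The
#' function is pure and deterministic: it reads nothing but `record` and
#' `config`.
#'
#' @param record A valid [cycle_record()]; an invalid record is rejected
#'   with its validation findings.
#' @param config An [engine_config()].
#' @return A [tier_recommendation()]; flagged symptoms are attached as
#'   attribute `"flagged_symptoms"` when rule 4 contributes.
#' @examples
#' plan <- cycle_plan("p01", 4, "2020-05-15")
#' q <- questionnaire("p01", "2020-05-14", c(fatigue = 1, nausea = 0))
#' p <- lab_panel("p01", "2020-05-14",
#'                c(rbc = 4.5, wbc = 6, thrombocytes = 250, alt = 20,
#'                  ast = 22, bilirubin = 8, creatinine = 70))
#' decide(cycle_record(plan, q, p))  # tier 1
#' @export
decide <- function(record, config = engine_config()) {
  findings <- validate_record(record, config$catalog, config$ranges)
  if (length(findings)) {
    stop("invalid cycle record:\n  ",
         paste(findings, collapse = "\n  "), call. = FALSE)
  }
  ref_date <- record$plan$planned_infusion_date
  codes <- character(0)
  flagged <- character(0)

  panel <- record$panel
  if (is.null(panel)) {
    codes <- c(codes, "LABS_MISSING")
  } else if (!is_fresh(panel$sampled_on, ref_date, config$max_age_days)) {
    codes <- c(codes, "LABS_STALE")
  } else {
    ev <- evaluate_panel(panel, config$ranges)
    if (ev$overall == "OUT_OF_RANGE") codes <- c(codes, "LABS_OUT_OF_RANGE")
    if (ev$overall == "INCOMPLETE") codes <- c(codes, "LABS_MISSING")
  }

  q <- record$questionnaire
  if (is.null(q)) {
    codes <- c(codes, "EPRO_MISSING")
  } else if (!is_fresh(q$completed_on, ref_date, config$max_age_days)) {
    codes <- c(codes, "EPRO_STALE")
  } else {
    flagged <- flags_above_baseline(q, record$baseline,
                                    config$baseline_exemption)
    if (length(flagged)) codes <- c(codes, "SYMPTOM_GE2_ABOVE_BASELINE")
  }

  if ("LABS_OUT_OF_RANGE" %in% codes) {
    rec <- tier_recommendation(3L, codes)
  } else if (length(codes)) {
    rec <- tier_recommendation(2L, codes)
  } else {
    rec <- tier_recommendation(1L, "ALL_CLEAR")
  }
  if (length(flagged)) attr(rec, "flagged_symptoms") <- flagged
  rec
}

#' Decide every cycle in a cohort log
#'
#' Runs [decide()] over each record. Under the `"first_questionnaire"`
#' baseline policy, a record without an explicit baseline is decided
#' against the patient's earliest-dated questionnaire in the log's
#' questionnaire pool (ties broken by list order).
#'
#' @param log A [cohort_log()].
#' @param config An [engine_config()].
#' @return The log with `decisions` filled in.
#' @export
decide_cohort <- function(log, config = engine_config()) {
  stopifnot(inherits(log, "cohort_log"))
  first_q <- list()
  if (config$baseline_policy == "first_questionnaire") {
    for (q in log$questionnaires) {
      cur <- first_q[[q$patient_id]]
      if (is.null(cur) || q$completed_on < cur$completed_on) {
        first_q[[q$patient_id]] <- q
      }
    }
  }
  decisions <- lapply(log$records, function(rec) {
    if (is.null(rec$baseline) &&
        config$baseline_policy == "first_questionnaire") {
      rec$baseline <- first_q[[rec$plan$patient_id]]
    }
    decide(rec, config)
  })
  cohort_log(log$records, decisions, log$questionnaires)
}

#' Record a care-team override
#'
#' The care team can always override the engine. The original engine tier
#' and rationale are preserved unchanged as the audit trail; only
#' `overridden_tier` and `override_note` are set on the returned copy.
#' Overrides must be attributable: an empty note is rejected.
#'
#' @param rec A [tier_recommendation()].
#' @param new_tier Integer 1-3.
#' @param note Non-empty attribution/justification text.
#' @return A new [tier_recommendation()] with the override recorded.
#' @export
apply_override <- function(rec, new_tier, note) {
  stopifnot(inherits(rec, "tier_recommendation"))
  if (!is.character(note) || length(note) != 1L || !nzchar(trimws(note))) {
    stop("override note must be non-empty (overrides must be attributable)",
         call. = FALSE)
  }
  tier_recommendation(rec$tier, rec$rationale,
                      overridden_tier = new_tier, override_note = note)
}

#' Effective tier of a recommendation
#'
#' @param rec A [tier_recommendation()].
#' @return The overridden tier when an override is recorded, else the
#'   engine tier.
#' @export
effective_tier <- function(rec) {
  stopifnot(inherits(rec, "tier_recommendation"))
  if (is.null(rec$overridden_tier)) rec$tier else rec$overridden_tier
}
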