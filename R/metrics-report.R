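# Performance and symptom-prevalence reports over a cohort log.

#' Round half away from zero
#'
#' Commercial rounding used for all printed percentages (`round()` in R
#' rounds half to even, which would turn 24.45 into 24.4).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  # pre-round at 8 decimals so a decimal half stored just below .5 in
  # binary (e.g. 0.15 * 10 = 1.4999...) still rounds away from zero
  sign(x) * floor(round(abs(x) * m, 8L) + 0.5) / m
}

pct1 <- function(n, total) round_half_up(100 * n / total, 1L)

#' Performance report for a decided cohort
#'
#' Computes the tool's headline performance metrics over a cohort log:
#' how many cycles had a questionnaire completed within the freshness
#' window before the planned infusion (same [is_fresh()] rule as the
#' engine), how many of those had all symptoms at grade <= 1
#' ("symptoms acceptable"), how many cycles had all seven analytes in
#' range, and the effective tier distribution. Percentages are
#' round-half-away-from-zero to one decimal.
#'
#' @param log A [cohort_log()]; decisions are computed with the supplied
#'   config if absent.
#' @param config An [engine_config()].
#' @return An object of class `performance_report`.
#' @examples
#' \donttest{
#' rep <- performance(decide_cohort(build_echo_fixture()))
#' rep$tiers
#' }
#' @export
performance <- function(log, config = engine_config()) {
  stopifnot(inherits(log, "cohort_log"))
  if (is.null(log$decisions)) log <- decide_cohort(log, config)
  n <- length(log$records)
  if (n == 0L) {
    return(structure(list(n_cycles = 0L,
                          fresh_questionnaire = c(n = 0L),
                          symptoms_acceptable = c(n = 0L),
                          labs_acceptable = c(n = 0L),
                          tiers = data.frame(tier = 1:3, n = 0L)),
                     class = "performance_report"))
  }
  fresh <- vapply(log$records, function(r) {
    !is.null(r$questionnaire) &&
      is_fresh(r$questionnaire$completed_on,
               r$plan$planned_infusion_date, config$max_age_days)
  }, logical(1))
  acceptable <- fresh & vapply(log$records, function(r) {
    !is.null(r$questionnaire) && max_grade(r$questionnaire) <= 1L
  }, logical(1))
  labs_ok <- vapply(log$records, function(r) {
    !is.null(r$panel) &&
      evaluate_panel(r$panel, config$ranges)$overall == "IN_RANGE"
  }, logical(1))
  tiers <- vapply(log$decisions, effective_tier, integer(1))
  tier_n <- vapply(1:3, function(t) sum(tiers == t), integer(1))

  structure(
    list(n_cycles = n,
         fresh_questionnaire = c(n = sum(fresh),
                                 pct = pct1(sum(fresh), n)),
         symptoms_acceptable = c(n = sum(acceptable),
                                 pct = pct1(sum(acceptable), n)),
         labs_acceptable = c(n = sum(labs_ok),
                             pct = pct1(sum(labs_ok), n)),
         tiers = data.frame(tier = 1:3, n = tier_n,
                            pct = pct1(tier_n, n))),
    class = "performance_report"
  )
}

#' @export
print.performance_report <- function(x, ...) {
  cat("Decision-support performance over", x$n_cycles, "cycles\n")
  if (x$n_cycles == 0L) return(invisible(x))
  row <- function(label, v) {
    cat(sprintf("  %-45s %4d (%.1f%%)\n", label, v[["n"]], v[["pct"]]))
  }
  row("questionnaire completed and fresh", x$fresh_questionnaire)
  row("symptom grading acceptable (all <= 1)", x$symptoms_acceptable)
  row("laboratory values in range", x$labs_acceptable)
  for (i in 1:3) {
    row(paste0("tier ", i, " (", .tier_labels[i], ")"),
        c(n = x$tiers$n[i], pct = x$tiers$pct[i]))
  }
  invisible(x)
}

#' Symptom-prevalence report
#'
#' Per symptom: in how many completed questionnaires it was reported
#' (grade >= 1; a grade-0 entry denotes absence of the symptom), as a
#' percentage of all completed questionnaires; and how many individual
#' grade-3/4 records it contributed, as a percentage of all grade-3/4
#' records. Invariant to questionnaire ordering.
#'
#' @param questionnaires List of [questionnaire()] objects.
#' @param catalog A [symptom_catalog()].
#' @return An object of class `prevalence_report`: list with
#'   `n_questionnaires`, `n_grade34_total` and `table` (one row per
#'   catalog symptom).
#' @export
prevalence <- function(questionnaires,
                       catalog = default_symptom_catalog()) {
  syms <- as.character(catalog)
  nq <- length(questionnaires)
  if (nq == 0L) {
    return(structure(list(n_questionnaires = 0L, n_grade34_total = 0L,
                          table = data.frame(symptom = character(0))),
                     class = "prevalence_report"))
  }
  reported <- stats::setNames(integer(length(syms)), syms)
  severe <- stats::setNames(integer(length(syms)), syms)
  for (q in questionnaires) {
    r <- q$reports
    rep_syms <- intersect(r$symptom[r$grade >= 1L], syms)
    reported[rep_syms] <- reported[rep_syms] + 1L
    sev_syms <- intersect(r$symptom[r$grade >= 3L], syms)
    severe[sev_syms] <- severe[sev_syms] + 1L
  }
  n34 <- sum(severe)
  tab <- data.frame(
    symptom = syms,
    n_reported = unname(reported),
    pct_reported = pct1(unname(reported), nq),
    n_grade34 = unname(severe),
    pct_grade34 = if (n34 > 0L) pct1(unname(severe), n34) else NA_real_,
    stringsAsFactors = FALSE
  )
  structure(list(n_questionnaires = nq, n_grade34_total = n34, table = tab),
            class = "prevalence_report")
}

#' @export
print.prevalence_report <- function(x, ...) {
  cat("Symptom prevalence over", x$n_questionnaires,
      "completed questionnaires (", x$n_grade34_total,
      "grade-3/4 records )\n")
  if (x$n_questionnaires == 0L) return(invisible(x))
  tab <- x$table[order(-x$table$n_reported), ]
  print(utils::head(tab, 10L), row.names = FALSE)
  invisible(x)
}
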