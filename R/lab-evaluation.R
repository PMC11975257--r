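# Laboratory-panel screening against reference ranges, and the shared
# data-freshness rule.

#' Evaluate a laboratory panel against reference ranges
#'
#' Classifies each of the seven analytes as `in_range` (inclusive
#' comparison `low <= value <= high`), `below_low`, `above_high` or
#' `missing`, and derives the overall fitness status: `IN_RANGE` iff all
#' seven analytes are in range; `OUT_OF_RANGE` iff at least one analyte is
#' outside its bounds; `INCOMPLETE` iff no analyte is out of range but at
#' least one is missing. An absent panel is entirely missing, hence
#' `INCOMPLETE`. `INCOMPLETE` is kept distinct from `OUT_OF_RANGE` so the
#' decision engine can route missing data to tier 2 (manual evaluation)
#' rather than tier 3 (postpone).
#'
#' @param panel A [lab_panel()] or `NULL`.
#' @param ranges A [reference_ranges()] set covering all seven analytes.
#' @return An object of class `panel_evaluation`: list with `statuses`
#'   (named character vector over [lab_analytes()]) and `overall`.
#' @examples
#' evaluate_panel(NULL)$overall  # "INCOMPLETE"
#' @export
evaluate_panel <- function(panel, ranges = default_reference_ranges()) {
  ranges <- if (inherits(ranges, "reference_ranges")) ranges else
    reference_ranges(ranges)
  if (any(ranges$low > ranges$high)) {
    stop("malformed reference range: low > high", call. = FALSE)
  }
  statuses <- vapply(lab_analytes(), function(a) {
    v <- if (is.null(panel)) NA_real_ else {
      i <- match(a, panel$results$analyte)
      if (is.na(i)) NA_real_ else panel$results$value[i]
    }
    if (is.na(v)) return("missing")
    r <- ranges[ranges$analyte == a, ]
    if (v < r$low) "below_low" else if (v > r$high) "above_high"
    else "in_range"
  }, character(1))
  overall <- if (any(statuses %in% c("below_low", "above_high"))) {
    "OUT_OF_RANGE"
  } else if (any(statuses == "missing")) {
    "INCOMPLETE"
  } else {
    "IN_RANGE"
  }
  structure(list(statuses = statuses, overall = overall),
            class = "panel_evaluation")
}

#' @export
print.panel_evaluation <- function(x, ...) {
  cat("Panel evaluation:", x$overall, "\n")
  off <- x$statuses[x$statuses != "in_range"]
  if (length(off)) {
    cat(paste0("  ", names(off), ": ", off, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Data-freshness rule
#'
#' An observation supports an automated decision only if it was made on or
#' before the reference date (future-dated data is invalid for a
#' pre-infusion decision) and is at most `max_age_days` whole days old.
#' The default of 3 days reproduces the "more than 3 days old" staleness
#' cut-off applied to both questionnaires and laboratory panels.
#'
#' @param observed_on Observation date.
#' @param reference_date Date the decision is made for (the planned
#'   infusion date).
#' @param max_age_days Maximum tolerated age in whole days (>= 0).
#' @return `TRUE` iff `0 <= reference_date - observed_on <= max_age_days`.
#' @examples
#' is_fresh(as.Date("2020-05-12"), as.Date("2020-05-15"), 3)  # TRUE
#' is_fresh(as.Date("2020-05-11"), as.Date("2020-05-15"), 3)  # FALSE
#' @export
is_fresh <- function(observed_on, reference_date, max_age_days = 3L) {
  stopifnot(max_age_days >= 0)
  age <- as.integer(as.Date(reference_date) - as.Date(observed_on))
  age >= 0L & age <= max_age_days
}
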