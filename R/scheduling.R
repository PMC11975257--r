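# Event state machine: times questionnaire/lab collection around each
# planned cycle and re-programs both when a cycle is postponed.

#' Scheduling configuration
#'
#' Lead times are whole days before the planned infusion; the real
#' production lead times are deployment choices, so all are configurable.
#'
#' @param questionnaire_lead_days Days before infusion to send the
#'   questionnaire (default 3, the freshness window).
#' @param lab_lead_days Days before infusion to collect labs (default 1).
#' @param postpone_delay_days Days a tier-3 postponement shifts the
#'   infusion (default 7, the conventional one-week chemotherapy delay).
#' @param reservation_merge_window_days Reservations for one patient
#'   within this many days are treated as one treatment event (default 3;
#'   covers ambulatory-pump removal appointments booked alongside the
#'   infusion).
#' @return An object of class `scheduling_config`.
#' @export
scheduling_config <- function(questionnaire_lead_days = 3L,
                              lab_lead_days = 1L,
                              postpone_delay_days = 7L,
                              reservation_merge_window_days = 3L) {
  cfg <- list(questionnaire_lead_days = as.integer(questionnaire_lead_days),
              lab_lead_days = as.integer(lab_lead_days),
              postpone_delay_days = as.integer(postpone_delay_days),
              reservation_merge_window_days =
                as.integer(reservation_merge_window_days))
  if (any(vapply(cfg, function(x) is.na(x) || x < 0L, logical(1)))) {
    stop("all scheduling parameters must be non-negative integers",
         call. = FALSE)
  }
  structure(cfg, class = "scheduling_config")
}

scheduled_event <- function(kind, due_on, plan) {
  kind <- match.arg(kind, c("SEND_QUESTIONNAIRE", "COLLECT_LABS",
                            "NOTIFY_GO", "NOTIFY_POSTPONED"))
  structure(
    list(kind = kind, due_on = as.Date(due_on),
         patient_id = plan$patient_id, cycle_number = plan$cycle_number),
    class = "scheduled_event"
  )
}

#' @export
print.scheduled_event <- function(x, ...) {
  cat(x$kind, "due", format(x$due_on), "for patient", x$patient_id,
      "cycle", x$cycle_number, "\n")
  invisible(x)
}

#' Schedule data collection for one planned cycle
#'
#' Synchronizes data collection with the treatment plan: exactly one
#' questionnaire send and one laboratory collection, each a configured
#' number of days before the planned infusion.
#'
#' @param plan A [cycle_plan()].
#' @param cfg A [scheduling_config()].
#' @return List of two `scheduled_event`s (`SEND_QUESTIONNAIRE`,
#'   `COLLECT_LABS`).
#' @examples
#' ev <- schedule_cycle(cycle_plan("p01", 1, "2020-05-15"))
#' ev[[1]]$due_on  # 2020-05-12
#' @export
schedule_cycle <- function(plan, cfg = scheduling_config()) {
  stopifnot(inherits(plan, "cycle_plan"))
  list(
    scheduled_event("SEND_QUESTIONNAIRE",
                    plan$planned_infusion_date - cfg$questionnaire_lead_days,
                    plan),
    scheduled_event("COLLECT_LABS",
                    plan$planned_infusion_date - cfg$lab_lead_days, plan)
  )
}

#' React to a tier decision for a planned cycle
#'
#' The state machine's transition on a decision (using the effective tier,
#' so overrides are honoured): tier 1 keeps the plan and notifies the
#' patient of the confirmed timetable (`NOTIFY_GO`); tier 2 keeps the plan
#' and emits no automatic events, because the yellow pathway is a human
#' evaluation step; tier 3 postpones the infusion by
#' `postpone_delay_days`, notifies the patient (`NOTIFY_POSTPONED`) and
#' re-programs questionnaire and laboratory collection for the new date
#' via [schedule_cycle()].
#'
#' @param plan A [cycle_plan()].
#' @param rec A [tier_recommendation()].
#' @param cfg A [scheduling_config()].
#' @return List with `plan` (unchanged, or the re-dated plan on tier 3)
#'   and `events` (list of `scheduled_event`s).
#' @export
on_decision <- function(plan, rec, cfg = scheduling_config()) {
  stopifnot(inherits(plan, "cycle_plan"),
            inherits(rec, "tier_recommendation"))
  tier <- effective_tier(rec)
  if (tier == 1L) {
    list(plan = plan,
         events = list(scheduled_event("NOTIFY_GO",
                                       plan$planned_infusion_date, plan)))
  } else if (tier == 2L) {
    list(plan = plan, events = list())
  } else {
    new_plan <- cycle_plan(plan$patient_id, plan$cycle_number,
                           plan$planned_infusion_date +
                             cfg$postpone_delay_days,
                           plan$regimen_label)
    list(plan = new_plan,
         events = c(list(scheduled_event("NOTIFY_POSTPONED",
                                         plan$planned_infusion_date, plan)),
                    schedule_cycle(new_plan, cfg)))
  }
}

#' Merge near-adjacent treatment reservations
#'
#' When two reservations are booked at once for the same treatment (for
#' example an infusion plus the ambulatory-pump removal two days later),
#' only the earliest should drive questionnaire and laboratory
#' collection. Reservations are clustered transitively: any plan within
#' `reservation_merge_window_days` of the previous one joins its cluster,
#' and every plan after the cluster head is marked as a linked
#' reservation (`linked = TRUE`, `linked_to` = head cycle number) that
#' generates no collection events. Idempotent.
#'
#' @param plans List of [cycle_plan()]s for one patient, sorted by date.
#' @param cfg A [scheduling_config()].
#' @return The plans, each with `linked`/`linked_to` fields set.
#' @export
merge_reservations <- function(plans, cfg = scheduling_config()) {
  if (length(plans) == 0L) return(plans)
  pid <- unique(vapply(plans, function(p) p$patient_id, character(1)))
  if (length(pid) != 1L) {
    stop("merge_reservations expects plans for a single patient",
         call. = FALSE)
  }
  dates <- as.Date(vapply(plans, function(p)
    as.character(p$planned_infusion_date), character(1)))
  if (is.unsorted(dates)) {
    stop("plans must be sorted by planned infusion date", call. = FALSE)
  }
  head_idx <- 1L
  for (i in seq_along(plans)) {
    if (i > 1L &&
        as.integer(dates[i] - dates[i - 1L]) <=
          cfg$reservation_merge_window_days) {
      plans[[i]]$linked <- TRUE
      plans[[i]]$linked_to <- plans[[head_idx]]$cycle_number
    } else {
      head_idx <- i
      plans[[i]]$linked <- FALSE
      plans[[i]]$linked_to <- NULL
    }
  }
  plans
}

#' Collection events for a patient's merged reservations
#'
#' Convenience over [merge_reservations()] + [schedule_cycle()]: only
#' cluster heads generate collection events.
#'
#' @inheritParams merge_reservations
#' @return List of `scheduled_event`s.
#' @export
schedule_reservations <- function(plans, cfg = scheduling_config()) {
  merged <- merge_reservations(plans, cfg)
  heads <- Filter(function(p) !isTRUE(p$linked), merged)
  do.call(c, lapply(heads, schedule_cycle, cfg = cfg))
}
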