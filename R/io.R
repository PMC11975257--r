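# File formats and declarative configuration. JSON is the canonical
# on-disk format (records are nested); CSV is supported for lab panels.

q_to_list <- function(q) {
  if (is.null(q)) return(NULL)
  list(patient_id = q$patient_id,
       completed_on = format(q$completed_on),
       reports = lapply(seq_len(nrow(q$reports)), function(i) {
         list(symptom = q$reports$symptom[i],
              grade = q$reports$grade[i])
       }))
}

q_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  questionnaire(x$patient_id, x$completed_on,
                data.frame(
                  symptom = vapply(x$reports, `[[`, character(1), "symptom"),
                  grade = vapply(x$reports, function(r)
                    as.integer(r$grade), integer(1)),
                  stringsAsFactors = FALSE))
}

panel_to_list <- function(p) {
  if (is.null(p)) return(NULL)
  list(patient_id = p$patient_id,
       sampled_on = format(p$sampled_on),
       results = lapply(seq_len(nrow(p$results)), function(i) {
         list(analyte = p$results$analyte[i],
              value = p$results$value[i])
       }))
}

panel_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  lab_panel(x$patient_id, x$sampled_on,
            data.frame(
              analyte = vapply(x$results, `[[`, character(1), "analyte"),
              value = vapply(x$results, function(r)
                as.numeric(r$value), numeric(1)),
              stringsAsFactors = FALSE))
}

record_to_list <- function(r) {
  list(plan = list(patient_id = r$plan$patient_id,
                   cycle_number = r$plan$cycle_number,
                   planned_infusion_date =
                     format(r$plan$planned_infusion_date),
                   regimen_label = r$plan$regimen_label),
       questionnaire = q_to_list(r$questionnaire),
       panel = panel_to_list(r$panel),
       baseline = q_to_list(r$baseline))
}

record_from_list <- function(x) {
  cycle_record(
    cycle_plan(x$plan$patient_id, x$plan$cycle_number,
               x$plan$planned_infusion_date,
               if (is.null(x$plan$regimen_label)) "" else
                 x$plan$regimen_label),
    questionnaire = q_from_list(x$questionnaire),
    panel = panel_from_list(x$panel),
    baseline = q_from_list(x$baseline))
}

decision_to_list <- function(d) {
  list(tier = d$tier, rationale = as.list(d$rationale),
       overridden_tier = d$overridden_tier,
       override_note = d$override_note,
       flagged_symptoms = as.list(attr(d, "flagged_symptoms")))
}

decision_from_list <- function(x) {
  d <- tier_recommendation(x$tier, vapply(x$rationale, as.character,
                                          character(1)),
                           overridden_tier = x$overridden_tier,
                           override_note = x$override_note)
  if (length(x$flagged_symptoms)) {
    attr(d, "flagged_symptoms") <- vapply(x$flagged_symptoms,
                                          as.character, character(1))
  }
  d
}

#' Write / read a cohort log as JSON
#'
#' Lossless round-trip of a [cohort_log()] including decisions and
#' overrides, with stable field ordering for diffability. Malformed
#' records are reported with their index and the underlying finding;
#' input files are never mutated.
#'
#' @param log A [cohort_log()].
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns
#'   the [cohort_log()].
#' @export
write_cohort <- function(log, path) {
  stopifnot(inherits(log, "cohort_log"))
  x <- list(records = lapply(log$records, record_to_list),
            decisions = if (is.null(log$decisions)) NULL else
              lapply(log$decisions, decision_to_list),
            questionnaires = lapply(log$questionnaires, q_to_list))
  jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  parse_at <- function(items, what, f) {
    lapply(seq_along(items), function(i) {
      tryCatch(f(items[[i]]), error = function(e) {
        stop(what, " ", i, ": ", conditionMessage(e), call. = FALSE)
      })
    })
  }
  records <- parse_at(x$records, "record", record_from_list)
  decisions <- if (is.null(x$decisions)) NULL else
    parse_at(x$decisions, "decision", decision_from_list)
  questionnaires <- if (is.null(x$questionnaires)) NULL else
    parse_at(x$questionnaires, "questionnaire", q_from_list)
  cohort_log(records, decisions, questionnaires)
}

#' Read laboratory panels from CSV
#'
#' Expects columns `patient_id`, `sampled_on`, `analyte`, `value`; rows
#' are grouped into one [lab_panel()] per patient and sampling date.
#'
#' @param path CSV file path.
#' @return List of [lab_panel()] objects.
#' @export
read_lab_panels_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "sampled_on", "analyte", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("lab panel CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(df$patient_id, df$sampled_on, sep = "\r")
  unname(lapply(split(df, key), function(g) {
    lab_panel(g$patient_id[1], g$sampled_on[1],
              data.frame(analyte = g$analyte, value = g$value,
                         stringsAsFactors = FALSE))
  }))
}

#' Write alert events as JSON lines
#'
#' One JSON object per line, the audit-trail format for the urgency
#' algorithm's output.
#'
#' @param alerts List of [alert_event()] objects.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_alerts <- function(alerts, path) {
  lines <- vapply(alerts, function(a) {
    jsonlite::toJSON(list(patient_id = a$patient_id, symptom = a$symptom,
                          grade = a$grade, trigger = a$trigger,
                          raised_on = format(a$raised_on)),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Load the application configuration
#'
#' Reads a YAML or JSON configuration bundling the engine, scheduling,
#' reference-range, catalog and rubric settings, validates it, applies
#' documented defaults for omitted optional fields (each applied default
#' is reported via `message()`), and returns the assembled configuration.
#' Schema violations are collected and reported together, each naming the
#' offending key.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file. The only
#'   mandatory section is `ranges` (per-analyte `low`/`high`/`unit`).
#' @return An object of class `app_config`: list with `engine`
#'   ([engine_config()]), `scheduling` ([scheduling_config()]) and
#'   `rubric` ([grading_rubric()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  violations <- character(0)
  defaults <- character(0)

  if (is.null(raw$ranges)) {
    violations <- c(violations, "ranges: required section is missing")
  } else {
    for (a in lab_analytes()) {
      r <- raw$ranges[[a]]
      if (is.null(r)) {
        violations <- c(violations, paste0("ranges.", a, ": missing"))
      } else {
        lo <- if (is.null(r$low)) -Inf else as.numeric(r$low)
        hi <- if (is.null(r$high)) Inf else as.numeric(r$high)
        if (is.na(lo) || is.na(hi)) {
          violations <- c(violations,
                          paste0("ranges.", a, ": non-numeric bound"))
        } else if (lo > hi) {
          violations <- c(violations, paste0("ranges.", a, ": low > high"))
        }
      }
    }
  }

  get_opt <- function(value, key, default) {
    if (is.null(value)) {
      defaults <<- c(defaults, paste0(key, " = ", paste(default,
                                                        collapse = ",")))
      default
    } else value
  }
  max_age <- get_opt(raw$max_age_days, "max_age_days", 3L)
  if (!is.numeric(max_age) || max_age < 0) {
    violations <- c(violations, "max_age_days: must be >= 0")
  }
  policy <- get_opt(raw$baseline_policy, "baseline_policy",
                    "first_questionnaire")
  if (!policy %in% c("first_questionnaire", "explicit")) {
    violations <- c(violations,
                    "baseline_policy: must be first_questionnaire|explicit")
  }
  exemption <- get_opt(raw$baseline_exemption, "baseline_exemption",
                       "grade_exceeds")
  if (!exemption %in% c("grade_exceeds", "absolute")) {
    violations <- c(violations,
                    "baseline_exemption: must be grade_exceeds|absolute")
  }
  catalog <- get_opt(raw$catalog, "catalog", .default_symptoms)
  catalog <- unlist(catalog)
  if (anyDuplicated(catalog) || length(catalog) == 0) {
    violations <- c(violations, "catalog: must be unique and non-empty")
  }
  sch <- if (is.null(raw$scheduling)) list() else raw$scheduling
  sch_val <- function(key, default) {
    v <- get_opt(sch[[key]], paste0("scheduling.", key), default)
    if (!is.numeric(v) || v < 0) {
      violations <<- c(violations,
                       paste0("scheduling.", key, ": must be >= 0"))
      default
    } else v
  }
  q_lead <- sch_val("questionnaire_lead_days", 3L)
  l_lead <- sch_val("lab_lead_days", 1L)
  delay <- sch_val("postpone_delay_days", 7L)
  window <- sch_val("reservation_merge_window_days", 3L)

  if (length(violations)) {
    stop("invalid configuration:\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  }
  for (d in defaults) message("config default applied: ", d)

  ranges <- reference_ranges(raw$ranges)
  rubric <- if (is.null(raw$rubric) || identical(raw$rubric, "identity")) {
    identity_rubric()
  } else {
    grading_rubric(raw$rubric$rules,
                   identity = isTRUE(raw$rubric$identity))
  }
  structure(
    list(engine = engine_config(max_age_days = max_age, ranges = ranges,
                                catalog = symptom_catalog(catalog),
                                baseline_policy = policy,
                                baseline_exemption = exemption),
         scheduling = scheduling_config(q_lead, l_lead, delay, window),
         rubric = rubric),
    class = "app_config"
  )
}

#' Save an application configuration
#'
#' Writes an [load_config()]-compatible YAML document; `load_config` of
#' the result reproduces the configuration.
#'
#' @param config An `app_config`.
#' @param path Output path (YAML).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "app_config"))
  rg <- config$engine$ranges
  ranges <- stats::setNames(lapply(seq_len(nrow(rg)), function(i) {
    out <- list()
    if (is.finite(rg$low[i])) out$low <- rg$low[i]
    if (is.finite(rg$high[i])) out$high <- rg$high[i]
    out$unit <- rg$unit[i]
    out
  }), rg$analyte)
  doc <- list(
    max_age_days = config$engine$max_age_days,
    baseline_policy = config$engine$baseline_policy,
    baseline_exemption = config$engine$baseline_exemption,
    catalog = as.character(config$engine$catalog),
    ranges = ranges,
    scheduling = unclass(config$scheduling)
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}
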