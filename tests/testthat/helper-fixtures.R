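# Shared builders for unit tests: one patient, one plan, in-range panels.

test_plan <- function(infusion = "2020-05-15", pid = "p01", cycle = 4L) {
  cycle_plan(pid, cycle, infusion, "oxaliplatin doublet")
}

in_range_panel_values <- function() {
  c(rbc = 4.8, wbc = 7, thrombocytes = 250, alt = 25, ast = 25,
    bilirubin = 10, creatinine = 80)
}

test_panel <- function(sampled = "2020-05-14", pid = "p01",
                       overrides = c()) {
  v <- in_range_panel_values()
  v[names(overrides)] <- overrides
  lab_panel(pid, sampled, v)
}

test_q <- function(grades = c(fatigue = 0), completed = "2020-05-14",
                   pid = "p01") {
  questionnaire(pid, completed, grades)
}

# record with labs in range and a fresh, all-clear questionnaire, then
# modified per the named arguments
test_record <- function(questionnaire = test_q(), panel = test_panel(),
                        baseline = NULL, infusion = "2020-05-15") {
  cycle_record(test_plan(infusion), questionnaire, panel, baseline)
}
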