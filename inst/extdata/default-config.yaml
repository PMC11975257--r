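# Default application configuration.
#
# The reference ranges below are illustrative standard adult values with a
# chemotherapy-style thrombocyte floor. They are NOT the bounds used by any
# particular trial or site: deployments must set the limits mandated by the
# regimen's summary of product characteristics and local practice.
max_age_days: 3
baseline_policy: first_questionnaire
baseline_exemption: grade_exceeds
ranges:
  rbc:          {low: 3.5,  high: 6.1,  unit: "10^12/L"}
  wbc:          {low: 3.0,  high: 11.0, unit: "10^9/L"}
  thrombocytes: {low: 100,  high: 400,  unit: "10^9/L"}
  alt:          {low: 0,    high: 50,   unit: "U/L"}
  ast:          {low: 0,    high: 50,   unit: "U/L"}
  bilirubin:    {low: 0,    high: 21,   unit: "umol/L"}
  creatinine:   {low: 40,   high: 120,  unit: "umol/L"}
scheduling:
  questionnaire_lead_days: 3
  lab_lead_days: 1
  postpone_delay_days: 7
  reservation_merge_window_days: 3
rubric: identity
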