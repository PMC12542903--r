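# Closed enumerations used throughout the model. Resource categories mirror
# the six rows of the unit-cost table; keys are fixed so a mis-typed cost row
# fails validation instead of silently dropping out of the dot product.
comorbidity_levels <- c("cardiovascular", "renal", "bone", "neuropsychiatric")
cohort_levels <- c("recent", "longstanding")
resource_levels <- c(
  "hospital_admissions", "diagnostic_tests", "ed_visits",
  "outpatient_visits", "hiv_visits", "blood_tests"
)
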