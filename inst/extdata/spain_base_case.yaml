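schema_version: 1
update_rule: at_risk
population:
  national_population: 48610287.707061901688576
  hiv_prevalence: 0.0031
  diagnosed_fraction: 0.925
  recent_fraction: 0.396
  annual_mortality: 0.0207
cohorts:
- cohort: recent
  size_baseline: 55198.440000000002328
  mean_age_baseline: 34.0
- cohort: longstanding
  size_baseline: 84191.559999999997672
  mean_age_baseline: 48.0
epi:
- comorbidity: cardiovascular
  cohort: recent
  baseline_prevalence: 0.04800811608906
  incidence_young: 0.007646199519513
  incidence_old: 0.007646199519513
  age_threshold: 50.0
  annual_incidence_reduction: 0.01
- comorbidity: cardiovascular
  cohort: longstanding
  baseline_prevalence: 0.171001995438997
  incidence_young: 0.03594117765897
  incidence_old: 0.03594117765897
  age_threshold: 50.0
  annual_incidence_reduction: 0.01
- comorbidity: renal
  cohort: recent
  baseline_prevalence: 0.023007663182304
  incidence_young: 0.003772379393922
  incidence_old: 0.003772379393922
  age_threshold: 50.0
  annual_incidence_reduction: 0.01
- comorbidity: renal
  cohort: longstanding
  baseline_prevalence: 0.077002565564424
  incidence_young: 0.013253651355626
  incidence_old: 0.013253651355626
  age_threshold: 50.0
  annual_incidence_reduction: 0.01
- comorbidity: bone
  cohort: recent
  baseline_prevalence: 0.06900487327669
  incidence_young: 0.013701774558285
  incidence_old: 0.013701774558285
  age_threshold: 50.0
  annual_incidence_reduction: 0.01
- comorbidity: bone
  cohort: longstanding
  baseline_prevalence: 0.165003800836184
  incidence_young: 0.030089297360973
  incidence_old: 0.030089297360973
  age_threshold: 50.0
  annual_incidence_reduction: 0.01
- comorbidity: neuropsychiatric
  cohort: recent
  baseline_prevalence: 0.04500081523216
  incidence_young: 0.009132145292824
  incidence_old: 0.009132145292824
  age_threshold: 50.0
  annual_incidence_reduction: 0.01
- comorbidity: neuropsychiatric
  cohort: longstanding
  baseline_prevalence: 0.16299648422653
  incidence_young: 0.021337601909181
  incidence_old: 0.021337601909181
  age_threshold: 50.0
  annual_incidence_reduction: 0.01
resource_use:
- comorbidity: bone
  resource: hospital_admissions
  quantity: 0.32
- comorbidity: bone
  resource: diagnostic_tests
  quantity: 3.23
- comorbidity: bone
  resource: ed_visits
  quantity: 0.8
- comorbidity: bone
  resource: outpatient_visits
  quantity: 1.3
- comorbidity: bone
  resource: hiv_visits
  quantity: 2.9
- comorbidity: bone
  resource: blood_tests
  quantity: 7.85
- comorbidity: cardiovascular
  resource: hospital_admissions
  quantity: 0.63
- comorbidity: cardiovascular
  resource: diagnostic_tests
  quantity: 3.88
- comorbidity: cardiovascular
  resource: ed_visits
  quantity: 1.31
- comorbidity: cardiovascular
  resource: outpatient_visits
  quantity: 1.62
- comorbidity: cardiovascular
  resource: hiv_visits
  quantity: 3.21
- comorbidity: cardiovascular
  resource: blood_tests
  quantity: 9.199999999999999
- comorbidity: neuropsychiatric
  resource: hospital_admissions
  quantity: 0.83
- comorbidity: neuropsychiatric
  resource: diagnostic_tests
  quantity: 4.24
- comorbidity: neuropsychiatric
  resource: ed_visits
  quantity: 1.95
- comorbidity: neuropsychiatric
  resource: outpatient_visits
  quantity: 1.67
- comorbidity: neuropsychiatric
  resource: hiv_visits
  quantity: 3.02
- comorbidity: neuropsychiatric
  resource: blood_tests
  quantity: 8.43
- comorbidity: renal
  resource: hospital_admissions
  quantity: 0.84
- comorbidity: renal
  resource: diagnostic_tests
  quantity: 4.6
- comorbidity: renal
  resource: ed_visits
  quantity: 1.98
- comorbidity: renal
  resource: outpatient_visits
  quantity: 1.72
- comorbidity: renal
  resource: hiv_visits
  quantity: 3.06
- comorbidity: renal
  resource: blood_tests
  quantity: 8.640000000000001
unit_costs:
- resource: hospital_admissions
  unit_cost: 4669.0
  origin_year: 2024.0
- resource: diagnostic_tests
  unit_cost: 157.22999999999999
  origin_year: 2024.0
- resource: ed_visits
  unit_cost: 225.930000000000007
  origin_year: 2024.0
- resource: outpatient_visits
  unit_cost: 158.210000000000008
  origin_year: 2024.0
- resource: hiv_visits
  unit_cost: 158.210000000000008
  origin_year: 2024.0
- resource: blood_tests
  unit_cost: 30.960000000000001
  origin_year: 2024.0
cpi:
- year: 2024.0
  index: 100.0
econ:
  discount_rate: 0.03
  base_year: 2024.0
  horizon_start: 2024.0
  horizon_end: 2034.0
scenarios:
- scenario: cardiovascular_darunavir
  source: expert
  cohort: recent
  comorbidity: cardiovascular
  delta_pp: 1.13
- scenario: cardiovascular_darunavir
  source: expert
  cohort: longstanding
  comorbidity: cardiovascular
  delta_pp: 1.88
- scenario: renal_tenofovir_disoproxil
  source: expert
  cohort: recent
  comorbidity: renal
  delta_pp: 2.93
- scenario: renal_tenofovir_disoproxil
  source: expert
  cohort: longstanding
  comorbidity: renal
  delta_pp: 7.23
- scenario: bone_tenofovir_disoproxil
  source: expert
  cohort: recent
  comorbidity: bone
  delta_pp: 2.38
- scenario: bone_tenofovir_disoproxil
  source: expert
  cohort: longstanding
  comorbidity: bone
  delta_pp: 4.66
- scenario: neuropsychiatric_dolutegravir_expert
  source: expert
  cohort: recent
  comorbidity: neuropsychiatric
  delta_pp: 1.88
- scenario: neuropsychiatric_dolutegravir_expert
  source: expert
  cohort: longstanding
  comorbidity: neuropsychiatric
  delta_pp: 2.05
- scenario: neuropsychiatric_bictegravir_expert
  source: expert
  cohort: recent
  comorbidity: neuropsychiatric
  delta_pp: 1.25
- scenario: neuropsychiatric_bictegravir_expert
  source: expert
  cohort: longstanding
  comorbidity: neuropsychiatric
  delta_pp: 2.0
- scenario: neuropsychiatric_dolutegravir_literature
  source: literature
  cohort: recent
  comorbidity: neuropsychiatric
  delta_pp: 2.58
- scenario: neuropsychiatric_dolutegravir_literature
  source: literature
  cohort: longstanding
  comorbidity: neuropsychiatric
  delta_pp: 2.58
- scenario: neuropsychiatric_bictegravir_literature
  source: literature
  cohort: recent
  comorbidity: neuropsychiatric
  delta_pp: 0.7
- scenario: neuropsychiatric_bictegravir_literature
  source: literature
  cohort: longstanding
  comorbidity: neuropsychiatric
  delta_pp: 0.7
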