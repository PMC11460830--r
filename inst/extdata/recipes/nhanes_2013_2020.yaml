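# Recode recipe: pooled 2013-March 2020 NHANES public-use files
# (demographics + diabetes questionnaire + glycohemoglobin + plasma
# glucose, merged on SEQN and pre-converted to CSV).  Multi-cycle weights
# must be pre-pooled by the user (e.g. divided by the number of cycles, or
# the special pre-pandemic weights); cycle-combination rules vary by
# analyte and are deliberately not automated here -- see the NHANES
# analytic guidelines.
source: nhanes_2013_2020
design:
  weight: WTMECPRP     # pooled examination weight, supplied pre-combined
  stratum: SDMVSTRA
  psu: SDMVPSU
filters:
  age_min: 18
  age_max: 44
on_unknown: drop
variables:
  age:
    source: RIDAGEYR
  diabetes:
    # self-reported prior diagnosis OR elevated labs; set mode: self_report
    # for the sensitivity analysis using self-report alone
    mode: self_or_lab
    self_report:
      source: DIQ010
      yes_codes: [1]
      no_codes: [2, 3]   # 3 = borderline counts as no prior diagnosis
      missing_codes: [7, 9]
    a1c:
      source: LBXGH
      threshold: 6.5
    glucose:
      source: LBXGLU
      threshold: 126
  asthma:
    source: MCQ010
    yes_codes: [1]
    no_codes: [2]
    missing_codes: [7, 9]
  obesity:
    mode: bmi
    source: BMXBMI      # measured BMI
    scale: 1
  sex:
    source: RIAGENDR
    male_codes: [1]
    female_codes: [2]
  race:
    source: RIDRETH3
    map:
      Latino: [1, 2]
      White: [3]
      Black: [4]
      Asian: [6]
      Other: [7]
  insurance:
    source: HIQ011      # any health insurance coverage
    yes_codes: [1]
    no_codes: [2]
  income:
    source: INDFMPIR    # family income / poverty threshold ratio
    map: {}             # recoded by pir_breaks instead of a code map
    pir_breaks: [1.3, 3.5]
    pir_labels: ["<=130%", "130-350%", ">350%"]
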