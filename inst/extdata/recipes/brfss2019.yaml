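# Recode recipe: 2019 BRFSS public-use file (pre-converted to CSV).
# Column names follow the BRFSS codebook; leading underscores in BRFSS
# variable names (e.g. _LLCPWT) are assumed converted to X_LLCPWT by the
# CSV import, the R default for syntactically invalid names.
source: brfss2019
design:
  weight: X_LLCPWT
  stratum: X_STSTR
  psu: X_PSU
filters:
  age_min: 18
  age_max: 44
  # "in care": reported having at least one personal health care provider
  in_care:
    source: PERSDOC2
    yes_codes: [1, 2]
on_unknown: drop     # 7 = don't know, 9 = refused -> dropped with a log entry
variables:
  age:
    source: X_AGE80
  diabetes:
    mode: self_report
    self_report:
      source: DIABETE4
      yes_codes: [1]
      # 2 = yes, pregnancy-only; 3 = no; 4 = prediabetes
      no_codes: [2, 3, 4]
      missing_codes: [7, 9]
  asthma:
    source: ASTHMA3
    yes_codes: [1]
    no_codes: [2]
    missing_codes: [7, 9]
  obesity:
    mode: bmi
    source: X_BMI5      # BMI x 100, self-reported height/weight
    scale: 100
  sex:
    source: X_SEX
    male_codes: [1]
    female_codes: [2]
  race:
    source: X_RACE
    map:
      White: [1]
      Black: [2]
      Asian: [4]
      Latino: [8]
      Other: [3, 5, 6, 7]
  insurance:
    source: HLTHPLN1
    yes_codes: [1]
    no_codes: [2]
  income:
    source: INCOME2
    map:
      "<50k": [1, 2, 3, 4, 5, 6]
      "50-<75k": [7]
      ">=75k": [8]
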