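# Independent oracles and fixture builders shared across the suite.

# Direct transcription of the diabetes phenotype rule, evaluated on raw
# per-patient event vectors (no shared code with classify_diabetes).
dm_rule_bruteforce <- function(dx_encounter_ids, a1c_values, n_core_meds) {
  (length(unique(dx_encounter_ids)) >= 2) ||
    (length(dx_encounter_ids) >= 1 && sum(a1c_values >= 6.5) >= 2) ||
    (n_core_meds >= 1)
}

asthma_rule_bruteforce <- function(dx_encounter_ids, n_asthma_meds) {
  (length(unique(dx_encounter_ids)) >= 2) || (n_asthma_meds >= 2)
}

# Single-patient event tables from compact descriptions.
one_patient_events <- function(dm_dx_enc = integer(), asthma_dx_enc = integer(),
                               a1c = numeric(), meds = character(),
                               n_encounters = 6) {
  list(
    diagnoses = data.frame(
      patient_id = rep(1L, length(dm_dx_enc) + length(asthma_dx_enc)),
      encounter_index = c(dm_dx_enc, asthma_dx_enc),
      condition = rep(c("diabetes", "asthma"),
                      c(length(dm_dx_enc), length(asthma_dx_enc)))),
    labs = data.frame(patient_id = rep(1L, length(a1c)),
                      lab_type = rep("a1c", length(a1c)), value = a1c),
    medications = data.frame(patient_id = rep(1L, length(meds)),
                             med_class = meds),
    encounters = data.frame(patient_id = rep(1L, n_encounters),
                            encounter_index = seq_len(n_encounters) - 1L,
                            is_routine_exam = FALSE,
                            has_endo_ros = FALSE, has_resp_ros = FALSE))
}

# Exhaustive log-likelihood grid around a fitted optimum (2-parameter fit).
loglik_logistic <- function(beta, x, y) {
  p <- plogis(as.vector(x %*% beta))
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# Small analysis-table-like frame with known covariates for direct fits.
fake_analysis_table <- function(n, seed = 1) {
  set.seed(seed)
  tab <- data.frame(
    patient_id = seq_len(n),
    age = runif(n, 18, 44),
    sex = factor(sample(c("female", "male"), n, TRUE),
                 levels = c("female", "male")),
    race_eth = factor(sample(c("White", "Black", "Latino", "Asian", "Other"),
                             n, TRUE, prob = c(.5, .15, .2, .1, .05)),
                      levels = c("White", "Black", "Latino", "Asian", "Other")),
    medicaid = runif(n) < 0.25,
    neighborhood_id = sample(1:12, n, TRUE),
    poverty_stratum = factor(sample(c("<10%", "10-<20%", "20-<30%", ">=30%"),
                                    n, TRUE),
                             levels = c("<10%", "10-<20%", "20-<30%", ">=30%")),
    duration = runif(n, 0, 4),
    total_encounters = rnbinom(n, size = 1, mu = 8) + 1L,
    any_routine_exam = runif(n) < 0.3,
    any_dm_lab = runif(n) < 0.4,
    obese_star = runif(n) < 0.2,
    stringsAsFactors = FALSE)
  tab$race_eth_observed <- tab$race_eth
  tab
}

# Synthetic raw survey extracts shaped like the public files the shipped
# recipes expect (synthetic stand-ins; no real survey records).
synthetic_brfss_raw <- function(n = 800, seed = 7) {
  set.seed(seed)
  data.frame(
    X_LLCPWT = runif(n, 100, 5000),
    X_STSTR = sample(1:6, n, TRUE),
    X_PSU = sample(1:500, n, TRUE),
    X_AGE80 = sample(18:80, n, TRUE),
    PERSDOC2 = sample(c(1, 2, 3, 7, 9), n, TRUE, prob = c(.5, .2, .25, .03, .02)),
    DIABETE4 = sample(c(1, 2, 3, 4, 7, 9), n, TRUE,
                      prob = c(.13, .02, .78, .04, .02, .01)),
    ASTHMA3 = sample(c(1, 2, 7, 9), n, TRUE, prob = c(.12, .85, .02, .01)),
    X_BMI5 = round(runif(n, 1800, 4500)),
    X_SEX = sample(1:2, n, TRUE),
    X_RACE = sample(c(1:8), n, TRUE, prob = c(.55, .12, .02, .06, .02, .02, .03, .18)),
    HLTHPLN1 = sample(c(1, 2), n, TRUE, prob = c(.88, .12)),
    INCOME2 = sample(1:8, n, TRUE))
}

synthetic_nhanes_raw <- function(n = 600, seed = 11) {
  set.seed(seed)
  data.frame(
    WTMECPRP = runif(n, 2000, 90000),
    SDMVSTRA = sample(130:140, n, TRUE),
    SDMVPSU = sample(1:2, n, TRUE),
    RIDAGEYR = sample(12:79, n, TRUE),
    DIQ010 = sample(c(1, 2, 3, 7, 9), n, TRUE, prob = c(.07, .88, .03, .01, .01)),
    LBXGH = round(runif(n, 4.5, 9.5), 1),
    LBXGLU = round(runif(n, 70, 220)),
    MCQ010 = sample(c(1, 2, 7, 9), n, TRUE, prob = c(.13, .84, .02, .01)),
    BMXBMI = round(runif(n, 17, 45), 1),
    RIAGENDR = sample(1:2, n, TRUE),
    RIDRETH3 = sample(c(1, 2, 3, 4, 6, 7), n, TRUE),
    HIQ011 = sample(c(1, 2), n, TRUE, prob = c(.8, .2)),
    INDFMPIR = round(runif(n, 0, 5), 2))
}

# Small configs keep the unit suites fast; acceptance uses full sizes.
small_config <- function(n = 2000, seed = 1, ...) {
  ehr_config(n_patients = n, seed = seed, ...)
}
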