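#' Rule-based computable phenotype for diabetes
#'
#' A patient satisfies the diabetes phenotype (`dm_star`) iff any of:
#' \itemize{
#'   \item at least 2 diabetes encounter diagnoses on distinct encounters;
#'   \item at least 1 diabetes encounter diagnosis and at least 2 elevated
#'     A1c results (>= 6.5, boundary inclusive);
#'   \item at least 1 antidiabetes prescription from the core class
#'     (metformin and acarbose do not count).
#' }
#' Glucose labs never enter this rule (they only feed the `any_dm_lab`
#' utilization summary).  Duplicate diagnosis rows on the same encounter
#' count once; whether distinct encounters are required is configurable via
#' `distinct_encounters`.
#'
#' @param diagnoses,labs,medications event tables in the
#'   [generate_events()] schema (any subset of patients).
#' @param patient_ids vector of patient ids defining the output order; ids
#'   with no events classify as `FALSE`.
#' @param a1c_threshold elevated-A1c cutoff, default 6.5.
#' @param distinct_encounters require the 2 diagnoses to fall on distinct
#'   encounters (default `TRUE`).
#' @return logical vector aligned with `patient_ids`.
#' @export
classify_diabetes <- function(diagnoses, labs, medications, patient_ids,
                              a1c_threshold = 6.5,
                              distinct_encounters = TRUE) {
  idx <- function(ids) match(ids, patient_ids)
  np <- length(patient_ids)

  dx <- diagnoses[diagnoses$condition == "diabetes", , drop = FALSE]
  if (distinct_encounters)
    dx <- unique(dx[, c("patient_id", "encounter_index")])
  n_dx <- tabulate(idx(dx$patient_id), nbins = np)

  elev <- labs[labs$lab_type == "a1c" & labs$value >= a1c_threshold, ,
               drop = FALSE]
  n_a1c <- tabulate(idx(elev$patient_id), nbins = np)

  core <- medications[medications$med_class == "antidiabetes_core", ,
                      drop = FALSE]
  n_med <- tabulate(idx(core$patient_id), nbins = np)

  n_dx >= 2 | (n_dx >= 1 & n_a1c >= 2) | n_med >= 1
}

#' Rule-based computable phenotype for asthma
#'
#' True iff at least 2 asthma encounter diagnoses on distinct encounters,
#' or at least 2 asthma-medication prescriptions.  One diagnosis plus one
#' prescription does not qualify: the rule is a disjunction of two
#' independent >=2 counts.
#'
#' @inheritParams classify_diabetes
#' @return logical vector aligned with `patient_ids`.
#' @export
classify_asthma <- function(diagnoses, medications, patient_ids,
                            distinct_encounters = TRUE) {
  idx <- function(ids) match(ids, patient_ids)
  np <- length(patient_ids)
  dx <- diagnoses[diagnoses$condition == "asthma", , drop = FALSE]
  if (distinct_encounters)
    dx <- unique(dx[, c("patient_id", "encounter_index")])
  n_dx <- tabulate(idx(dx$patient_id), nbins = np)
  med <- medications[medications$med_class == "asthma_med", , drop = FALSE]
  n_med <- tabulate(idx(med$patient_id), nbins = np)
  n_dx >= 2 | n_med >= 2
}

#' Computable phenotype for obesity
#'
#' True iff BMI is recorded and >= 30 kg/m2 (boundary inclusive).  Missing
#' BMI classifies as non-obese -- deliberately no correction, matching how
#' rule-based phenotypes treat absent evidence as absence of disease.
#'
#' @param bmi numeric vector, `NA` when unrecorded.
#' @return logical vector.
#' @export
classify_obesity <- function(bmi) {
  !is.na(bmi) & bmi >= 30
}

#' Registered data-sufficiency definitions
#'
#' `default`: at least one encounter with an endocrinology review of
#' systems, or classified diabetic (so `dm_star` implies sufficiency).
#' Sensitivity-analysis variants widen (`or_*`) or tighten (`and_dm_lab`)
#' the review-of-systems arm with evidence tied to the other phenotypes;
#' every variant keeps the `dm_star` disjunct, preserving the
#' near-perfect-specificity assumption that classified diabetics are
#' observed.
#'
#' @return character vector of known `definition_id`s.
#' @export
sufficiency_definitions <- function() {
  c("default", "or_dm_lab", "or_bmi", "or_resp_ros", "and_dm_lab")
}

#' Flag patients with sufficient data
#'
#' @param encounters encounter table (needs `has_endo_ros`, and
#'   `has_resp_ros` for the respiratory variant).
#' @param dm_star logical vector of diabetes phenotype, aligned with
#'   `patient_ids`.
#' @param patient_ids patient id vector defining output order.
#' @param definition_id one of [sufficiency_definitions()].
#' @param any_dm_lab,bmi_recorded per-patient logicals, required by the
#'   corresponding variants.
#' @return logical vector `sufficient`, aligned with `patient_ids`.
#' @export
flag_sufficiency <- function(encounters, dm_star, patient_ids,
                             definition_id = "default",
                             any_dm_lab = NULL, bmi_recorded = NULL) {
  if (!definition_id %in% sufficiency_definitions())
    stop("unknown sufficiency definition_id: '", definition_id, "'",
         call. = FALSE)
  np <- length(patient_ids)
  any_flag <- function(col) {
    hit <- encounters[encounters[[col]], "patient_id"]
    tabulate(match(hit, patient_ids), nbins = np) > 0
  }
  endo <- any_flag("has_endo_ros")
  switch(definition_id,
    default = endo | dm_star,
    or_dm_lab = {
      if (is.null(any_dm_lab)) stop("any_dm_lab required for 'or_dm_lab'")
      endo | any_dm_lab | dm_star
    },
    or_bmi = {
      if (is.null(bmi_recorded)) stop("bmi_recorded required for 'or_bmi'")
      endo | bmi_recorded | dm_star
    },
    or_resp_ros = endo | any_flag("has_resp_ros") | dm_star,
    and_dm_lab = {
      if (is.null(any_dm_lab)) stop("any_dm_lab required for 'and_dm_lab'")
      (endo & any_dm_lab) | dm_star
    })
}

#' Build the per-patient analysis table
#'
#' Collapses an [generate_dataset()] bundle (or user-supplied tables in the
#' same schema) to one row per patient: demographics, utilization summaries
#' (`total_encounters`, `duration`, `any_routine_exam`, `any_dm_lab` over
#' A1c and both glucose types), the observed phenotypes (`dm_star`,
#' `asthma_star`, `obese_star`), the sufficiency flag `sufficient`, and --
#' when the bundle carries them -- the generator's hidden true states for
#' recovery checks.  `race_eth` is the analysis race variable: observed
#' where present, otherwise imputed by a single draw from the known
#' neighborhood-conditional distribution (a deliberate stand-in for
#' surname-based imputation); the draw is seeded from the dataset
#' configuration so the table is deterministic given the dataset.
#'
#' @param dataset an `ehr_dataset` (or a list with the same table names).
#' @param sufficiency a `definition_id` from [sufficiency_definitions()].
#' @return `data.frame` of class `analysis_table`, one row per patient.
#' @export
build_analysis_table <- function(dataset, sufficiency = "default") {
  pts <- dataset$patients
  np <- nrow(pts)
  ids <- pts$patient_id
  if (anyDuplicated(ids)) stop("duplicate patient_id in patients table")

  enc <- dataset$encounters
  if (anyDuplicated(enc[, c("patient_id", "encounter_index")]))
    stop("encounter_index not unique within patient")
  check_ref <- function(tb, nm) {
    if (nrow(tb) == 0) return(invisible())
    key <- paste(tb$patient_id, tb$encounter_index)
    ek <- paste(enc$patient_id, enc$encounter_index)
    if (!all(key %in% ek))
      stop(nm, " table references encounters that do not exist")
  }
  check_ref(dataset$diagnoses, "diagnoses")

  total_encounters <- tabulate(match(enc$patient_id, ids), nbins = np)
  any_routine <- tabulate(match(enc$patient_id[enc$is_routine_exam], ids),
                          nbins = np) > 0
  any_dm_lab <- tabulate(match(dataset$labs$patient_id, ids), nbins = np) > 0

  dm_star <- classify_diabetes(dataset$diagnoses, dataset$labs,
                               dataset$medications, ids)
  asthma_star <- classify_asthma(dataset$diagnoses, dataset$medications, ids)
  obese_star <- classify_obesity(pts$bmi)
  sufficient <- flag_sufficiency(enc, dm_star, ids,
                                 definition_id = sufficiency,
                                 any_dm_lab = any_dm_lab,
                                 bmi_recorded = !is.na(pts$bmi))

  tab <- data.frame(
    patient_id = ids,
    age = pts$age, sex = pts$sex,
    race_eth_observed = pts$race_eth_observed,
    medicaid = pts$medicaid,
    neighborhood_id = pts$neighborhood_id,
    poverty_stratum = pts$poverty_stratum,
    bmi = pts$bmi,
    duration = pts$duration,
    total_encounters = total_encounters,
    any_routine_exam = any_routine,
    any_dm_lab = any_dm_lab,
    dm_star = dm_star,
    asthma_star = asthma_star,
    obese_star = obese_star,
    sufficient = sufficient,
    stringsAsFactors = FALSE)

  tab$race_eth <- impute_race(pts, dataset$neighborhoods,
                              seed = dataset$config$seed)
  for (nm in c("true_diabetes", "true_asthma", "true_obesity",
               "race_eth_true"))
    if (!is.null(pts[[nm]])) tab[[nm]] <- pts[[nm]]
  attr(tab, "sufficiency_definition") <- sufficiency
  class(tab) <- c("analysis_table", "data.frame")
  tab
}

# Known-probability surrogate for surname/geocoding race imputation: missing
# race is drawn once from the generator's neighborhood-level distribution.
impute_race <- function(patients, neighborhoods, seed = NULL) {
  race <- patients$race_eth_observed
  miss <- is.na(race)
  if (!any(miss)) return(race)
  if (is.null(neighborhoods) || is.null(neighborhoods$race_probs)) {
    # fall back to the observed marginal distribution
    pr <- prop.table(table(race[!miss]))
    probs <- matrix(as.numeric(pr), nrow = sum(miss), ncol = length(pr),
                    byrow = TRUE)
    lv <- names(pr)
  } else {
    probs <- neighborhoods$race_probs[patients$neighborhood_id[miss], ,
                                      drop = FALSE]
    lv <- colnames(neighborhoods$race_probs)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed((seed + 1000003L) %% .Machine$integer.max)
  }
  race[miss] <- factor(lv[draw_categorical(probs)], levels = levels(race))
  race
}
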