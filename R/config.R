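#' Generator configuration for synthetic EHR populations
#'
#' Builds and validates the configuration object consumed by
#' [generate_population()], [generate_events()] and [generate_dataset()].
#' The defaults encode an in-care urban young-adult population (ages 18-44)
#' in which both informed-presence bias (chronic disease raises the
#' encounter rate, and every encounter is an opportunity for the disease to
#' be coded) and diagnostic-suspicion bias (subgroup-differential lab
#' screening) are active.  All true parameters are retained so that
#' estimator recovery can be checked against known truth.
#'
#' Baseline prevalences are interpreted at the reference covariate pattern
#' (White, female, age 31, non-Medicaid, lowest poverty stratum, no
#' comorbidity); marginal prevalences are higher once the log odds ratios
#' are applied.
#'
#' @param n_patients number of patients to simulate.
#' @param seed integer RNG seed stored with the configuration.
#' @param baseline_prevalence named list with elements `diabetes`, `asthma`,
#'   `obesity`, each a probability in (0,1) at the reference pattern.
#' @param true_log_or named list of named numeric vectors giving the
#'   log odds ratios of the true-disease logistic models (see
#'   [default_true_log_or()] for the recognised coefficient names, which
#'   include the obesity->diabetes and asthma->diabetes effects).
#' @param encounter_model list: `mean` and `size` of the negative-binomial
#'   encounter count, `min_encounters` floor (an in-care sample has at
#'   least one encounter), and `log_mult`, named log-scale multipliers on
#'   the encounter mean for `diabetes`, `asthma`, `male`, `age` (per year,
#'   centered at 31) and `medicaid`.
#' @param documentation_model list of per-encounter documentation
#'   probabilities: `p_diabetes_dx`, `p_asthma_dx` (diagnosis coding given
#'   true disease -- the false-negative driver), `p_dm_lab` with `lab_mult`
#'   subgroup multipliers (diagnostic suspicion), `p_endo_ros`,
#'   `p_resp_ros`, `p_routine`, `p_bmi`, and medication dispensing
#'   probabilities `p_dm_med_core`, `p_dm_med_metformin`,
#'   `p_metformin_nondm`, `p_asthma_med`.
#' @param lab_value_model list: A1c mean/SD conditional on true diabetes
#'   (`a1c_mean_dm`, `a1c_sd_dm`, `a1c_mean_nondm`, `a1c_sd_nondm`),
#'   truncated below at 3.
#' @param missing_race_prob probability race/ethnicity is unrecorded.
#' @param missing_race_enc_coef optional log-odds coefficient of
#'   `log1p(encounters)` (centered) on race missingness; 0 means missing
#'   completely at random.
#' @param n_neighborhoods number of neighborhood (PUMA-like) clusters.
#' @param neighborhood_effects list with `suff_sd`, the SD of the
#'   neighborhood random intercept on the per-encounter endocrinology
#'   review-of-systems log odds (the sufficiency propensity).
#' @param demographics list of population composition parameters:
#'   `p_male`, `age_range`, `max_duration_years`, `poverty_probs` (the four
#'   neighborhood poverty strata), `race_city` (city-wide race/ethnicity
#'   distribution), `race_concentration` (Dirichlet concentration for
#'   neighborhood-level race mixes; smaller = more segregated), and
#'   `medicaid_by_poverty` (Medicaid probability per poverty stratum).
#'
#' @return an object of class `ehr_config` (a validated named list).
#' @seealso [config_no_misclassification()], [write_ehr_config()]
#' @export
ehr_config <- function(n_patients = 20000,
                       seed = 1L,
                       baseline_prevalence = list(diabetes = 0.018,
                                                  asthma = 0.08,
                                                  obesity = 0.15),
                       true_log_or = default_true_log_or(),
                       encounter_model = list(
                         mean = 13, size = 0.5, min_encounters = 1,
                         log_mult = c(diabetes = log(1.9), asthma = log(1.4),
                                      male = log(0.85), age = 0.01,
                                      medicaid = 0)),
                       documentation_model = list(
                         p_diabetes_dx = 0.08, p_asthma_dx = 0.08,
                         p_dm_lab = 0.06,
                         lab_mult = c(Black = 1.3, Latino = 1.3, Asian = 0.8,
                                      Other = 1.0, obesity = 2.0),
                         p_endo_ros = 0.06, p_resp_ros = 0.06,
                         p_routine = 0.025, p_bmi = 0.30,
                         p_dm_med_core = 0.03, p_dm_med_metformin = 0.04,
                         p_metformin_nondm = 0.003, p_asthma_med = 0.10),
                       lab_value_model = list(a1c_mean_dm = 7.5, a1c_sd_dm = 1.0,
                                              a1c_mean_nondm = 5.4,
                                              a1c_sd_nondm = 0.4),
                       missing_race_prob = 0.19,
                       missing_race_enc_coef = 0,
                       n_neighborhoods = 40,
                       neighborhood_effects = list(suff_sd = 0.3),
                       demographics = list(
                         p_male = 0.38,
                         age_range = c(18, 44),
                         max_duration_years = 4,
                         poverty_probs = c(0.175, 0.317, 0.359, 0.149),
                         race_city = c(White = 0.521, Black = 0.127,
                                       Latino = 0.191, Asian = 0.108,
                                       Other = 0.053),
                         race_concentration = 8,
                         medicaid_by_poverty = c(0.12, 0.18, 0.25, 0.35))) {
  cfg <- list(n_patients = n_patients,
              seed = seed,
              baseline_prevalence = baseline_prevalence,
              true_log_or = true_log_or,
              encounter_model = encounter_model,
              documentation_model = documentation_model,
              lab_value_model = lab_value_model,
              missing_race_prob = missing_race_prob,
              missing_race_enc_coef = missing_race_enc_coef,
              n_neighborhoods = n_neighborhoods,
              neighborhood_effects = neighborhood_effects,
              demographics = demographics)
  cfg <- normalize_ehr_config(cfg)
  validate_ehr_config(cfg)
  class(cfg) <- "ehr_config"
  cfg
}

#' Default true-disease log odds ratios
#'
#' Named coefficient vectors for the three true-disease logistic models.
#' Recognised names: `Black`, `Latino`, `Asian`, `Other` (vs White),
#' `age` (per year, centered at 31), `male` (vs female), `medicaid`,
#' `poverty10`, `poverty20`, `poverty30` (vs the `<10%` stratum), and for
#' diabetes additionally `obesity` and `asthma` -- the conditional
#' asthma-diabetes odds ratio that estimators are asked to recover is
#' `exp(true_log_or$diabetes["asthma"])`, 1.4 by default.
#'
#' @return named list with elements `diabetes`, `asthma`, `obesity`.
#' @export
default_true_log_or <- function() {
  list(
    diabetes = c(Black = log(1.8), Latino = log(1.8), Asian = log(1.4),
                 Other = log(1.2), age = 0.06, male = log(1.15),
                 medicaid = log(1.3), poverty10 = log(1.1),
                 poverty20 = log(1.2), poverty30 = log(1.3),
                 obesity = log(3.0), asthma = log(1.4)),
    asthma = c(Black = log(1.8), Latino = log(1.5), Asian = log(0.8),
               Other = log(1.1), age = 0, male = log(0.8),
               medicaid = log(1.3), poverty10 = log(1.1),
               poverty20 = log(1.2), poverty30 = log(1.4)),
    obesity = c(Black = log(1.8), Latino = log(1.6), Asian = log(0.5),
                Other = log(1.2), age = 0.02, male = log(0.9),
                medicaid = log(1.4), poverty10 = log(1.2),
                poverty20 = log(1.4), poverty30 = log(1.6))
  )
}

#' A configuration with no outcome misclassification
#'
#' Returns a copy of `config` in which every per-encounter documentation
#' probability is 1, every patient has at least two encounters (so each
#' true case can accumulate the two diagnosis codes the phenotype
#' requires), BMI is always recorded, race/ethnicity is fully observed,
#' and utilization is independent of disease and of every covariate (all
#' encounter multipliers and the neighborhood sufficiency intercept SD set
#' to 0).  Under this configuration the observed phenotypes equal the true
#' disease states and the probability that a non-case is flagged
#' sufficient is the same for everyone, so restriction or weighting by
#' sufficiency shifts only the intercept: all four estimators target the
#' same conditional odds ratio -- the reference scenario for
#' parameter-recovery checks.
#'
#' @param config an `ehr_config`; defaults to `ehr_config()`.
#' @return an `ehr_config`.
#' @export
config_no_misclassification <- function(config = ehr_config()) {
  dm <- config$documentation_model
  dm$p_diabetes_dx <- 1
  dm$p_asthma_dx <- 1
  dm$p_bmi <- 1
  config$documentation_model <- dm
  config$encounter_model$min_encounters <- 2L
  config$encounter_model$log_mult[] <- 0
  config$neighborhood_effects$suff_sd <- 0
  config$missing_race_prob <- 0
  config$missing_race_enc_coef <- 0
  validate_ehr_config(config)
  config
}

# yaml round-trips named numeric vectors as lists; coerce the known
# vector-valued fields back so that read(write(cfg)) is lossless.
normalize_ehr_config <- function(cfg) {
  num_vec <- function(x) {
    if (is.null(x)) return(NULL)
    out <- unlist(x)
    storage.mode(out) <- "double"
    out
  }
  cfg$n_patients <- as.integer(cfg$n_patients)
  cfg$seed <- as.integer(cfg$seed)
  cfg$baseline_prevalence <- lapply(cfg$baseline_prevalence, as.numeric)
  cfg$true_log_or <- lapply(cfg$true_log_or, num_vec)
  cfg$encounter_model$log_mult <- num_vec(cfg$encounter_model$log_mult)
  cfg$encounter_model$mean <- as.numeric(cfg$encounter_model$mean)
  cfg$encounter_model$size <- as.numeric(cfg$encounter_model$size)
  cfg$encounter_model$min_encounters <- as.integer(cfg$encounter_model$min_encounters)
  cfg$documentation_model$lab_mult <- num_vec(cfg$documentation_model$lab_mult)
  for (nm in setdiff(names(cfg$documentation_model), "lab_mult"))
    cfg$documentation_model[[nm]] <- as.numeric(cfg$documentation_model[[nm]])
  cfg$lab_value_model <- lapply(cfg$lab_value_model, as.numeric)
  cfg$missing_race_prob <- as.numeric(cfg$missing_race_prob)
  cfg$missing_race_enc_coef <- as.numeric(cfg$missing_race_enc_coef)
  cfg$n_neighborhoods <- as.integer(cfg$n_neighborhoods)
  cfg$neighborhood_effects$suff_sd <- as.numeric(cfg$neighborhood_effects$suff_sd)
  dem <- cfg$demographics
  dem$p_male <- as.numeric(dem$p_male)
  dem$age_range <- as.numeric(unlist(dem$age_range))
  dem$max_duration_years <- as.numeric(dem$max_duration_years)
  dem$poverty_probs <- as.numeric(unlist(dem$poverty_probs))
  dem$race_city <- num_vec(dem$race_city)
  dem$race_concentration <- as.numeric(dem$race_concentration)
  dem$medicaid_by_poverty <- as.numeric(unlist(dem$medicaid_by_poverty))
  cfg$demographics <- dem
  cfg
}

validate_ehr_config <- function(cfg) {
  chk_prob <- function(x, field) {
    if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
      stop("invalid probability in field '", field, "'", call. = FALSE)
  }
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      is.na(cfg$n_patients) || cfg$n_patients < 1)
    stop("invalid value in field 'n_patients': must be a positive integer",
         call. = FALSE)
  for (nm in c("diabetes", "asthma", "obesity")) {
    p <- cfg$baseline_prevalence[[nm]]
    if (is.null(p) || !is.numeric(p) || is.na(p) || p <= 0 || p >= 1)
      stop("invalid value in field 'baseline_prevalence$", nm,
           "': must be in (0,1)", call. = FALSE)
  }
  for (nm in names(cfg$true_log_or)) {
    b <- cfg$true_log_or[[nm]]
    if (!is.numeric(b) || anyNA(b) || any(!is.finite(b)))
      stop("invalid coefficient in field 'true_log_or$", nm, "'", call. = FALSE)
  }
  em <- cfg$encounter_model
  if (!is.numeric(em$mean) || em$mean <= 0)
    stop("invalid value in field 'encounter_model$mean'", call. = FALSE)
  if (!is.numeric(em$size) || em$size <= 0)
    stop("invalid value in field 'encounter_model$size': dispersion must be > 0",
         call. = FALSE)
  if (em$min_encounters < 0)
    stop("invalid value in field 'encounter_model$min_encounters'", call. = FALSE)
  dm <- cfg$documentation_model
  for (nm in c("p_diabetes_dx", "p_asthma_dx", "p_dm_lab", "p_endo_ros",
               "p_resp_ros", "p_routine", "p_bmi", "p_dm_med_core",
               "p_dm_med_metformin", "p_metformin_nondm", "p_asthma_med"))
    chk_prob(dm[[nm]], paste0("documentation_model$", nm))
  if (any(dm$lab_mult < 0))
    stop("invalid value in field 'documentation_model$lab_mult'", call. = FALSE)
  chk_prob(cfg$missing_race_prob, "missing_race_prob")
  if (cfg$n_neighborhoods < 1)
    stop("invalid value in field 'n_neighborhoods'", call. = FALSE)
  if (cfg$neighborhood_effects$suff_sd < 0)
    stop("invalid value in field 'neighborhood_effects$suff_sd'", call. = FALSE)
  dem <- cfg$demographics
  chk_prob(dem$p_male, "demographics$p_male")
  if (abs(sum(dem$poverty_probs) - 1) > 1e-6)
    stop("invalid value in field 'demographics$poverty_probs': must sum to 1",
         call. = FALSE)
  if (abs(sum(dem$race_city) - 1) > 1e-6)
    stop("invalid value in field 'demographics$race_city': must sum to 1",
         call. = FALSE)
  chk_prob(dem$medicaid_by_poverty, "demographics$medicaid_by_poverty")
  invisible(cfg)
}

#' Write / read a generator configuration (YAML)
#'
#' Configurations round-trip losslessly: `read_ehr_config(write_ehr_config(cfg))`
#' reproduces `cfg` exactly (types and names restored).
#'
#' @param config an `ehr_config`.
#' @param path file path for the YAML document.
#' @return `write_ehr_config` returns `path` invisibly; `read_ehr_config`
#'   returns an `ehr_config`.
#' @export
write_ehr_config <- function(config, path) {
  stopifnot(inherits(config, "ehr_config"))
  # named atomic vectors must become maps, not sequences, to keep names
  mapify <- function(x) {
    if (is.list(x)) lapply(x, mapify)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(mapify(unclass(config)), path, precision = 17)
  invisible(path)
}

#' @rdname write_ehr_config
#' @export
read_ehr_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  cfg <- normalize_ehr_config(cfg)
  validate_ehr_config(cfg)
  class(cfg) <- "ehr_config"
  cfg
}

#' @export
print.ehr_config <- function(x, ...) {
  cat("<ehr_config>\n")
  cat("  patients:", x$n_patients, " seed:", x$seed,
      " neighborhoods:", x$n_neighborhoods, "\n")
  cat("  reference prevalence: DM", x$baseline_prevalence$diabetes,
      "| asthma", x$baseline_prevalence$asthma,
      "| obesity", x$baseline_prevalence$obesity, "\n")
  cat("  true asthma->diabetes OR:",
      round(exp(x$true_log_or$diabetes[["asthma"]]), 3), "\n")
  cat("  encounters: NB(mean", x$encounter_model$mean, ", size",
      x$encounter_model$size, "), DM multiplier",
      round(exp(x$encounter_model$log_mult[["diabetes"]]), 2), "\n")
  cat("  per-encounter documentation: dx(DM)",
      x$documentation_model$p_diabetes_dx, "| dx(asthma)",
      x$documentation_model$p_asthma_dx, "\n")
  invisible(x)
}
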