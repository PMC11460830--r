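#' Generate a synthetic patient population
#'
#' Draws demographics, neighborhood membership and the true chronic-disease
#' states (obesity, asthma, diabetes -- in that causal order, since obesity
#' and asthma enter the diabetes model) from the configured logistic
#' models.  The returned table contains both the hidden truth (`true_*`
#' columns, `race_eth_true`, `bmi_true`) and the observed view
#' (`race_eth_observed`, possibly missing; `bmi`, masked later by
#' [generate_dataset()] once encounter counts are known).
#'
#' @param config an [ehr_config()].
#' @return a `data.frame` with one row per patient and attribute
#'   `neighborhoods` (the neighborhood-level race mixes, poverty strata and
#'   sufficiency random intercepts used downstream).
#' @export
generate_population <- function(config) {
  validate_ehr_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  dem <- config$demographics

  nb <- make_neighborhoods(config)
  neighborhood_id <- sample.int(config$n_neighborhoods, n, replace = TRUE)
  poverty_stratum <- factor(nb$poverty_stratum[neighborhood_id],
                            levels = poverty_levels())

  race_levels <- names(dem$race_city)
  race_idx <- draw_categorical(nb$race_probs[neighborhood_id, , drop = FALSE])
  race_eth_true <- factor(race_levels[race_idx], levels = race_levels)

  age <- stats::runif(n, dem$age_range[1], dem$age_range[2])
  sex <- factor(ifelse(stats::runif(n) < dem$p_male, "male", "female"),
                levels = c("female", "male"))
  medicaid <- stats::runif(n) <
    dem$medicaid_by_poverty[as.integer(poverty_stratum)]
  duration <- stats::runif(n, 0, dem$max_duration_years)

  xb <- function(coefs, extra = 0) {
    lp <- rep(0, n)
    add <- function(nm, v) if (!is.na(coefs[nm])) lp + coefs[[nm]] * v else lp
    for (rl in setdiff(race_levels, "White"))
      lp <- lp + ifelse(race_eth_true == rl, coef0(coefs, rl), 0)
    lp <- lp + coef0(coefs, "age") * (age - 31) +
      coef0(coefs, "male") * (sex == "male") +
      coef0(coefs, "medicaid") * medicaid +
      coef0(coefs, "poverty10") * (poverty_stratum == "10-<20%") +
      coef0(coefs, "poverty20") * (poverty_stratum == "20-<30%") +
      coef0(coefs, "poverty30") * (poverty_stratum == ">=30%")
    lp + extra
  }

  b <- config$true_log_or
  p0 <- config$baseline_prevalence
  true_obesity <- stats::runif(n) <
    stats::plogis(stats::qlogis(p0$obesity) + xb(b$obesity))
  true_asthma <- stats::runif(n) <
    stats::plogis(stats::qlogis(p0$asthma) + xb(b$asthma))
  lp_dm <- stats::qlogis(p0$diabetes) + xb(b$diabetes) +
    coef0(b$diabetes, "obesity") * true_obesity +
    coef0(b$diabetes, "asthma") * true_asthma
  true_diabetes <- stats::runif(n) < stats::plogis(lp_dm)

  # latent BMI consistent with the obesity state; observed only if recorded
  bmi_true <- ifelse(true_obesity,
                     truncnorm_above(n, 34, 3, 30),
                     truncnorm_below(n, 26, 3, 30))

  race_eth_observed <- race_eth_true
  if (config$missing_race_prob > 0 && config$missing_race_enc_coef == 0)
    race_eth_observed[stats::runif(n) < config$missing_race_prob] <- NA

  out <- data.frame(
    patient_id = seq_len(n),
    age = age, sex = sex,
    race_eth_true = race_eth_true,
    race_eth_observed = race_eth_observed,
    medicaid = medicaid,
    neighborhood_id = neighborhood_id,
    poverty_stratum = poverty_stratum,
    true_diabetes = true_diabetes,
    true_asthma = true_asthma,
    true_obesity = true_obesity,
    bmi_true = bmi_true,
    bmi = bmi_true,
    duration = duration,
    stringsAsFactors = FALSE)
  attr(out, "neighborhoods") <- nb
  out
}

poverty_levels <- function() c("<10%", "10-<20%", "20-<30%", ">=30%")

coef0 <- function(coefs, nm) {
  v <- coefs[nm]
  if (is.na(v)) 0 else unname(v)
}

make_neighborhoods <- function(config) {
  k <- config$n_neighborhoods
  dem <- config$demographics
  poverty <- sample(poverty_levels(), k, replace = TRUE,
                    prob = dem$poverty_probs)
  # Dirichlet race mix per neighborhood around the city-wide distribution
  a <- dem$race_concentration * dem$race_city
  g <- matrix(stats::rgamma(k * length(a), shape = rep(a, each = k)),
              nrow = k)
  race_probs <- g / rowSums(g)
  colnames(race_probs) <- names(dem$race_city)
  u_suff <- stats::rnorm(k, 0, config$neighborhood_effects$suff_sd)
  list(neighborhood_id = seq_len(k), poverty_stratum = poverty,
       race_probs = race_probs, u_suff = u_suff)
}

# row-wise categorical draw from a matrix of probabilities
draw_categorical <- function(p) {
  cp <- t(apply(p, 1, cumsum))
  u <- stats::runif(nrow(p)) * cp[, ncol(cp)]
  max.col(u <= cp, ties.method = "first")
}

truncnorm_above <- function(n, mean, sd, lo) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), 1)
  stats::qnorm(u, mean, sd)
}

truncnorm_below <- function(n, mean, sd, hi) {
  u <- stats::runif(n, 0, stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate encounter, diagnosis, lab and medication streams
#'
#' Encounter counts follow the configured negative-binomial model with
#' log-linear multipliers (true disease raises utilization -- the informed
#' presence mechanism).  Disease diagnosis codes and disease-specific
#' medications are emitted only for patients whose true state is positive,
#' one independent Bernoulli draw per encounter, so the downstream
#' phenotypes have specificity 1 by construction and false negatives
#' concentrate among low utilizers.  Diabetes-related lab orders apply the
#' configured subgroup multipliers (diagnostic suspicion); endocrinology
#' and respiratory review-of-systems flags are independent per-encounter
#' Bernoulli draws, with a neighborhood random intercept on the
#' endocrinology flag.
#'
#' @param patients output of [generate_population()].
#' @param config the same [ehr_config()].
#' @return list of class `ehr_events` with data frames `encounters`
#'   (`patient_id`, `encounter_index`, `is_routine_exam`, `has_endo_ros`,
#'   `has_resp_ros`), `diagnoses` (`patient_id`, `encounter_index`,
#'   `condition`), `labs` (`patient_id`, `lab_type`, `value`) and
#'   `medications` (`patient_id`, `med_class`).
#' @export
generate_events <- function(patients, config) {
  validate_ehr_config(config)
  n <- nrow(patients)
  em <- config$encounter_model
  dm <- config$documentation_model
  nb <- attr(patients, "neighborhoods")
  if (is.null(nb)) nb <- list(u_suff = rep(0, config$n_neighborhoods))

  lm_ <- em$log_mult
  mu <- em$mean * exp(
    coef0(lm_, "diabetes") * patients$true_diabetes +
    coef0(lm_, "asthma") * patients$true_asthma +
    coef0(lm_, "male") * (patients$sex == "male") +
    coef0(lm_, "age") * (patients$age - 31) +
    coef0(lm_, "medicaid") * patients$medicaid)
  n_enc <- pmax(stats::rnbinom(n, size = em$size, mu = mu),
                em$min_encounters)

  pid <- rep.int(patients$patient_id, n_enc)
  m <- length(pid)
  eidx <- sequence(n_enc) - 1L

  p_ros <- stats::plogis(stats::qlogis(dm$p_endo_ros) +
                           nb$u_suff[patients$neighborhood_id])
  encounters <- data.frame(
    patient_id = pid,
    encounter_index = eidx,
    is_routine_exam = stats::runif(m) < dm$p_routine,
    has_endo_ros = stats::runif(m) < rep.int(p_ros, n_enc),
    has_resp_ros = stats::runif(m) < dm$p_resp_ros)

  # diagnosis codes: true cases only (specificity 1 by construction)
  dm_hit <- rep.int(patients$true_diabetes, n_enc) &
    stats::runif(m) < dm$p_diabetes_dx
  as_hit <- rep.int(patients$true_asthma, n_enc) &
    stats::runif(m) < dm$p_asthma_dx
  diagnoses <- data.frame(
    patient_id = c(pid[dm_hit], pid[as_hit]),
    encounter_index = c(eidx[dm_hit], eidx[as_hit]),
    condition = rep(c("diabetes", "asthma"), c(sum(dm_hit), sum(as_hit))))

  # diabetes-related lab orders with subgroup screening multipliers
  lmu <- dm$lab_mult
  race_mult <- rep(1, n)
  for (rl in intersect(names(lmu), levels(patients$race_eth_true)))
    race_mult[patients$race_eth_true == rl] <- lmu[[rl]]
  p_lab <- pmin(dm$p_dm_lab * race_mult *
                  ifelse(patients$true_obesity, coefm(lmu, "obesity"), 1), 1)
  lab_hit <- stats::runif(m) < rep.int(p_lab, n_enc)
  lab_pid <- pid[lab_hit]
  k <- length(lab_pid)
  lab_type <- sample(c("a1c", "fasting_glucose", "random_glucose"), k,
                     replace = TRUE, prob = c(0.5, 0.25, 0.25))
  is_dm <- patients$true_diabetes[lab_pid]
  lv <- config$lab_value_model
  value <- numeric(k)
  a1c <- lab_type == "a1c"
  value[a1c] <- pmax(stats::rnorm(sum(a1c),
                                  ifelse(is_dm[a1c], lv$a1c_mean_dm, lv$a1c_mean_nondm),
                                  ifelse(is_dm[a1c], lv$a1c_sd_dm, lv$a1c_sd_nondm)), 3)
  fg <- lab_type == "fasting_glucose"
  value[fg] <- pmax(stats::rnorm(sum(fg), ifelse(is_dm[fg], 150, 90),
                                 ifelse(is_dm[fg], 30, 10)), 40)
  rg <- lab_type == "random_glucose"
  value[rg] <- pmax(stats::rnorm(sum(rg), ifelse(is_dm[rg], 180, 100),
                                 ifelse(is_dm[rg], 40, 15)), 40)
  labs <- data.frame(patient_id = lab_pid, lab_type = lab_type, value = value)

  # medications: per-encounter dispensing opportunities, stored per event
  med_rows <- function(mask_patient, p) {
    hit <- rep.int(mask_patient, n_enc) & stats::runif(m) < p
    pid[hit]
  }
  core <- med_rows(patients$true_diabetes, dm$p_dm_med_core)
  metf <- c(med_rows(patients$true_diabetes, dm$p_dm_med_metformin),
            med_rows(!patients$true_diabetes, dm$p_metformin_nondm))
  asth <- med_rows(patients$true_asthma, dm$p_asthma_med)
  medications <- data.frame(
    patient_id = c(core, metf, asth),
    med_class = rep(c("antidiabetes_core", "metformin_or_acarbose", "asthma_med"),
                    c(length(core), length(metf), length(asth))))

  structure(list(encounters = encounters, diagnoses = diagnoses,
                 labs = labs, medications = medications),
            class = "ehr_events")
}

coefm <- function(v, nm) if (is.na(v[nm])) 1 else unname(v[nm])

#' Generate a complete synthetic EHR dataset
#'
#' Composes [generate_population()] and [generate_events()] under a single
#' seed, then resolves the event-dependent observation processes: BMI is
#' recorded with per-encounter probability `p_bmi` (so low utilizers are
#' more often missing BMI), and, when `missing_race_enc_coef` is nonzero,
#' race missingness depends on utilization.
#'
#' @param config an [ehr_config()].
#' @param seed optional override of `config$seed`.
#' @return list of class `ehr_dataset`: `patients`, `encounters`,
#'   `diagnoses`, `labs`, `medications`, `neighborhoods`, `config`.
#' @export
generate_dataset <- function(config, seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  patients <- generate_population(config)
  events <- generate_events(patients, config)
  nb <- attr(patients, "neighborhoods")

  n_enc <- tabulate(events$encounters$patient_id, nbins = nrow(patients))
  p_bmi_rec <- 1 - (1 - config$documentation_model$p_bmi)^n_enc
  recorded <- stats::runif(nrow(patients)) < p_bmi_rec
  patients$bmi[!recorded] <- NA_real_

  if (config$missing_race_enc_coef != 0 && config$missing_race_prob > 0) {
    z <- log1p(n_enc) - mean(log1p(n_enc))
    p_miss <- stats::plogis(stats::qlogis(config$missing_race_prob) +
                              config$missing_race_enc_coef * z)
    patients$race_eth_observed <- patients$race_eth_true
    patients$race_eth_observed[stats::runif(nrow(patients)) < p_miss] <- NA
  }
  attr(patients, "neighborhoods") <- NULL

  structure(list(patients = patients,
                 encounters = events$encounters,
                 diagnoses = events$diagnoses,
                 labs = events$labs,
                 medications = events$medications,
                 neighborhoods = nb,
                 config = config),
            class = "ehr_dataset")
}

#' @export
print.ehr_dataset <- function(x, ...) {
  cat("<ehr_dataset>", nrow(x$patients), "patients,",
      nrow(x$encounters), "encounters,",
      nrow(x$diagnoses), "diagnoses,",
      nrow(x$labs), "labs,",
      nrow(x$medications), "medication events\n")
  cat("  seed:", x$config$seed,
      " true DM prevalence:", round(mean(x$patients$true_diabetes), 4), "\n")
  invisible(x)
}

#' Write / read an EHR dataset bundle
#'
#' One CSV per table plus `config.yaml` and `manifest.json`; the manifest
#' records the seed, the table row counts and an MD5 hash of the serialized
#' configuration so that a reloaded bundle can be checked for integrity.
#'
#' @param dataset an `ehr_dataset`.
#' @param dir directory to create/populate.
#' @return `write_ehr_dataset` returns `dir` invisibly; `read_ehr_dataset`
#'   returns the reconstructed `ehr_dataset`.
#' @export
write_ehr_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ehr_dataset"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  tabs <- c("patients", "encounters", "diagnoses", "labs", "medications")
  for (tb in tabs) {
    path <- file.path(dir, paste0(tb, ".csv"))
    ok <- tryCatch({
      utils::write.csv(dataset[[tb]], path, row.names = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("failed to write table to ", path, call. = FALSE)
  }
  nbp <- file.path(dir, "neighborhoods.csv")
  nb <- dataset$neighborhoods
  nb_df <- data.frame(neighborhood_id = nb$neighborhood_id,
                      poverty_stratum = nb$poverty_stratum,
                      u_suff = nb$u_suff)
  nb_df <- cbind(nb_df, as.data.frame(nb$race_probs))
  utils::write.csv(nb_df, nbp, row.names = FALSE)
  cfgp <- file.path(dir, "config.yaml")
  write_ehr_config(dataset$config, cfgp)
  manifest <- list(
    format = "ehrbias-dataset", version = 1L,
    seed = dataset$config$seed,
    config_md5 = unname(tools::md5sum(cfgp)),
    rows = lapply(dataset[tabs], nrow))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_ehr_dataset
#' @export
read_ehr_dataset <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp))
    stop("no manifest.json found in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mp)
  cfgp <- file.path(dir, "config.yaml")
  config <- read_ehr_config(cfgp)
  if (!identical(unname(tools::md5sum(cfgp)), manifest$config_md5))
    warning("config hash does not match manifest in ", dir)
  rd <- function(tb, colClasses = NA) {
    path <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(path)) stop("missing table file: ", path, call. = FALSE)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  patients <- rd("patients")
  race_lv <- names(config$demographics$race_city)
  patients$sex <- factor(patients$sex, levels = c("female", "male"))
  patients$race_eth_true <- factor(patients$race_eth_true, levels = race_lv)
  patients$race_eth_observed <- factor(patients$race_eth_observed,
                                       levels = race_lv)
  patients$poverty_stratum <- factor(patients$poverty_stratum,
                                     levels = poverty_levels())
  nb_df <- rd("neighborhoods")
  nb <- list(neighborhood_id = nb_df$neighborhood_id,
             poverty_stratum = nb_df$poverty_stratum,
             race_probs = as.matrix(nb_df[, race_lv, drop = FALSE]),
             u_suff = nb_df$u_suff)
  empty_fix <- function(df, cols) {
    # read.csv types empty tables as logical; restore declared columns
    for (nm in names(cols)) if (nrow(df) == 0) df[[nm]] <- vector(cols[[nm]], 0)
    df
  }
  structure(list(patients = patients,
                 encounters = rd("encounters"),
                 diagnoses = empty_fix(rd("diagnoses"),
                                       c(patient_id = "integer",
                                         encounter_index = "integer",
                                         condition = "character")),
                 labs = empty_fix(rd("labs"),
                                  c(patient_id = "integer",
                                    lab_type = "character",
                                    value = "numeric")),
                 medications = empty_fix(rd("medications"),
                                         c(patient_id = "integer",
                                           med_class = "character")),
                 neighborhoods = nb,
                 config = config),
            class = "ehr_dataset")
}
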