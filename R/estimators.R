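#' Model specification for the EHR estimation strategies
#'
#' Encodes the two study questions and their adjustment sets: odds of
#' observed diabetes (`dm_star`) by race/ethnicity adjusted for age and
#' sex, or by observed asthma adjusted for age, sex, race/ethnicity,
#' Medicaid, observed obesity and neighborhood poverty stratum.  Reference
#' levels are White, female and the lowest poverty stratum.
#'
#' @param exposure `"asthma"` or `"race"`.
#' @param race_handling `"surrogate_imputation"` (use the `race_eth`
#'   column, missing race filled from the known neighborhood-conditional
#'   distribution) or `"complete_case"` (use `race_eth_observed`, dropping
#'   rows with missing race).
#' @return list of class `ehr_model_spec` with elements `exposure`,
#'   `race_var`, `rhs` (adjustment terms) and `exposure_terms`.
#' @export
model_spec <- function(exposure = c("asthma", "race"),
                       race_handling = c("surrogate_imputation",
                                         "complete_case")) {
  exposure <- match.arg(exposure)
  race_handling <- match.arg(race_handling)
  race_var <- if (race_handling == "surrogate_imputation") "race_eth"
              else "race_eth_observed"
  if (exposure == "asthma") {
    rhs <- c("asthma_star", "age", "sex", race_var, "medicaid",
             "obese_star", "poverty_stratum")
    exposure_terms <- "asthma_starTRUE"
  } else {
    rhs <- c(race_var, "age", "sex")
    exposure_terms <- paste0(race_var, c("Black", "Latino", "Asian", "Other"))
  }
  structure(list(exposure = exposure, race_handling = race_handling,
                 race_var = race_var, rhs = rhs,
                 exposure_terms = exposure_terms),
            class = "ehr_model_spec")
}

prepare_fit_data <- function(table, spec, extra_terms = character()) {
  rhs <- c(spec$rhs, extra_terms)
  keep <- stats::complete.cases(table[, intersect(rhs, names(table))])
  tab <- table[keep, , drop = FALSE]
  f <- stats::as.formula(paste("dm_star ~", paste(rhs, collapse = " + ")))
  mf <- stats::model.frame(f, tab, drop.unused.levels = TRUE)
  x <- stats::model.matrix(f, mf)
  list(x = x, y = as.numeric(tab$dm_star), tab = tab, formula = f)
}

#' Naive estimation on the full sample
#'
#' Fits the outcome model for `dm_star` on every patient, ignoring the
#' misclassification process entirely; any `weights` column present in the
#' table is ignored by design.
#'
#' @param table an analysis table from [build_analysis_table()].
#' @param spec an [model_spec()]; or pass `exposure` to build one.
#' @param exposure,race_handling shortcut arguments forwarded to
#'   [model_spec()] when `spec` is `NULL`.
#' @return an `ehr_fit` labelled `"naive"`.
#' @export
estimate_naive <- function(table, spec = NULL, exposure = "asthma",
                           race_handling = "surrogate_imputation") {
  if (is.null(spec)) spec <- model_spec(exposure, race_handling)
  d <- prepare_fit_data(table, spec)
  fit <- fit_logistic(d$x, d$y, method = "naive",
                      exposure_terms = spec$exposure_terms)
  fit$formula <- deparse(d$formula)
  fit
}

#' Estimation restricted to the sufficient-data subset
#'
#' Same outcome model as [estimate_naive()] but fit only on patients whose
#' record is flagged as sufficient, treating the insufficient records'
#' outcomes as missing rather than negative.
#'
#' @inheritParams estimate_naive
#' @return an `ehr_fit` labelled `"sufficiency"`.
#' @export
estimate_sufficiency <- function(table, spec = NULL, exposure = "asthma",
                                 race_handling = "surrogate_imputation") {
  if (is.null(spec)) spec <- model_spec(exposure, race_handling)
  sub <- table[table$sufficient, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("no patients satisfy the sufficiency definition", call. = FALSE)
  d <- prepare_fit_data(sub, spec)
  fit <- fit_logistic(d$x, d$y, method = "sufficiency",
                      exposure_terms = spec$exposure_terms)
  fit$formula <- deparse(d$formula)
  fit
}

#' Model the probability of having sufficient data
#'
#' Logistic regression of the sufficiency indicator on demographics,
#' utilization (log1p encounters, duration, routine-exam and
#' diabetes-lab indicators) and neighborhood: fixed neighborhood dummies
#' by default, or an approximate random intercept via `lme4::glmer`.
#' With a single neighborhood the cluster term is dropped with a warning.
#'
#' @param table an analysis table (needs `sufficient`, demographics,
#'   utilization columns, `neighborhood_id`).
#' @param cluster `"fixed"` or `"random"`.
#' @param race_var race column used as predictor.
#' @return numeric vector of fitted probabilities `p_hat` aligned with the
#'   rows of `table`, with attributes `marginal` (mean of `sufficient`)
#'   and `model`.
#' @export
fit_sufficiency_model <- function(table, cluster = c("fixed", "random"),
                                  race_var = "race_eth") {
  cluster <- match.arg(cluster)
  tab <- table
  tab$log_enc <- log1p(tab$total_encounters)
  tab$neigh <- factor(tab$neighborhood_id)
  base <- paste("sufficient ~ age + sex +", race_var,
                "+ medicaid + poverty_stratum + log_enc + duration",
                "+ any_routine_exam + any_dm_lab")
  single <- nlevels(tab$neigh) < 2
  if (single)
    warning("single neighborhood: cluster term dropped from sufficiency model")
  if (cluster == "fixed") {
    # neighborhood dummies absorb any neighborhood-level covariate
    # (poverty stratum is one), so drop it to keep the design full rank
    base_fx <- if (single) base else
      sub(" + poverty_stratum", "", base, fixed = TRUE)
    f <- stats::as.formula(if (single) base_fx else paste(base_fx, "+ neigh"))
    mf <- stats::model.frame(f, tab, drop.unused.levels = TRUE)
    x <- stats::model.matrix(f, mf)
    y <- as.numeric(mf$sufficient)
    fit <- fit_logistic(x, y, method = "sufficiency_model")
    p_hat <- as.vector(stats::plogis(x %*% fit$coefficients))
    model <- fit
  } else {
    if (single) {
      f <- stats::as.formula(base)
      g <- stats::glm(f, data = tab, family = stats::binomial())
      p_hat <- as.vector(stats::fitted(g))
      model <- g
    } else {
      f <- stats::as.formula(paste(base, "+ (1 | neigh)"))
      g <- lme4::glmer(f, data = tab, family = stats::binomial(),
                       nAGQ = 0,
                       control = lme4::glmerControl(calc.derivs = FALSE))
      p_hat <- as.vector(stats::fitted(g))
      model <- g
    }
  }
  p_hat <- pmin(pmax(p_hat, 1e-12), 1 - 1e-12)
  attr(p_hat, "marginal") <- mean(table$sufficient)
  attr(p_hat, "model") <- model
  p_hat
}

#' Stabilized inverse-probability weights
#'
#' `w_i = p_bar / p_hat_i` for patients with `S_i = 1`, where `p_bar` is
#' the marginal probability of sufficiency: the inverse of the predicted
#' probability of having sufficient data, multiplied by the overall
#' probability of having sufficient data.  When the sufficiency model is
#' correctly specified the weighted sufficient subset represents the full
#' population and `mean(w) -> 1`.
#'
#' @param p_hat fitted sufficiency probabilities (one per patient).
#' @param s binary/logical sufficiency indicator, same length.
#' @param patient_id optional ids carried into the result.
#' @param truncate optional length-2 probability vector: truncate weights
#'   at these quantiles (default `NULL`, off).
#' @return data frame of class `weight_vector` with one row per `S = 1`
#'   patient: `patient_id`, `w`, `p_hat`, `p_bar`.
#' @export
compute_stabilized_weights <- function(p_hat, s, patient_id = NULL,
                                       truncate = NULL) {
  s <- as.logical(s)
  if (length(p_hat) != length(s))
    stop("p_hat and s must have the same length", call. = FALSE)
  if (any(p_hat <= 0 | p_hat >= 1)) {
    if (is.null(truncate))
      stop("fitted probabilities at 0 or 1; enable truncation to proceed",
           call. = FALSE)
    p_hat <- pmin(pmax(p_hat, 1e-12), 1 - 1e-12)
  }
  p_bar <- mean(s)
  if (is.null(patient_id)) patient_id <- seq_along(s)
  w <- p_bar / p_hat[s]
  if (!is.null(truncate)) {
    q <- stats::quantile(w, truncate)
    w <- pmin(pmax(w, q[1]), q[2])
  }
  structure(data.frame(patient_id = patient_id[s], w = w,
                       p_hat = p_hat[s], p_bar = p_bar),
            class = c("weight_vector", "data.frame"))
}

#' Stabilized-IPW estimation on the sufficient subset
#'
#' Fits the outcome model on `S = 1` patients, weighted by the stabilized
#' inverse-probability-of-sufficiency weights; robust sandwich variance
#' (weights treated as known) by default.
#'
#' @inheritParams estimate_naive
#' @param weights optional `weight_vector` from
#'   [compute_stabilized_weights()]; computed from
#'   [fit_sufficiency_model()] when `NULL`.
#' @param cluster passed to [fit_sufficiency_model()] when weights are
#'   computed internally.
#' @return an `ehr_fit` labelled `"ipw"`.
#' @export
estimate_ipw <- function(table, spec = NULL, exposure = "asthma",
                         race_handling = "surrogate_imputation",
                         weights = NULL, cluster = "fixed") {
  if (is.null(spec)) spec <- model_spec(exposure, race_handling)
  if (is.null(weights)) {
    p_hat <- fit_sufficiency_model(table, cluster = cluster,
                                   race_var = spec$race_var)
    weights <- compute_stabilized_weights(p_hat, table$sufficient,
                                          patient_id = table$patient_id)
  }
  sub <- table[table$sufficient, , drop = FALSE]
  w <- weights$w[match(sub$patient_id, weights$patient_id)]
  if (anyNA(w)) stop("weights do not cover the sufficient subset",
                     call. = FALSE)
  d <- prepare_fit_data(cbind(sub, .w = w), spec)
  fit <- fit_logistic(d$x, d$y, weights = d$tab$.w, variance = "robust",
                      method = "ipw", exposure_terms = spec$exposure_terms)
  fit$formula <- deparse(d$formula)
  fit
}

#' Utilization-adjusted (DAG) estimation on the full sample
#'
#' The naive model plus a total-encounters term, treating encounter count
#' as a confounder of the observed-outcome/observed-exposure relationship
#' (the informed-presence path).  The default transform is quartile bins
#' of the encounter count: with heavily overdispersed utilization a smooth
#' monotone adjustment (`log1p`, also available, as is `linear`) conditions
#' so finely on utilization -- itself a common effect of the two diseases --
#' that the collider path it opens overwhelms the confounding it removes
#' and the estimate undershoots the truth; coarse bins remove the bulk of
#' the informed-presence confounding while limiting that amplification.
#'
#' @inheritParams estimate_naive
#' @param encounter_transform `"quartile"`, `"log1p"` or `"linear"`.
#' @return an `ehr_fit` labelled `"dag"`; the encounter coefficient(s) are
#'   reported in `fit$encounter_coef`.
#' @export
estimate_dag <- function(table, spec = NULL, exposure = "asthma",
                         race_handling = "surrogate_imputation",
                         encounter_transform = c("quartile", "log1p",
                                                 "linear")) {
  if (is.null(spec)) spec <- model_spec(exposure, race_handling)
  encounter_transform <- match.arg(encounter_transform)
  tab <- table
  enc_term <- switch(encounter_transform,
    log1p = { tab$enc_adj <- log1p(tab$total_encounters); "enc_adj" },
    linear = { tab$enc_adj <- tab$total_encounters; "enc_adj" },
    quartile = {
      q <- stats::quantile(tab$total_encounters, c(0.25, 0.5, 0.75))
      tab$enc_adj <- cut(tab$total_encounters,
                         breaks = unique(c(-Inf, q, Inf)),
                         labels = FALSE)
      tab$enc_adj <- factor(tab$enc_adj)
      "enc_adj"
    })
  d <- prepare_fit_data(tab, spec, extra_terms = enc_term)
  fit <- fit_logistic(d$x, d$y, method = "dag",
                      exposure_terms = spec$exposure_terms)
  fit$formula <- deparse(d$formula)
  fit$encounter_transform <- encounter_transform
  enc_cols <- grep("^enc_adj", names(fit$coefficients), value = TRUE)
  fit$encounter_coef <- fit$coefficients[enc_cols]
  fit
}

#' Run one or more estimation strategies on an analysis table
#'
#' @param table an analysis table.
#' @param methods subset of `c("naive", "sufficiency", "ipw", "dag")`.
#' @inheritParams estimate_naive
#' @return named list of `ehr_fit` objects.
#' @export
estimate_all <- function(table, methods = c("naive", "sufficiency",
                                            "ipw", "dag"),
                         exposure = "asthma",
                         race_handling = "surrogate_imputation") {
  methods <- match.arg(methods, several.ok = TRUE)
  spec <- model_spec(exposure, race_handling)
  fits <- list()
  for (m in methods) {
    fits[[m]] <- switch(m,
      naive = estimate_naive(table, spec),
      sufficiency = estimate_sufficiency(table, spec),
      ipw = estimate_ipw(table, spec),
      dag = estimate_dag(table, spec))
  }
  fits
}
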