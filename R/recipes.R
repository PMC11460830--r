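#' Read a survey recode recipe
#'
#' A recipe is a declarative YAML description of how to turn a raw survey
#' extract (pre-converted to CSV; fixed-width/transport parsing is out of
#' scope) into the analytic table the benchmark models expect: design
#' columns, inclusion filters (age window, in-care indicator), and
#' variable recodes for diabetes, asthma, obesity, sex, race/ethnicity,
#' insurance and income.  Recipes for the 2019 BRFSS and the pooled
#' 2013-March 2020 NHANES public-use files ship with the package
#' ([recipe_brfss2019()], [recipe_nhanes_2013_2020()]); ambiguous codings
#' (e.g. don't-know/refused) are explicit recipe options rather than
#' hard-coded choices.
#'
#' @param path YAML file path.
#' @return list of class `survey_recipe`.
#' @export
read_recipe <- function(path) {
  if (!file.exists(path)) stop("recipe file not found: ", path, call. = FALSE)
  r <- yaml::read_yaml(path)
  structure(r, class = "survey_recipe")
}

#' @rdname read_recipe
#' @export
recipe_brfss2019 <- function() {
  read_recipe(system.file("extdata", "recipes", "brfss2019.yaml",
                          package = "ehrbias", mustWork = TRUE))
}

#' @rdname read_recipe
#' @export
recipe_nhanes_2013_2020 <- function() {
  read_recipe(system.file("extdata", "recipes", "nhanes_2013_2020.yaml",
                          package = "ehrbias", mustWork = TRUE))
}

#' Apply a recode recipe to a raw survey table
#'
#' Filters to the analytic subset (age window, optionally in-care), builds
#' the analysis variables, logs the row count after every filter step (as
#' the `filter_log` attribute and optionally via messages), and returns a
#' [survey_design()].  Missing source columns are an error naming the
#' column; unknown category codes follow the recipe's `on_unknown` policy
#' (`"drop"` with a log entry, `"na"`, or `"error"`).
#'
#' @param raw data frame of the raw survey extract.
#' @param recipe a `survey_recipe`.
#' @param verbose emit a message per filter step.
#' @return a `survey_design` whose `data` holds the recoded analysis
#'   variables; attribute `filter_log` records the subsetting cascade.
#' @export
apply_recipe <- function(raw, recipe, verbose = FALSE) {
  stopifnot(inherits(recipe, "survey_recipe"))
  log <- list()
  note <- function(step, n) {
    log[[length(log) + 1]] <<- data.frame(step = step, rows = n)
    if (verbose) message(step, ": ", n, " rows")
  }
  need <- function(col) {
    if (!col %in% names(raw))
      stop("missing column in survey table: '", col, "'", call. = FALSE)
    raw[[col]]
  }
  note("input", nrow(raw))

  keep <- rep(TRUE, nrow(raw))
  flt <- recipe$filters
  age <- need(recipe$variables$age$source)
  keep <- keep & !is.na(age) & age >= flt$age_min & age <= flt$age_max
  raw2 <- raw[keep, , drop = FALSE]
  note(sprintf("age %d-%d", flt$age_min, flt$age_max), nrow(raw2))

  if (!is.null(flt$in_care)) {
    v <- raw2[[flt$in_care$source]]
    if (is.null(v))
      stop("missing column in survey table: '", flt$in_care$source, "'",
           call. = FALSE)
    keep2 <- v %in% flt$in_care$yes_codes
    raw2 <- raw2[keep2, , drop = FALSE]
    note("in care (personal provider)", nrow(raw2))
  }

  on_unknown <- recipe$on_unknown %||% "drop"
  decode_yn <- function(spec, label) {
    v <- raw2[[spec$source]]
    if (is.null(v))
      stop("missing column in survey table: '", spec$source, "'",
           call. = FALSE)
    out <- rep(NA, length(v))
    out[v %in% spec$yes_codes] <- TRUE
    out[v %in% spec$no_codes] <- FALSE
    unknown <- !is.na(v) & is.na(out) & !v %in% (spec$missing_codes %||% integer())
    if (any(unknown) && on_unknown == "error")
      stop("unknown codes in '", spec$source, "': ",
           paste(unique(v[unknown]), collapse = ", "), call. = FALSE)
    out
  }

  vars <- recipe$variables
  out <- data.frame(row.names = seq_len(nrow(raw2)))
  out$age <- raw2[[vars$age$source]]

  dm <- decode_yn(vars$diabetes$self_report, "diabetes")
  if (identical(vars$diabetes$mode, "self_or_lab")) {
    a1c <- suppressWarnings(as.numeric(raw2[[vars$diabetes$a1c$source]]))
    glu <- suppressWarnings(as.numeric(raw2[[vars$diabetes$glucose$source]]))
    lab_pos <- (!is.na(a1c) & a1c >= vars$diabetes$a1c$threshold) |
      (!is.na(glu) & glu >= vars$diabetes$glucose$threshold)
    dm[lab_pos] <- TRUE
    dm[is.na(dm) & (!is.na(a1c) | !is.na(glu))] <- lab_pos[is.na(dm) &
                                                            (!is.na(a1c) | !is.na(glu))]
  }
  out$diabetes <- dm
  out$asthma <- decode_yn(vars$asthma, "asthma")

  if (identical(vars$obesity$mode, "bmi")) {
    bmi <- suppressWarnings(as.numeric(raw2[[vars$obesity$source]])) /
      (vars$obesity$scale %||% 1)
    out$obesity <- !is.na(bmi) & bmi >= 30
  } else {
    out$obesity <- decode_yn(vars$obesity, "obesity")
  }

  sx <- raw2[[vars$sex$source]]
  out$sex <- factor(ifelse(sx %in% vars$sex$male_codes, "male",
                    ifelse(sx %in% vars$sex$female_codes, "female", NA)),
                    levels = c("female", "male"))

  rr <- raw2[[vars$race$source]]
  race <- rep(NA_character_, length(rr))
  for (lv in names(vars$race$map)) race[rr %in% vars$race$map[[lv]]] <- lv
  out$race_eth <- factor(race,
                         levels = c("White", "Black", "Latino", "Asian",
                                    "Other"))

  ins <- raw2[[vars$insurance$source]]
  out$insured <- rep(NA, length(ins))
  out$insured[ins %in% vars$insurance$yes_codes] <- TRUE
  out$insured[ins %in% vars$insurance$no_codes] <- FALSE

  inc <- raw2[[vars$income$source]]
  if (!is.null(vars$income$pir_breaks)) {
    # continuous income-to-poverty ratio cut at the configured breaks
    out$income <- cut(suppressWarnings(as.numeric(inc)),
                      breaks = c(-Inf, unlist(vars$income$pir_breaks), Inf),
                      labels = unlist(vars$income$pir_labels))
  } else {
    ilv <- rep(NA_character_, length(inc))
    for (lv in names(vars$income$map)) ilv[inc %in% vars$income$map[[lv]]] <- lv
    out$income <- factor(ilv, levels = names(vars$income$map))
  }

  if (on_unknown == "drop") {
    core <- c("diabetes", "asthma", "sex", "race_eth")
    ok <- stats::complete.cases(out[, core])
    dropped <- sum(!ok)
    out <- out[ok, , drop = FALSE]
    raw2 <- raw2[ok, , drop = FALSE]
    note("drop unknown/missing analysis codes", nrow(out))
  }

  des <- recipe$design
  dsn <- survey_design(out,
                       weights = raw2[[des$weight]],
                       strata = if (!is.null(des$stratum)) raw2[[des$stratum]],
                       psu = if (!is.null(des$psu)) raw2[[des$psu]])
  attr(dsn, "filter_log") <- do.call(rbind, log)
  attr(dsn, "source") <- recipe$source
  dsn
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benchmark model formulas for survey designs
#'
#' The survey analogue of [model_spec()]: diabetes by race/ethnicity
#' adjusted for age and sex, or by asthma adjusted for age, sex,
#' race/ethnicity, obesity, insurance and income level.
#'
#' @param exposure `"asthma"` or `"race"`.
#' @return a formula.
#' @export
survey_model_formula <- function(exposure = c("asthma", "race")) {
  exposure <- match.arg(exposure)
  if (exposure == "asthma")
    diabetes ~ asthma + age + sex + race_eth + obesity + insured + income
  else
    diabetes ~ race_eth + age + sex
}
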