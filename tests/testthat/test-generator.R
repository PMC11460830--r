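test_that("true-disease prevalence follows the configured model under the null", {
  cfg <- ehr_config(n_patients = 100000, seed = 31,
                    baseline_prevalence = list(diabetes = 0.03, asthma = 0.08,
                                               obesity = 0.15))
  cfg$true_log_or <- lapply(cfg$true_log_or, function(v) { v[] <- 0; v })
  pop <- generate_population(cfg)
  # binomial sampling oracle: phat within 3 SEs of p
  se <- sqrt(0.03 * 0.97 / nrow(pop))
  expect_lt(abs(mean(pop$true_diabetes) - 0.03), 3 * se)

  # null asthma->diabetes effect: crude true-state OR ~ 1
  tb <- table(pop$true_asthma, pop$true_diabetes)
  or <- (tb[2, 2] * tb[1, 1]) / (tb[1, 2] * tb[2, 1])
  se_logor <- sqrt(sum(1 / tb))
  expect_lt(abs(log(or)), 3 * se_logor)
})

test_that("generation is deterministic given the seed", {
  cfg <- small_config(n = 500, seed = 77)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  for (tb in c("patients", "encounters", "diagnoses", "labs", "medications"))
    expect_identical(d1[[tb]], d2[[tb]])
  d3 <- generate_dataset(cfg, seed = 78)
  expect_false(identical(d1$encounters, d3$encounters))
})

test_that("encounter counts follow the configured negative binomial", {
  cfg <- small_config(n = 20000, seed = 5)
  cfg$encounter_model$log_mult[] <- 0
  cfg$encounter_model$min_encounters <- 0L
  pop <- generate_population(cfg)
  ev <- generate_events(pop, cfg)
  n_enc <- tabulate(ev$encounters$patient_id, nbins = nrow(pop))
  mu <- cfg$encounter_model$mean
  size <- cfg$encounter_model$size
  expect_lt(abs(mean(n_enc) - mu) / mu, 0.05)
  expect_lt(abs(var(n_enc) - (mu + mu^2 / size)) / (mu + mu^2 / size), 0.10)
})

test_that("perfect documentation leaves no diabetic without two diagnosis codes", {
  cfg <- small_config(n = 1500, seed = 2)
  cfg$documentation_model$p_diabetes_dx <- 1
  cfg$encounter_model$min_encounters <- 2L
  pop <- generate_population(cfg)
  ev <- generate_events(pop, cfg)
  dm_dx <- ev$diagnoses[ev$diagnoses$condition == "diabetes", ]
  ndx <- tabulate(match(dm_dx$patient_id, pop$patient_id), nbins = nrow(pop))
  expect_true(all(ndx[pop$true_diabetes] >= 2))
})

test_that("zero documentation probability empties the diagnosis stream", {
  cfg <- small_config(n = 800, seed = 3)
  cfg$documentation_model$p_diabetes_dx <- 0
  cfg$documentation_model$p_asthma_dx <- 0
  pop <- generate_population(cfg)
  ev <- generate_events(pop, cfg)
  expect_equal(nrow(ev$diagnoses), 0)
})

test_that("diagnosis codes are emitted only for true cases (specificity 1)", {
  ds <- generate_dataset(small_config(n = 4000, seed = 12))
  tab <- build_analysis_table(ds)
  expect_true(all(ds$diagnoses$condition %in% c("diabetes", "asthma")))
  dm_coded <- unique(ds$diagnoses$patient_id[ds$diagnoses$condition == "diabetes"])
  expect_true(all(ds$patients$true_diabetes[dm_coded]))
  expect_false(any(tab$dm_star & !tab$true_diabetes))
  expect_false(any(tab$asthma_star & !tab$true_asthma))
})

test_that("diabetes raises utilization when its encounter multiplier exceeds 1", {
  cfg <- small_config(n = 800)
  diffs <- vapply(1:50, function(i) {
    cfg$seed <- 400 + i
    pop <- generate_population(cfg)
    ev <- generate_events(pop, cfg)
    n_enc <- tabulate(ev$encounters$patient_id, nbins = nrow(pop))
    mean(n_enc[pop$true_diabetes]) - mean(n_enc[!pop$true_diabetes])
  }, numeric(1))
  # sign test across replicates: P(all but <=5 positive) under H0 ~ 0
  expect_gte(sum(diffs > 0), 45)
})

test_that("phenotype sensitivity rises with documentation and utilization", {
  doc_grid <- c(0.02, 0.10, 0.50)
  enc_grid <- c(2, 8, 25)
  sens <- matrix(NA_real_, 3, 3)
  for (i in seq_along(doc_grid)) for (j in seq_along(enc_grid)) {
    hits <- 0; cases <- 0
    for (r in 1:10) {
      cfg <- small_config(n = 1500, seed = 7000 + 100 * i + 10 * j + r)
      cfg$documentation_model$p_diabetes_dx <- doc_grid[i]
      cfg$documentation_model$p_dm_med_core <- 0   # isolate the dx pathway
      cfg$encounter_model$mean <- enc_grid[j]
      ds <- generate_dataset(cfg)
      tab <- build_analysis_table(ds)
      hits <- hits + sum(tab$dm_star & tab$true_diabetes)
      cases <- cases + sum(tab$true_diabetes)
    }
    sens[i, j] <- hits / cases
  }
  expect_true(all(diff(sens) > -0.02))       # along documentation
  expect_true(all(t(diff(t(sens))) > -0.02)) # along utilization
  expect_true(all(sens > 0 & sens <= 1))
})

test_that("dataset bundles round-trip through disk with manifest integrity", {
  ds <- generate_dataset(small_config(n = 300, seed = 21))
  dir <- withr::local_tempdir()
  write_ehr_dataset(ds, dir)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 21)
  expect_match(manifest$config_md5, "^[0-9a-f]{32}$")
  back <- read_ehr_dataset(dir)
  expect_equal(back$patients, ds$patients, tolerance = 1e-12)
  expect_equal(back$diagnoses, ds$diagnoses)
  expect_equal(back$medications, ds$medications)
  expect_equal(back$labs, ds$labs, tolerance = 1e-12)
  expect_equal(back$encounters, ds$encounters)
  expect_identical(back$config, ds$config)
})

test_that("a one-patient, zero-encounter dataset is valid and degenerate", {
  cfg <- small_config(n = 1, seed = 4)
  cfg$encounter_model$mean <- 1e-8
  cfg$encounter_model$min_encounters <- 0L
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$patients), 1)
  expect_equal(nrow(ds$encounters), 0)
  expect_equal(nrow(ds$diagnoses), 0)
  tab <- build_analysis_table(ds)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$total_encounters, 0)
  expect_false(tab$dm_star)
  expect_false(tab$sufficient)
})
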