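# Shared small dataset for the estimator contract tests.
est_tab <- local({
  ds <- generate_dataset(small_config(n = 6000, seed = 42))
  build_analysis_table(ds)
})

test_that("reference coding follows the study conventions", {
  fit <- estimate_naive(est_tab, exposure = "race")
  ot <- odds_ratio(fit)
  expect_setequal(ot$term, paste0("race_eth", c("Black", "Latino", "Asian",
                                                "Other")))
  # White is the reference: no coefficient, OR fixed at 1 by construction
  expect_false("race_ethWhite" %in% names(coef(fit)))
  fit2 <- estimate_naive(est_tab, exposure = "asthma")
  expect_true(all(c("asthma_starTRUE", "obese_starTRUE", "sexmale",
                    "poverty_stratum>=30%") %in% names(coef(fit2))))
})

test_that("naive estimation ignores any weights present in the table", {
  tab_w <- est_tab
  tab_w$weights <- runif(nrow(tab_w), 0.2, 5)
  f1 <- estimate_naive(est_tab)
  f2 <- estimate_naive(tab_w)
  expect_identical(coef(f1), coef(f2))
})

test_that("sufficiency model recovers a null selection mechanism", {
  set.seed(15)
  tab <- fake_analysis_table(20000)
  tab$sufficient <- runif(nrow(tab)) < 0.4
  p_hat <- fit_sufficiency_model(tab)
  expect_lt(abs(mean(p_hat) - 0.4), 3 * sqrt(0.4 * 0.6 / nrow(tab)))
  fit <- attr(p_hat, "model")
  slopes <- coef(fit)[c("age", "sexmale", "log_enc", "duration")]
  se <- sqrt(diag(vcov(fit)))[names(slopes)]
  expect_true(all(abs(slopes / se) < 4))
  # predictions are a function of covariates, invariant to row order
  perm <- sample(nrow(tab))
  p_perm <- fit_sufficiency_model(tab[perm, ])
  expect_equal(as.numeric(p_perm), as.numeric(p_hat)[perm], tolerance = 1e-6)
})

test_that("random-intercept mode works and degrades gracefully", {
  set.seed(16)
  tab <- fake_analysis_table(3000)
  tab$sufficient <- runif(nrow(tab)) < plogis(-0.4 + 0.1 * tab$neighborhood_id)
  p_r <- fit_sufficiency_model(tab, cluster = "random")
  expect_true(all(p_r > 0 & p_r < 1))
  tab1 <- tab
  tab1$neighborhood_id <- 1L
  expect_warning(fit_sufficiency_model(tab1, cluster = "random"),
                 "single neighborhood")
})

test_that("stabilized weights follow their defining identity", {
  # direct formula arithmetic
  w <- compute_stabilized_weights(p_hat = c(0.8, 0.4, 0.5),
                                  s = c(TRUE, TRUE, FALSE))
  expect_equal(w$p_bar, rep(2 / 3, 2))
  expect_equal(w$w, c((2 / 3) / 0.8, (2 / 3) / 0.4))
  # p_hat equal to the marginal gives unit weights
  w1 <- compute_stabilized_weights(rep(0.5, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(w1$w, rep(1, 5))
  expect_error(compute_stabilized_weights(c(0, 0.5), c(TRUE, TRUE)),
               "truncation")
  wt <- compute_stabilized_weights(c(1e-15, 0.5), c(TRUE, TRUE),
                                   truncate = c(0.1, 0.9))
  expect_true(all(is.finite(wt$w)))
})

test_that("mean stabilized weight approaches 1 under a correct model", {
  set.seed(77)
  tab <- fake_analysis_table(30000)
  lp <- -0.6 + 0.03 * (tab$age - 31) + 0.4 * (tab$sex == "male") +
    0.5 * log1p(tab$total_encounters) - 0.15 * mean(log1p(tab$total_encounters))
  tab$sufficient <- runif(nrow(tab)) < plogis(lp - mean(lp))
  p_hat <- fit_sufficiency_model(tab)
  w <- compute_stabilized_weights(p_hat, tab$sufficient)
  expect_lt(abs(mean(w$w) - 1), 0.02)
})

test_that("estimator degenerations hold exactly", {
  # sufficiency == naive when everyone is sufficient
  tab_all <- est_tab
  tab_all$sufficient <- TRUE
  expect_equal(coef(estimate_sufficiency(tab_all)),
               coef(estimate_naive(tab_all)), tolerance = 1e-12)
  # ipw == sufficiency when all weights are 1
  unit_w <- structure(
    data.frame(patient_id = est_tab$patient_id,
               w = 1, p_hat = mean(est_tab$sufficient),
               p_bar = mean(est_tab$sufficient)),
    class = c("weight_vector", "data.frame"))
  f_ipw <- estimate_ipw(est_tab, weights = unit_w)
  f_suf <- estimate_sufficiency(est_tab)
  expect_equal(coef(f_ipw), coef(f_suf), tolerance = 1e-10)
  # rescaling every weight leaves the point estimates unchanged
  dbl_w <- unit_w
  dbl_w$w <- rep(2, nrow(dbl_w))
  expect_equal(coef(estimate_ipw(est_tab, weights = dbl_w)),
               coef(f_ipw), tolerance = 1e-10)
  # empty sufficient subset is an explicit error
  tab_none <- est_tab
  tab_none$sufficient <- FALSE
  expect_error(estimate_sufficiency(tab_none), "sufficiency")
})

test_that("utilization adjustment reports its encounter coefficient", {
  f_log <- estimate_dag(est_tab, encounter_transform = "log1p")
  expect_true("enc_adj" %in% names(coef(f_log)))
  expect_identical(f_log$encounter_coef, coef(f_log)["enc_adj"])
  f_q <- estimate_dag(est_tab)
  expect_identical(f_q$encounter_transform, "quartile")
  expect_true(length(f_q$encounter_coef) >= 2)
})

test_that("irrelevant utilization leaves the adjusted estimate at the naive one", {
  cfg <- config_no_misclassification(small_config(n = 8000))
  diffs <- vapply(1:6, function(i) {
    ds <- generate_dataset(cfg, seed = 600 + i)
    tab <- build_analysis_table(ds)
    odds_ratio(estimate_dag(tab))$logor - odds_ratio(estimate_naive(tab))$logor
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
})

test_that("complete-case race handling drops unrecorded race", {
  fit_cc <- estimate_naive(est_tab, exposure = "race",
                           race_handling = "complete_case")
  expect_equal(fit_cc$n, sum(!is.na(est_tab$race_eth_observed)))
  fit_si <- estimate_naive(est_tab, exposure = "race")
  expect_equal(fit_si$n, nrow(est_tab))
})
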