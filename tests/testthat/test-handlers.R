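test_that("zero imputation fills zeros and flags missingness", {
  coh <- toy_cohort(P = c(0.7, 0.2, 0.9), Y = c(1, 0, 1), R = c(0, 1, 0))
  prep <- prepare_zero_indicator(coh)
  expect_equal(prep$predictor, c(0.7, 0, 0.9))
  expect_equal(prep$indicator, c(0L, 1L, 0L))
  expect_equal(prep$outcome, coh$Y)
  expect_equal(handler_state(prep)$method, "zero_indicator")

  # degenerate case: nothing missing -> raw design, all-zero indicator
  full <- toy_cohort(P = c(0.1, 0.4), Y = c(0, 1), R = c(0, 0))
  prep_full <- prepare_zero_indicator(full)
  expect_equal(prep_full$predictor, full$P)
  expect_true(all(prep_full$indicator == 0L))
})

test_that("mean imputation learns the observed mean of the cohort at hand", {
  coh <- toy_cohort(P = c(0.2, 0.4, 0.8), Y = c(0, 1, 1), R = c(0, 0, 1))
  prep <- prepare_mean_indicator(coh)
  expect_equal(handler_state(prep)$learned_mean, 0.3)
  expect_equal(prep$predictor, c(0.2, 0.4, 0.3))
  expect_equal(prep$indicator, c(0L, 0L, 1L))

  # independent group-by recomputation on a generated cohort
  big <- generate_cohort(3000, seed = 5) |>
    apply_missingness(mechanism_informative(), seed = 6)
  oracle <- tapply(big$P, big$R, mean)[["0"]]
  expect_equal(handler_state(prepare_mean_indicator(big))$learned_mean, oracle)

  none_obs <- toy_cohort(P = c(0.2, 0.4), Y = c(0, 1), R = c(1, 1))
  expect_error(prepare_mean_indicator(none_obs),
               class = "misshift_handler_inapplicable")
})

test_that("complete-case analysis keeps exactly the observed subjects", {
  coh <- toy_cohort(P = seq(0.05, 0.95, length.out = 10),
                    Y = rep(c(0, 1), 5), R = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0))
  prep <- prepare_complete_case(coh)
  expect_equal(nrow(prep), 6)
  expect_setequal(prep$id, coh$id[coh$R == 0L])
  expect_false("indicator" %in% names(prep))

  all_missing <- toy_cohort(P = c(0.2, 0.4), Y = c(0, 1), R = c(1, 1))
  expect_error(prepare_complete_case(all_missing),
               class = "misshift_handler_inapplicable")

  none_missing <- toy_cohort(P = c(0.2, 0.4), Y = c(0, 1), R = c(0, 0))
  expect_equal(nrow(prepare_complete_case(none_missing)), 2)
})

test_that("PMM imputes only observed donor values, within their support", {
  coh <- generate_cohort(2000, seed = 7) |>
    apply_missingness(mechanism_informative(), seed = 8)
  prep <- pmm_impute(coh, donor_count = 5, seed = 9)
  observed <- coh$P_observed[coh$R == 0L]
  imputed <- prep$predictor[coh$R == 1L]
  expect_true(all(imputed %in% observed))
  expect_true(all(imputed >= min(observed) & imputed <= max(observed)))
  # observed subjects pass through untouched
  expect_equal(prep$predictor[coh$R == 0L], observed)
  # reproducible under a fixed seed
  expect_identical(as.data.frame(prep),
                   as.data.frame(pmm_impute(coh, donor_count = 5, seed = 9)))
  st <- handler_state(prep)
  expect_equal(st$method, "chained_imputation")
  expect_equal(st$pmm_donor_count, 5L)
  expect_length(st$pmm_draw$beta_star, 2)
})

test_that("PMM degenerate and error cases behave as documented", {
  full <- toy_cohort(P = c(0.1, 0.5, 0.9), Y = c(0, 1, 1), R = c(0, 0, 0))
  prep <- pmm_impute(full, seed = 1)
  expect_equal(prep$predictor, full$P)
  expect_null(handler_state(prep)$pmm_draw)

  sparse <- toy_cohort(P = c(0.1, 0.5, 0.9), Y = c(0, 1, 1), R = c(1, 1, 0))
  expect_error(pmm_impute(sparse, donor_count = 5, seed = 1),
               class = "misshift_handler_inapplicable")
  expect_error(pmm_impute(full, donor_count = 0),
               class = "misshift_invalid_parameter")
})

test_that("PMM imputations sit between the outcome-stratum means of observed P", {
  coh <- generate_cohort(20000, seed = 17) |>
    apply_missingness(mechanism_informative(), seed = 18)
  prep <- pmm_impute(coh, seed = 19)
  imputed_mean <- mean(prep$predictor[coh$R == 1L])
  obs <- coh[coh$R == 0L, ]
  m0 <- mean(obs$P_observed[obs$Y == 0])
  m1 <- mean(obs$P_observed[obs$Y == 1])
  expect_gt(imputed_mean, min(m0, m1))
  expect_lt(imputed_mean, max(m0, m1))
})

test_that("handler preparation is idempotent and uses only the cohort at hand", {
  coh <- generate_cohort(1000, seed = 23) |>
    apply_missingness(mechanism_informative(), seed = 24)
  for (m in c("zero", "mean", "cca")) {
    p1 <- prepare_cohort(coh, m)
    p2 <- prepare_cohort(coh, m)
    expect_identical(as.data.frame(p1), as.data.frame(p2))
  }
  # mean imputation recomputes from the application cohort, not a carried
  # development mean: two cohorts with different observed means learn
  # different means
  other <- generate_cohort(1000, seed = 25) |>
    apply_missingness(mechanism_mcar(0.5), seed = 26)
  expect_false(isTRUE(all.equal(
    handler_state(prepare_mean_indicator(coh))$learned_mean,
    handler_state(prepare_mean_indicator(other))$learned_mean)))
})

test_that("zero- and mean-indicator designs are reparameterizations: identical fitted probabilities", {
  coh <- generate_cohort(5000, seed = 29) |>
    apply_missingness(mechanism_informative(), seed = 30)
  fit_zero <- fit_logistic(prepare_zero_indicator(coh))
  prep_mean <- prepare_mean_indicator(coh)
  fit_mean <- fit_logistic(prep_mean)
  p_zero <- predict_probability(fit_zero, prepare_zero_indicator(coh))
  p_mean <- predict_probability(fit_mean, prep_mean)
  expect_equal(p_zero, p_mean, tolerance = 1e-6)
})

test_that("indicator models saturate the missing group at its outcome rate", {
  coh <- generate_cohort(5000, seed = 33) |>
    apply_missingness(mechanism_informative(), seed = 34)
  prep <- prepare_zero_indicator(coh)
  fit <- fit_logistic(prep)
  p <- predict_probability(fit, prep)
  rate_missing <- mean(coh$Y[coh$R == 1L])
  expect_equal(unique(round(p[coh$R == 1L], 10)),
               round(rate_missing, 10), tolerance = 1e-6)
})
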