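test_that("generated cohorts follow the logistic outcome model deterministically", {
  coh1 <- generate_cohort(500, seed = 11)
  coh2 <- generate_cohort(500, seed = 11)
  expect_identical(coh1, coh2)

  params <- generation_params()
  expect_equal(coh1$true_risk,
               plogis(params$intercept + params$coef_P * coh1$P +
                        params$coef_U * coh1$U))
  expect_true(all(coh1$true_risk > 0 & coh1$true_risk < 1))
  expect_true(all(coh1$P >= 0 & coh1$P <= 1))
  expect_true(all(coh1$Y %in% 0:1))
  expect_identical(coh1$P_observed, coh1$P)

  # a different seed changes the draws
  expect_false(identical(coh1$P, generate_cohort(500, seed = 12)$P))

  expect_error(generate_cohort(0, seed = 1), class = "misshift_invalid_parameter")
  expect_error(generation_params(intercept = Inf),
               class = "misshift_invalid_parameter")
})

test_that("cohort CSV serialization round-trips losslessly, including masked values", {
  coh <- generate_cohort(200, seed = 3) |>
    apply_missingness(mechanism_informative(), seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(coh))
  # missing P_observed is an empty field, never a sentinel value
  raw <- readLines(path)
  expect_identical(raw[1], "id,P,U,true_risk,Y,R,P_observed")
  expect_true(any(grepl(",$", raw[-1])))
})

test_that("missingness probabilities match their closed forms", {
  inf <- mechanism_informative()
  expect_equal(missingness_probability(0, 0, inf), plogis(3))
  expect_equal(missingness_probability(0.5, 0.5, inf), 0.5)
  expect_equal(missingness_probability(c(0.1, 0.9), c(0.2, 0.3), inf),
               plogis(3 - 2 * c(0.1, 0.9) - 2 * c(0.2, 0.3) -
                        4 * c(0.1, 0.9) * c(0.2, 0.3)))
  expect_equal(missingness_probability(c(0, 1), c(1, 0), mechanism_none()),
               c(0, 0))
  expect_equal(missingness_probability(c(0, 1), c(1, 0), mechanism_all()),
               c(1, 1))
  expect_equal(missingness_probability(0.3, 0.8, mechanism_mcar(0.25)), 0.25)
  expect_error(missingness_probability(-0.1, 0.5, inf),
               class = "misshift_invalid_parameter")
  expect_error(mechanism_mcar(1.2), class = "misshift_invalid_parameter")
})

test_that("outcome prevalence and informative missingness match quadrature expectations", {
  params <- generation_params()
  risk_fun <- function(p, u) plogis(params$intercept + params$coef_P * p +
                                      params$coef_U * u)
  miss_fun <- function(p, u) plogis(3 - 2 * p - 2 * u - 4 * p * u)
  ey <- unit_square_mean(risk_fun)
  er <- unit_square_mean(miss_fun)

  n <- 20000
  reps <- 20
  seeds <- 100 + seq_len(reps)
  prev <- numeric(reps)
  miss <- numeric(reps)
  for (i in seq_len(reps)) {
    coh <- generate_cohort(n, seed = seeds[i]) |>
      apply_missingness(mechanism_informative(), seed = seeds[i] + 1000)
    prev[i] <- mean(coh$Y)
    miss[i] <- mean(coh$R)
  }
  se_prev <- sqrt(ey * (1 - ey) / (reps * n))
  se_miss <- sqrt(er * (1 - er) / (reps * n))
  expect_lt(abs(mean(prev) - ey), 3 * se_prev)
  expect_lt(abs(mean(miss) - er), 3 * se_miss)

  # mean true risk itself agrees with the quadrature value
  big <- generate_cohort(200000, seed = 999)
  se_risk <- sd(big$true_risk) / sqrt(nrow(big))
  expect_lt(abs(mean(big$true_risk) - ey), 3 * se_risk)
})

test_that("masking is exact for every mechanism and leaves the cohort untouched", {
  base <- generate_cohort(5000, seed = 21)
  for (mech in list(mechanism_informative(), mechanism_none(),
                    mechanism_mcar(0.5), mechanism_all())) {
    coh <- apply_missingness(base, mech, seed = 22)
    expect_identical(sum(is.na(coh$P_observed)), sum(coh$R == 1L))
    expect_identical(coh$P_observed[coh$R == 0L], coh$P[coh$R == 0L])
    # the mechanism draws its own substream: P, U, Y, true_risk unchanged
    expect_identical(coh[c("id", "P", "U", "true_risk", "Y")],
                     base[c("id", "P", "U", "true_risk", "Y")])
  }
  none <- apply_missingness(base, mechanism_none(), seed = 1)
  expect_true(all(none$R == 0L))
  all_m <- apply_missingness(base, mechanism_all(), seed = 1)
  expect_true(all(all_m$R == 1L))
  expect_identical(apply_missingness(base, mechanism_mcar(0.5), seed = 7),
                   apply_missingness(base, mechanism_mcar(0.5), seed = 7))
})

test_that("MCAR missingness is uncorrelated with P, U and Y", {
  coh <- generate_cohort(100000, seed = 31) |>
    apply_missingness(mechanism_mcar(0.5), seed = 32)
  se <- 1 / sqrt(nrow(coh))
  expect_lt(abs(cor(coh$R, coh$P)), 3 * se)
  expect_lt(abs(cor(coh$R, coh$U)), 3 * se)
  expect_lt(abs(cor(coh$R, coh$Y)), 3 * se)
})

test_that("informative missingness matches its conditional expectation within strata", {
  coh <- generate_cohort(100000, seed = 41) |>
    apply_missingness(mechanism_informative(), seed = 42)
  stratum <- coh$P < 0.1 & coh$U < 0.1
  p_true <- mean(plogis(3 - 2 * coh$P[stratum] - 2 * coh$U[stratum] -
                          4 * coh$P[stratum] * coh$U[stratum]))
  se <- sqrt(p_true * (1 - p_true) / sum(stratum))
  expect_lt(abs(mean(coh$R[stratum]) - p_true), 3 * se)
})
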