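# Exhaustive O(n^2) pair-count concordance: the independent oracle for the
# rank-sum c-statistic.
cstat_brute <- function(predicted, outcomes) {
  cases <- predicted[outcomes == 1]
  controls <- predicted[outcomes == 0]
  total <- 0
  for (a in cases) {
    for (b in controls) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
  }
  total / (length(cases) * length(controls))
}

# Hand-built cohort with fully specified fields, for handler unit tests.
toy_cohort <- function(P, Y, R, U = rep(0.5, length(P))) {
  params <- generation_params()
  tibble::tibble(
    id = seq_along(P), P = P, U = U,
    true_risk = stats::plogis(params$intercept + params$coef_P * P +
                                params$coef_U * U),
    Y = as.integer(Y), R = as.integer(R),
    P_observed = ifelse(R == 1L, NA_real_, P)
  )
}

# Quadrature expectation of f(P, U) over the unit square (independent
# oracle for marginal prevalence / missingness checks).
unit_square_mean <- function(f) {
  pracma::integral2(f, 0, 1, 0, 1, reltol = 1e-10)$Q
}
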