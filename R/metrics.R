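#' Per-subject prediction errors against the generating truth
#'
#' `error_i = predicted_i - true_risk_i`: positive values mean
#' over-prediction. This sign convention makes a positive mean prediction
#' error cohere with a negative calibration-in-the-large on the same
#' predictions.
#'
#' @param predicted Predicted probabilities in \[0, 1\].
#' @param true_risk True outcome risks from the generating mechanism.
#' @return Numeric vector of errors.
#' @export
prediction_errors <- function(predicted, true_risk) {
  if (length(predicted) != length(true_risk)) {
    abort("`predicted` and `true_risk` must have equal length.",
          class = "misshift_interface_error")
  }
  if (any(predicted < 0 | predicted > 1, na.rm = TRUE)) {
    abort("`predicted` must lie in [0, 1].", class = "misshift_interface_error")
  }
  predicted - true_risk
}

#' Root mean squared prediction error
#'
#' `sqrt(mean(errors^2))` — the population (n) denominator, as opposed to
#' the sample (n-1) denominator used for the SD of the errors.
#'
#' @param errors Numeric vector of prediction errors.
#' @return Non-negative scalar.
#' @export
rmspe <- function(errors) {
  if (length(errors) == 0) {
    abort("RMSPE is undefined for an empty error vector.",
          class = "misshift_undefined_metric")
  }
  sqrt(mean(errors^2))
}

#' Concordance (c-) statistic
#'
#' The probability that a randomly chosen case receives a higher prediction
#' than a randomly chosen non-case, ties counted 1/2 — the Mann–Whitney
#' statistic. Computed via midranks in O(n log n); equals the exhaustive
#' pair count exactly, including under ties (constant predictions give
#' exactly 0.5).
#'
#' @param predicted Predicted probabilities (any monotone score works: the
#'   c-statistic is invariant under strictly increasing transforms).
#' @param outcomes Binary outcomes (0/1); both classes must be present.
#' @return Scalar in \[0, 1\].
#' @export
c_statistic <- function(predicted, outcomes) {
  check_binary_metric_args(predicted, outcomes, need_both_classes = TRUE)
  n1 <- as.numeric(sum(outcomes == 1))
  n0 <- as.numeric(sum(outcomes == 0))
  r <- rank(predicted)  # midranks handle ties
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and binary outcome.
#'
#' @inheritParams c_statistic
#' @return Scalar in \[0, 1\].
#' @export
brier_score <- function(predicted, outcomes) {
  check_binary_metric_args(predicted, outcomes, need_both_classes = FALSE)
  mean((predicted - outcomes)^2)
}

#' Calibration-in-the-large
#'
#' The intercept of a logistic recalibration model: outcomes regressed on an
#' intercept only, with the logit of the predictions as a fixed offset.
#' Zero means mean predictions match mean outcomes on the log-odds scale;
#' negative values indicate over-prediction. Predictions are clipped to
#' `[1e-10, 1 - 1e-10]` before taking logits.
#'
#' @inheritParams c_statistic
#' @return Scalar on the log-odds scale.
#' @export
calibration_in_the_large <- function(predicted, outcomes) {
  check_binary_metric_args(predicted, outcomes, need_both_classes = TRUE)
  lp <- qlogis(pmin(pmax(predicted, 1e-10), 1 - 1e-10))
  fit <- suppressWarnings(
    glm(outcomes ~ 1, offset = lp, family = binomial(),
        control = glm.control(epsilon = 1e-10, maxit = 100))
  )
  as.numeric(coef(fit)[1])
}

check_binary_metric_args <- function(predicted, outcomes, need_both_classes) {
  if (length(predicted) == 0 || length(outcomes) == 0) {
    abort("Metric is undefined on empty input.",
          class = "misshift_undefined_metric")
  }
  if (length(predicted) != length(outcomes)) {
    abort("`predicted` and `outcomes` must have equal length.",
          class = "misshift_interface_error")
  }
  if (!all(outcomes %in% c(0, 1))) {
    abort("`outcomes` must be binary 0/1.", class = "misshift_interface_error")
  }
  if (need_both_classes && length(unique(outcomes)) < 2) {
    abort("Metric is undefined when only one outcome class is present.",
          class = "misshift_undefined_metric")
  }
  invisible(NULL)
}

#' Summarise predictive performance
#'
#' Computes the five-number performance summary for one set of predictions:
#' mean and SD (sample, n-1 denominator) of the prediction error against the
#' generating truth, the root mean squared prediction error (population
#' denominator), the c-statistic, the Brier score and
#' calibration-in-the-large against the realised outcomes. Only subjects
#' with predictions enter — a complete-case handler at application time
#' evaluates the retained subset only.
#'
#' @param predicted Predicted probabilities.
#' @param true_risk True risks under the generating mechanism (same length).
#' @param outcomes Realised binary outcomes (same length).
#' @return A one-row tibble: `n_evaluated`, `mean_prediction_error`,
#'   `sd_prediction_error`, `rmspe`, `c_statistic`, `brier`,
#'   `calibration_in_the_large`.
#' @examples
#' coh <- generate_cohort(2000, seed = 1)
#' summarize_performance(coh$true_risk, coh$true_risk, coh$Y)
#' @export
summarize_performance <- function(predicted, true_risk, outcomes) {
  if (length(true_risk) != length(predicted)) {
    abort("`predicted` and `true_risk` must have equal length.",
          class = "misshift_interface_error")
  }
  err <- prediction_errors(predicted, true_risk)
  tibble::tibble(
    n_evaluated = length(predicted),
    mean_prediction_error = mean(err),
    sd_prediction_error = sd(err),
    rmspe = rmspe(err),
    c_statistic = c_statistic(predicted, outcomes),
    brier = brier_score(predicted, outcomes),
    calibration_in_the_large = calibration_in_the_large(predicted, outcomes)
  )
}
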