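#' Missing-data handling strategies
#'
#' Four strategies turn a cohort with (possibly) missing `P` into a design
#' ready for logistic regression. Each follows a two-phase contract: the same
#' preparation is run at development time (before fitting) and again at
#' application time (before prediction), using only the cohort at hand —
#' mirroring deployment practice in which missing data are handled the same
#' way in both datasets.
#'
#' * `prepare_zero_indicator()`: missing `P` is imputed with 0 and a binary
#'   missingness indicator is added to the design.
#' * `prepare_mean_indicator()`: missing `P` is imputed with the mean of the
#'   observed values *of the cohort being prepared*, plus the indicator.
#' * `prepare_complete_case()`: only subjects with observed `P` are retained;
#'   no indicator.
#' * `pmm_impute()`: a single stochastic imputation by predictive mean
#'   matching using the observed `P` and the outcome `Y` (see its own help
#'   page); no indicator.
#'
#' `prepare_cohort()` dispatches on a method keyword (`"zero"`, `"mean"`,
#' `"cca"`, `"mi"`).
#'
#' The returned design is a tibble with columns `id`, `predictor`,
#' `indicator` (zero/mean only) and `outcome`, carrying a `handler_state`
#' attribute (retrievable with [handler_state()]) that records what the
#' handler learned — the imputation mean, the PMM coefficient draw — for
#' auditability.
#'
#' @param cohort A cohort tibble with `R` set (see [apply_missingness()]).
#' @param method One of `"zero"`, `"mean"`, `"cca"`, `"mi"`.
#' @param donor_count PMM donor pool size (passed to [pmm_impute()]).
#' @param seed Seed for the PMM draws (passed to [pmm_impute()]).
#'
#' @return A prepared-design tibble as described above.
#' @examples
#' coh <- generate_cohort(500, seed = 1) |>
#'   apply_missingness(mechanism_informative(), seed = 2)
#' prepare_cohort(coh, "zero")
#' @name prepare_cohort
NULL

#' @rdname prepare_cohort
#' @export
prepare_cohort <- function(cohort, method = c("zero", "mean", "cca", "mi"),
                           donor_count = 5, seed = NULL) {
  method <- match.arg(method)
  switch(method,
    zero = prepare_zero_indicator(cohort),
    mean = prepare_mean_indicator(cohort),
    cca  = prepare_complete_case(cohort),
    mi   = pmm_impute(cohort, donor_count = donor_count, seed = seed)
  )
}

#' @rdname prepare_cohort
#' @export
prepare_zero_indicator <- function(cohort) {
  check_cohort(cohort)
  out <- tibble::tibble(
    id = cohort$id,
    predictor = dplyr::if_else(cohort$R == 1L, 0, cohort$P_observed),
    indicator = cohort$R,
    outcome = cohort$Y
  )
  new_prepared(out, list(method = "zero_indicator"))
}

#' @rdname prepare_cohort
#' @export
prepare_mean_indicator <- function(cohort) {
  check_cohort(cohort)
  observed <- cohort$P_observed[cohort$R == 0L]
  if (length(observed) == 0) {
    abort("Mean imputation is inapplicable: no observed values of P to average.",
          class = "misshift_handler_inapplicable")
  }
  m <- mean(observed)
  out <- tibble::tibble(
    id = cohort$id,
    predictor = dplyr::if_else(cohort$R == 1L, m, cohort$P_observed),
    indicator = cohort$R,
    outcome = cohort$Y
  )
  new_prepared(out, list(method = "mean_indicator", learned_mean = m))
}

#' @rdname prepare_cohort
#' @export
prepare_complete_case <- function(cohort) {
  check_cohort(cohort)
  kept <- dplyr::filter(cohort, .data$R == 0L)
  if (nrow(kept) == 0) {
    abort("Complete-case analysis is inapplicable: no subjects with observed P.",
          class = "misshift_handler_inapplicable")
  }
  out <- tibble::tibble(
    id = kept$id, predictor = kept$P_observed, outcome = kept$Y
  )
  new_prepared(out, list(method = "complete_case"))
}

#' Single imputation by predictive mean matching
#'
#' Imputes missing `P` values with one draw of predictive mean matching
#' (PMM), the default elementary imputation method of chained-equations
#' software, using the observed `P` and the outcome `Y`:
#'
#' 1. Ordinary least squares of `P` on an intercept and `Y` among subjects
#'    with observed `P`.
#' 2. A Bayesian draw of the residual variance (scaled inverse chi-square)
#'    and of the coefficients (normal around the OLS estimate).
#' 3. Predicted values: observed subjects under the OLS point estimate,
#'    missing subjects under the drawn coefficients (type-1 matching).
#' 4. For each missing subject, the `donor_count` observed subjects with the
#'    closest predicted values form the donor pool — ties at the pool
#'    boundary are all included — and one donor is drawn uniformly; its
#'    *observed* `P` becomes the imputed value.
#'
#' Because donors contribute their observed values, imputations are always
#' elements of the observed-`P` multiset (hot-deck property). A single
#' imputed dataset is produced; there is no pooling over multiple
#' imputations. Note the procedure uses the outcome `Y`, at application time
#' too — deliberate here, since the study protocol handles missing data
#' identically at development and deployment, but a real deployment would
#' not know `Y`.
#'
#' @param cohort A cohort tibble with `R` set.
#' @param donor_count Donor pool size (default 5).
#' @param seed Integer seed making the imputation reproducible; `NULL` uses
#'   the current RNG state.
#'
#' @return A prepared-design tibble (`id`, `predictor`, `outcome`) whose
#'   `handler_state` records the seed, donor count and coefficient draw.
#' @examples
#' coh <- generate_cohort(500, seed = 1) |>
#'   apply_missingness(mechanism_informative(), seed = 2)
#' prep <- pmm_impute(coh, seed = 3)
#' handler_state(prep)$pmm_draw
#' @export
pmm_impute <- function(cohort, donor_count = 5, seed = NULL) {
  check_cohort(cohort)
  if (!is.numeric(donor_count) || length(donor_count) != 1 ||
      donor_count < 1 || donor_count != floor(donor_count)) {
    abort("`donor_count` must be a positive integer.",
          class = "misshift_invalid_parameter")
  }
  obs <- which(cohort$R == 0L)
  mis <- which(cohort$R == 1L)
  if (length(mis) > 0 && length(obs) < donor_count) {
    abort(sprintf(
      "PMM is inapplicable: %d observed values of P but %d donors required.",
      length(obs), donor_count), class = "misshift_handler_inapplicable")
  }
  state <- list(method = "chained_imputation",
                imputation_seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                pmm_donor_count = as.integer(donor_count))
  predictor <- cohort$P_observed

  if (length(mis) > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    y_obs <- cohort$P_observed[obs]
    X_obs <- cbind(1, cohort$Y[obs])
    X_mis <- cbind(1, cohort$Y[mis])
    xtx <- crossprod(X_obs)
    # tiny ridge guards against a single-class Y among the observed subjects
    V <- tryCatch(solve(xtx), error = function(e)
      solve(xtx + diag(1e-5 * pmax(diag(xtx), 1))))
    beta_hat <- drop(V %*% crossprod(X_obs, y_obs))
    resid <- y_obs - drop(X_obs %*% beta_hat)
    df <- max(length(obs) - ncol(X_obs), 1)
    sigma2_star <- sum(resid^2) / rchisq(1, df)
    beta_star <- beta_hat +
      drop(t(chol(V)) %*% rnorm(ncol(X_obs))) * sqrt(sigma2_star)
    yhat_obs <- drop(X_obs %*% beta_hat)
    yhat_mis <- drop(X_mis %*% beta_star)

    # donor search per distinct target prediction (Y is binary, so there are
    # at most two); pool = the donor_count closest donors plus all boundary ties
    imputed <- numeric(length(mis))
    for (v in unique(yhat_mis)) {
      tgt <- which(yhat_mis == v)
      d <- abs(yhat_obs - v)
      thr <- sort(d, partial = donor_count)[donor_count]
      pool <- which(d <= thr)
      picks <- pool[sample.int(length(pool), length(tgt), replace = TRUE)]
      imputed[tgt] <- y_obs[picks]
    }
    predictor[mis] <- imputed
    state$pmm_draw <- list(beta_hat = beta_hat, beta_star = beta_star,
                           sigma2_star = sigma2_star)
  }

  out <- tibble::tibble(id = cohort$id, predictor = predictor,
                        outcome = cohort$Y)
  new_prepared(out, state)
}

new_prepared <- function(data, state) {
  attr(data, "handler_state") <- state
  class(data) <- c("prepared_design", class(data))
  data
}

#' Inspect what a handler learned
#'
#' @param prepared A prepared-design tibble from [prepare_cohort()] and
#'   friends.
#' @return A list with at least `method`; mean imputation adds
#'   `learned_mean`, PMM adds `imputation_seed`, `pmm_donor_count` and
#'   `pmm_draw`.
#' @export
handler_state <- function(prepared) {
  st <- attr(prepared, "handler_state")
  if (is.null(st)) {
    abort("`prepared` does not carry a handler state; was it produced by `prepare_cohort()`?",
          class = "misshift_interface_error")
  }
  st
}

#' Write a prepared design to CSV (for debugging)
#'
#' @param prepared A prepared-design tibble.
#' @param path File path.
#' @return `prepared`, invisibly.
#' @export
write_prepared <- function(prepared, path) {
  readr::write_csv(as.data.frame(prepared), path, na = "")
  invisible(prepared)
}
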