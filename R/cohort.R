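#' Parameters of the outcome-generating model
#'
#' The synthetic cohorts carry two independent Uniform(0,1) predictors: `P`,
#' which is potentially observed, and `U`, which is never available to the
#' prediction model. The binary outcome `Y` is drawn from a Bernoulli
#' distribution with
#' \deqn{\Pr(Y = 1 \mid P, U) = \mathrm{expit}(\beta_0 + \beta_P P + \beta_U U).}
#' The defaults (`-5`, `3`, `5`) give an outcome prevalence of about 34%.
#'
#' @param intercept Intercept \eqn{\beta_0} of the outcome linear predictor.
#' @param coef_P Coefficient \eqn{\beta_P} on the observable predictor `P`.
#' @param coef_U Coefficient \eqn{\beta_U} on the unobserved predictor `U`.
#'
#' @return An object of class `generation_params`.
#' @examples
#' generation_params()
#' @export
generation_params <- function(intercept = -5, coef_P = 3, coef_U = 5) {
  for (v in c(intercept, coef_P, coef_U)) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      abort("All outcome-model coefficients must be finite scalars.",
            class = "misshift_invalid_parameter")
    }
  }
  structure(
    list(intercept = intercept, coef_P = coef_P, coef_U = coef_U),
    class = "generation_params"
  )
}

#' @export
print.generation_params <- function(x, ...) {
  cat(sprintf("<generation_params> Pr(Y=1) = expit(%g + %g P + %g U)\n",
              x$intercept, x$coef_P, x$coef_U))
  invisible(x)
}

#' Missing-data mechanisms
#'
#' A `missingness_mechanism` describes how the missingness flag `R` (1 = `P`
#' missing) is generated:
#'
#' * `informative`: \eqn{\Pr(R=1 \mid P,U) = \mathrm{expit}(\gamma_0 +
#'   \gamma_P P + \gamma_U U + \gamma_{PU} P U)}. With the default
#'   coefficients (3, -2, -2, -4) about half the cohort is missing and
#'   missingness depends on both predictors — including the unobserved `U`,
#'   so the mechanism is missing-not-at-random and absence of `P` is itself
#'   predictive of the outcome.
#' * `none`: `P` is observed for everyone.
#' * `mcar`: missing completely at random with probability `mcar_rate`.
#' * `all`: `P` is missing for everyone.
#'
#' `mechanism_informative()`, `mechanism_none()`, `mechanism_mcar()` and
#' `mechanism_all()` are convenience constructors.
#'
#' @param variant One of `"informative"`, `"none"`, `"mcar"`, `"all"`.
#' @param mcar_rate Marginal missingness probability used by the `mcar`
#'   variant; must lie in \[0, 1\].
#' @param informative_coefs Named numeric vector of the four coefficients of
#'   the informative linear predictor: `intercept`, `P`, `U`, `PU`.
#'
#' @return An object of class `missingness_mechanism`.
#' @examples
#' mechanism_informative()
#' mechanism_mcar(0.5)
#' @export
missingness_mechanism <- function(variant = c("informative", "none", "mcar", "all"),
                                  mcar_rate = 0.5,
                                  informative_coefs = c(intercept = 3, P = -2,
                                                        U = -2, PU = -4)) {
  variant <- match.arg(variant)
  if (!is.numeric(mcar_rate) || length(mcar_rate) != 1 ||
      is.na(mcar_rate) || mcar_rate < 0 || mcar_rate > 1) {
    abort("`mcar_rate` must be a single value in [0, 1].",
          class = "misshift_invalid_parameter")
  }
  if (length(informative_coefs) != 4 || !all(is.finite(informative_coefs))) {
    abort("`informative_coefs` must be four finite values (intercept, P, U, PU).",
          class = "misshift_invalid_parameter")
  }
  names(informative_coefs) <- c("intercept", "P", "U", "PU")
  structure(
    list(variant = variant, mcar_rate = mcar_rate,
         informative_coefs = informative_coefs),
    class = "missingness_mechanism"
  )
}

#' @rdname missingness_mechanism
#' @export
mechanism_informative <- function(informative_coefs = c(intercept = 3, P = -2,
                                                        U = -2, PU = -4)) {
  missingness_mechanism("informative", informative_coefs = informative_coefs)
}

#' @rdname missingness_mechanism
#' @export
mechanism_none <- function() missingness_mechanism("none")

#' @rdname missingness_mechanism
#' @export
mechanism_mcar <- function(mcar_rate = 0.5) {
  missingness_mechanism("mcar", mcar_rate = mcar_rate)
}

#' @rdname missingness_mechanism
#' @export
mechanism_all <- function() missingness_mechanism("all")

#' @export
print.missingness_mechanism <- function(x, ...) {
  desc <- switch(x$variant,
    informative = sprintf("Pr(R=1) = expit(%g + %g P + %g U + %g PU)",
                          x$informative_coefs[1], x$informative_coefs[2],
                          x$informative_coefs[3], x$informative_coefs[4]),
    none = "Pr(R=1) = 0 (fully observed)",
    mcar = sprintf("Pr(R=1) = %g (MCAR)", x$mcar_rate),
    all  = "Pr(R=1) = 1 (fully missing)")
  cat(sprintf("<missingness_mechanism: %s> %s\n", x$variant, desc))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Draws `n` subjects with independent Uniform(0,1) predictors `P` and `U`,
#' the true outcome risk implied by `params`, and a Bernoulli outcome `Y`.
#' The missingness flag `R` is left unset (`NA`) until a mechanism is imposed
#' with [apply_missingness()]; `P_observed` starts out equal to `P`.
#'
#' `true_risk` is always computed from the true `P`, even after `P` is
#' masked: prediction error is defined against the generating mechanism, not
#' against what a model can see.
#'
#' @param n Number of subjects (positive integer). Default 20000.
#' @param params A [generation_params()] object.
#' @param seed Integer seed; identical `(n, params, seed)` give a
#'   bit-identical cohort. `NULL` uses the current RNG state.
#'
#' @return A tibble with columns `id`, `P`, `U`, `true_risk`, `Y`, `R`,
#'   `P_observed`.
#' @examples
#' coh <- generate_cohort(1000, seed = 1)
#' mean(coh$Y)
#' @seealso [apply_missingness()], [write_cohort()]
#' @export
generate_cohort <- function(n = 20000, params = generation_params(), seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 || n != floor(n)) {
    abort("`n` must be a positive integer.", class = "misshift_invalid_parameter")
  }
  stopifnot(inherits(params, "generation_params"))
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(as.integer(seed))
  P <- runif(n)
  U <- runif(n)
  true_risk <- plogis(params$intercept + params$coef_P * P + params$coef_U * U)
  Y <- rbinom(n, 1L, true_risk)
  tibble::tibble(
    id = seq_len(n), P = P, U = U, true_risk = true_risk,
    Y = Y, R = NA_integer_, P_observed = P
  )
}

#' Missingness probability of a mechanism
#'
#' Evaluates \eqn{\Pr(R = 1 \mid P, U)} for each subject under a given
#' mechanism. Vectorised over `P` and `U`.
#'
#' @param P,U Predictor values in \[0, 1\] (recycled to a common length).
#' @param mechanism A [missingness_mechanism()].
#'
#' @return Numeric vector of probabilities in \[0, 1\].
#' @examples
#' missingness_probability(0.5, 0.5, mechanism_informative())  # 0.5
#' @export
missingness_probability <- function(P, U, mechanism = mechanism_informative()) {
  stopifnot(inherits(mechanism, "missingness_mechanism"))
  if (any(P < 0 | P > 1, na.rm = TRUE) || any(U < 0 | U > 1, na.rm = TRUE)) {
    abort("`P` and `U` must lie in [0, 1].", class = "misshift_invalid_parameter")
  }
  k <- max(length(P), length(U))
  P <- rep_len(P, k)
  U <- rep_len(U, k)
  switch(mechanism$variant,
    informative = {
      g <- mechanism$informative_coefs
      plogis(g[["intercept"]] + g[["P"]] * P + g[["U"]] * U + g[["PU"]] * P * U)
    },
    none = rep(0, k),
    mcar = rep(mechanism$mcar_rate, k),
    all  = rep(1, k)
  )
}

#' Impose a missing-data mechanism on a cohort
#'
#' Draws `R ~ Bernoulli(Pr(R=1 | P, U))` per subject under `mechanism` and
#' masks `P_observed` (sets it to `NA`) wherever `R = 1`. `P`, `U`,
#' `true_risk` and `Y` are untouched, so changing the mechanism never changes
#' the underlying cohort — missingness consumes its own random substream via
#' `seed`.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param mechanism A [missingness_mechanism()].
#' @param seed Integer seed for the missingness draws; `NULL` uses the
#'   current RNG state.
#'
#' @return The cohort with `R` and `P_observed` set.
#' @examples
#' coh <- generate_cohort(1000, seed = 1) |>
#'   apply_missingness(mechanism_informative(), seed = 2)
#' mean(coh$R)
#' @export
apply_missingness <- function(cohort, mechanism = mechanism_informative(),
                              seed = NULL) {
  check_cohort(cohort, require_R = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  pr <- missingness_probability(cohort$P, cohort$U, mechanism)
  flag <- as.integer(rbinom(nrow(cohort), 1L, pr))
  dplyr::mutate(cohort,
    R = !!flag,
    P_observed = dplyr::if_else(.data$R == 1L, NA_real_, .data$P)
  )
}

check_cohort <- function(cohort, require_R = TRUE) {
  needed <- c("id", "P", "U", "true_risk", "Y", "R", "P_observed")
  if (!is.data.frame(cohort) || !all(needed %in% names(cohort))) {
    abort(paste0("`cohort` must be a data frame with columns ",
                 paste(needed, collapse = ", "), "."),
          class = "misshift_interface_error")
  }
  if (require_R && anyNA(cohort$R)) {
    abort("Missingness has not been applied to this cohort; call `apply_missingness()` first.",
          class = "misshift_interface_error")
  }
  invisible(cohort)
}

#' Read and write cohorts as CSV
#'
#' Cohorts serialise to plain CSV with header
#' `id,P,U,true_risk,Y,R,P_observed`; a missing `P_observed` is written as an
#' empty field. Doubles are written in shortest round-trippable form, so a
#' write/read round trip is lossless.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#'
#' @return `write_cohort()` returns `cohort` invisibly; `read_cohort()`
#'   returns the cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  check_cohort(cohort, require_R = FALSE)
  readr::write_csv(cohort, path, na = "")
  invisible(cohort)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  readr::read_csv(
    path, na = "",
    col_types = readr::cols(
      id = readr::col_integer(), P = readr::col_double(),
      U = readr::col_double(), true_risk = readr::col_double(),
      Y = readr::col_integer(), R = readr::col_integer(),
      P_observed = readr::col_double()
    ),
    progress = FALSE
  )
}
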