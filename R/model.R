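#' Fit a logistic prediction model on a prepared design
#'
#' Maximum-likelihood binary logistic regression of `outcome` on every other
#' column of the design except `id`, in column order (for the standard
#' handlers that is `predictor` plus, for the indicator methods,
#' `indicator`). Fitting is by iteratively reweighted least squares via
#' [stats::glm()] with a tight convergence tolerance, so score-equation
#' identities (mean fitted probability = outcome prevalence; saturated-group
#' probabilities) hold to numerical precision.
#'
#' Complete separation does not abort: the fit is returned with
#' `converged = FALSE` and a warning, so simulation pipelines can degrade
#' gracefully on small or degenerate cohorts.
#'
#' @param data A prepared-design tibble (columns `id`, covariates,
#'   `outcome`), e.g. from [prepare_cohort()].
#' @param tolerance Convergence tolerance on the relative change in
#'   deviance. Default `1e-8`.
#' @param max_iterations IRLS iteration cap. Default 100.
#'
#' @return An object of class `logistic_fit`: a list with
#'   `coefficient_names`, `coefficients`, `converged`, `log_likelihood`,
#'   `n_fit` and `tolerance`.
#' @examples
#' coh <- generate_cohort(2000, seed = 1) |>
#'   apply_missingness(mechanism_informative(), seed = 2)
#' fit <- prepare_cohort(coh, "zero") |> fit_logistic()
#' tidy(fit)
#' @export
fit_logistic <- function(data, tolerance = 1e-8, max_iterations = 100) {
  if (!is.data.frame(data) || !"outcome" %in% names(data) || nrow(data) == 0) {
    abort("`data` must be a non-empty design with an `outcome` column.",
          class = "misshift_interface_error")
  }
  covariates <- setdiff(names(data), c("id", "outcome"))
  if (length(covariates) == 0) {
    abort("`data` has no covariate columns.", class = "misshift_interface_error")
  }
  y <- data$outcome
  if (length(unique(y)) < 2) {
    abort("Outcome has a single class; the logistic fit is degenerate.",
          class = "misshift_degenerate_fit")
  }

  X <- as.data.frame(data[covariates])
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = X, family = binomial(),
        control = glm.control(epsilon = tolerance, maxit = max_iterations)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  converged <- isTRUE(fit$converged) && !separated
  if (!converged) {
    warn("Logistic fit did not converge cleanly (possible separation); coefficients returned with converged = FALSE.",
         class = "misshift_nonconvergence")
  }
  structure(
    list(
      coefficient_names = c("(Intercept)", covariates),
      coefficients = setNames(as.numeric(coef(fit)),
                              c("(Intercept)", covariates)),
      converged = converged,
      log_likelihood = as.numeric(logLik(fit)),
      n_fit = nrow(data),
      tolerance = tolerance
    ),
    class = "logistic_fit"
  )
}

#' Predicted outcome probabilities from a fitted model
#'
#' Applies the fitted logistic model to a prepared design: the expit of the
#' linear predictor, per included subject. Subjects a handler excluded (e.g.
#' complete-case analysis at application time) are simply absent from the
#' design and receive no prediction.
#'
#' @param model A `logistic_fit`.
#' @param data A prepared-design tibble whose covariate columns match the
#'   model's `coefficient_names`.
#'
#' @return Numeric vector of probabilities, one per row of `data`.
#' @export
predict_probability <- function(model, data) {
  stopifnot(inherits(model, "logistic_fit"))
  covariates <- model$coefficient_names[-1]
  have <- setdiff(names(data), c("id", "outcome"))
  if (!setequal(have, covariates)) {
    abort(sprintf(
      "Design columns (%s) do not match model covariates (%s).",
      paste(have, collapse = ", "), paste(covariates, collapse = ", ")),
      class = "misshift_interface_error")
  }
  X <- cbind(1, as.matrix(data[covariates]))
  plogis(drop(X %*% model$coefficients))
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d, logLik = %.3f, converged = %s\n",
              x$n_fit, x$log_likelihood, x$converged))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Tidy a fitted logistic prediction model
#'
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @return `tidy()`: a tibble with `term` and `estimate`; `glance()`: a
#'   one-row tibble with `converged`, `log_likelihood`, `n_fit` and `df`.
#' @method tidy logistic_fit
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble::tibble(term = x$coefficient_names,
                 estimate = as.numeric(x$coefficients))
}

#' @rdname tidy.logistic_fit
#' @method glance logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(converged = x$converged,
                 log_likelihood = x$log_likelihood,
                 n_fit = x$n_fit,
                 df = length(x$coefficients))
}

#' Serialise a fitted model to JSON and back
#'
#' @param model A `logistic_fit`.
#' @param path File path.
#' @return `write_model()` returns `model` invisibly; `read_model()` the
#'   restored `logistic_fit`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "logistic_fit"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(model)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$coefficients <- setNames(as.numeric(x$coefficients),
                             x$coefficient_names)
  structure(x, class = "logistic_fit")
}
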