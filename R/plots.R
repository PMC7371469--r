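#' Plot predicted probability against true risk
#'
#' `autoplot()` on a `missing_study` draws the prediction-versus-truth
#' scatter for every populated (scenario, method) cell on a subsample of
#' evaluated subjects, predictions jittered for visual clarity, with the
#' identity line as the perfect-calibration reference. Points for subjects
#' whose `P` was missing are coloured separately — under the indicator
#' methods these collapse onto a single predicted value.
#'
#' @param object A `missing_study` from [run_study()].
#' @param scenarios Scenarios to include (default: all run).
#' @param methods Methods to include (default: all run).
#' @param sample_size Subjects sampled per cell (default 500).
#' @param jitter Half-width of the uniform jitter on predictions
#'   (default 0.02).
#' @param seed Seed for the subsampling and jitter.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' res <- run_study(study_config(n_dev = 2000, n_app = 2000, seed = 42))
#' autoplot(res, scenarios = c(1, 2), methods = "zero")
#' @method autoplot missing_study
#' @export
autoplot.missing_study <- function(object, scenarios = NULL, methods = NULL,
                                   sample_size = 500, jitter = 0.02,
                                   seed = 1, ...) {
  scenarios <- scenarios %||% object$config$scenarios
  methods <- methods %||% object$config$methods
  grid <- tidyr::expand_grid(scenario = as.character(scenarios),
                             method = methods)
  seeds <- derive_seeds(seed, paste0(grid$scenario, "_", grid$method))
  df <- purrr::pmap(grid, function(scenario, method) {
    key <- paste0("s", scenario, "_", method)
    if (is.null(object$cells[[key]])) return(NULL)
    export_plot_data(object, scenario, method, sample_size = sample_size,
                     jitter = jitter,
                     seed = seeds[[paste0(scenario, "_", method)]])
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(
      scenario = scenario_labels[.data$scenario],
      method = method_labels[.data$method],
      `P missing` = factor(.data$R, c(0, 1), c("observed", "missing"))
    )

  ggplot2::ggplot(df, ggplot2::aes(x = .data$true_risk,
                                   y = .data$predicted_jittered,
                                   colour = .data$`P missing`)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::facet_grid(method ~ scenario) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "True risk (generating mechanism)",
                  y = "Predicted probability (jittered)") +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "bottom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
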