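#' Configure a missingness-transportability study
#'
#' Bundles every knob of the simulation experiment. The defaults reproduce
#' the reference study design: development and application cohorts of 20000
#' subjects, informative missingness at development, the four handling
#' methods, and four application scenarios —
#'
#' 1. the development (informative) mechanism again,
#' 2. no missing values,
#' 3. missing completely at random in an expected 50% of subjects,
#' 4. `P` missing for everyone.
#'
#' @param n_dev,n_app Development / application cohort sizes.
#' @param seed Master seed; every random component of the study draws from a
#'   substream derived deterministically from it.
#' @param replications Number of independent repetitions of the whole study
#'   (>= 1). The first replication is the headline result; with more than
#'   one, Monte Carlo summaries across replications are added.
#' @param methods Subset of `c("zero", "mean", "cca", "mi")`.
#' @param scenarios Subset of `1:4`.
#' @param donor_count PMM donor pool size.
#' @param mcar_rate Missingness probability of scenario 3.
#' @param params [generation_params()] of the outcome model.
#' @param verbose Emit a structured log line per (scenario, method) cell.
#'
#' @return An object of class `study_config`.
#' @examples
#' study_config(n_dev = 2000, n_app = 2000, seed = 7)
#' @export
study_config <- function(n_dev = 20000, n_app = 20000, seed = 1,
                         replications = 1,
                         methods = c("zero", "mean", "cca", "mi"),
                         scenarios = 1:4, donor_count = 5, mcar_rate = 0.5,
                         params = generation_params(), verbose = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (n_dev < 1 || n_app < 1 || replications < 1) {
    abort("Cohort sizes and `replications` must be positive.",
          class = "misshift_invalid_parameter")
  }
  if (!all(scenarios %in% 1:4)) {
    abort("`scenarios` must be a subset of 1:4.",
          class = "misshift_invalid_parameter")
  }
  structure(
    list(n_dev = as.integer(n_dev), n_app = as.integer(n_app),
         seed = as.integer(seed), replications = as.integer(replications),
         methods = methods, scenarios = sort(unique(as.integer(scenarios))),
         donor_count = as.integer(donor_count), mcar_rate = mcar_rate,
         params = params, verbose = isTRUE(verbose)),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(
    "<study_config> n_dev=%d n_app=%d seed=%d reps=%d methods=%s scenarios=%s donors=%d\n",
    x$n_dev, x$n_app, x$seed, x$replications,
    paste(x$methods, collapse = ","), paste(x$scenarios, collapse = ","),
    x$donor_count))
  invisible(x)
}

#' Read a study configuration from a YAML / key-value file
#'
#' Keys mirror the arguments of [study_config()]; unknown keys raise an
#' error. Values given in the file override the defaults.
#'
#' @param path Path to a YAML (or flat `key: value`) file.
#' @param ... Overrides applied on top of the file (e.g. from CLI flags;
#'   flags win).
#' @return A `study_config`.
#' @export
read_study_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(study_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort(paste0("Unknown configuration keys: ", paste(bad, collapse = ", ")),
          class = "misshift_invalid_parameter")
  }
  do.call(study_config, vals)
}

#' Application-scenario missingness mechanisms
#'
#' @param scenario Integer 1-4.
#' @param mcar_rate MCAR probability for scenario 3.
#' @return A [missingness_mechanism()].
#' @export
scenario_mechanism <- function(scenario, mcar_rate = 0.5) {
  switch(as.character(scenario),
    "1" = mechanism_informative(),
    "2" = mechanism_none(),
    "3" = mechanism_mcar(mcar_rate),
    "4" = mechanism_all(),
    abort("`scenario` must be 1, 2, 3 or 4.",
          class = "misshift_invalid_parameter"))
}

metric_cols <- c("n_evaluated", "mean_prediction_error", "sd_prediction_error",
                 "rmspe", "c_statistic", "brier", "calibration_in_the_large")

na_report <- function() {
  tibble::tibble(
    n_evaluated = NA_integer_, mean_prediction_error = NA_real_,
    sd_prediction_error = NA_real_, rmspe = NA_real_, c_statistic = NA_real_,
    brier = NA_real_, calibration_in_the_large = NA_real_
  )
}

#' Run the full missingness-transportability study
#'
#' Executes the complete experiment defined by a [study_config()]:
#'
#' 1. generate a development cohort and impose informative missingness;
#' 2. for each handling method, prepare the development design and fit a
#'    logistic prediction model of the outcome on the prepared `P` (plus
#'    missingness indicator where the method adds one);
#' 3. fit the reference model on the same development cohort with `P` fully
#'    observed;
#' 4. generate an independent application cohort and, per scenario, impose
#'    that scenario's missingness mechanism, re-apply the same handling
#'    method (recomputed from the application cohort, as deployment would),
#'    predict, and score against both the realised outcomes and the true
#'    generating risk.
#'
#' Cells where a handler cannot run (e.g. mean imputation or complete-case
#' analysis when `P` is missing for everyone) are recorded as not applicable
#' rather than failing the study. With `replications > 1` the whole pipeline
#' repeats on independent substreams and across-replication Monte Carlo
#' summaries are attached; the headline `table` and per-subject `cells`
#' always come from the first replication.
#'
#' @param config A [study_config()].
#' @return An object of class `missing_study`: a list with `table`
#'   (tibble of one row per (scenario, method) cell incl. the reference row),
#'   `cells` (per-cell tibbles of `id`, `true_risk`, `Y`, `R`, `predicted`),
#'   `models` (the fitted `logistic_fit`s), `development` (a one-row tibble
#'   of development-cohort margins: outcome prevalence, missingness rate,
#'   outcome rates by missingness group), `replicates` (per-replication
#'   tables), `summary` (across-replication mean / SD / Monte Carlo SE per
#'   metric, when `replications > 1`), `config`, `seeds` and `timestamp`.
#' @examples
#' res <- run_study(study_config(n_dev = 2000, n_app = 2000, seed = 42))
#' res$table
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  rep_seeds <- derive_seeds(config$seed,
                            paste0("rep", seq_len(config$replications)))
  reps <- purrr::map(rep_seeds, function(s) run_single_study(config, s))

  replicates <- purrr::imap(reps, function(r, nm) {
    dplyr::mutate(r$table, replication = match(nm, names(rep_seeds)),
                  .before = 1)
  })
  replicate_table <- dplyr::bind_rows(replicates)

  summary <- NULL
  if (config$replications > 1) {
    summary <- replicate_table |>
      dplyr::filter(.data$applicable) |>
      tidyr::pivot_longer(dplyr::all_of(setdiff(metric_cols, "n_evaluated")),
                          names_to = "metric", values_to = "value") |>
      dplyr::group_by(.data$scenario, .data$method, .data$metric) |>
      dplyr::summarise(
        mean = mean(.data$value),
        mc_sd = sd(.data$value),
        mc_se = sd(.data$value) / sqrt(dplyr::n()),
        n_replications = dplyr::n(),
        .groups = "drop"
      )
  }

  structure(
    list(table = reps[[1]]$table, cells = reps[[1]]$cells,
         models = reps[[1]]$models, development = reps[[1]]$development,
         replicates = replicate_table,
         summary = summary, config = config, seeds = rep_seeds,
         timestamp = format(Sys.time(), tz = "UTC")),
    class = "missing_study"
  )
}

run_single_study <- function(config, seed) {
  labels <- c("dev_gen", "dev_miss", "app_gen", "dev_mi",
              paste0("miss_s", 1:4), paste0("mi_s", 1:4), "plot")
  seeds <- derive_seeds(seed, labels)

  dev <- generate_cohort(config$n_dev, config$params, seeds[["dev_gen"]]) |>
    apply_missingness(mechanism_informative(), seeds[["dev_miss"]])

  models <- list()
  for (m in config$methods) {
    models[[m]] <- tryCatch(
      fit_logistic(prepare_cohort(dev, m, donor_count = config$donor_count,
                                  seed = seeds[["dev_mi"]])),
      misshift_handler_inapplicable = function(e) NULL
    )
  }
  ref_design <- tibble::tibble(id = dev$id, predictor = dev$P, outcome = dev$Y)
  models[["reference"]] <- fit_logistic(ref_design)

  app <- generate_cohort(config$n_app, config$params, seeds[["app_gen"]])

  rows <- list()
  cells <- list()

  ref_app <- tibble::tibble(id = app$id, predictor = app$P, outcome = app$Y)
  ref_pred <- predict_probability(models[["reference"]], ref_app)
  rows[["reference"]] <- dplyr::bind_cols(
    tibble::tibble(scenario = "reference", method = "reference",
                   applicable = TRUE),
    summarize_performance(ref_pred, app$true_risk, app$Y))
  cells[["reference"]] <- tibble::tibble(
    id = app$id, true_risk = app$true_risk, Y = app$Y, R = 0L,
    predicted = ref_pred)

  for (s in config$scenarios) {
    mech <- scenario_mechanism(s, config$mcar_rate)
    app_s <- apply_missingness(app, mech, seeds[[paste0("miss_s", s)]])
    for (m in config$methods) {
      key <- paste0("s", s, "_", m)
      prep <- if (is.null(models[[m]])) NULL else tryCatch(
        prepare_cohort(app_s, m, donor_count = config$donor_count,
                       seed = seeds[[paste0("mi_s", s)]]),
        misshift_handler_inapplicable = function(e) NULL
      )
      if (is.null(prep)) {
        rows[[key]] <- dplyr::bind_cols(
          tibble::tibble(scenario = as.character(s), method = m,
                         applicable = FALSE),
          na_report())
        next
      }
      pred <- predict_probability(models[[m]], prep)
      truth <- app_s[match(prep$id, app_s$id), ]
      rows[[key]] <- dplyr::bind_cols(
        tibble::tibble(scenario = as.character(s), method = m,
                       applicable = TRUE),
        summarize_performance(pred, truth$true_risk, truth$Y))
      cells[[key]] <- tibble::tibble(
        id = prep$id, true_risk = truth$true_risk, Y = truth$Y,
        R = truth$R, predicted = pred)
      if (config$verbose) {
        rlang::inform(sprintf(
          "cell scenario=%s method=%s n_fit=%d n_evaluated=%d converged=%s",
          s, m, models[[m]]$n_fit, nrow(prep), models[[m]]$converged))
      }
    }
  }

  development <- tibble::tibble(
    n = nrow(dev), prevalence = mean(dev$Y), missingness_rate = mean(dev$R),
    outcome_rate_missing = mean(dev$Y[dev$R == 1L]),
    outcome_rate_observed = mean(dev$Y[dev$R == 0L])
  )

  list(table = dplyr::bind_rows(rows), cells = cells, models = models,
       development = development, seeds = seeds)
}

method_labels <- c(reference = "No missing values", zero = "Zero imputation",
                   mean = "Mean imputation", cca = "CCA",
                   mi = "Multiple imputation")
scenario_labels <- c(reference = "Reference", "1" = "Scenario 1",
                     "2" = "Scenario 2", "3" = "Scenario 3",
                     "4" = "Scenario 4")

#' Render the study result as a performance table
#'
#' Formats the populated (applicable) cells of a study in the conventional
#' layout: the reference row first, then scenarios 1-4 with methods ordered
#' zero imputation, mean imputation, complete-case analysis, multiple
#' imputation; metrics rounded to `digits` decimals. `format = "data"`
#' returns a tibble ready for `readr::write_csv()`; `format = "text"`
#' returns aligned text lines.
#'
#' @param result A `missing_study` from [run_study()].
#' @param format `"data"` (tibble) or `"text"` (character vector).
#' @param digits Decimal places (default 3).
#' @return A tibble or a character vector, per `format`.
#' @export
render_table <- function(result, format = c("data", "text"), digits = 3) {
  stopifnot(inherits(result, "missing_study"))
  format <- match.arg(format)
  tab <- result$table |>
    dplyr::filter(.data$applicable) |>
    dplyr::mutate(
      scenario_label = scenario_labels[.data$scenario],
      method_label = method_labels[.data$method],
      dplyr::across(dplyr::all_of(setdiff(metric_cols, "n_evaluated")),
                    ~ round(.x, digits))
    ) |>
    dplyr::arrange(match(.data$scenario, names(scenario_labels)),
                   match(.data$method, names(method_labels))) |>
    dplyr::select(scenario = "scenario_label", method = "method_label",
                  "mean_prediction_error", "sd_prediction_error", "rmspe",
                  "c_statistic", "brier", "calibration_in_the_large")
  if (format == "data") return(tab)

  fmt <- function(x) ifelse(is.na(x), "NA", formatC(x, digits = digits,
                                                    format = "f"))
  body <- tab |>
    dplyr::mutate(err = paste0(fmt(.data$mean_prediction_error), " (",
                               fmt(.data$sd_prediction_error), ")")) |>
    dplyr::select("scenario", "method", "err", "rmspe", "c_statistic",
                  "brier", "calibration_in_the_large") |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric), fmt))
  header <- c("Scenario", "Method", "Mean prediction error (SD)", "RMSPE",
              "C-statistic", "Brier score", "Calibration-in-the-large")
  mat <- rbind(header, as.matrix(body))
  widths <- apply(nchar(mat), 2, max)
  unname(apply(mat, 1, function(r)
    paste(mapply(formatC, r, width = widths, flag = "-"), collapse = "  ")))
}

#' @export
print.missing_study <- function(x, ...) {
  cat(sprintf("<missing_study> seed=%d reps=%d n_dev=%d n_app=%d (%s)\n",
              x$config$seed, x$config$replications, x$config$n_dev,
              x$config$n_app, x$timestamp))
  cat(render_table(x, format = "text"), sep = "\n")
  invisible(x)
}

#' Tidy and glance methods for study results
#'
#' `tidy()` returns the per-cell performance table in long-friendly wide
#' form (one row per scenario-method cell); `glance()` a one-row summary of
#' the configuration and run.
#'
#' @param x A `missing_study`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy missing_study
#' @export
tidy.missing_study <- function(x, ...) x$table

#' @rdname tidy.missing_study
#' @method glance missing_study
#' @export
glance.missing_study <- function(x, ...) {
  tibble::tibble(
    n_dev = x$config$n_dev, n_app = x$config$n_app, seed = x$config$seed,
    replications = x$config$replications,
    n_cells = nrow(x$table), n_applicable = sum(x$table$applicable),
    timestamp = x$timestamp
  )
}

#' Export prediction-versus-truth plot data for one cell
#'
#' Samples `sample_size` evaluated subjects (uniformly, without replacement)
#' from one (scenario, method) cell and returns their true risk and
#' predicted probability, with optional uniform jitter (±`jitter`) added to
#' a copy of the predictions for plotting; the raw predictions are always
#' retained.
#'
#' @param result A `missing_study`.
#' @param scenario `"reference"` or a scenario number 1-4.
#' @param method One of `"reference"`, `"zero"`, `"mean"`, `"cca"`, `"mi"`
#'   (ignored and taken as `"reference"` when `scenario = "reference"`).
#' @param sample_size Number of subjects to sample (default 500). If it
#'   exceeds the number of evaluated subjects, all are returned with a
#'   warning.
#' @param jitter Half-width of the uniform jitter on the predicted values
#'   (default 0: none).
#' @param seed Seed for sampling and jitter.
#' @return A tibble with `id`, `true_risk`, `Y`, `R`, `predicted`,
#'   `predicted_jittered`, `scenario`, `method`.
#' @export
export_plot_data <- function(result, scenario, method = "zero",
                             sample_size = 500, jitter = 0, seed = NULL) {
  stopifnot(inherits(result, "missing_study"))
  key <- if (identical(as.character(scenario), "reference")) "reference"
         else paste0("s", scenario, "_", method)
  cell <- result$cells[[key]]
  if (is.null(cell)) {
    abort(sprintf("Cell (scenario %s, method %s) is not applicable or was not run.",
                  scenario, method), class = "misshift_interface_error")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  k <- min(sample_size, nrow(cell))
  if (sample_size > nrow(cell)) {
    warn(sprintf("Requested %d subjects but only %d were evaluated; returning all.",
                 sample_size, nrow(cell)))
  }
  out <- cell[sort(sample.int(nrow(cell), k)), ]
  out$predicted_jittered <- out$predicted + runif(k, -jitter, jitter)
  out$scenario <- as.character(scenario)
  out$method <- if (key == "reference") "reference" else method
  out
}

#' Write a study result to disk
#'
#' Writes `results.json` (the full result: configuration, seeds, per-cell
#' table, per-replication tables and Monte Carlo summary) and `table.csv`
#' (the rendered performance table) into `dir`.
#'
#' @param result A `missing_study`.
#' @param dir Output directory (created if needed).
#' @return `result`, invisibly.
#' @export
write_study <- function(result, dir) {
  stopifnot(inherits(result, "missing_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  payload <- list(
    config = unclass(result$config[setdiff(names(result$config), "params")]),
    params = unclass(result$config$params),
    seeds = as.list(result$seeds),
    timestamp = result$timestamp,
    table = result$table,
    replicates = result$replicates,
    summary = result$summary
  )
  jsonlite::write_json(payload, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  readr::write_csv(render_table(result), file.path(dir, "table.csv"), na = "NA")
  invisible(result)
}
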