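# Orchestration: one call per country runs read -> interpolate -> rates
# -> calibrate -> simulate -> density gaps (with optional COVID shock),
# and a batch driver assembles a summary table across countries with a
# family-wide Bonferroni correction.

#' Run the full pipeline for one country
#'
#' Builds the single-year stock panel from the grouped tables, estimates
#' exit rates (falling back to supplied reference rates and a reference
#' age/sex distribution when the country lacks age/sex stocks), estimates
#' the inflow level and entrant sex split, calibrates the entry
#' parameters, simulates to the forecast horizon, and computes density
#' gaps per field plus the all-physician total under every population
#' scenario.
#'
#' @param tables named list of [raw_table()]s; requires
#'   `stocks_by_field`, `graduates` and `population_projection`;
#'   `stocks_by_age_sex` and `migrants` are optional (the former triggers
#'   the reference-rate fallback when absent).
#' @param config a [country_config()].
#' @param method `"grid"` or `"gradient"` calibration.
#' @param objective chi-squared mode, see [chi_squared()].
#' @param seed seed for gradient calibration.
#' @param covid `NULL` or a [covid_shock_config()].
#' @param reference_rates optional `exit_rate_table` used as fallback.
#' @param reference_distribution optional data frame `sex`, `age`,
#'   `weight` (weights sum to 1) giving the age/sex structure assumed for
#'   countries without age/sex stocks.
#' @param n_tests Bonferroni family size for the p-values; defaults to
#'   the number of hypotheses in this country's report (fields + "all").
#' @return list of class `country_result`: `fit`, `run`, `gaps` (a
#'   `gap_report` data frame), `gamma`, `inflow`, `panel`.
#' @export
run_country <- function(tables, config, method = c("grid", "gradient"),
                        objective = c("final_year", "all_years"),
                        seed = 1L, covid = NULL,
                        reference_rates = NULL,
                        reference_distribution = NULL,
                        n_tests = NULL) {
  method <- match.arg(method)
  objective <- match.arg(objective)
  stopifnot(inherits(config, "country_config"))
  need <- c("stocks_by_field", "graduates", "population_projection")
  miss <- setdiff(need, names(tables))
  if (length(miss) > 0L) {
    stop("missing input table(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }

  # stage: stocks -> single-year panel + exit rates
  if (!is.null(tables$stocks_by_age_sex)) {
    panel <- build_stock_panel(tables$stocks_by_age_sex,
                               tables$stocks_by_field)
    gamma <- estimate_exit_rates(compute_net_rates(panel),
                                 reference = reference_rates)
  } else {
    if (is.null(reference_rates) || is.null(reference_distribution)) {
      stop("country lacks age/sex stocks: reference_rates and ",
           "reference_distribution are required", call. = FALSE)
    }
    w <- reference_distribution
    if (abs(sum(w$weight) - 1) > 1e-9) {
      stop("reference_distribution weights must sum to 1", call. = FALSE)
    }
    ft <- tables$stocks_by_field
    rows <- do.call(rbind, lapply(unique(ft$year), function(y) {
      sl <- ft[ft$year == y, ]
      do.call(rbind, lapply(seq_len(nrow(sl)), function(r) {
        data.frame(country = config$country, field = sl$field[r],
                   sex = w$sex, age = w$age, year = y,
                   count = sl$count[r] * w$weight, stringsAsFactors = FALSE)
      }))
    }))
    panel <- stock_panel(rows)
    gamma <- reference_rates
  }

  # stage: inflow level and entrant sex split
  sex_split <- entrant_sex_split(panel, config$last_data_year)
  inflow <- inflow_series(tables$graduates, tables$migrants,
                          sex_split = sex_split)
  inflow$forecast_level <- estimate_inflow(inflow, config$inflow_window)

  # stage: calibration
  fit <- if (method == "grid") {
    calibrate_grid(panel, gamma, inflow, config, objective = objective)
  } else {
    calibrate_gradient(panel, gamma, inflow, config, seed = seed,
                       objective = objective)
  }

  # stage: forecast + validation error
  run <- run_model(panel, fit$params, gamma, inflow, config)
  rmse <- validation_rmse(run, panel)
  fit$rmse_i <- rmse

  # stage: density gaps
  pop <- population_scenario(tables$population_projection)
  scenarios <- unique(pop$scenario)
  if (!("baseline" %in% scenarios)) {
    stop("population projection lacks a 'baseline' scenario", call. = FALSE)
  }
  alts <- setdiff(scenarios, "baseline")
  anchor <- config$last_data_year
  Tmax <- config$forecast_end - anchor
  Y <- inflow$forecast_level
  report_fields <- c(run$fields, "all")
  if (is.null(n_tests)) n_tests <- length(report_fields)

  rows <- lapply(report_fields, function(f) {
    curve <- requirement_curve(panel, pop, f, anchor_year = anchor,
                               scenario = "baseline")
    dg <- density_gap(run, curve, inflow, T = Tmax)
    rmse_f <- if (f == "all") sqrt(sum(rmse^2)) else rmse[[f]]
    sigma_DG <- propagate_error(rmse_f, Tmax) / (Tmax * Y)
    p <- if (sigma_DG > 0) gap_significance(dg$DG, sigma_DG, n_tests) else NA
    dg_alt <- vapply(alts, function(sc) {
      density_gap(run, requirement_curve(panel, pop, f,
                                         anchor_year = anchor,
                                         scenario = sc),
                  inflow, T = Tmax)$DG
    }, numeric(1))
    env <- range(c(dg$DG, dg_alt))
    cov_add <- NA_real_; cov_delta <- NA_real_
    if (!is.null(covid)) {
      cs <- covid_shock(curve, covid, run = run, inflow = inflow)
      cov_add <- cs$additional_per_year
      cov_delta <- cs$delta_DG
    }
    data.frame(country = config$country, field = f, T = Tmax,
               DG = dg$DG, sigma_DG = sigma_DG, p_value = p,
               DG_min = env[1L], DG_max = env[2L],
               covid_additional_per_year = cov_add,
               covid_delta_DG = cov_delta, stringsAsFactors = FALSE)
  })
  gaps <- do.call(rbind, rows)
  if (is.null(covid)) {
    gaps$covid_additional_per_year <- NULL
    gaps$covid_delta_DG <- NULL
  }
  class(gaps) <- c("gap_report", "data.frame")
  structure(list(fit = fit, run = run, gaps = gaps, gamma = gamma,
                 inflow = inflow, panel = panel, config = config),
            class = "country_result")
}

#' @export
print.country_result <- function(x, ...) {
  cat(sprintf("<country_result %s chi2=%.3e>\n", x$config$country,
              x$fit$chi2))
  print(as.data.frame(x$gaps), digits = 3)
  invisible(x)
}

#' Batch-run several countries into a combined report
#'
#' Runs [run_country()] per entry with per-country failure isolation: a
#' stage error in one country is reported and that country is skipped.
#' p-values are Bonferroni-corrected with the family size equal to the
#' total number of hypothesis rows in the combined report, so results do
#' not depend on country ordering.
#'
#' @param countries named list; each element a list with members `tables`
#'   and `config` (passed to [run_country()]).
#' @param ... further arguments passed to every [run_country()] call.
#' @return list of class `batch_result`: `report` (combined `gap_report`)
#'   and `results` (per-country `country_result` or `NULL` on failure).
#' @export
run_batch <- function(countries, ...) {
  results <- vector("list", length(countries))
  names(results) <- names(countries)
  for (nm in names(countries)) {
    results[[nm]] <- tryCatch(
      run_country(countries[[nm]]$tables, countries[[nm]]$config,
                  n_tests = 1L, ...),
      error = function(e) {
        message("country ", nm, " failed: ", conditionMessage(e))
        NULL
      })
  }
  ok <- !vapply(results, is.null, logical(1))
  if (!any(ok)) stop("all countries failed", call. = FALSE)
  report <- do.call(rbind, lapply(results[ok], function(r) r$gaps))
  n_tests <- nrow(report)
  report$p_value <- gap_significance(report$DG, report$sigma_DG, n_tests)
  report <- report[order(report$country, report$field), ]
  rownames(report) <- NULL
  class(report) <- c("gap_report", "data.frame")
  structure(list(report = report, results = results, n_tests = n_tests),
            class = "batch_result")
}

#' Export a model run as tidy CSV
#' @param run a [run_model()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "model_run"))
  utils::write.csv(run$totals, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a gap report as CSV
#' @param gaps a `gap_report` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gap_report <- function(gaps, path) {
  stopifnot(inherits(gaps, "gap_report"))
  utils::write.csv(as.data.frame(gaps), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
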