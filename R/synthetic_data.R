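# Synthetic country generator. Emulates the shapes of the five source
# tables (stocks by age/sex, stocks by field, graduates, migrants,
# population projections) by running the supply model itself forward from
# a parametric initial age pyramid under known ground-truth parameters.
# Every downstream module is therefore testable offline, with parameter
# recovery as the end-to-end check.

#' Logistic exit-hazard curve
#'
#' A parametric stand-in for the empirical age pattern of effective exit
#' rates: essentially zero through the main working ages, rising around
#' retirement to a plateau:
#' `gamma(a) = plateau / (1 + exp(-steepness * (a - age_half)))`.
#'
#' @param age_half age (years) at half the plateau.
#' @param steepness logistic slope, 1/years.
#' @param plateau asymptotic exit probability, in `[0,1]`.
#' @param ages ages to evaluate (default 25-73, the cohort-transition
#'   range).
#' @return `exit_rate_table` with identical curves for both sexes and
#'   `source = "synthetic"`.
#' @export
generate_exit_curve <- function(age_half = 62, steepness = 0.5,
                                plateau = 0.30, ages = 25:73) {
  if (plateau < 0 || plateau > 1) stop("plateau must lie in [0,1]",
                                       call. = FALSE)
  g <- plateau / (1 + exp(-steepness * (ages - age_half)))
  out <- expand.grid(sex = pf_sexes, age = ages,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$sex, out$age), ]
  out$gamma <- g[match(out$age, ages)]
  out$n_years_averaged <- 0L
  out$source <- "synthetic"
  rownames(out) <- NULL
  class(out) <- c("exit_rate_table", "data.frame")
  out
}

#' Specification of a synthetic country
#'
#' The stated world of the generator: a mid-sized country of ~5000
#' physicians observed 2000-2019, two fields with a 30/70 generalist/
#' specialist split, an entry probability near one, a logistic exit curve
#' plateauing around retirement, roughly constant inflow, mild population
#' growth, and 1% multiplicative observation noise on reported counts.
#'
#' @param seed RNG seed; the generator is fully reproducible given it.
#' @param years observed data years.
#' @param forecast_end last projection year (population tables reach it).
#' @param fields field labels (2 for the minimal model, 6 for the
#'   extended shape).
#' @param field_shares initial stock shares per field (sum 1).
#' @param p_enter,p ground-truth entry and field-choice probabilities
#'   (`p` recycled/normalized to the fields).
#' @param exit_age_half,exit_steepness,exit_plateau logistic exit-curve
#'   parameters, see [generate_exit_curve()].
#' @param total_stock initial total head-count.
#' @param mean_age,sd_age initial age-pyramid shape (normal weights over
#'   ages 25-74).
#' @param sex_ratio_F share of women in the initial stock and among
#'   entrants.
#' @param graduates_level,migrants_level annual inflow components.
#' @param inflow_trend multiplicative annual trend on both components.
#' @param inflow_noise_sd lognormal sd of year-to-year inflow noise.
#' @param noise_sd lognormal sd of multiplicative observation noise on
#'   reported (grouped) counts; 0 gives noise-free tables.
#' @param pop_base base population at the first year.
#' @param pop_growth named annual growth rates per scenario; must include
#'   `baseline`.
#' @param country ISO-2-style label for the tables.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, years = 2000:2019,
                           forecast_end = 2040L,
                           fields = c("GP", "specialist"),
                           field_shares = c(0.3, 0.7),
                           p_enter = 0.9, p = c(0.3, 0.7),
                           exit_age_half = 62, exit_steepness = 0.5,
                           exit_plateau = 0.30,
                           total_stock = 5000, mean_age = 47, sd_age = 10,
                           sex_ratio_F = 0.55,
                           graduates_level = 130, migrants_level = 30,
                           inflow_trend = 0, inflow_noise_sd = 0,
                           noise_sd = 0.01,
                           pop_base = 1e6,
                           pop_growth = c(baseline = 0.002,
                                          high_migration = 0.007,
                                          low_fertility = -0.003),
                           country = "SY") {
  if (total_stock <= 0) stop("degenerate spec: zero initial stock",
                             call. = FALSE)
  if (abs(sum(field_shares) - 1) > 1e-9 || any(field_shares < 0)) {
    stop("field_shares must be nonnegative and sum to 1", call. = FALSE)
  }
  if (length(p) != length(fields)) stop("p must match fields", call. = FALSE)
  if (noise_sd < 0 || inflow_noise_sd < 0) stop("noise sd must be >= 0",
                                                call. = FALSE)
  if (!("baseline" %in% names(pop_growth))) {
    stop("pop_growth must include a 'baseline' scenario", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), years = as.integer(years),
                 forecast_end = as.integer(forecast_end),
                 fields = fields, field_shares = field_shares,
                 params = model_params(p_enter, stats::setNames(p, fields)),
                 exit_age_half = exit_age_half,
                 exit_steepness = exit_steepness,
                 exit_plateau = exit_plateau,
                 total_stock = total_stock, mean_age = mean_age,
                 sd_age = sd_age, sex_ratio_F = sex_ratio_F,
                 graduates_level = graduates_level,
                 migrants_level = migrants_level,
                 inflow_trend = inflow_trend,
                 inflow_noise_sd = inflow_noise_sd,
                 noise_sd = noise_sd, pop_base = pop_base,
                 pop_growth = pop_growth, country = country),
            class = "synthetic_spec")
}

# 10-year group label of each single age 25..74
pf_group_label <- stats::setNames(pf_group_of_age, pf_ages)

#' Generate a synthetic country panel with known ground truth
#'
#' Runs the supply model forward from the spec's initial pyramid under
#' the true parameters, aggregates the single-year stocks into 10-year
#' groups, applies multiplicative log-normal observation noise, and emits
#' all five table kinds in the package's CSV schema. The ground truth
#' (exact single-year stocks, parameters, exit curve, inflow) is returned
#' alongside, so estimators can be checked against it.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_panel`: `tables` (named list of five
#'   [raw_table()]s) and `truth` (list with `panel` ([stock_panel()]),
#'   `params`, `gamma`, `inflow`, `spec`).
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  restore <- pf_local_rng(spec$seed)
  on.exit(restore(), add = TRUE)

  years <- spec$years
  t0 <- years[1L]
  K <- length(spec$fields)

  # initial single-year pyramid
  w_age <- stats::dnorm(pf_ages, spec$mean_age, spec$sd_age)
  w_age <- w_age / sum(w_age)
  sexw <- stats::setNames(c(spec$sex_ratio_F, 1 - spec$sex_ratio_F), pf_sexes)
  N0 <- array(0, dim = c(length(pf_ages), 2L, K),
              dimnames = list(age = pf_ages, sex = pf_sexes,
                              field = spec$fields))
  for (k in seq_len(K)) {
    for (s in 1:2) {
      N0[, s, k] <- spec$total_stock * spec$field_shares[k] *
        sexw[s] * w_age
    }
  }

  # observed inflow series (graduates + migrants), optional trend/noise
  n_steps <- length(years) - 1L
  steps <- seq_len(n_steps)
  trend <- (1 + spec$inflow_trend)^steps
  gnoise <- if (spec$inflow_noise_sd > 0)
    exp(stats::rnorm(n_steps, 0, spec$inflow_noise_sd)) else rep(1, n_steps)
  mnoise <- if (spec$inflow_noise_sd > 0)
    exp(stats::rnorm(n_steps, 0, spec$inflow_noise_sd)) else rep(1, n_steps)
  grads <- spec$graduates_level * trend * gnoise
  migs <- spec$migrants_level * trend * mnoise
  inflow <- inflow_series(
    graduates = data.frame(year = years[-1L], count = grads),
    migrants = data.frame(year = years[-1L], count = migs),
    sex_split = sexw)

  gamma <- generate_exit_curve(spec$exit_age_half, spec$exit_steepness,
                               spec$exit_plateau)

  # forward simulation over the observed window
  states <- vector("list", length(years))
  states[[1L]] <- model_state(N0, t0)
  for (i in seq_along(years)[-1L]) {
    states[[i]] <- model_step(states[[i - 1L]], spec$params, gamma, inflow,
                              last_data_year = max(years))
  }

  truth_rows <- do.call(rbind, lapply(seq_along(years), function(i) {
    N <- states[[i]]$N
    do.call(rbind, lapply(seq_len(K), function(k) {
      do.call(rbind, lapply(1:2, function(s) {
        data.frame(country = spec$country, field = spec$fields[k],
                   sex = pf_sexes[s], age = pf_ages, year = years[i],
                   count = N[, s, k], stringsAsFactors = FALSE)
      }))
    }))
  }))
  truth_panel <- stock_panel(truth_rows)

  noisy <- function(x) {
    if (spec$noise_sd > 0) x * exp(stats::rnorm(length(x), 0, spec$noise_sd))
    else x
  }

  # stocks by age group and sex: all fields summed, 10-year groups
  agg <- truth_rows
  agg$age_group <- pf_group_label[as.character(agg$age)]
  by_group <- stats::aggregate(count ~ sex + age_group + year, agg, sum)
  by_group$country <- spec$country
  by_group$count <- noisy(by_group$count)
  stocks_age_sex <- raw_table(
    by_group[c("country", "year", "sex", "age_group", "count")],
    "stocks_by_age_sex")

  by_field <- stats::aggregate(count ~ field + year, agg, sum)
  by_field$country <- spec$country
  by_field$count <- noisy(by_field$count)
  stocks_field <- raw_table(by_field[c("country", "year", "field", "count")],
                            "stocks_by_field")

  graduates <- raw_table(
    data.frame(country = spec$country, year = years[-1L], count = grads),
    "graduates")
  migrants <- raw_table(
    data.frame(country = spec$country, year = years[-1L], count = migs),
    "migrants")

  proj_years <- t0:spec$forecast_end
  pop <- do.call(rbind, lapply(names(spec$pop_growth), function(sc) {
    data.frame(country = spec$country, scenario = sc, year = proj_years,
               count = spec$pop_base *
                 (1 + spec$pop_growth[[sc]])^(proj_years - t0),
               stringsAsFactors = FALSE)
  }))
  population <- raw_table(pop, "population_projection")

  structure(list(
    tables = list(stocks_by_age_sex = stocks_age_sex,
                  stocks_by_field = stocks_field,
                  graduates = graduates, migrants = migrants,
                  population_projection = population),
    truth = list(panel = truth_panel, params = spec$params, gamma = gamma,
                 inflow = inflow, spec = spec)),
    class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  sp <- x$truth$spec
  cat(sprintf(
    "<synthetic_panel %s seed=%d years=%s fields=[%s] noise_sd=%g>\n",
    sp$country, sp$seed, paste(range(sp$years), collapse = "-"),
    paste(sp$fields, collapse = ", "), sp$noise_sd))
  invisible(x)
}

#' Write a synthetic panel's tables and ground truth to a directory
#'
#' Emits the five CSVs plus a `truth.json` sidecar with the generating
#' parameters.
#'
#' @param sp a [generate_panel()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_panel <- function(sp, dir) {
  stopifnot(inherits(sp, "synthetic_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (kind in names(sp$tables)) {
    write_table(sp$tables[[kind]], file.path(dir, paste0(kind, ".csv")))
  }
  spec <- sp$truth$spec
  truth <- list(seed = spec$seed, p_enter = spec$params$p_enter,
                p = as.list(spec$params$p),
                exit_curve = list(age_half = spec$exit_age_half,
                                  steepness = spec$exit_steepness,
                                  plateau = spec$exit_plateau),
                noise_sd = spec$noise_sd)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
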