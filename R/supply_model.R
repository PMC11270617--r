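# Simulation core. One model year applies three processes to the stock
# N_i(s,a,t) of physicians in field i, sex s, age a:
#   1. entry:  new physicians (graduates + migrants) enter with
#      probability p_enter and choose field i with probability p_i; the
#      annual inflow Y(t+1) is split by sex and spread uniformly over the
#      entry ages;
#   2. aging:  everyone ages one year; the cohort leaving the top age is
#      removed (forced exit);
#   3. exit:   a fraction gamma(s,a) of each cohort leaves.
# Together: N_i(s,a+1,t+1) = (1 - gamma(s,a)) N_i(s,a,t) + p_enter p_i Y(s,a+1,t+1).
# Stocks are continuous (real-valued) and the engine is deterministic.

#' Model parameters: entry and field-choice probabilities
#'
#' @param p_enter probability that a graduate/migrant enters the
#'   workforce, in `[0,1]`.
#' @param p named (or unnamed) vector of field-choice probabilities on the
#'   probability simplex; in the 2-field case `c(GP = p_GP,
#'   specialist = 1 - p_GP)`.
#' @return list of class `model_params`.
#' @export
model_params <- function(p_enter, p) {
  p_enter <- as.numeric(p_enter)
  nm <- names(p)
  p <- as.numeric(p)
  names(p) <- if (is.null(nm)) paste0("field", seq_along(p)) else nm
  if (length(p_enter) != 1L || p_enter < 0 || p_enter > 1) {
    stop("p_enter must be a probability in [0,1]", call. = FALSE)
  }
  if (any(p < 0 | p > 1) || abs(sum(p) - 1) > 1e-12) {
    stop("field-choice probabilities must lie in [0,1] and sum to 1",
         call. = FALSE)
  }
  structure(list(p_enter = p_enter, p = p), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params p_enter=%.3f p=[%s]>\n", x$p_enter,
              paste(sprintf("%s=%.3f", names(x$p), x$p), collapse = ", ")))
  invisible(x)
}

#' Model state at one year
#'
#' @param N numeric array `[age, sex, field]` with dimnames.
#' @param year integer model year.
#' @return list of class `model_state`.
#' @export
model_state <- function(N, year) {
  stopifnot(is.array(N), length(dim(N)) == 3L)
  if (any(!is.finite(N)) || any(N < 0)) {
    stop("stocks must be finite and nonnegative", call. = FALSE)
  }
  structure(list(N = N, year = as.integer(year),
                 ages = as.integer(dimnames(N)$age)),
            class = "model_state")
}

#' @export
print.model_state <- function(x, ...) {
  cat(sprintf("<model_state year=%d total=%.1f fields=[%s]>\n", x$year,
              sum(x$N), paste(dimnames(x$N)$field, collapse = ", ")))
  invisible(x)
}

#' Initialize the model from data
#'
#' Sets `N_i(s,a,t0) = X_i(s,a,t0)`: the state equals the data slice
#' exactly.
#'
#' @param panel a [stock_panel()].
#' @param t0 initialization year; the panel must contain a complete slice.
#' @return a [model_state()].
#' @export
initialize_model <- function(panel, t0) {
  stopifnot(inherits(panel, "stock_panel"))
  if (!(t0 %in% panel$year)) {
    stop("panel has no data for initialization year ", t0, call. = FALSE)
  }
  model_state(pf_panel_array(panel, t0), t0)
}

# inflow amount for a model year: observed while <= last_data_year,
# constant forecast level afterwards
pf_inflow_for_year <- function(inflow, year, last_data_year) {
  if (year <= last_data_year) {
    i <- match(year, inflow$table$year)
    if (is.na(i)) stop("no observed inflow for data year ", year, call. = FALSE)
    inflow$table$total[i]
  } else {
    if (is.null(inflow$forecast_level)) {
      stop("inflow forecast_level is unset; see estimate_inflow()",
           call. = FALSE)
    }
    inflow$forecast_level
  }
}

#' Advance the model by one year
#'
#' Applies the update equation
#' `N_i(s,a+1,t+1) = (1 - gamma(s,a)) N_i(s,a,t) + p_enter p_i Y(s,a+1,t+1)`
#' for ages above the minimum; the youngest age receives only the entry
#' term, and the cohort aging out of the top modelled age is removed.
#' `Y(s,a,t+1)` distributes the annual inflow by the series' sex split and
#' uniformly over its entry ages.
#'
#' @param state a [model_state()].
#' @param params a [model_params()]; `params$p` must be named by the
#'   state's fields (or match their number).
#' @param gamma an `exit_rate_table` (see [estimate_exit_rates()]) or a
#'   scalar rate; values outside `[0,1]` are an error (a rate above 1
#'   would create negative stocks).
#' @param inflow an [inflow_series()], or `NULL` with `Y` given directly.
#' @param Y optional total inflow for the target year, overriding the
#'   series lookup (used by test harnesses).
#' @param last_data_year boundary between observed and forecast inflow;
#'   defaults to the last year in `inflow$table`.
#' @return the [model_state()] at `state$year + 1`.
#' @export
model_step <- function(state, params, gamma, inflow = NULL, Y = NULL,
                       last_data_year = NULL) {
  stopifnot(inherits(state, "model_state"), inherits(params, "model_params"))
  ages <- state$ages
  n <- length(ages)
  fields <- dimnames(state$N)$field
  K <- length(fields)
  p <- params$p
  if (!is.null(names(p)) && all(fields %in% names(p))) {
    p <- p[fields]
  } else if (length(p) != K) {
    stop("params$p does not match the state's fields", call. = FALSE)
  }
  if (is.null(Y)) {
    if (is.null(inflow)) stop("either inflow or Y must be given", call. = FALSE)
    if (is.null(last_data_year)) last_data_year <- max(inflow$table$year)
    Y <- pf_inflow_for_year(inflow, state$year + 1L, last_data_year)
  }
  entry_ages <- if (!is.null(inflow)) inflow$entry_ages else 25:34
  sex_split <- if (!is.null(inflow)) inflow$sex_split else
    stats::setNames(c(0.5, 0.5), pf_sexes)
  g <- pf_gamma_matrix(gamma, ages)

  N <- state$N
  N1 <- array(0, dim = dim(N), dimnames = dimnames(N))
  surv <- (1 - g[-n, , drop = FALSE])
  for (k in seq_len(K)) {
    N1[-1L, , k] <- surv * N[-n, , k]
  }
  rows <- which(ages %in% entry_ages)
  if (length(rows) > 0L && Y > 0) {
    per_age <- Y / length(entry_ages)
    for (k in seq_len(K)) {
      for (s in seq_along(pf_sexes)) {
        N1[rows, s, k] <- N1[rows, s, k] +
          params$p_enter * p[[k]] * per_age * sex_split[[pf_sexes[s]]]
      }
    }
  }
  model_state(N1, state$year + 1L)
}

#' Run the model over calibration, validation and forecast years
#'
#' Initializes from the panel at `config$t0` and iterates [model_step()]
#' to `config$forecast_end`. Observed annual inflow is used through
#' `config$last_data_year`; the constant `forecast_level` afterwards.
#' Years are labelled `calibration` (t0), `validation`
#' (t0+1 .. last_data_year) and `forecast`.
#'
#' @param panel a [stock_panel()] providing the initial slice.
#' @param params a [model_params()].
#' @param gamma exit rates (see [model_step()]).
#' @param inflow an [inflow_series()] with `forecast_level` set whenever
#'   `forecast_end > last_data_year`.
#' @param config a [country_config()].
#' @return list of class `model_run`: `totals` (data frame `country`,
#'   `field`, `year`, `phase`, `M`), `states` (per-year [model_state()]s),
#'   plus the inputs.
#' @export
run_model <- function(panel, params, gamma, inflow, config) {
  stopifnot(inherits(config, "country_config"))
  state <- initialize_model(panel, config$t0)
  years <- config$t0:config$forecast_end
  states <- vector("list", length(years))
  names(states) <- years
  states[[1L]] <- state
  for (i in seq_along(years)[-1L]) {
    states[[i]] <- model_step(states[[i - 1L]], params, gamma, inflow,
                              last_data_year = config$last_data_year)
  }
  fields <- dimnames(state$N)$field
  phase <- ifelse(years == config$t0, "calibration",
                  ifelse(years <= config$last_data_year, "validation",
                         "forecast"))
  totals <- do.call(rbind, lapply(seq_along(years), function(i) {
    data.frame(country = config$country, field = fields, year = years[i],
               phase = phase[i],
               M = vapply(seq_along(fields),
                          function(k) sum(states[[i]]$N[, , k]), numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(totals) <- NULL
  structure(list(totals = totals, states = states, years = years,
                 phase = stats::setNames(phase, years), fields = fields,
                 params = params, config = config),
            class = "model_run")
}

#' @export
print.model_run <- function(x, ...) {
  last <- x$totals[x$totals$year == max(x$totals$year), ]
  cat(sprintf("<model_run %s %d-%d: %s>\n", x$config$country,
              min(x$years), max(x$years),
              paste(sprintf("%s=%.0f", last$field, last$M), collapse = ", ")))
  invisible(x)
}

#' Per-field totals of a model run
#' @param run a [run_model()] result.
#' @return data frame `field`, `year`, `phase`, `M`.
#' @export
run_totals <- function(run) {
  stopifnot(inherits(run, "model_run"))
  run$totals[c("field", "year", "phase", "M")]
}

## Fast path used by the calibrators ---------------------------------------
# Same update equation on a flat (age x sex*field) matrix; the grid search
# evaluates it ~10^4 times, so avoid the labelled-array bookkeeping.

# returns list(N0, one_minus_g, entry_cols_sex, entry_rows, K)
pf_fast_setup <- function(panel, gamma, inflow, config,
                          end_year = config$forecast_end) {
  arr <- pf_panel_array(panel, config$t0)
  fields <- dimnames(arr)$field
  K <- length(fields)
  n <- length(pf_ages)
  N0 <- matrix(arr, nrow = n, ncol = 2L * K)  # columns: (F,M) per field
  g <- pf_gamma_matrix(gamma)
  one_minus_g <- 1 - g[-n, rep(1:2, K), drop = FALSE]
  years <- (config$t0 + 1L):end_year
  Yv <- vapply(years, pf_inflow_for_year, numeric(1), inflow = inflow,
               last_data_year = config$last_data_year)
  entry_rows <- which(pf_ages %in% inflow$entry_ages)
  split_sf <- rep(as.numeric(inflow$sex_split[pf_sexes]), K)  # per column
  field_of_col <- rep(seq_len(K), each = 2L)
  list(N0 = N0, one_minus_g = one_minus_g, Y = Yv, years = years,
       entry_rows = entry_rows, split_sf = split_sf,
       field_of_col = field_of_col, fields = fields, K = K, n = n)
}

# per-field totals M[K, length(years)+1] for given (p_enter, p)
pf_fast_run <- function(fs, p_enter, p) {
  n <- fs$n; K <- fs$K
  per_entry <- p_enter * p[fs$field_of_col] * fs$split_sf /
    length(fs$entry_rows)
  nT <- length(fs$Y)
  M <- matrix(0, K, nT + 1L)
  N <- fs$N0
  cs <- colSums(N)
  for (k in seq_len(K)) M[k, 1L] <- cs[2L * k - 1L] + cs[2L * k]
  er <- fs$entry_rows
  ner <- length(er)
  for (t in seq_len(nT)) {
    N <- rbind(0, fs$one_minus_g * N[-n, , drop = FALSE])
    if (fs$Y[t] > 0) {
      N[er, ] <- N[er, ] + rep(fs$Y[t] * per_entry, each = ner)
    }
    cs <- colSums(N)
    for (k in seq_len(K)) M[k, t + 1L] <- cs[2L * k - 1L] + cs[2L * k]
  }
  M
}
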