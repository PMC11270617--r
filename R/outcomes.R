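# Outcome measures. The forecast stock per field is compared with a
# constant-density requirement curve: the number of physicians needed to
# keep physicians-per-population at the anchor-year (2019) level under a
# population scenario. The density gap normalizes the difference by the
# horizon times the annual inflow, so it reads as the fraction of annual
# entrants to add (DG > 0 means projected oversupply relative to constant
# density) or remove per year. The COVID-19 demand shock inflates the
# requirement by the fraction of the population at increased risk of
# needing outpatient care after infection.

#' Population scenario trajectories
#'
#' @param x a `population_projection` [raw_table()] or a data frame with
#'   columns `scenario`, `year`, `population` (or `count`).
#' @return data frame of class `population_scenario` with columns
#'   `scenario`, `year`, `population`.
#' @export
population_scenario <- function(x) {
  df <- as.data.frame(x)
  if ("count" %in% names(df) && !("population" %in% names(df))) {
    names(df)[names(df) == "count"] <- "population"
  }
  need <- c("scenario", "year", "population")
  if (!all(need %in% names(df))) {
    stop("population_scenario needs columns scenario, year, population",
         call. = FALSE)
  }
  df <- df[need]
  df$year <- as.integer(df$year)
  df$population <- as.numeric(df$population)
  if (any(!is.finite(df$population)) || any(df$population <= 0)) {
    stop("population must be positive and finite", call. = FALSE)
  }
  df <- df[order(df$scenario, df$year), ]
  rownames(df) <- NULL
  class(df) <- c("population_scenario", "data.frame")
  df
}

#' Constant-density requirement curve
#'
#' Physicians needed per year to keep the field's density at the
#' anchor-year level: `C_i(t) = Z_i(anchor) * pop(t) / pop(anchor)`. The
#' curve equals the observed stock exactly at the anchor year.
#'
#' @param panel observed [stock_panel()] (provides `Z_i(anchor)`).
#' @param population a [population_scenario()].
#' @param field field label, or `"all"` for the summed stock.
#' @param anchor_year density anchor (2019-style); defaults to the last
#'   panel year.
#' @param scenario population scenario label.
#' @return data frame of class `requirement_curve` with columns `field`,
#'   `year`, `C`, `scenario`; attributes `anchor_year`, `anchor_stock`.
#' @export
requirement_curve <- function(panel, population, field,
                              anchor_year = max(panel$year),
                              scenario = "baseline") {
  stopifnot(inherits(panel, "stock_panel"),
            inherits(population, "population_scenario"))
  z <- panel_totals(panel)
  Z_anchor <- if (identical(field, "all")) {
    sum(z$total[z$year == anchor_year])
  } else {
    z$total[z$field == field & z$year == anchor_year]
  }
  if (length(Z_anchor) != 1L || is.na(Z_anchor) ||
      !(anchor_year %in% panel$year)) {
    stop("panel has no stock for field '", field, "' at anchor year ",
         anchor_year, call. = FALSE)
  }
  pop <- population[population$scenario == scenario, ]
  if (!(anchor_year %in% pop$year)) {
    stop("population scenario '", scenario, "' lacks the anchor year ",
         anchor_year, call. = FALSE)
  }
  pop_anchor <- pop$population[pop$year == anchor_year]
  out <- data.frame(field = field, year = pop$year,
                    C = Z_anchor * pop$population / pop_anchor,
                    scenario = scenario, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("requirement_curve", "data.frame"),
            anchor_year = as.integer(anchor_year), anchor_stock = Z_anchor)
}

# modelled totals for a field ("all" sums fields) by year
pf_run_M <- function(run, field) {
  tot <- run$totals
  if (identical(field, "all")) {
    agg <- stats::aggregate(M ~ year, tot, sum)
    stats::setNames(agg$M, agg$year)
  } else {
    sl <- tot[tot$field == field, ]
    if (nrow(sl) == 0L) stop("run has no field '", field, "'", call. = FALSE)
    stats::setNames(sl$M, sl$year)
  }
}

#' Density gap between forecast supply and constant-density requirement
#'
#' `DG(T) = (M_i(anchor+T) - C_i(anchor+T)) / (T * Y)` where `Y` is the
#' constant forecast inflow. Returns the annual series for
#' `T = 1 .. Tmax` together with the terminal value. A positive gap reads
#' as the fraction of annual entrants that could be removed per year
#' while still holding density constant; a negative gap as the fraction
#' to add.
#'
#' @param run a [run_model()] result covering the horizon.
#' @param curve a [requirement_curve()]; its field selects the run totals
#'   (`"all"` sums all fields).
#' @param inflow an [inflow_series()] with positive `forecast_level`.
#' @param T terminal horizon in years; defaults to the last forecast year
#'   minus the anchor year.
#' @return list of class `density_gap`: `series` (data frame `T`, `year`,
#'   `M`, `C`, `DG`), `DG` (terminal value), `T`, `anchor_year`, `field`,
#'   `scenario`, `Y`.
#' @export
density_gap <- function(run, curve, inflow, T = NULL) {
  stopifnot(inherits(run, "model_run"), inherits(curve, "requirement_curve"),
            inherits(inflow, "inflow_series"))
  Y <- inflow$forecast_level
  if (is.null(Y) || !is.finite(Y) || Y <= 0) {
    stop("inflow forecast level must be positive; see estimate_inflow()",
         call. = FALSE)
  }
  anchor <- attr(curve, "anchor_year")
  field <- unique(curve$field)
  M <- pf_run_M(run, field)
  years_avail <- intersect(as.integer(names(M)), curve$year)
  Tmax <- if (is.null(T)) max(years_avail) - anchor else as.integer(T)
  if (Tmax < 1L) stop("horizon T must be >= 1", call. = FALSE)
  horizons <- seq_len(Tmax)
  yrs <- anchor + horizons
  if (!all(yrs %in% years_avail)) {
    stop("run/curve do not cover the horizon ", anchor + Tmax, call. = FALSE)
  }
  Mh <- as.numeric(M[as.character(yrs)])
  Ch <- curve$C[match(yrs, curve$year)]
  series <- data.frame(T = horizons, year = yrs, M = Mh, C = Ch,
                       DG = (Mh - Ch) / (horizons * Y))
  structure(list(series = series, DG = series$DG[Tmax], T = Tmax,
                 anchor_year = anchor, field = field,
                 scenario = unique(curve$scenario), Y = Y),
            class = "density_gap")
}

#' @export
print.density_gap <- function(x, ...) {
  cat(sprintf("<density_gap %s/%s: DG(%d)=%.1f%% (anchor %d)>\n",
              x$field, x$scenario, x$T, 100 * x$DG, x$anchor_year))
  invisible(x)
}

#' Two-sided significance of a density gap
#'
#' Assuming normally distributed forecast errors:
#' `p = 2 * (1 - Phi(|DG| / sigma_DG))`, Bonferroni-multiplied by the
#' number of hypotheses tested in the batch and capped at 1.
#'
#' @param DG density gap (dimensionless fraction).
#' @param sigma_DG its propagated standard error on the same scale, `> 0`.
#' @param n_tests number of hypotheses in the family, `>= 1`.
#' @return p-value in `(0, 1]`.
#' @export
gap_significance <- function(DG, sigma_DG, n_tests = 1L) {
  if (any(sigma_DG <= 0)) stop("sigma_DG must be positive", call. = FALSE)
  if (any(n_tests < 1L)) stop("n_tests must be >= 1", call. = FALSE)
  pmin(1, n_tests * 2 * (1 - stats::pnorm(abs(DG) / sigma_DG)))
}

#' Attenuated post-2022 outpatient-care risk
#'
#' Applies the vaccination/variant attenuation to the baseline increased
#' risk of needing outpatient care after a SARS-CoV-2 infection:
#' `r = r_baseline * (1 - attenuation)`. With the default baseline of 20%
#' (hazard ratio 1.2) and 74% attenuation this gives 5.2%.
#'
#' @param r_baseline baseline increased risk, in `[0,1]`.
#' @param attenuation fractional reduction, in `[0,1]`.
#' @return attenuated risk probability.
#' @examples
#' attenuated_risk(0.20, 0.74)  # 0.052
#' @export
attenuated_risk <- function(r_baseline = 0.20, attenuation = 0.74) {
  if (r_baseline < 0 || r_baseline > 1 || attenuation < 0 || attenuation > 1) {
    stop("r_baseline and attenuation must lie in [0,1]", call. = FALSE)
  }
  r_baseline * (1 - attenuation)
}

#' COVID-19 demand-shock configuration
#'
#' Holds the per-year infection probability `I(t)` and increased
#' outpatient-care risk `r(t)`. The risk is the baseline 20% (hazard
#' ratio 1.2) for years before `attenuation_from` and the attenuated
#' value (5.2% with the 74% default) from then on. Infection
#' probabilities beyond the last supplied year are held at the last
#' supplied level (the conservative "same as 2022" assumption); years
#' before the first supplied year have `I = 0`.
#'
#' @param infection_prob named numeric vector of annual infection
#'   probabilities, names = years (e.g. `c("2020" = 0.05, "2021" = 0.15,
#'   "2022" = 0.30)`), or a single unnamed value applied from
#'   `first_shock_year` on.
#' @param r_baseline baseline increased outpatient-care risk.
#' @param attenuation fractional risk reduction from `attenuation_from`.
#' @param attenuation_from first year with attenuated risk.
#' @param first_shock_year used when `infection_prob` is a single unnamed
#'   value.
#' @return list of class `covid_shock_config` with vectorized functions
#'   `I(years)` and `r(years)`.
#' @export
covid_shock_config <- function(infection_prob = c("2020" = 0.05,
                                                  "2021" = 0.15,
                                                  "2022" = 0.30),
                               r_baseline = 0.20, attenuation = 0.74,
                               attenuation_from = 2022L,
                               first_shock_year = 2020L) {
  if (is.null(names(infection_prob))) {
    if (length(infection_prob) != 1L) {
      stop("unnamed infection_prob must be a single value", call. = FALSE)
    }
    infection_prob <- stats::setNames(infection_prob, first_shock_year)
  }
  iy <- as.integer(names(infection_prob))
  iv <- as.numeric(infection_prob)
  if (any(iv < 0 | iv > 1)) stop("I(t) must lie in [0,1]", call. = FALSE)
  r_att <- attenuated_risk(r_baseline, attenuation)
  I_fun <- function(years) {
    out <- numeric(length(years))
    for (j in seq_along(years)) {
      y <- years[j]
      out[j] <- if (y < min(iy)) 0 else if (y > max(iy)) iv[which.max(iy)] else {
        k <- match(y, iy)
        if (is.na(k)) stop("infection probability undefined for year ", y,
                           call. = FALSE)
        iv[k]
      }
    }
    out
  }
  r_fun <- function(years) ifelse(years >= attenuation_from, r_att, r_baseline)
  structure(list(I = I_fun, r = r_fun, infection_prob = infection_prob,
                 r_baseline = r_baseline, attenuation = attenuation,
                 attenuation_from = as.integer(attenuation_from)),
            class = "covid_shock_config")
}

#' Apply the COVID-19 demand shock to a requirement curve
#'
#' Replaces `C_i(t)` by `C_i(t) * (1 + I(t) * r(t))`: the additional
#' demand from the fraction of the population at increased risk of
#' needing outpatient care after infection. Also reports the mean annual
#' increment in required physicians over the post-anchor years and, when
#' a model run and inflow are supplied, the absolute change in the
#' terminal density gap.
#'
#' @param curve a [requirement_curve()].
#' @param shock a [covid_shock_config()].
#' @param run optional [run_model()] result (for the density-gap delta).
#' @param inflow optional [inflow_series()] (ditto).
#' @return list of class `covid_shock_result`: `curve` (shocked
#'   requirement curve), `additional_per_year` (mean annual extra
#'   physicians over the post-anchor years), and, when `run`/`inflow` are
#'   given, `delta_DG` (absolute difference of terminal density gaps),
#'   `dg_shocked`, `dg_baseline`.
#' @export
covid_shock <- function(curve, shock, run = NULL, inflow = NULL) {
  stopifnot(inherits(curve, "requirement_curve"),
            inherits(shock, "covid_shock_config"))
  anchor <- attr(curve, "anchor_year")
  years <- curve$year
  factor <- 1 + shock$I(years) * shock$r(years)
  shocked <- curve
  shocked$C <- curve$C * factor
  post <- years > anchor
  additional <- if (any(post)) mean(shocked$C[post] - curve$C[post]) else 0
  out <- list(curve = shocked, additional_per_year = additional,
              delta_DG = NULL)
  if (!is.null(run) && !is.null(inflow)) {
    dg0 <- density_gap(run, curve, inflow)
    dg1 <- density_gap(run, shocked, inflow)
    out$delta_DG <- abs(dg1$DG - dg0$DG)
    out$dg_baseline <- dg0
    out$dg_shocked <- dg1
  }
  class(out) <- "covid_shock_result"
  out
}

#' @export
print.covid_shock_result <- function(x, ...) {
  cat(sprintf("<covid_shock_result +%.1f physicians/yr%s>\n",
              x$additional_per_year,
              if (is.null(x$delta_DG)) "" else
                sprintf(" delta_DG=%.2f%%", 100 * x$delta_DG)))
  invisible(x)
}
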