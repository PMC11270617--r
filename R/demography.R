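# Demographic estimation: 10-year age groups -> single-year ages, net
# rates of change, effective exit rates, inflow level and entrant sex
# split. Exit rates are "effective": the net exit component of the
# year-on-year cohort change, absorbing retirement, emigration, death and
# field changes in one nonnegative probability per sex and age.

## Stock panel --------------------------------------------------------------

#' Construct a single-year-age stock panel
#'
#' The central container: physician head-counts by country, field, sex,
#' single-year age (25-74) and year. Every (field, sex, year) slice must
#' cover the full age range; missing years are simply absent.
#'
#' @param df data frame with columns `country`, `field`, `sex`, `age`,
#'   `year`, `count`.
#' @return data frame of class `stock_panel`.
#' @export
stock_panel <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("country", "field", "sex", "age", "year", "count")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("stock_panel: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[need]
  df$age <- as.integer(df$age)
  df$year <- as.integer(df$year)
  df$count <- as.numeric(df$count)
  if (any(!is.finite(df$count)) || any(df$count < 0)) {
    stop("stock_panel: counts must be finite and nonnegative", call. = FALSE)
  }
  if (any(!(df$age %in% pf_ages))) {
    stop("stock_panel: ages must lie in ", min(pf_ages), "-", max(pf_ages),
         call. = FALSE)
  }
  if (any(!(df$sex %in% pf_sexes))) {
    stop("stock_panel: sex must be one of ", paste(pf_sexes, collapse = ","),
         call. = FALSE)
  }
  counts <- stats::aggregate(count ~ field + sex + year, df, length)
  if (any(counts$count != length(pf_ages))) {
    bad <- counts[counts$count != length(pf_ages), ]
    stop("stock_panel: incomplete age coverage for ",
         paste(sprintf("%s/%s/%d", bad$field, bad$sex, bad$year),
               collapse = ", "), call. = FALSE)
  }
  df <- df[order(df$field, df$sex, df$year, df$age), ]
  rownames(df) <- NULL
  class(df) <- c("stock_panel", "data.frame")
  df
}

#' @export
print.stock_panel <- function(x, ...) {
  cat(sprintf("<stock_panel %s: fields=[%s] years=%s total(last)=%.0f>\n",
              paste(unique(x$country), collapse = ","),
              paste(unique(x$field), collapse = ", "),
              paste(range(x$year), collapse = "-"),
              sum(x$count[x$year == max(x$year)])))
  invisible(x)
}

# per-field annual totals Z_i(t)
#' Total stock per field and year
#' @param panel a [stock_panel()].
#' @return data frame `field`, `year`, `total`.
#' @export
panel_totals <- function(panel) {
  stopifnot(inherits(panel, "stock_panel"))
  out <- stats::aggregate(count ~ field + year, as.data.frame(panel), sum)
  names(out)[names(out) == "count"] <- "total"
  out[order(out$field, out$year), ]
}

# dense array [age, sex, field] for one year
pf_panel_array <- function(panel, year) {
  sl <- panel[panel$year == year, ]
  if (nrow(sl) == 0L) stop("panel has no year ", year, call. = FALSE)
  fields <- unique(panel$field)
  arr <- array(0, dim = c(length(pf_ages), length(pf_sexes), length(fields)),
               dimnames = list(age = pf_ages, sex = pf_sexes, field = fields))
  arr[cbind(match(sl$age, pf_ages), match(sl$sex, pf_sexes),
            match(sl$field, fields))] <- sl$count
  arr
}

## Age-group interpolation --------------------------------------------------

# group midpoints: 25-34 -> 29.5, ..., 65-74 -> 69.5
pf_group_mid <- c(`25-34` = 29.5, `35-44` = 39.5, `45-54` = 49.5,
                  `55-64` = 59.5, `65-74` = 69.5)
pf_group_of_age <- rep(pf_age_groups_model, each = 10L)

#' Interpolate 10-year age-group totals to single-year ages
#'
#' Each group's mean count per age year is anchored at the group mid-age;
#' counts change linearly between adjacent mid-ages and are flat beyond
#' the outermost mid-ages. Within each group the ten single-year counts
#' are then rescaled so the group total is conserved exactly.
#'
#' @param grouped either a named numeric vector with names
#'   `"25-34" ... "65-74"`, or a `stocks_by_age_sex` [raw_table()] slice
#'   for a single country/sex/year (the `age_group`/`count` columns are
#'   used; `<25` and `75+` rows are dropped with a warning).
#' @return named numeric vector of counts for ages 25 to 74; group sums
#'   equal the input totals.
#' @examples
#' interpolate_age_groups(setNames(rep(100, 5), c("25-34", "35-44",
#'   "45-54", "55-64", "65-74")))
#' @export
interpolate_age_groups <- function(grouped) {
  if (is.data.frame(grouped)) {
    drop <- grouped$age_group %in% setdiff(pf_age_groups_all, pf_age_groups_model)
    if (any(drop)) {
      warning("dropping out-of-range age group(s): ",
              paste(unique(grouped$age_group[drop]), collapse = ", "),
              call. = FALSE)
      grouped <- grouped[!drop, ]
    }
    if (anyDuplicated(grouped$age_group)) {
      stop("interpolate_age_groups: expects a single country/sex/year slice",
           call. = FALSE)
    }
    grouped <- stats::setNames(grouped$count, grouped$age_group)
  }
  missing_grp <- setdiff(pf_age_groups_model, names(grouped))
  if (length(missing_grp) > 0L) {
    stop("missing age group(s): ", paste(missing_grp, collapse = ", "),
         call. = FALSE)
  }
  totals <- as.numeric(grouped[pf_age_groups_model])
  if (any(!is.finite(totals)) || any(totals < 0)) {
    stop("group totals must be finite and nonnegative", call. = FALSE)
  }
  means <- totals / 10
  vals <- stats::approx(pf_group_mid, means, xout = pf_ages, rule = 2)$y
  vals <- pmax(vals, 0)
  # conserve each group total exactly
  for (g in seq_along(pf_age_groups_model)) {
    idx <- which(pf_group_of_age == pf_age_groups_model[g])
    s <- sum(vals[idx])
    vals[idx] <- if (s > 0) vals[idx] * (totals[g] / s) else 0
  }
  stats::setNames(vals, pf_ages)
}

#' Build a per-field single-year stock panel from grouped tables
#'
#' Interpolates the all-physician age/sex pyramid of each year to single
#' ages, then (optionally) splits it across fields in proportion to the
#' per-field annual totals: the source tables report the age/sex structure
#' only for all physicians combined, so every field is assumed to share it.
#'
#' @param stocks_age_sex `stocks_by_age_sex` [raw_table()].
#' @param stocks_field optional `stocks_by_field` [raw_table()]; when
#'   `NULL` a single field `"all"` is used.
#' @return a [stock_panel()] (years present in both tables when splitting).
#' @export
build_stock_panel <- function(stocks_age_sex, stocks_field = NULL) {
  stopifnot(inherits(stocks_age_sex, "raw_table"),
            attr(stocks_age_sex, "table_kind") == "stocks_by_age_sex")
  country <- unique(stocks_age_sex$country)
  if (length(country) != 1L) {
    stop("build_stock_panel: one country at a time", call. = FALSE)
  }
  tab <- stocks_age_sex[stocks_age_sex$age_group %in% pf_age_groups_model, ]
  years <- sort(unique(tab$year))

  shares <- NULL
  if (!is.null(stocks_field)) {
    stopifnot(inherits(stocks_field, "raw_table"),
              attr(stocks_field, "table_kind") == "stocks_by_field")
    years <- intersect(years, unique(stocks_field$year))
  }

  out <- list()
  for (y in years) {
    pyramid <- list()
    for (s in pf_sexes) {
      sl <- tab[tab$year == y & tab$sex == s, ]
      if (nrow(sl) < length(pf_age_groups_model)) {
        stop("incomplete age/sex coverage in year ", y, " sex ", s,
             call. = FALSE)
      }
      pyramid[[s]] <- interpolate_age_groups(
        stats::setNames(sl$count, sl$age_group))
    }
    if (is.null(stocks_field)) {
      frac <- stats::setNames(1, "all")
    } else {
      fl <- stocks_field[stocks_field$year == y, ]
      tot <- sum(fl$count)
      if (tot <= 0) stop("zero field total in year ", y, call. = FALSE)
      frac <- stats::setNames(fl$count / tot, fl$field)
    }
    for (f in names(frac)) {
      for (s in pf_sexes) {
        out[[length(out) + 1L]] <- data.frame(
          country = country, field = f, sex = s, age = pf_ages, year = y,
          count = pyramid[[s]] * frac[[f]], stringsAsFactors = FALSE)
      }
    }
  }
  stock_panel(do.call(rbind, out))
}

## Net rates and exit rates -------------------------------------------------

#' Net rates of change per sex, age and year
#'
#' For each cohort, the relative change between its stock at age `a` in
#' year `t` and the same cohort's stock at age `a+1` in year `t+1`:
#' `alpha(s,a,t) = (X(s,a+1,t+1) - X(s,a,t)) / X(s,a,t)`. Cells with a
#' zero denominator are flagged invalid rather than raising an error.
#'
#' @param panel a [stock_panel()].
#' @param field field label to restrict to; `NULL` (default) aggregates
#'   all fields, mirroring the all-physician source of the age/sex data.
#' @return data frame of class `net_rate_table` with columns `sex`, `age`,
#'   `year`, `alpha`, `valid`; ages 25-73, years with a successor present.
#' @export
compute_net_rates <- function(panel, field = NULL) {
  stopifnot(inherits(panel, "stock_panel"))
  df <- as.data.frame(panel)
  if (!is.null(field)) {
    if (!(field %in% df$field)) stop("unknown field: ", field, call. = FALSE)
    df <- df[df$field == field, ]
  }
  agg <- stats::aggregate(count ~ sex + age + year, df, sum)
  years <- sort(unique(agg$year))
  pairs <- years[(years + 1L) %in% years]
  if (length(pairs) == 0L) {
    stop("panel must cover at least two consecutive years", call. = FALSE)
  }
  X <- array(NA_real_,
             dim = c(length(pf_ages), length(pf_sexes), length(years)),
             dimnames = list(age = pf_ages, sex = pf_sexes, year = years))
  X[cbind(match(agg$age, pf_ages), match(agg$sex, pf_sexes),
          match(agg$year, years))] <- agg$count

  ages_from <- pf_ages[-length(pf_ages)]          # 25..73
  out <- expand.grid(age = ages_from, sex = pf_sexes, year = pairs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i0 <- cbind(match(out$age, pf_ages), match(out$sex, pf_sexes),
              match(out$year, years))
  i1 <- cbind(match(out$age + 1L, pf_ages), match(out$sex, pf_sexes),
              match(out$year + 1L, years))
  x0 <- X[i0]; x1 <- X[i1]
  out$valid <- is.finite(x0) & is.finite(x1) & x0 > 0
  out$alpha <- ifelse(out$valid, (x1 - x0) / x0, NA_real_)
  out <- out[c("sex", "age", "year", "alpha", "valid")]
  class(out) <- c("net_rate_table", "data.frame")
  out
}

#' Effective exit rates per sex and age
#'
#' Averages the nonnegative exit component of the net rates over all valid
#' years: `gamma(s,a) = mean_t max(0, -alpha(s,a,t))`, clipped to `[0,1]`.
#' The rate is stored as a magnitude, so the supply model's shrinkage term
#' `(1 - gamma) * N` never exceeds `N`. Exit rates are shared across
#' fields. Cells with no valid year fall back to `reference` rates.
#'
#' @param net a `net_rate_table` from [compute_net_rates()].
#' @param reference optional `exit_rate_table` used to fill cells with no
#'   valid observation (see [reference_exit_rates()]).
#' @return data frame of class `exit_rate_table` with columns `sex`, `age`
#'   (25-73), `gamma`, `n_years_averaged`, `source`.
#' @export
estimate_exit_rates <- function(net, reference = NULL) {
  stopifnot(inherits(net, "net_rate_table"))
  if (nrow(net) == 0L) stop("empty net-rate table", call. = FALSE)
  ages_from <- pf_ages[-length(pf_ages)]
  out <- expand.grid(sex = pf_sexes, age = ages_from,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$sex, out$age), ]
  out$gamma <- NA_real_
  out$n_years_averaged <- 0L
  out$source <- "country"
  for (k in seq_len(nrow(out))) {
    sl <- net[net$sex == out$sex[k] & net$age == out$age[k] & net$valid, ]
    if (nrow(sl) > 0L) {
      out$gamma[k] <- min(1, max(0, mean(pmax(0, -sl$alpha))))
      out$n_years_averaged[k] <- nrow(sl)
    }
  }
  miss <- is.na(out$gamma)
  if (any(miss)) {
    if (is.null(reference)) {
      stop("no valid year for ",
           paste(sprintf("%s/%d", out$sex[miss], out$age[miss])[
             seq_len(min(5L, sum(miss)))], collapse = ", "),
           if (sum(miss) > 5L) " ..." else "",
           " and no reference rates supplied", call. = FALSE)
    }
    stopifnot(inherits(reference, "exit_rate_table"))
    ref_key <- paste(reference$sex, reference$age)
    idx <- match(paste(out$sex[miss], out$age[miss]), ref_key)
    if (anyNA(idx)) stop("reference rates do not cover all missing cells",
                         call. = FALSE)
    out$gamma[miss] <- reference$gamma[idx]
    out$source[miss] <- "reference"
  }
  rownames(out) <- NULL
  class(out) <- c("exit_rate_table", "data.frame")
  out
}

#' Reference exit rates from pooled countries
#'
#' Pools (sums) the single-year stocks of all countries with complete
#' age/sex data by sex, age and year, then estimates exit rates from the
#' pooled stocks. Used as a fallback for countries that do not report
#' age- and sex-specific stocks.
#'
#' @param panels list of [stock_panel()] objects, one per country.
#' @return `exit_rate_table` with `source = "reference"`.
#' @export
reference_exit_rates <- function(panels) {
  if (!is.list(panels) || length(panels) == 0L) {
    stop("no complete country panels supplied", call. = FALSE)
  }
  ok <- vapply(panels, function(p) {
    inherits(p, "stock_panel") && length(unique(p$year)) >= 2L
  }, logical(1))
  if (!any(ok)) stop("no complete country panels supplied", call. = FALSE)
  pooled <- do.call(rbind, lapply(panels[ok], as.data.frame))
  agg <- stats::aggregate(count ~ sex + age + year, pooled, sum)
  agg$country <- "POOLED"; agg$field <- "all"
  rates <- estimate_exit_rates(compute_net_rates(stock_panel(agg)))
  rates$source <- "reference"
  rates
}

# gamma lookup matrix [age 25..74, sex]; age 74 value is irrelevant for the
# update (that cohort ages out) but kept at 0 for a rectangular lookup
pf_gamma_matrix <- function(gamma, ages = pf_ages) {
  if (is.numeric(gamma) && length(gamma) == 1L) {
    m <- matrix(gamma, length(ages), length(pf_sexes))
  } else if (inherits(gamma, "exit_rate_table") || is.data.frame(gamma)) {
    m <- matrix(0, length(ages), length(pf_sexes))
    idx <- cbind(match(gamma$age, ages), match(gamma$sex, pf_sexes))
    keep <- !is.na(idx[, 1L])
    m[idx[keep, , drop = FALSE]] <- gamma$gamma[keep]
  } else {
    stop("gamma must be a scalar or an exit_rate_table", call. = FALSE)
  }
  if (any(m < 0 | m > 1)) {
    stop("exit rates must lie in [0, 1]", call. = FALSE)
  }
  dimnames(m) <- list(age = ages, sex = pf_sexes)
  m
}

## Inflow -------------------------------------------------------------------

#' Annual workforce inflow series
#'
#' Entrants per year: graduates plus immigrating physicians, with the sex
#' split and entry-age range applied when the supply model distributes the
#' inflow over cells. Missing years in one component are treated as zero
#' inflow through that channel (with a warning), since the sum needs
#' aligned years.
#'
#' @param graduates either a `graduates` [raw_table()] or a data frame
#'   with columns `year`, `count`.
#' @param migrants same shape as `graduates`, or `NULL` for none.
#' @param sex_split named numeric `c(F = , M = )` summing to 1; see
#'   [entrant_sex_split()].
#' @param entry_ages integer ages over which entrants are spread
#'   uniformly.
#' @param forecast_level constant annual inflow assumed beyond the data
#'   window; usually set from [estimate_inflow()].
#' @return list of class `inflow_series` with element `table` (columns
#'   `year`, `graduates`, `migrants`, `total`).
#' @export
inflow_series <- function(graduates, migrants = NULL,
                          sex_split = c(F = 0.5, M = 0.5),
                          entry_ages = 25:34, forecast_level = NULL) {
  gtab <- as.data.frame(graduates)[c("year", "count")]
  years <- sort(unique(gtab$year))
  mtab <- if (is.null(migrants)) data.frame(year = integer(0), count = numeric(0))
          else as.data.frame(migrants)[c("year", "count")]
  years <- sort(union(years, mtab$year))
  g <- gtab$count[match(years, gtab$year)]
  m <- mtab$count[match(years, mtab$year)]
  if (anyNA(g) || (nrow(mtab) > 0L && anyNA(m))) {
    warning("inflow components missing for some years; treated as 0",
            call. = FALSE)
  }
  g[is.na(g)] <- 0
  m[is.na(m)] <- 0
  if (abs(sum(sex_split) - 1) > 1e-12 || any(sex_split < 0)) {
    stop("sex_split must be nonnegative and sum to 1", call. = FALSE)
  }
  sex_split <- sex_split[pf_sexes]
  structure(list(
    table = data.frame(year = years, graduates = g, migrants = m,
                       total = g + m),
    sex_split = sex_split,
    entry_ages = as.integer(entry_ages),
    forecast_level = forecast_level), class = "inflow_series")
}

#' @export
print.inflow_series <- function(x, ...) {
  cat(sprintf(
    "<inflow_series years=%s mean Y=%.1f forecast_level=%s split F=%.2f>\n",
    paste(range(x$table$year), collapse = "-"), mean(x$table$total),
    if (is.null(x$forecast_level)) "unset" else sprintf("%.1f", x$forecast_level),
    x$sex_split[["F"]]))
  invisible(x)
}

#' Estimate the forecast inflow level
#'
#' Unweighted mean of the total annual inflow `Y(t)` over a window of
#' observed years; this level is held constant over all forecast years.
#'
#' @param inflow an [inflow_series()].
#' @param window integer years, all of which must be observed.
#' @return numeric forecast level.
#' @examples
#' inf <- inflow_series(data.frame(year = 2017:2019, count = c(100, 110, 120)))
#' estimate_inflow(inf, 2017:2019)  # 110
#' @export
estimate_inflow <- function(inflow, window) {
  stopifnot(inherits(inflow, "inflow_series"))
  window <- as.integer(window)
  if (length(window) == 0L) stop("empty inflow window", call. = FALSE)
  miss <- setdiff(window, inflow$table$year)
  if (length(miss) > 0L) {
    stop("inflow window years not observed: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  mean(inflow$table$total[inflow$table$year %in% window])
}

#' Sex split of new entrants
#'
#' Proportions of female and male physicians in the entry-age range
#' (25-34) in a reference year, across all fields; applied to all future
#' entrants (graduates and migrants alike).
#'
#' @param panel a [stock_panel()].
#' @param year reference year (2019-style).
#' @param entry_ages ages defining the entrant group.
#' @return named numeric `c(F = , M = )` summing to 1.
#' @export
entrant_sex_split <- function(panel, year, entry_ages = 25:34) {
  stopifnot(inherits(panel, "stock_panel"))
  sl <- panel[panel$year == year & panel$age %in% entry_ages, ]
  if (nrow(sl) == 0L) stop("reference year ", year, " not in panel",
                           call. = FALSE)
  tot <- vapply(pf_sexes, function(s) sum(sl$count[sl$sex == s]), numeric(1))
  if (sum(tot) <= 0) {
    stop("zero total stock in entry ages ", min(entry_ages), "-",
         max(entry_ages), " in ", year, call. = FALSE)
  }
  tot / sum(tot)
}
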