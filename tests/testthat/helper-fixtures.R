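# Fixtures are built in code; no files are read. Helpers construct the
# small labelled objects the tests need and one independently-coded
# model evaluation used as the calibration oracle.

SEXES <- c("F", "M")
AGES <- 25:74
GROUPS <- c("25-34", "35-44", "45-54", "55-64", "65-74")

# a stocks_by_age_sex raw table from a matrix [group x year] per sex
grouped_table <- function(by_sex_year, years, country = "ZZ") {
  rows <- do.call(rbind, lapply(SEXES, function(s) {
    do.call(rbind, lapply(seq_along(years), function(j) {
      data.frame(country = country, year = years[j], sex = s,
                 age_group = GROUPS, count = by_sex_year[[s]][, j],
                 stringsAsFactors = FALSE)
    }))
  }))
  raw_table(rows, "stocks_by_age_sex")
}

# stock panel with counts uniform over sex x age given totals [field x year]
flat_panel <- function(fields, years, totals, country = "ZZ") {
  rows <- do.call(rbind, lapply(seq_along(fields), function(k) {
    do.call(rbind, lapply(seq_along(years), function(j) {
      expand.grid(country = country, field = fields[k], sex = SEXES,
                  age = AGES, year = years[j],
                  count = totals[k, j] / (length(SEXES) * length(AGES)),
                  stringsAsFactors = FALSE)
    }))
  }))
  stock_panel(rows)
}

# panel whose every age/sex cell follows count = base * ratio^(t - years[1]);
# all cohort net rates are then exactly ratio - 1
geometric_panel <- function(years, ratio, base = 100, country = "ZZ",
                            field = "all") {
  rows <- do.call(rbind, lapply(seq_along(years), function(j) {
    expand.grid(country = country, field = field, sex = SEXES, age = AGES,
                year = years[j], count = base * ratio^(j - 1),
                stringsAsFactors = FALSE)
  }))
  stock_panel(rows)
}

# hand-built model_run (the documented structure) for formula-level tests
stub_run <- function(config, fields, years, M, country = "ZZ") {
  phase <- ifelse(years == config$t0, "calibration",
                  ifelse(years <= config$last_data_year, "validation",
                         "forecast"))
  totals <- do.call(rbind, lapply(seq_along(years), function(i) {
    data.frame(country = country, field = fields, year = years[i],
               phase = phase[i], M = M[, i], stringsAsFactors = FALSE)
  }))
  structure(list(totals = totals, years = years,
                 phase = stats::setNames(phase, years), fields = fields,
                 config = config), class = "model_run")
}

# hand-built net-rate table
net_table <- function(sex, age, year, alpha) {
  out <- data.frame(sex = sex, age = age, year = year, alpha = alpha,
                    valid = is.finite(alpha), stringsAsFactors = FALSE)
  class(out) <- c("net_rate_table", "data.frame")
  out
}

# single-field, F-only model state over arbitrary ages
toy_state <- function(counts_F, ages, year = 2000, field = "f") {
  N <- array(0, dim = c(length(ages), 2L, 1L),
             dimnames = list(age = ages, sex = SEXES, field = field))
  N[, 1L, 1L] <- counts_F
  model_state(N, year)
}

# inflow series with a single constant level
const_inflow <- function(years, level, split = c(F = 0.5, M = 0.5),
                         entry_ages = 25:34, forecast_level = level) {
  inflow_series(data.frame(year = years, count = level),
                sex_split = split, entry_ages = entry_ages,
                forecast_level = forecast_level)
}

# Independently coded model evaluation: explicit per-sex/per-field
# recursion of N(a+1,t+1) = (1-gamma(a)) N(a,t) + entry, straight from
# the update equation. Used as the exhaustive-grid oracle. The setup
# (initial vectors, rates, inflow lookups) is hoisted so an exhaustive
# grid stays affordable; the recursion itself is re-evaluated per point.
naive_prepare <- function(panel, gamma_tab, inflow, t0, t_end) {
  fields <- unique(panel$field)
  df <- as.data.frame(panel)
  gam <- sapply(SEXES, function(s) {
    g <- numeric(length(AGES))
    sl <- gamma_tab[gamma_tab$sex == s, ]
    g[match(sl$age, AGES)] <- sl$gamma
    g
  })
  init <- list()
  for (f in fields) for (s in SEXES) {
    sl <- df[df$field == f & df$sex == s & df$year == t0, ]
    init[[paste(f, s)]] <- sl$count[match(AGES, sl$age)]
  }
  Ytab <- inflow$table
  Y_of <- sapply((t0 + 1):t_end, function(yr) {
    if (yr %in% Ytab$year) Ytab$total[Ytab$year == yr]
    else inflow$forecast_level
  })
  z <- aggregate(count ~ field, df[df$year == t_end, ], sum)
  list(fields = fields, gam = gam, init = init, Y = Y_of,
       split = inflow$sex_split,
       entry_idx = which(AGES %in% inflow$entry_ages),
       n_entry = length(inflow$entry_ages),
       Z = stats::setNames(z$count, z$field)[fields])
}

naive_field_totals <- function(prep, pe, p) {
  n <- length(AGES)
  M <- sapply(prep$fields, function(f) {
    tot <- 0
    for (s in SEXES) {
      v <- prep$init[[paste(f, s)]]
      ent <- pe * p[[f]] * prep$split[[s]] / prep$n_entry
      for (j in seq_along(prep$Y)) {
        nv <- c(0, (1 - prep$gam[1:(n - 1L), s]) * v[1:(n - 1L)])
        nv[prep$entry_idx] <- nv[prep$entry_idx] + ent * prep$Y[j]
        v <- nv
      }
      tot <- tot + sum(v)
    }
    tot
  })
  stats::setNames(M, prep$fields)
}

# naive chi-squared at the final year from naive totals
naive_chi2 <- function(prep, pe, p) {
  M <- naive_field_totals(prep, pe, p)
  w <- prep$Z / sum(prep$Z)
  sum(w * ((prep$Z - M) / prep$Z)^2)
}

# one cached noise-free synthetic world shared across test files
synth_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- generate_panel(synthetic_spec(noise_sd = 0))
      inf <- g$truth$inflow
      inf$forecast_level <- estimate_inflow(inf, 2014:2019)
      g$truth$inflow <- inf
      cache <<- g
    }
    cache
  }
})
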