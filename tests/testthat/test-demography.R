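test_that("interpolation: uniform, zero and hand-computed cases", {
  uni <- interpolate_age_groups(stats::setNames(rep(100, 5), GROUPS))
  expect_equal(unname(uni), rep(10, 50))

  zero <- interpolate_age_groups(stats::setNames(rep(0, 5), GROUPS))
  expect_equal(unname(zero), rep(0, 50))

  # independent closed form: anchor group means at mid-ages, straight
  # lines between, flat ends, then rescale each group to its total
  totals <- c(100, 200, 200, 200, 200)
  mids <- c(29.5, 39.5, 49.5, 59.5, 69.5)
  means <- totals / 10
  expect_vals <- sapply(25:74, function(a) {
    if (a <= mids[1]) return(means[1])
    if (a >= mids[5]) return(means[5])
    j <- findInterval(a, mids)
    means[j] + (means[j + 1] - means[j]) * (a - mids[j]) / (mids[j + 1] - mids[j])
  })
  for (g in 1:5) {
    idx <- ((g - 1) * 10 + 1):(g * 10)
    expect_vals[idx] <- expect_vals[idx] * totals[g] / sum(expect_vals[idx])
  }
  got <- interpolate_age_groups(stats::setNames(totals, GROUPS))
  expect_equal(unname(got), expect_vals, tolerance = 1e-12)
  # within-group sums exact; nondecreasing over the rising 25-44 span
  expect_equal(as.numeric(tapply(got, rep(1:5, each = 10), sum)), totals)
  expect_true(all(diff(got[1:20]) >= -1e-12))

  expect_error(interpolate_age_groups(c(`25-34` = 100)), "missing age group")
})

test_that("interpolation conserves group totals over random profiles", {
  set.seed(7)
  for (i in 1:200) {
    totals <- stats::runif(5, 0, 5000) * stats::rbinom(5, 1, 0.9)
    v <- interpolate_age_groups(stats::setNames(totals, GROUPS))
    sums <- as.numeric(tapply(v, rep(1:5, each = 10), sum))
    expect_equal(unname(sums), totals, tolerance = 1e-9)
    expect_true(all(v >= 0))
  }
})

test_that("out-of-range input groups are dropped with a warning", {
  sl <- data.frame(age_group = c("<25", GROUPS, "75+"),
                   count = c(5, rep(100, 5), 7))
  expect_warning(v <- interpolate_age_groups(sl), "out-of-range")
  expect_equal(sum(v), 500)
})

test_that("net rates follow the cohort formula and flag zero stocks", {
  # steady state: every cohort keeps its size
  p_const <- geometric_panel(2000:2001, ratio = 1)
  nr <- compute_net_rates(p_const)
  expect_true(all(nr$valid))
  expect_equal(nr$alpha, rep(0, nrow(nr)))

  # 10% cohort shrinkage
  p_shrink <- geometric_panel(2000:2001, ratio = 0.9)
  nr2 <- compute_net_rates(p_shrink)
  expect_equal(nr2$alpha, rep(-0.1, nrow(nr2)), tolerance = 1e-12)

  # zero stocks -> invalid, not an error
  p_zero <- geometric_panel(2000:2001, ratio = 1, base = 0)
  nr3 <- compute_net_rates(p_zero)
  expect_false(any(nr3$valid))
  expect_true(all(is.na(nr3$alpha)))
})

test_that("exit rates average the rectified net rates", {
  grid <- expand.grid(sex = SEXES, age = 25:73, stringsAsFactors = FALSE)

  # alpha constant at -0.05 over 5 years -> gamma 0.05
  nt <- do.call(rbind, lapply(2000:2004, function(y) {
    g <- grid; g$year <- y; g$alpha <- -0.05; g
  }))
  rates <- estimate_exit_rates(net_table(nt$sex, nt$age, nt$year, nt$alpha))
  expect_equal(rates$gamma, rep(0.05, nrow(rates)))
  expect_true(all(rates$n_years_averaged == 5L))

  # mixed (+0.02, -0.10) -> mean(0, 0.10) = 0.05
  nt2 <- do.call(rbind, lapply(1:2, function(j) {
    g <- grid; g$year <- 1999 + j; g$alpha <- c(0.02, -0.10)[j]; g
  }))
  rates2 <- estimate_exit_rates(net_table(nt2$sex, nt2$age, nt2$year, nt2$alpha))
  expect_equal(rates2$gamma, rep(0.05, nrow(rates2)))

  # pure growth -> gamma 0
  nt3 <- grid; nt3$year <- 2000; nt3$alpha <- 0.3
  rates3 <- estimate_exit_rates(net_table(nt3$sex, nt3$age, nt3$year, nt3$alpha))
  expect_equal(rates3$gamma, rep(0, nrow(rates3)))

  expect_error(estimate_exit_rates(net_table(character(0), integer(0),
                                             integer(0), numeric(0))),
               "empty")
})

test_that("exit rates are invariant to uniform stock rescaling", {
  g <- synth_world()
  r1 <- estimate_exit_rates(compute_net_rates(g$truth$panel))
  scaled <- as.data.frame(g$truth$panel)
  scaled$count <- scaled$count * 3.7
  r2 <- estimate_exit_rates(compute_net_rates(stock_panel(scaled)))
  expect_equal(r1$gamma, r2$gamma, tolerance = 1e-12)
})

test_that("missing cells fall back to reference rates, never undefined", {
  # panel with zero stocks for one sex: no valid years there
  df <- as.data.frame(geometric_panel(2000:2002, ratio = 0.95))
  df$count[df$sex == "M"] <- 0
  nr <- compute_net_rates(stock_panel(df))
  expect_error(estimate_exit_rates(nr), "no valid year")
  ref <- generate_exit_curve(60, 0.4, 0.2)
  rates <- estimate_exit_rates(nr, reference = ref)
  expect_false(any(is.na(rates$gamma)))
  expect_true(all(rates$source[rates$sex == "M"] == "reference"))
  expect_true(all(rates$source[rates$sex == "F"] == "country"))
  expect_true(all(rates$gamma >= 0 & rates$gamma <= 1))
})

test_that("reference rates pool stocks across countries", {
  a <- geometric_panel(2000:2001, 0.98, country = "AA")
  b <- geometric_panel(2000:2001, 0.94, country = "BB")
  own <- estimate_exit_rates(compute_net_rates(a))
  # pooling a country with itself changes nothing (ratio invariance)
  expect_equal(reference_exit_rates(list(a))$gamma, own$gamma)
  expect_equal(reference_exit_rates(list(a, a))$gamma, own$gamma)
  # equal stocks at rates 0.02 and 0.06 pool to 0.04
  pooled <- reference_exit_rates(list(a, b))
  expect_equal(pooled$gamma, rep(0.04, nrow(pooled)), tolerance = 1e-12)
  expect_true(all(pooled$source == "reference"))
  expect_error(reference_exit_rates(list()), "no complete country")
})

test_that("inflow level is the window mean", {
  inf <- inflow_series(data.frame(year = 2017:2019, count = c(100, 110, 120)))
  expect_equal(estimate_inflow(inf, 2017:2019), 110)
  expect_equal(estimate_inflow(inf, 2019), 120)
  expect_error(estimate_inflow(inf, integer(0)), "empty")
  expect_error(estimate_inflow(inf, 2010:2019), "not observed")

  # graduates + migrants are additive per year
  inf2 <- inflow_series(data.frame(year = 2014:2019, count = 400),
                        data.frame(year = 2014:2019, count = 100))
  expect_equal(estimate_inflow(inf2, 2014:2019), 500)
  expect_equal(inf2$table$total, inf2$table$graduates + inf2$table$migrants)
})

test_that("entrant sex split normalizes the 25-34 stocks", {
  totals <- matrix(1000, 1, 1)
  df <- as.data.frame(flat_panel("all", 2019, totals))
  df$count <- ifelse(df$sex == "F" & df$age <= 34, 6,
                     ifelse(df$sex == "M" & df$age <= 34, 4, 1))
  split <- entrant_sex_split(stock_panel(df), 2019)
  expect_equal(unname(split), c(0.6, 0.4))
  expect_equal(sum(split), 1)

  df$count[df$sex == "F" & df$age <= 34] <- 0
  expect_equal(unname(entrant_sex_split(stock_panel(df), 2019)), c(0, 1))

  df$count[df$age <= 34] <- 0
  expect_error(entrant_sex_split(stock_panel(df), 2019), "zero total")
  expect_error(entrant_sex_split(stock_panel(df), 1990), "not in panel")
})
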