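test_that("chi-squared matches the weighted hand formula", {
  cfg <- country_config("ZZ", 2018, 2019, 2020)
  fields <- c("GP", "specialist")
  years <- 2018:2019
  # data Z = (100, 300) in 2019; model M = (90, 330)
  panel <- flat_panel(fields, years, rbind(c(100, 100), c(300, 300)))
  run <- stub_run(cfg, fields, years, rbind(c(100, 90), c(300, 330)))
  expect_equal(chi_squared(run, panel, "final_year"),
               0.25 * 0.1^2 + 0.75 * 0.1^2)
  # perfect fit
  run0 <- stub_run(cfg, fields, years, rbind(c(100, 100), c(300, 300)))
  expect_equal(chi_squared(run0, panel, "final_year"), 0)
  # all-years mode averages the per-year expression
  expect_equal(chi_squared(run, panel, "all_years"), 0.01 / 2)
  # invariance to common rescaling of Z and M
  panel10 <- flat_panel(fields, years, 10 * rbind(c(100, 100), c(300, 300)))
  run10 <- stub_run(cfg, fields, years, 10 * rbind(c(100, 90), c(300, 330)))
  expect_equal(chi_squared(run10, panel10, "final_year"),
               chi_squared(run, panel, "final_year"))
  # zero observed totals are an error
  panelz <- flat_panel(fields, years, rbind(c(100, 0), c(300, 300)))
  expect_error(chi_squared(run, panelz, "final_year"), "positive")
})

test_that("grid calibration recovers known parameters", {
  g <- synth_world()
  cfg <- country_config("SY", 2000, 2019, 2040)
  fit <- calibrate_grid(g$truth$panel, g$truth$gamma, g$truth$inflow, cfg)
  expect_lte(abs(fit$params$p_enter - 0.9), 0.01)
  expect_lte(abs(fit$params$p[["GP"]] - 0.3), 0.01)
  expect_lte(fit$chi2, 1e-6)
  expect_identical(fit$method, "grid")
})

test_that("grid ties break to the lexicographic smallest point", {
  g <- synth_world()
  cfg <- country_config("SY", 2000, 2019, 2040)
  inf0 <- g$truth$inflow
  inf0$table$graduates <- 0; inf0$table$migrants <- 0; inf0$table$total <- 0
  inf0$forecast_level <- 0
  fit <- calibrate_grid(g$truth$panel, g$truth$gamma, inf0, cfg,
                        grid_step = 0.05)
  expect_identical(fit$params$p_enter, 0)
  expect_identical(unname(fit$params$p[1]), 0)
})

test_that("grid optimum equals an independently coded exhaustive search", {
  g <- synth_world()
  cfg <- country_config("SY", 2000, 2019, 2040)
  fit <- calibrate_grid(g$truth$panel, g$truth$gamma, g$truth$inflow, cfg,
                        grid_step = 0.05)
  prep <- naive_prepare(g$truth$panel, g$truth$gamma, g$truth$inflow,
                        2000, 2019)
  vals <- (0:20) / 20  # the same 0.05 grid points calibrate_grid visits
  best <- Inf; best_pt <- c(NA, NA)
  for (pe in vals) {
    for (p1 in vals) {
      chi <- naive_chi2(prep, pe, c(GP = p1, specialist = 1 - p1))
      if (chi < best) { best <- chi; best_pt <- c(pe, p1) }
    }
  }
  expect_identical(unname(fit$params$p_enter), best_pt[1])
  expect_identical(unname(fit$params$p[["GP"]]), best_pt[2])
})

test_that("gradient calibration matches the grid and is deterministic", {
  g <- synth_world()
  cfg <- country_config("SY", 2000, 2019, 2040)
  grid <- calibrate_grid(g$truth$panel, g$truth$gamma, g$truth$inflow, cfg)
  grad <- calibrate_gradient(g$truth$panel, g$truth$gamma, g$truth$inflow,
                             cfg, seed = 11)
  expect_lte(grad$chi2, grid$chi2 + 1e-6)
  expect_lte(abs(grad$params$p_enter - grid$params$p_enter), 0.01)
  expect_lte(abs(grad$params$p[["GP"]] - grid$params$p[["GP"]]), 0.01)
  grad2 <- calibrate_gradient(g$truth$panel, g$truth$gamma, g$truth$inflow,
                              cfg, seed = 11)
  expect_identical(grad, grad2)
})

test_that("gradient calibration recovers a 6-field parameter vector", {
  fields <- c("GP_c", "GP_e", "GP_n", "sp_c", "sp_e", "sp_n")
  p_true <- c(0.10, 0.12, 0.08, 0.30, 0.25, 0.15)
  sp <- synthetic_spec(seed = 3, fields = fields,
                       field_shares = c(0.1, 0.1, 0.1, 0.3, 0.2, 0.2),
                       p = p_true, p_enter = 0.85, noise_sd = 0)
  g <- generate_panel(sp)
  inf <- g$truth$inflow
  inf$forecast_level <- estimate_inflow(inf, 2014:2019)
  cfg <- country_config("SY", 2000, 2019, 2040, fields = fields)
  fit <- calibrate_gradient(g$truth$panel, g$truth$gamma, inf, cfg,
                            seed = 5)
  expect_lte(abs(fit$params$p_enter - 0.85), 0.02)
  expect_true(all(abs(fit$params$p[fields] - p_true) <= 0.02))
})

test_that("validation RMSE follows its closed forms", {
  cfg <- country_config("ZZ", 2000, 2005, 2010)
  fields <- c("GP", "specialist")
  years <- 2000:2005
  Z <- rbind(rep(100, 6), rep(300, 6))
  panel <- flat_panel(fields, years, Z)
  # perfect fit
  expect_equal(unname(validation_rmse(stub_run(cfg, fields, years, Z), panel)),
               c(0, 0))
  # constant +10 offset
  expect_equal(unname(validation_rmse(stub_run(cfg, fields, years, Z + 10),
                                      panel)),
               c(10, 10))
  # residuals (3, -4) over two validation years
  years2 <- 2003:2005
  cfg2 <- country_config("ZZ", 2003, 2005, 2010)
  Z2 <- rbind(rep(100, 3), rep(300, 3))
  M2 <- Z2; M2[, 2] <- M2[, 2] + 3; M2[, 3] <- M2[, 3] - 4
  got <- validation_rmse(stub_run(cfg2, fields, years2, M2),
                         flat_panel(fields, years2, Z2))
  expect_equal(unname(got), rep(sqrt(12.5), 2))
  # fewer than two validation years is an error
  cfg3 <- country_config("ZZ", 2004, 2005, 2010)
  expect_error(validation_rmse(stub_run(cfg3, fields, 2004:2005,
                                        Z2[, 1:2]),
                               flat_panel(fields, 2004:2005, Z2[, 1:2])),
               "at least 2")
})

test_that("error propagation scales with the square root of the horizon", {
  expect_equal(propagate_error(7, 1), 7)
  expect_equal(propagate_error(7, 4), 14)
  expect_equal(propagate_error(7, 0), 0)
  sig <- propagate_error(7, 1:21)
  expect_true(all(diff(sig) > 0))
  expect_error(propagate_error(7, -1), "nonnegative")
  expect_equal(dim(propagate_error(c(1, 2), c(1, 4))), c(2L, 2L))
})

test_that("fit results serialize to JSON", {
  g <- synth_world()
  cfg <- country_config("SY", 2000, 2019, 2040)
  fit <- calibrate_grid(g$truth$panel, g$truth$gamma, g$truth$inflow, cfg,
                        grid_step = 0.25)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit(fit, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$p_enter, fit$params$p_enter)
  expect_identical(back$method, "grid")
})
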