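# Parameter estimation. The entry probability p_enter and the
# field-choice probabilities p_i are the model's only free parameters;
# they are fitted by minimizing a weighted chi-squared distance between
# modelled and observed per-field totals. Two fitters: an exhaustive
# 0.01-step grid (2-field case) and projected gradient descent with
# seeded random restarts (any number of fields).

# observed per-field totals for the compared years; matrix [K, years]
pf_Z_matrix <- function(panel, fields, years) {
  z <- panel_totals(panel)
  Z <- matrix(NA_real_, length(fields), length(years),
              dimnames = list(fields, years))
  idx <- z$field %in% fields & z$year %in% years
  z <- z[idx, ]
  Z[cbind(match(z$field, fields), match(z$year, years))] <- z$total
  if (anyNA(Z)) stop("panel lacks totals for some compared field/years",
                     call. = FALSE)
  if (any(Z <= 0)) stop("observed totals Z_i must be positive in compared years",
                        call. = FALSE)
  Z
}

# chi^2 for one year: sum_i w_i ((Z_i - M_i)/Z_i)^2, w_i = Z_i / sum(Z)
pf_chi2_year <- function(Z, M) {
  w <- Z / sum(Z)
  sum(w * ((Z - M) / Z)^2)
}

#' Weighted chi-squared distance between model and data
#'
#' Per compared year, `chi2 = sum_i w_i ((Z_i - M_i)/Z_i)^2` with weights
#' `w_i = Z_i / sum_i Z_i`, the share of field `i` in the observed stock
#' of that year. `final_year` mode evaluates the expression at the last
#' data year only (the calibration target); `all_years` averages it over
#' every observed year from `t0` to the last data year.
#'
#' @param run a [run_model()] result.
#' @param panel the observed [stock_panel()].
#' @param mode `"final_year"` or `"all_years"`.
#' @return nonnegative scalar; 0 iff model equals data in the compared
#'   years.
#' @export
chi_squared <- function(run, panel, mode = c("final_year", "all_years")) {
  mode <- match.arg(mode)
  stopifnot(inherits(run, "model_run"), inherits(panel, "stock_panel"))
  cfg <- run$config
  years <- if (mode == "final_year") cfg$last_data_year else
    intersect(run$years[run$years <= cfg$last_data_year],
              unique(panel$year))
  if (length(years) == 0L) stop("no compared years in common", call. = FALSE)
  Z <- pf_Z_matrix(panel, run$fields, years)
  tot <- run$totals
  chis <- vapply(seq_along(years), function(j) {
    M <- tot$M[tot$year == years[j]][match(run$fields,
                                           tot$field[tot$year == years[j]])]
    pf_chi2_year(Z[, j], M)
  }, numeric(1))
  mean(chis)
}

# chi^2 from a fast-path totals matrix M [K, t0..end]
pf_chi2_fast <- function(M, fs_years0, Z, compare_idx) {
  if (length(compare_idx) == 1L) {
    pf_chi2_year(Z[, 1L], M[, compare_idx])
  } else {
    mean(vapply(seq_along(compare_idx), function(j)
      pf_chi2_year(Z[, j], M[, compare_idx[j]]), numeric(1)))
  }
}

#' Fit result container
#' @keywords internal
pf_fit_result <- function(params, chi2, method, objective_mode,
                          grid_step = NA_real_, rmse = NULL,
                          converged = TRUE, seed = NA_integer_) {
  structure(list(params = params, chi2 = chi2, method = method,
                 objective_mode = objective_mode, grid_step = grid_step,
                 rmse_i = rmse, converged = converged, seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result [%s/%s] chi2=%.3e p_enter=%.3f p=[%s]>\n",
              x$method, x$objective_mode, x$chi2, x$params$p_enter,
              paste(sprintf("%s=%.3f", names(x$params$p), x$params$p),
                    collapse = ", ")))
  invisible(x)
}

# shared setup for both calibrators: fast-path state + Z + compare indices
pf_calib_setup <- function(panel, gamma, inflow, config, objective) {
  fs <- pf_fast_setup(panel, gamma, inflow,
                      config, end_year = config$last_data_year)
  all_years <- c(config$t0, fs$years)        # t0 .. last_data_year
  cmp_years <- if (objective == "final_year") config$last_data_year else
    intersect(all_years, unique(panel$year))
  Z <- pf_Z_matrix(panel, fs$fields, cmp_years)
  list(fs = fs, Z = Z, compare_idx = match(cmp_years, all_years))
}

#' Calibrate the 2-field model by exhaustive grid search
#'
#' Evaluates the chi-squared objective on the full `(p_enter, p_1)` grid
#' in steps of `grid_step` (default 0.01: 101 x 101 points) and returns
#' the minimizer. Ties are broken lexicographically: smallest `p_enter`,
#' then smallest first-field probability.
#'
#' @param panel observed [stock_panel()] with exactly two fields.
#' @param gamma exit rates (see [model_step()]).
#' @param inflow an [inflow_series()].
#' @param config a [country_config()].
#' @param objective `"final_year"` (default) or `"all_years"`, see
#'   [chi_squared()].
#' @param grid_step grid increment.
#' @param keep_surface if `TRUE`, attach the full chi-squared grid as
#'   attribute `surface`.
#' @return a `fit_result` with elements `params`, `chi2`, `method`,
#'   `objective_mode`, `grid_step`.
#' @export
calibrate_grid <- function(panel, gamma, inflow, config,
                           objective = c("final_year", "all_years"),
                           grid_step = 0.01, keep_surface = FALSE) {
  objective <- match.arg(objective)
  su <- pf_calib_setup(panel, gamma, inflow, config, objective)
  K <- su$fs$K
  if (K != 2L) {
    stop("grid calibration is defined for the 2-field model; use ",
         "calibrate_gradient() for ", K, " fields", call. = FALSE)
  }
  nsteps <- round(1 / grid_step)
  vals <- (0:nsteps) / nsteps
  best <- Inf; best_pe <- vals[1L]; best_p1 <- vals[1L]
  surface <- if (keep_surface)
    matrix(NA_real_, length(vals), length(vals),
           dimnames = list(p_enter = vals, p1 = vals)) else NULL
  for (i in seq_along(vals)) {
    pe <- vals[i]
    for (j in seq_along(vals)) {
      p1 <- vals[j]
      M <- pf_fast_run(su$fs, pe, c(p1, 1 - p1))
      chi <- pf_chi2_fast(M, NULL, su$Z, su$compare_idx)
      if (keep_surface) surface[i, j] <- chi
      if (chi < best) { best <- chi; best_pe <- pe; best_p1 <- p1 }
    }
  }
  params <- model_params(best_pe,
                         stats::setNames(c(best_p1, 1 - best_p1), su$fs$fields))
  out <- pf_fit_result(params, best, "grid", objective, grid_step = grid_step)
  if (keep_surface) attr(out, "surface") <- surface
  out
}

# Euclidean projection of v onto the probability simplex (sort-based)
pf_project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

#' Calibrate by projected gradient descent with random restarts
#'
#' Minimizes the chi-squared objective over `p_enter` in `[0,1]` and the
#' field-choice vector `p` on the probability simplex, using
#' central-difference numeric gradients, Armijo backtracking line search
#' and Euclidean projection after each step. Randomized restarts (the
#' "stochastic" element; there is no data-subsampling dimension here) are
#' drawn from a seeded RNG, so results are reproducible. Works for any
#' number of fields; for two fields it agrees with [calibrate_grid()] up
#' to grid resolution.
#'
#' @inheritParams calibrate_grid
#' @param seed integer seed driving the restart draws.
#' @param restarts number of random starting points (plus one fixed
#'   central start).
#' @param maxit maximum iterations per restart.
#' @param tol stop a restart when the objective improvement falls below
#'   this.
#' @return a `fit_result`; `converged = FALSE` (with a warning) if no
#'   restart reached the improvement tolerance.
#' @export
calibrate_gradient <- function(panel, gamma, inflow, config, seed = 1L,
                               objective = c("final_year", "all_years"),
                               restarts = 3L, maxit = 400L, tol = 1e-12) {
  objective <- match.arg(objective)
  su <- pf_calib_setup(panel, gamma, inflow, config, objective)
  K <- su$fs$K
  if (K < 2L) stop("need at least two fields", call. = FALSE)

  fobj <- function(theta) {
    M <- pf_fast_run(su$fs, theta[1L], theta[-1L])
    pf_chi2_fast(M, NULL, su$Z, su$compare_idx)
  }
  project <- function(theta) {
    c(min(1, max(0, theta[1L])), pf_project_simplex(theta[-1L]))
  }
  ngrad <- function(theta, h = 1e-6) {
    vapply(seq_along(theta), function(d) {
      tp <- theta; tm <- theta
      tp[d] <- theta[d] + h; tm[d] <- theta[d] - h
      (fobj(project(tp)) - fobj(project(tm))) / (2 * h)
    }, numeric(1))
  }
  descend <- function(theta0) {
    theta <- project(theta0)
    f <- fobj(theta)
    converged <- FALSE
    for (it in seq_len(maxit)) {
      g <- ngrad(theta)
      step <- 1
      improved <- FALSE
      for (ls in 1:40) {
        cand <- project(theta - step * g)
        fc <- fobj(cand)
        if (fc < f - 1e-4 * step * sum(g^2)) {
          improved <- TRUE; break
        }
        step <- step / 2
      }
      if (!improved) { converged <- TRUE; break }
      if (f - fc < tol) { theta <- cand; f <- fc; converged <- TRUE; break }
      theta <- cand; f <- fc
    }
    list(theta = theta, f = f, converged = converged)
  }

  starts <- list(c(0.5, rep(1 / K, K)))
  if (restarts > 0L) {
    rng <- pf_local_rng(seed)
    on.exit(rng(), add = TRUE)
    for (r in seq_len(restarts)) {
      pe <- stats::runif(1)
      pr <- stats::runif(K)
      starts[[length(starts) + 1L]] <- c(pe, pr / sum(pr))
    }
  }
  best <- NULL
  any_conv <- FALSE
  for (s in starts) {
    res <- descend(s)
    any_conv <- any_conv || res$converged
    if (is.null(best) || res$f < best$f) best <- res
  }
  if (!any_conv) {
    warning("gradient calibration did not converge after ", restarts + 1L,
            " starts; returning best found", call. = FALSE)
  }
  params <- model_params(best$theta[1L],
                         stats::setNames(best$theta[-1L], su$fs$fields))
  pf_fit_result(params, best$f, "gradient", objective,
                converged = any_conv, seed = as.integer(seed))
}

#' Per-field validation RMSE
#'
#' Root-mean-square deviation between modelled and observed per-field
#' totals over the validation years (every year after initialization up
#' to the last data year that is present in the panel).
#'
#' @param run a [run_model()] result.
#' @param panel observed [stock_panel()].
#' @return named numeric vector, one RMSE per field.
#' @export
validation_rmse <- function(run, panel) {
  stopifnot(inherits(run, "model_run"), inherits(panel, "stock_panel"))
  cfg <- run$config
  years <- intersect(run$years[run$years > cfg$t0 &
                                 run$years <= cfg$last_data_year],
                     unique(panel$year))
  if (length(years) < 2L) {
    stop("need at least 2 validation years present in both run and panel",
         call. = FALSE)
  }
  Z <- pf_Z_matrix(panel, run$fields, years)
  tot <- run$totals
  out <- vapply(seq_along(run$fields), function(k) {
    f <- run$fields[k]
    M <- tot$M[tot$field == f][match(years, tot$year[tot$field == f])]
    sqrt(mean((M - Z[k, ])^2))
  }, numeric(1))
  stats::setNames(out, run$fields)
}

#' Propagate validation error to a forecast horizon
#'
#' Gaussian propagation under independent annual increments: the forecast
#' standard error after `h` years is `rmse * sqrt(h)`, nondecreasing in
#' `h` and equal to the validation RMSE at `h = 1`.
#'
#' @param rmse per-field validation RMSE (scalar or vector).
#' @param h horizon in years, `>= 0`; vectorized.
#' @return `rmse * sqrt(h)` with recycling (outer structure when both are
#'   vectors: a matrix `length(rmse) x length(h)`).
#' @export
propagate_error <- function(rmse, h) {
  if (any(h < 0)) stop("horizon must be nonnegative", call. = FALSE)
  if (any(rmse < 0)) stop("rmse must be nonnegative", call. = FALSE)
  if (length(rmse) > 1L && length(h) > 1L) {
    outer(rmse, sqrt(h))
  } else {
    rmse * sqrt(h)
  }
}

#' Serialize a fit result to JSON
#' @param fit a `fit_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  x <- list(method = fit$method, objective_mode = fit$objective_mode,
            p_enter = fit$params$p_enter, p = as.list(fit$params$p),
            chi2 = fit$chi2, grid_step = fit$grid_step,
            rmse = if (is.null(fit$rmse_i)) NULL else as.list(fit$rmse_i),
            converged = fit$converged, seed = fit$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# run a function with a temporary RNG state; returns a restore function
pf_local_rng <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}
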