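# Tabular I/O for EUROSTAT-dialect panels: tidy CSV, one observation per
# row, explicit header. Five table kinds cover physician stocks by age and
# sex, stocks by field, graduate counts, immigrant-physician counts, and
# population projections by scenario.

## Constructors & validation ------------------------------------------------

#' Construct a validated raw table
#'
#' A `raw_table` is a tidy data frame in one of five fixed schemas, the
#' on-disk interchange format of the package. Validation is total: any
#' malformed input raises a structured error naming the offending rows;
#' a partially valid table is never returned.
#'
#' @param rows data frame with the columns required for `table_kind`.
#' @param table_kind one of `"stocks_by_age_sex"`, `"stocks_by_field"`,
#'   `"graduates"`, `"migrants"`, `"population_projection"`.
#' @return A data frame of class `raw_table` with attribute `table_kind`.
#' @examples
#' rt <- raw_table(data.frame(country = "AA", year = 2019, sex = "F",
#'                            age_group = "25-34", count = 100),
#'                 "stocks_by_age_sex")
#' attr(rt, "table_kind")
#' @export
raw_table <- function(rows, table_kind) {
  table_kind <- match.arg(table_kind, pf_table_kinds)
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  cols <- pf_schema[[table_kind]]

  missing_cols <- setdiff(cols, names(rows))
  if (length(missing_cols) > 0L) {
    stop("schema error [", table_kind, "]: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rows <- rows[cols]
  rows$year <- as.integer(rows$year)
  rows$count <- as.numeric(rows$count)

  problems <- character(0)
  bad <- function(idx, what) {
    if (any(idx)) {
      problems <<- c(problems, paste0(
        what, " at row(s) ", paste(utils::head(which(idx), 10L), collapse = ", "),
        if (sum(idx) > 10L) sprintf(" (and %d more)", sum(idx) - 10L) else ""))
    }
  }
  bad(is.na(rows$year), "missing/non-integer year")
  bad(!is.finite(rows$count), "missing or non-finite count")
  bad(is.finite(rows$count) & rows$count < 0,
      "negative count")
  if ("sex" %in% cols) {
    bad(!(rows$sex %in% pf_sexes),
        paste0("sex not in {", paste(pf_sexes, collapse = ","),
               "} (totals rows are rejected)"))
  }
  if ("age_group" %in% cols) {
    bad(!(rows$age_group %in% pf_age_groups_all),
        paste0("age_group not in {", paste(pf_age_groups_all, collapse = ","), "}"))
  }

  key_cols <- setdiff(cols, "count")
  key <- do.call(paste, c(rows[key_cols], sep = "\r"))
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    keys <- unique(gsub("\r", "/", key[dup]))
    problems <- c(problems, paste0(
      "duplicate key(s): ", paste(utils::head(keys, 5L), collapse = "; "),
      if (length(keys) > 5L) sprintf(" (and %d more)", length(keys) - 5L) else ""))
  }

  if (length(problems) > 0L) {
    stop("validation error [", table_kind, "]:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }

  rows <- rows[order(key), , drop = FALSE]
  rownames(rows) <- NULL
  class(rows) <- c("raw_table", "data.frame")
  attr(rows, "table_kind") <- table_kind
  rows
}

#' Read a panel table from CSV
#'
#' @param path path to a CSV file with the header required by `table_kind`.
#' @param table_kind schema to validate against, see [raw_table()].
#' @return validated [raw_table()].
#' @export
read_table <- function(path, table_kind) {
  table_kind <- match.arg(table_kind, pf_table_kinds)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rows <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  raw_table(rows, table_kind)
}

#' Write a panel table to CSV
#'
#' Inverse of [read_table()]: `read_table(write_table(x, f), kind)` is the
#' identity on validated tables modulo row order.
#'
#' @param table a [raw_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  stopifnot(inherits(table, "raw_table"))
  out <- as.data.frame(table)
  # full-precision counts so write -> read is lossless
  out$count <- vapply(out$count, function(x) {
    s <- format(x, digits = 15)
    if (as.numeric(s) != x) s <- sprintf("%.17g", x)
    s
  }, character(1))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.raw_table <- function(x, ...) {
  cat(sprintf("<raw_table kind=%s rows=%d years=%s>\n",
              attr(x, "table_kind"), nrow(x),
              paste(range(x$year), collapse = "-")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

## Country configuration ----------------------------------------------------

#' Country configuration for a model run
#'
#' Holds the observation/forecast window and field structure for one
#' country. `t0` is the calibration start: the first break-free year with
#' complete data (see [select_calibration_start()]).
#'
#' @param country ISO-2 country code.
#' @param t0 calibration start year.
#' @param last_data_year last year with observed data (2019-style).
#' @param forecast_end forecast horizon year (2040-style).
#' @param fields ordered character vector of field labels.
#' @param inflow_window integer years over which the forecast inflow level
#'   is averaged; defaults to the last six data years
#'   (`(last_data_year-5):last_data_year`).
#' @param inflow_window_mode `"fixed"` uses `inflow_window` as given;
#'   `"last3"` overrides it with the three most recent data years.
#' @param breaks integer years flagged as series breaks; all must precede
#'   `t0`.
#' @return list of class `country_config`.
#' @export
country_config <- function(country, t0, last_data_year, forecast_end,
                           fields = c("GP", "specialist"),
                           inflow_window = NULL,
                           inflow_window_mode = c("fixed", "last3"),
                           breaks = integer(0)) {
  inflow_window_mode <- match.arg(inflow_window_mode)
  t0 <- as.integer(t0)
  last_data_year <- as.integer(last_data_year)
  forecast_end <- as.integer(forecast_end)
  breaks <- as.integer(breaks)
  if (!(t0 <= last_data_year && last_data_year <= forecast_end)) {
    stop("require t0 <= last_data_year <= forecast_end", call. = FALSE)
  }
  if (length(breaks) > 0L && max(breaks) >= t0) {
    stop("series breaks must all precede t0 (breaks before t0 only)",
         call. = FALSE)
  }
  if (length(fields) < 1L || anyDuplicated(fields)) {
    stop("fields must be a non-empty vector of unique labels", call. = FALSE)
  }
  if (inflow_window_mode == "last3") {
    inflow_window <- (last_data_year - 2L):last_data_year
  } else if (is.null(inflow_window)) {
    inflow_window <- (last_data_year - 5L):last_data_year
  }
  structure(list(country = country, t0 = t0,
                 last_data_year = last_data_year,
                 forecast_end = forecast_end,
                 fields = as.character(fields),
                 inflow_window = as.integer(inflow_window),
                 inflow_window_mode = inflow_window_mode,
                 breaks = breaks),
            class = "country_config")
}

#' @export
print.country_config <- function(x, ...) {
  cat(sprintf("<country_config %s: t0=%d data to %d forecast to %d fields=[%s]>\n",
              x$country, x$t0, x$last_data_year, x$forecast_end,
              paste(x$fields, collapse = ", ")))
  invisible(x)
}

#' Read a country configuration from JSON
#'
#' Keys mirror the arguments of [country_config()].
#'
#' @param path path to a JSON file.
#' @return a [country_config()].
#' @export
read_country_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(country_config))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(country_config, cfg)
}

#' Find the calibration start year
#'
#' Returns the earliest year strictly after every flagged series break in
#' which the stocks-by-age-and-sex table has complete coverage: both sexes
#' and all five modelled 10-year age groups (25-34 ... 65-74) present.
#'
#' @param table a `stocks_by_age_sex` [raw_table()].
#' @param config a [country_config()] whose `breaks` are honoured, or an
#'   integer vector of break years directly (the function is typically
#'   called before the final config exists, to determine its `t0`).
#' @return integer year.
#' @export
select_calibration_start <- function(table, config = integer(0)) {
  stopifnot(inherits(table, "raw_table"),
            attr(table, "table_kind") == "stocks_by_age_sex")
  breaks <- if (inherits(config, "country_config")) config$breaks
            else as.integer(config)
  years <- sort(unique(table$year))
  if (length(years) < 2L) stop("insufficient data: need >= 2 years", call. = FALSE)
  min_year <- if (length(breaks) > 0L) max(breaks) + 1L else -Inf
  need <- length(pf_sexes) * length(pf_age_groups_model)
  for (y in years) {
    if (y < min_year) next
    sl <- table[table$year == y & table$age_group %in% pf_age_groups_model, ]
    if (nrow(unique(sl[c("sex", "age_group")])) == need) return(as.integer(y))
  }
  stop("insufficient data: no break-free year with complete age/sex coverage",
       call. = FALSE)
}
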