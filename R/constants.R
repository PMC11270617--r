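# Closed vocabularies shared across modules. Kept in their own file so
# they are defined before any top-level use at package load.

#' @keywords internal
"_PACKAGE"

# age-group labels accepted on input (ordered)
pf_age_groups_all <- c("<25", "25-34", "35-44", "45-54", "55-64", "65-74", "75+")

# age-group labels inside the modelled range 25-74 (ordered)
pf_age_groups_model <- c("25-34", "35-44", "45-54", "55-64", "65-74")

# modelled single-year ages
pf_ages <- 25:74

# sex labels; totals rows are rejected, never summed
pf_sexes <- c("F", "M")

pf_table_kinds <- c("stocks_by_age_sex", "stocks_by_field", "graduates",
                    "migrants", "population_projection")

# required columns per table kind; key = all but "count"
pf_schema <- list(
  stocks_by_age_sex     = c("country", "year", "sex", "age_group", "count"),
  stocks_by_field       = c("country", "year", "field", "count"),
  graduates             = c("country", "year", "count"),
  migrants              = c("country", "year", "count"),
  population_projection = c("country", "scenario", "year", "count")
)
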