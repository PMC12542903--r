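#' Assemble and validate a model configuration
#'
#' A `bia_config` bundles every input of the budget-impact model: the national
#' population parameters used to derive cohort sizes, the two since-diagnosis
#' cohorts, per-comorbidity epidemiology (baseline prevalence and age-banded
#' annual incidence with its annual reduction), resource-use profiles, unit
#' costs with their origin year, a CPI index series, economic settings
#' (discount rate, base year, horizon), and named counterfactual scenarios.
#' Every component is a tibble, so a configuration can be inspected and
#' manipulated with ordinary dplyr verbs before being passed to
#' [run_model()].
#'
#' All invariants are checked on construction: proportions and probabilities
#' must lie in `[0, 1]`, the annual incidence reduction in `[0, 1)`, the
#' epidemiology table must contain exactly one row per (comorbidity, cohort)
#' pair, every comorbidity must price all six resource categories, scenario
#' deltas must be non-negative, and the horizon must start at the base year.
#' Unknown comorbidity, cohort, or resource keys are rejected rather than
#' ignored. There are no silent defaults for epidemiological rates.
#'
#' @param population One-row data frame with columns `national_population`,
#'   `hiv_prevalence`, `diagnosed_fraction`, `recent_fraction`,
#'   `annual_mortality` (annual probability of death per person).
#' @param cohorts Data frame with columns `cohort` (one of `"recent"`,
#'   `"longstanding"`), `size_baseline` (persons at the horizon start;
#'   fractional persons are allowed and carried through all computations),
#'   and `mean_age_baseline` (years).
#' @param epi Data frame with one row per (comorbidity, cohort):
#'   `comorbidity`, `cohort`, `baseline_prevalence`, `incidence_young`,
#'   `incidence_old` (annual probabilities below / at-or-above the age
#'   threshold), `age_threshold` (years), and `annual_incidence_reduction`
#'   (proportional decay of incidence per year).
#' @param resource_use Data frame `comorbidity`, `resource`, `quantity`
#'   (events per patient-year); all six resource categories are required for
#'   every comorbidity.
#' @param unit_costs Data frame `resource`, `unit_cost` (euros per event),
#'   `origin_year` (calendar year the price is expressed in).
#' @param cpi Data frame `year`, `index` (consumer price index; any positive
#'   scale).
#' @param econ One-row data frame `discount_rate`, `base_year`,
#'   `horizon_start`, `horizon_end` (inclusive calendar years).
#' @param scenarios Optional data frame `scenario`, `source` (`"expert"` or
#'   `"literature"`), `comorbidity`, `cohort`, `delta_pp` (absolute
#'   percentage-point addition to baseline prevalence).
#' @param update_rule `"at_risk"` (incidence applies to the comorbidity-free
#'   pool, the default) or `"whole_cohort"` (incidence applies to all alive).
#' @param schema_version Integer schema version; currently `1`.
#'
#' @return A validated object of class `bia_config`.
#' @seealso [load_model_config()], [write_model_config()], [spain_fixture()]
#' @export
bia_config <- function(population, cohorts, epi, resource_use, unit_costs,
                       cpi, econ, scenarios = NULL, update_rule = "at_risk",
                       schema_version = 1L) {
  scenarios <- scenarios %||% tibble::tibble(
    scenario = character(), source = character(), comorbidity = character(),
    cohort = character(), delta_pp = double()
  )
  cfg <- structure(
    list(
      schema_version = as.integer(schema_version),
      update_rule = update_rule,
      population = tibble::as_tibble(population),
      cohorts = tibble::as_tibble(cohorts),
      epi = tibble::as_tibble(epi),
      resource_use = tibble::as_tibble(resource_use),
      unit_costs = tibble::as_tibble(unit_costs),
      cpi = tibble::as_tibble(cpi),
      econ = tibble::as_tibble(econ),
      scenarios = tibble::as_tibble(scenarios)
    ),
    class = "bia_config"
  )
  validate_config(cfg)
}

config_schema <- list(
  population = c("national_population", "hiv_prevalence", "diagnosed_fraction",
                 "recent_fraction", "annual_mortality"),
  cohorts = c("cohort", "size_baseline", "mean_age_baseline"),
  epi = c("comorbidity", "cohort", "baseline_prevalence", "incidence_young",
          "incidence_old", "age_threshold", "annual_incidence_reduction"),
  resource_use = c("comorbidity", "resource", "quantity"),
  unit_costs = c("resource", "unit_cost", "origin_year"),
  cpi = c("year", "index"),
  econ = c("discount_rate", "base_year", "horizon_start", "horizon_end"),
  scenarios = c("scenario", "source", "comorbidity", "cohort", "delta_pp")
)

check_fields <- function(df, table) {
  expected <- config_schema[[table]]
  missing <- setdiff(expected, names(df))
  if (length(missing) > 0) {
    abort(sprintf("config table '%s' is missing required field(s): %s",
                  table, paste(missing, collapse = ", ")),
          class = "plwhcost_schema_error")
  }
  unknown <- setdiff(names(df), expected)
  if (length(unknown) > 0) {
    abort(sprintf("config table '%s' has unknown field(s): %s",
                  table, paste(unknown, collapse = ", ")),
          class = "plwhcost_schema_error")
  }
  invisible(df)
}

check_range <- function(x, what, lo = 0, hi = 1, hi_open = FALSE, lo_open = FALSE) {
  bad <- !is.finite(x) | x < lo | x > hi |
    (hi_open & x == hi) | (lo_open & x == lo)
  if (any(bad)) {
    abort(sprintf(
      "%s must be in %s%s, %s%s; offending value(s): %s",
      what, if (lo_open) "(" else "[", format(lo),
      format(hi), if (hi_open) ")" else "]",
      paste(format(x[bad]), collapse = ", ")
    ), class = "plwhcost_validation_error")
  }
  invisible(x)
}

check_enum <- function(x, levels, what) {
  bad <- setdiff(unique(x), levels)
  if (length(bad) > 0) {
    abort(sprintf("unknown %s: %s (expected one of: %s)",
                  what, paste(bad, collapse = ", "),
                  paste(levels, collapse = ", ")),
          class = "plwhcost_validation_error")
  }
  invisible(x)
}

#' Validate a model configuration
#'
#' Runs the full invariant suite on a `bia_config` and aborts with a classed
#' error (`plwhcost_schema_error` for missing/unknown fields,
#' `plwhcost_validation_error` for out-of-range or inconsistent values)
#' naming the offending field or value. Called automatically by
#' [bia_config()] and [load_model_config()].
#'
#' @param config A `bia_config` (or a bare list with the same structure).
#' @return The configuration, invisibly, if valid.
#' @export
validate_config <- function(config) {
  required <- c("schema_version", "update_rule", names(config_schema))
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    abort(sprintf("config is missing component(s): %s",
                  paste(missing, collapse = ", ")),
          class = "plwhcost_schema_error")
  }
  unknown <- setdiff(names(config), required)
  if (length(unknown) > 0) {
    abort(sprintf("config has unknown component(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "plwhcost_schema_error")
  }
  if (!identical(as.integer(config$schema_version), 1L)) {
    abort(sprintf("unsupported schema_version: %s", config$schema_version),
          class = "plwhcost_schema_error")
  }
  check_enum(config$update_rule, c("at_risk", "whole_cohort"), "update_rule")
  for (tbl in names(config_schema)) check_fields(config[[tbl]], tbl)

  pop <- config$population
  if (nrow(pop) != 1) {
    abort("population must have exactly one row", class = "plwhcost_validation_error")
  }
  if (!is.finite(pop$national_population) || pop$national_population <= 0) {
    abort(sprintf("national_population must be > 0; offending value: %s",
                  format(pop$national_population)),
          class = "plwhcost_validation_error")
  }
  check_range(pop$hiv_prevalence, "hiv_prevalence")
  check_range(pop$diagnosed_fraction, "diagnosed_fraction")
  check_range(pop$recent_fraction, "recent_fraction")
  check_range(pop$annual_mortality, "annual_mortality", hi_open = TRUE)

  coh <- config$cohorts
  check_enum(coh$cohort, cohort_levels, "cohort label")
  if (anyDuplicated(coh$cohort)) {
    abort("cohort labels must be unique", class = "plwhcost_validation_error")
  }
  check_range(coh$size_baseline, "size_baseline", hi = Inf)
  check_range(coh$mean_age_baseline, "mean_age_baseline", hi = Inf, lo_open = TRUE)

  epi <- config$epi
  check_enum(epi$comorbidity, comorbidity_levels, "comorbidity")
  check_enum(epi$cohort, coh$cohort, "cohort label in epi")
  key <- paste(epi$comorbidity, epi$cohort)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicated (comorbidity, cohort) row(s) in epi: %s",
                  paste(unique(key[duplicated(key)]), collapse = "; ")),
          class = "plwhcost_validation_error")
  }
  full <- tidyr::expand_grid(comorbidity = unique(epi$comorbidity), cohort = coh$cohort)
  absent <- dplyr::anti_join(full, epi, by = c("comorbidity", "cohort"))
  if (nrow(absent) > 0) {
    abort(sprintf("epi is missing (comorbidity, cohort) row(s): %s",
                  paste(paste(absent$comorbidity, absent$cohort), collapse = "; ")),
          class = "plwhcost_validation_error")
  }
  check_range(epi$baseline_prevalence, "baseline_prevalence")
  check_range(epi$incidence_young, "incidence_young")
  check_range(epi$incidence_old, "incidence_old")
  check_range(epi$annual_incidence_reduction, "annual_incidence_reduction", hi_open = TRUE)
  check_range(epi$age_threshold, "age_threshold", hi = Inf, lo_open = TRUE)

  ru <- config$resource_use
  check_enum(ru$resource, resource_levels, "resource category")
  check_enum(ru$comorbidity, unique(epi$comorbidity), "comorbidity in resource_use")
  check_range(ru$quantity, "resource quantity", hi = Inf)
  per <- dplyr::count(ru, .data$comorbidity, .data$resource)
  if (any(per$n > 1)) {
    abort("duplicated (comorbidity, resource) rows in resource_use",
          class = "plwhcost_validation_error")
  }
  need <- tidyr::expand_grid(comorbidity = unique(epi$comorbidity), resource = resource_levels)
  absent <- dplyr::anti_join(need, ru, by = c("comorbidity", "resource"))
  if (nrow(absent) > 0) {
    abort(sprintf("resource_use is missing categor(ies): %s",
                  paste(paste(absent$comorbidity, absent$resource), collapse = "; ")),
          class = "plwhcost_validation_error")
  }

  uc <- config$unit_costs
  check_enum(uc$resource, resource_levels, "resource category in unit_costs")
  missing_rc <- setdiff(resource_levels, uc$resource)
  if (length(missing_rc) > 0) {
    abort(sprintf("unit_costs is missing resource categor(ies): %s",
                  paste(missing_rc, collapse = ", ")),
          class = "plwhcost_validation_error")
  }
  check_range(uc$unit_cost, "unit_cost", hi = Inf)

  check_range(config$cpi$index, "cpi index", hi = Inf, lo_open = TRUE)
  if (anyDuplicated(config$cpi$year)) {
    abort("duplicated years in cpi", class = "plwhcost_validation_error")
  }

  econ <- config$econ
  if (nrow(econ) != 1) {
    abort("econ must have exactly one row", class = "plwhcost_validation_error")
  }
  check_range(econ$discount_rate, "discount_rate", hi = Inf)
  if (econ$horizon_start != econ$base_year) {
    abort(sprintf("horizon_start (%s) must equal base_year (%s)",
                  econ$horizon_start, econ$base_year),
          class = "plwhcost_validation_error")
  }
  if (econ$horizon_end < econ$horizon_start) {
    abort("horizon_end must be >= horizon_start",
          class = "plwhcost_validation_error")
  }

  sc <- config$scenarios
  if (nrow(sc) > 0) {
    check_enum(sc$source, c("expert", "literature"), "scenario source")
    check_enum(sc$comorbidity, unique(epi$comorbidity), "comorbidity in scenarios")
    check_enum(sc$cohort, coh$cohort, "cohort label in scenarios")
    if (any(sc$delta_pp < 0)) {
      abort(sprintf("scenario delta_pp must be >= 0; offending value(s): %s",
                    paste(sc$delta_pp[sc$delta_pp < 0], collapse = ", ")),
            class = "plwhcost_validation_error")
    }
  }
  invisible(config)
}

#' @export
print.bia_config <- function(x, ...) {
  cat("<bia_config> schema v", x$schema_version, "\n", sep = "")
  cat("  horizon: ", x$econ$horizon_start, "-", x$econ$horizon_end,
      ", discount ", 100 * x$econ$discount_rate, "%, update rule: ",
      x$update_rule, "\n", sep = "")
  cat("  cohorts: ", paste(sprintf("%s (%.0f persons, mean age %.0f)",
                                   x$cohorts$cohort, x$cohorts$size_baseline,
                                   x$cohorts$mean_age_baseline), collapse = "; "),
      "\n", sep = "")
  cat("  comorbidities: ", paste(unique(x$epi$comorbidity), collapse = ", "), "\n",
      sep = "")
  cat("  scenarios: ", if (nrow(x$scenarios) == 0) "none" else
    paste(unique(x$scenarios$scenario), collapse = ", "), "\n", sep = "")
  invisible(x)
}

rows_to_tibble <- function(rows, table) {
  if (is.null(rows) || length(rows) == 0) {
    return(tibble::as_tibble(sapply(config_schema[[table]], function(f) logical(0),
                                    simplify = FALSE)))
  }
  purrr::map(rows, tibble::as_tibble_row) |> purrr::list_rbind()
}

#' Load a model configuration from YAML
#'
#' Reads a YAML (or JSON) configuration conforming to the documented schema
#' and returns a validated [bia_config]. Unknown keys anywhere in the file
#' are rejected; every invariant of [validate_config()] is enforced.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `bia_config`.
#' @examples
#' cfg <- load_model_config(system.file("extdata", "spain_base_case.yaml",
#'                                      package = "plwhcost"))
#' cfg$cohorts
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "plwhcost_io_error")
  }
  raw <- yaml::read_yaml(path)
  top <- c("schema_version", "update_rule", "population", "cohorts", "epi",
           "resource_use", "unit_costs", "cpi", "econ", "scenarios")
  unknown <- setdiff(names(raw), top)
  if (length(unknown) > 0) {
    abort(sprintf("config file has unknown top-level key(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "plwhcost_schema_error")
  }
  missing <- setdiff(setdiff(top, "scenarios"), names(raw))
  if (length(missing) > 0) {
    abort(sprintf("config file is missing required key(s): %s",
                  paste(missing, collapse = ", ")),
          class = "plwhcost_schema_error")
  }
  bia_config(
    population = tibble::as_tibble_row(raw$population),
    cohorts = rows_to_tibble(raw$cohorts, "cohorts"),
    epi = rows_to_tibble(raw$epi, "epi"),
    resource_use = rows_to_tibble(raw$resource_use, "resource_use"),
    unit_costs = rows_to_tibble(raw$unit_costs, "unit_costs"),
    cpi = rows_to_tibble(raw$cpi, "cpi"),
    econ = tibble::as_tibble_row(raw$econ),
    scenarios = rows_to_tibble(raw$scenarios, "scenarios"),
    update_rule = raw$update_rule,
    schema_version = raw$schema_version
  )
}

#' Write a model configuration to YAML
#'
#' Serializes a [bia_config] to the same schema read by
#' [load_model_config()]; `load_model_config(write_model_config(cfg, f))`
#' reproduces `cfg` field-for-field (numbers are written with 15 significant
#' digits).
#'
#' @param config A `bia_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(config, path) {
  validate_config(config)
  tbl_rows <- function(df) purrr::transpose(as.list(df))
  out <- list(
    schema_version = config$schema_version,
    update_rule = config$update_rule,
    population = as.list(config$population),
    cohorts = tbl_rows(config$cohorts),
    epi = tbl_rows(config$epi),
    resource_use = tbl_rows(config$resource_use),
    unit_costs = tbl_rows(config$unit_costs),
    cpi = tbl_rows(config$cpi),
    econ = as.list(config$econ),
    scenarios = tbl_rows(config$scenarios)
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Derive diagnosed-population and cohort sizes from national parameters
#'
#' The diagnosed population is `national_population x hiv_prevalence x
#' diagnosed_fraction`; the recently diagnosed cohort (<10 years since
#' diagnosis) is the `recent_fraction` share of it and the longstanding
#' cohort (>= 10 years) is the remainder. Fractional persons are retained:
#' rounding happens only in presentation layouts, never in computation, so
#' `recent + longstanding == total` exactly.
#'
#' @param population One-row data frame of national population parameters
#'   (see [bia_config()]).
#' @return A one-row tibble with columns `total_diagnosed`, `recent`,
#'   `longstanding` (persons, fractional).
#' @examples
#' derive_population(tibble::tibble(
#'   national_population = 1e6, hiv_prevalence = 0.0031,
#'   diagnosed_fraction = 0.925, recent_fraction = 0.396,
#'   annual_mortality = 0.0207
#' ))
#' @export
derive_population <- function(population) {
  population <- tibble::as_tibble(population)
  check_fields(population, "population")
  total <- population$national_population * population$hiv_prevalence *
    population$diagnosed_fraction
  recent <- total * population$recent_fraction
  tibble::tibble(
    total_diagnosed = total,
    recent = recent,
    longstanding = total - recent
  )
}

#' Baseline prevalence from a prevalent count and a cohort size
#'
#' @param count Prevalent persons with the comorbidity at baseline.
#' @param size Cohort size at baseline; must be positive and at least
#'   `count`.
#' @return `count / size`, vectorized over both arguments.
#' @export
derive_baseline_prevalence <- function(count, size) {
  if (any(size <= 0)) {
    abort(sprintf("cohort size must be > 0; offending value(s): %s",
                  paste(format(size[size <= 0]), collapse = ", ")),
          class = "plwhcost_validation_error")
  }
  if (any(count < 0 | count > size)) {
    bad <- count < 0 | count > size
    abort(sprintf("count must satisfy 0 <= count <= size; offending count(s): %s",
                  paste(format(count[bad]), collapse = ", ")),
          class = "plwhcost_validation_error")
  }
  count / size
}

#' Export a configuration as audit CSV tables
#'
#' Writes one CSV per configuration table (population, cohorts, epi,
#' resource_use, unit_costs, cpi, econ, scenarios) at full precision.
#'
#' @param config A `bia_config`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
export_config_csv <- function(config, dir) {
  validate_config(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- names(config_schema)
  paths <- vapply(tables, function(tbl) {
    p <- file.path(dir, paste0("config_", tbl, ".csv"))
    readr::write_csv(config[[tbl]], p)
    p
  }, character(1))
  invisible(paths)
}
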