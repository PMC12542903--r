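#' Project cohort sizes over the model horizon
#'
#' The cohorts are closed and static: nobody migrates between the
#' since-diagnosis cohorts and no newly diagnosed patients enter, so each
#' cohort decays geometrically under the single annual mortality rate,
#' `N(t+1) = N(t) (1 - m)`, and the cohort mean age advances by exactly one
#' year per annual cycle.
#'
#' @param config A [bia_config].
#' @return A tibble with one row per cohort and calendar year: `cohort`,
#'   `year`, `alive` (persons at cycle start, fractional), `mean_age`
#'   (years).
#' @examples
#' pop <- project_population(spain_fixture())
#' dplyr::filter(pop, year == 2034)
#' @export
project_population <- function(config) {
  validate_config(config)
  years <- seq(config$econ$horizon_start, config$econ$horizon_end)
  m <- config$population$annual_mortality
  tidyr::expand_grid(config$cohorts, year = years) |>
    dplyr::mutate(
      alive = .data$size_baseline * (1 - m)^(.data$year - years[1]),
      mean_age = .data$mean_age_baseline + (.data$year - years[1])
    ) |>
    dplyr::select("cohort", "year", "alive", "mean_age")
}

#' Annual comorbidity incidence at a given cycle
#'
#' Selects the incidence band from the cohort's mean age (`incidence_old`
#' when mean age is at or above `age_threshold`, otherwise
#' `incidence_young`) and applies the cumulative annual incidence reduction:
#' `band(age) x (1 - reduction)^years_since_base`. All arguments are
#' vectorized.
#'
#' @param incidence_young,incidence_old Annual probabilities for the two age
#'   bands.
#' @param age_threshold Age (years) at which the old band applies.
#' @param annual_incidence_reduction Proportional reduction of incidence per
#'   year since the base year.
#' @param mean_age Cohort mean age (years) in the cycle.
#' @param years_since_base Whole years elapsed since the base year (>= 0).
#' @return Annual incidence probability.
#' @examples
#' incidence_at(0.02, 0.04, 50, 0.01, mean_age = 48:52, years_since_base = 0:4)
#' @export
incidence_at <- function(incidence_young, incidence_old, age_threshold,
                         annual_incidence_reduction, mean_age,
                         years_since_base) {
  if (any(years_since_base < 0)) {
    abort("years_since_base must be >= 0", class = "plwhcost_validation_error")
  }
  band <- ifelse(mean_age >= age_threshold, incidence_old, incidence_young)
  band * (1 - annual_incidence_reduction)^years_since_base
}

#' Project prevalent comorbidity counts over the horizon
#'
#' Starting from baseline prevalent counts (by default `baseline_prevalence
#' x cohort size`), each comorbidity pool is updated once per annual cycle.
#' Under the default at-risk rule, incidence applies to the comorbidity-free
#' pool and mortality to everyone at cycle end:
#' `P(t+1) = [P(t) + i(t) (N(t) - P(t))] (1 - m)`.
#' Under the alternative whole-cohort rule (`update_rule = "whole_cohort"`
#' in the configuration) incidence applies to all alive:
#' `P(t+1) = [P(t) + i(t) N(t)] (1 - m)`, capped at the surviving cohort so
#' prevalent counts never exceed alive counts. The comorbidity is an
#' absorbing state (no remission), comorbidities are modelled independently
#' (a person may appear in several pools), and mortality does not differ by
#' comorbidity status. Counts are measured at cycle start; no half-cycle
#' correction is applied.
#'
#' @param config A [bia_config].
#' @param baseline_counts Optional tibble `comorbidity`, `cohort`, `count`
#'   overriding the baseline prevalent counts implied by the configuration's
#'   prevalences (used by the calibration and sensitivity routines).
#' @return A tibble `cohort`, `comorbidity`, `year`, `alive`, `prevalent`.
#' @examples
#' counts <- project_counts(spain_fixture())
#' dplyr::filter(counts, year %in% c(2024, 2034), comorbidity == "renal")
#' @export
project_counts <- function(config, baseline_counts = NULL) {
  validate_config(config)
  years <- seq(config$econ$horizon_start, config$econ$horizon_end)
  m <- config$population$annual_mortality

  series <- config$epi |>
    dplyr::left_join(config$cohorts, by = "cohort") |>
    dplyr::mutate(count = .data$baseline_prevalence * .data$size_baseline)
  if (!is.null(baseline_counts)) {
    series <- series |>
      dplyr::rows_update(tibble::as_tibble(baseline_counts),
                         by = c("comorbidity", "cohort"))
  }
  if (any(series$count > series$size_baseline | series$count < 0)) {
    bad <- series$count > series$size_baseline | series$count < 0
    abort(sprintf(
      "baseline count must satisfy 0 <= count <= cohort size; offending: %s",
      paste(sprintf("%s/%s (%s of %s)", series$comorbidity[bad],
                    series$cohort[bad], format(series$count[bad]),
                    format(series$size_baseline[bad])), collapse = "; ")
    ), class = "plwhcost_validation_error")
  }

  n_series <- nrow(series)
  P <- series$count
  N <- series$size_baseline
  prevalent <- matrix(NA_real_, nrow = n_series, ncol = length(years))
  alive <- matrix(NA_real_, nrow = n_series, ncol = length(years))
  for (k in seq_along(years)) {
    prevalent[, k] <- P
    alive[, k] <- N
    i_t <- incidence_at(series$incidence_young, series$incidence_old,
                        series$age_threshold, series$annual_incidence_reduction,
                        mean_age = series$mean_age_baseline + (k - 1),
                        years_since_base = k - 1)
    pool <- if (config$update_rule == "at_risk") N - P else N
    P <- pmin((P + i_t * pool) * (1 - m), N * (1 - m))
    N <- N * (1 - m)
  }

  tidyr::expand_grid(
    dplyr::select(series, "cohort", "comorbidity"),
    year = years
  ) |>
    dplyr::mutate(
      alive = as.vector(t(alive)),
      prevalent = as.vector(t(prevalent))
    ) |>
    dplyr::arrange(.data$cohort, .data$comorbidity, .data$year)
}

#' Person-years of prevalent comorbidity
#'
#' Each prevalent person contributes one person-year (PY) per annual cycle;
#' PY totals are the sum of prevalent counts over every year of the horizon
#' (an 11-year horizon contributes 11 cycles) and are additive across
#' cohorts and comorbidities.
#'
#' @param counts A count trajectory from [project_counts()] (any tibble with
#'   a `prevalent` column and the grouping columns in `by`).
#' @param by Character vector of grouping columns; use `character(0)` for
#'   the grand total.
#' @return A tibble of the grouping columns plus `person_years`.
#' @examples
#' person_years(project_counts(spain_fixture()), by = "comorbidity")
#' @export
person_years <- function(counts, by = c("cohort", "comorbidity")) {
  counts |>
    dplyr::summarise(person_years = sum(.data$prevalent),
                     .by = dplyr::all_of(by))
}
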