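#' Inflate a cost between calendar years with a CPI series
#'
#' Returns `amount x cpi(target_year) / cpi(origin_year)`. Both years must
#' be present in the index series; a missing year is an error naming the
#' year. Vectorized over `amount` and `origin_year`.
#'
#' @param amount Euros in `origin_year` prices.
#' @param origin_year,target_year Calendar years.
#' @param cpi Tibble `year`, `index`.
#' @return Euros in `target_year` prices.
#' @examples
#' cpi <- tibble::tibble(year = c(2020, 2024), index = c(100, 110))
#' inflate_cost(100, 2020, 2024, cpi)
#' @export
inflate_cost <- function(amount, origin_year, target_year, cpi) {
  idx <- setNames(cpi$index, as.character(cpi$year))
  needed <- unique(c(origin_year, target_year))
  missing <- needed[!as.character(needed) %in% names(idx)]
  if (length(missing) > 0) {
    abort(sprintf("CPI index has no entry for year(s): %s",
                  paste(missing, collapse = ", ")),
          class = "plwhcost_validation_error")
  }
  unname(amount * idx[as.character(target_year)] / idx[as.character(origin_year)])
}

#' Annual discount factor relative to the base year
#'
#' `(1 + discount_rate)^-(year - base_year)`; the base year itself carries
#' factor exactly 1. Years before the base year are an error: the model only
#' discounts forward from model entry.
#'
#' @param year Calendar year (vectorized).
#' @param base_year Base calendar year.
#' @param discount_rate Annual discount rate (proportion, e.g. `0.03`).
#' @return Discount factor(s) in `(0, 1]`.
#' @examples
#' discount_factor(2024:2026, 2024, 0.03)
#' @export
discount_factor <- function(year, base_year, discount_rate) {
  if (any(year < base_year)) {
    abort(sprintf("cannot discount years before the base year %s: %s",
                  base_year, paste(year[year < base_year], collapse = ", ")),
          class = "plwhcost_validation_error")
  }
  (1 + discount_rate)^(-(year - base_year))
}

#' Annual direct healthcare cost per prevalent patient
#'
#' For each comorbidity, the per-patient-year cost is the dot product of the
#' resource-use quantities (events per patient-year across the six resource
#' categories) and the unit costs, after inflating every unit cost from its
#' origin year to the economic base year via the CPI series.
#'
#' @param config A [bia_config].
#' @return A tibble `comorbidity`, `cost_per_py` (euros per patient-year in
#'   base-year prices).
#' @examples
#' per_patient_cost(spain_fixture())
#' @export
per_patient_cost <- function(config) {
  validate_config(config)
  costs <- config$unit_costs |>
    dplyr::mutate(unit_cost_base = inflate_cost(
      .data$unit_cost, .data$origin_year, config$econ$base_year, config$cpi
    ))
  config$resource_use |>
    dplyr::left_join(dplyr::select(costs, "resource", "unit_cost_base"),
                     by = "resource") |>
    dplyr::summarise(
      cost_per_py = sum(.data$quantity * .data$unit_cost_base),
      .by = "comorbidity"
    )
}

#' Annual and cumulative discounted cost trajectories
#'
#' Converts a prevalent-count trajectory into annual costs: undiscounted
#' annual cost is `prevalent(t) x cost_per_py`, the discounted cost applies
#' the base-year discount factor, and `cum_discounted` accumulates the
#' discounted stream within each cohort-comorbidity series. Costs accrue for
#' every prevalent person-year; decedents contribute through their last
#' counted cycle only.
#'
#' @param counts A count trajectory from [project_counts()].
#' @param per_patient A tibble `comorbidity`, `cost_per_py` from
#'   [per_patient_cost()].
#' @param econ One-row economic settings tibble (see [bia_config()]).
#' @return The `counts` tibble with added columns `cost`, `cost_discounted`,
#'   `cum_discounted` (euros).
#' @export
cost_trajectory <- function(counts, per_patient, econ) {
  missing <- setdiff(unique(counts$comorbidity), per_patient$comorbidity)
  if (length(missing) > 0) {
    abort(sprintf("no per-patient cost for comorbidit(ies): %s",
                  paste(missing, collapse = ", ")),
          class = "plwhcost_validation_error")
  }
  counts |>
    dplyr::left_join(per_patient, by = "comorbidity") |>
    dplyr::mutate(
      cost = .data$prevalent * .data$cost_per_py,
      cost_discounted = .data$cost *
        discount_factor(.data$year, econ$base_year, econ$discount_rate)
    ) |>
    dplyr::arrange(.data$cohort, .data$comorbidity, .data$year) |>
    dplyr::mutate(cum_discounted = cumsum(.data$cost_discounted),
                  .by = c("cohort", "comorbidity")) |>
    dplyr::select(-"cost_per_py")
}
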