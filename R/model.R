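#' Run the full budget-impact model
#'
#' Orchestrates projection and costing for one configuration: cohort
#' populations are projected over the horizon, prevalent comorbidity counts
#' follow the configured update rule, and prevalent person-years are costed
#' with CPI-inflated unit costs and annual discounting.
#'
#' @param config A [bia_config].
#' @param baseline_counts Optional baseline-count override, passed through
#'   to [project_counts()].
#' @return An object of class `bia_model` with components `config`,
#'   `population` (cohort trajectory), `counts` (prevalent trajectory),
#'   `per_patient` (euros per patient-year), and `costs` (annual and
#'   cumulative discounted euros). Use [tidy()] for the per-year table,
#'   [glance()] for one-row totals, and [autoplot()] for the cumulative
#'   cost curves.
#' @examples
#' fit <- run_model(spain_fixture())
#' glance(fit)
#' @export
run_model <- function(config, baseline_counts = NULL) {
  validate_config(config)
  population <- project_population(config)
  counts <- project_counts(config, baseline_counts = baseline_counts)
  per_patient <- per_patient_cost(config)
  costs <- cost_trajectory(counts, per_patient, config$econ)
  structure(
    list(config = config, population = population, counts = counts,
         per_patient = per_patient, costs = costs),
    class = "bia_model"
  )
}

#' @export
print.bia_model <- function(x, ...) {
  g <- glance(x)
  cat("<bia_model> ", g$horizon_start, "-", g$horizon_end, " (",
      x$config$update_rule, " rule)\n", sep = "")
  cat(sprintf("  %d cohorts x %d comorbidities; %.0f person-years of comorbidity\n",
              g$n_cohorts, g$n_comorbidities, g$total_person_years))
  cat(sprintf("  cumulative discounted cost: EUR %.1f million\n",
              g$total_cost_discounted / 1e6))
  invisible(x)
}

#' Tidy the per-year results of a fitted model
#'
#' @param x A `bia_model` from [run_model()].
#' @param ... Unused.
#' @return A tibble with one row per cohort, comorbidity, and year: `alive`,
#'   `prevalent`, `cost`, `cost_discounted`, `cum_discounted`.
#' @export
tidy.bia_model <- function(x, ...) {
  x$costs
}

#' One-row summary of a fitted model
#'
#' @param x A `bia_model` from [run_model()].
#' @param ... Unused.
#' @return A one-row tibble: horizon, dimensions, update rule, total
#'   person-years of comorbidity, and cumulative undiscounted and discounted
#'   cost.
#' @export
glance.bia_model <- function(x, ...) {
  tibble::tibble(
    horizon_start = x$config$econ$horizon_start,
    horizon_end = x$config$econ$horizon_end,
    n_cohorts = nrow(x$config$cohorts),
    n_comorbidities = length(unique(x$config$epi$comorbidity)),
    update_rule = x$config$update_rule,
    total_person_years = sum(x$counts$prevalent),
    total_cost = sum(x$costs$cost),
    total_cost_discounted = sum(x$costs$cost_discounted)
  )
}

#' Cumulative discounted cost curves per comorbidity
#'
#' @param object A `bia_model` from [run_model()].
#' @param ... Unused.
#' @return A ggplot of cumulative discounted cost (million euros, summed
#'   across cohorts) against calendar year, one line per comorbidity.
#' @export
autoplot.bia_model <- function(object, ...) {
  df <- object$costs |>
    dplyr::summarise(cost_discounted = sum(.data$cost_discounted),
                     .by = c("comorbidity", "year")) |>
    dplyr::arrange(.data$comorbidity, .data$year) |>
    dplyr::mutate(cum_million = cumsum(.data$cost_discounted) / 1e6,
                  .by = "comorbidity")
  ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$cum_million,
                                   colour = .data$comorbidity)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::scale_x_continuous(breaks = unique(df$year)) +
    ggplot2::labs(x = NULL, y = "Cumulative discounted cost (million €)",
                  colour = "Comorbidity") +
    ggplot2::theme_minimal()
}
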