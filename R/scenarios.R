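#' Apply a counterfactual prevalence shift to a configuration
#'
#' A named scenario adds absolute percentage-point deltas to the 2024
#' baseline prevalence of the affected (comorbidity, cohort) pairs, capping
#' the result at 1. Only the prevalent stock at model entry moves: incidence
#' schedules, mortality, and costs are untouched, so the scenario isolates
#' an increased prevalent burden attributable to prior regimen exposure.
#' Scenarios are full-exposure counterfactuals, applied one regimen at a
#' time and never market-share weighted.
#'
#' @param config A [bia_config] whose `scenarios` table contains the named
#'   scenario.
#' @param scenario Scenario name (a value of `config$scenarios$scenario`).
#' @return A new `bia_config` with shifted baseline prevalences and an empty
#'   scenario table.
#' @examples
#' shifted <- apply_prevalence_delta(spain_fixture(), "cardiovascular_darunavir")
#' dplyr::filter(shifted$epi, comorbidity == "cardiovascular")
#' @export
apply_prevalence_delta <- function(config, scenario) {
  validate_config(config)
  deltas <- dplyr::filter(config$scenarios, .data$scenario == !!scenario)
  if (nrow(deltas) == 0) {
    abort(sprintf("unknown scenario '%s'; available: %s", scenario,
                  paste(unique(config$scenarios$scenario), collapse = ", ")),
          class = "plwhcost_validation_error")
  }
  epi <- config$epi |>
    dplyr::left_join(dplyr::select(deltas, "comorbidity", "cohort", "delta_pp"),
                     by = c("comorbidity", "cohort")) |>
    dplyr::mutate(
      baseline_prevalence = pmin(
        1, .data$baseline_prevalence + dplyr::coalesce(.data$delta_pp, 0) / 100
      )
    ) |>
    dplyr::select(-"delta_pp")
  out <- config
  out$epi <- epi
  out$scenarios <- config$scenarios[0, ]
  validate_config(out)
}

#' Percentage increase of a scenario quantity over the current one
#'
#' @param current,scenario Positive totals (person-years or euros).
#' @return `100 * (scenario / current - 1)`.
#' @export
pct_increase <- function(current, scenario) {
  100 * (scenario / current - 1)
}

new_bia_comparison <- function(df, label, kind) {
  structure(df, class = c("bia_comparison", class(df)),
            label = label, kind = kind)
}

#' Run a paired current-vs-counterfactual model comparison
#'
#' Runs the full model twice — once as configured (current scenario) and
#' once with the named scenario's baseline-prevalence deltas applied — on
#' identical incidence, mortality, and cost inputs, and summarises per
#' comorbidity: prevalent person-years, cumulative discounted cost, and the
#' percentage increases on both bases. Person-year increases are computed on
#' undiscounted person-years and cost increases on discounted cost; the two
#' coincide exactly only at a zero discount rate.
#'
#' @param config A [bia_config] containing the scenario.
#' @param scenario Scenario name.
#' @return A `bia_comparison` tibble with one row per comorbidity:
#'   `current_py`, `scenario_py`, `py_increase_pct`, `current_cost`,
#'   `scenario_cost`, `incremental_cost`, `cost_increase_pct` (costs are
#'   cumulative discounted euros over the horizon).
#' @examples
#' run_scenario_comparison(spain_fixture(), "renal_tenofovir_disoproxil")
#' @export
run_scenario_comparison <- function(config, scenario) {
  current <- run_model(config)
  counterfactual <- run_model(apply_prevalence_delta(config, scenario))
  compare_models(current, counterfactual, label = scenario, kind = "scenario")
}

compare_models <- function(current, counterfactual, label, kind,
                           evaluated = NULL) {
  summarise_side <- function(fit, prefix) {
    fit$costs |>
      dplyr::summarise(py = sum(.data$prevalent),
                       cost = sum(.data$cost_discounted),
                       .by = "comorbidity") |>
      dplyr::rename_with(~ paste0(prefix, "_", .x), c("py", "cost"))
  }
  df <- summarise_side(current, "current") |>
    dplyr::left_join(summarise_side(counterfactual, "scenario"),
                     by = "comorbidity") |>
    dplyr::mutate(
      py_increase_pct = pct_increase(.data$current_py, .data$scenario_py),
      incremental_cost = .data$scenario_cost - .data$current_cost,
      cost_increase_pct = pct_increase(.data$current_cost, .data$scenario_cost)
    ) |>
    dplyr::relocate("py_increase_pct", .after = "scenario_py")
  if (!is.null(evaluated)) {
    df <- dplyr::mutate(df, evaluated = .data$comorbidity %in% evaluated)
  }
  new_bia_comparison(df, label = label, kind = kind)
}

#' @export
print.bia_comparison <- function(x, ...) {
  cat("<bia_comparison> ", attr(x, "kind"), ": ", attr(x, "label"),
      "\n", sep = "")
  NextMethod()
}

#' @export
tidy.bia_comparison <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.bia_comparison <- function(x, ...) {
  tibble::tibble(
    label = attr(x, "label"),
    kind = attr(x, "kind"),
    total_current_py = sum(x$current_py),
    total_scenario_py = sum(x$scenario_py),
    total_incremental_cost = sum(x$incremental_cost)
  )
}

#' Incremental discounted cost per comorbidity for a comparison
#'
#' @param object A `bia_comparison`.
#' @param ... Unused.
#' @return A ggplot bar chart of incremental cumulative discounted cost
#'   (million euros) per comorbidity.
#' @export
autoplot.bia_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$comorbidity,
                                   .data$incremental_cost / 1e6)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Incremental discounted cost (million €)",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' One-way sensitivity analysis by prevalence swap
#'
#' Replaces the baseline prevalence of selected cohorts with values from an
#' alternative source (for instance, a different national cohort study),
#' re-runs the model, and reports per-comorbidity differences against the
#' base case. Comorbidities for which the replacement source provides no
#' value in the selected cohorts keep their base-case prevalence and are
#' flagged `evaluated = FALSE` (their differences are zero by construction).
#'
#' @param config A [bia_config].
#' @param replacements Tibble `comorbidity`, `cohort`, `prevalence`
#'   (proportions in `[0, 1]`).
#' @param cohorts Cohort labels to modify; defaults to the cohorts named in
#'   `replacements`.
#' @return A `bia_comparison` with an `evaluated` flag;
#'   `incremental_cost` is swapped-minus-base cumulative discounted cost
#'   (negative when the replacement prevalence is lower).
#' @export
run_sensitivity_swap <- function(config, replacements,
                                 cohorts = unique(replacements$cohort)) {
  validate_config(config)
  replacements <- tibble::as_tibble(replacements)
  stopifnot(all(c("comorbidity", "cohort", "prevalence") %in% names(replacements)))
  check_enum(replacements$cohort, config$cohorts$cohort, "cohort label in replacements")
  check_enum(replacements$comorbidity, unique(config$epi$comorbidity),
             "comorbidity in replacements")
  check_enum(cohorts, config$cohorts$cohort, "cohort selector")
  check_range(replacements$prevalence, "replacement prevalence")
  replacements <- dplyr::filter(replacements, .data$cohort %in% !!cohorts)

  swapped <- config
  swapped$epi <- config$epi |>
    dplyr::left_join(dplyr::rename(replacements, new_prev = "prevalence"),
                     by = c("comorbidity", "cohort")) |>
    dplyr::mutate(baseline_prevalence = dplyr::coalesce(.data$new_prev,
                                                        .data$baseline_prevalence)) |>
    dplyr::select(-"new_prev")

  compare_models(run_model(config), run_model(swapped),
                 label = paste0("swap[", paste(cohorts, collapse = "+"), "]"),
                 kind = "sensitivity",
                 evaluated = unique(replacements$comorbidity))
}
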