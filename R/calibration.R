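#' Calibrate an annual incidence to an endpoint prevalent count
#'
#' Recovers the base (young-band) annual incidence that makes the
#' prevalent-count projection hit a target count after `n_cycles` annual
#' cycles, by bisection on `[0, 1]`. The old-band incidence is tied to the
#' young band through `old_young_ratio` (capped at probability 1): two
#' printed endpoints cannot identify two free band rates, so one scalar per
#' (comorbidity, cohort) is calibrated. Because the achieved endpoint count
#' is strictly increasing in the base incidence (given a baseline below the
#' cohort size), bisection is globally convergent; the bracket halves until
#' it is narrower than `tol`.
#'
#' @param target Prevalent persons to reproduce at the endpoint (cycle start
#'   of year `base + n_cycles`).
#' @param baseline Prevalent persons at the base year.
#' @param size Cohort size at the base year (persons; fractional allowed).
#' @param mean_age Cohort mean age at the base year (years).
#' @param mortality Annual mortality probability.
#' @param n_cycles Whole years between base year and endpoint (10 for a
#'   2024–2034 horizon).
#' @param decay Annual proportional incidence reduction.
#' @param old_young_ratio Old-band incidence as a multiple of the young
#'   band.
#' @param age_threshold Age (years) at which the old band applies.
#' @param update_rule `"at_risk"` or `"whole_cohort"`.
#' @param tol Bisection bracket tolerance on the incidence scale.
#' @param max_iter Maximum bisection iterations.
#' @return A one-row tibble: `incidence_young`, `incidence_old`, `achieved`
#'   (endpoint count at the fitted incidence), `residual`
#'   (achieved - target), `iterations`, `converged` (TRUE when
#'   `|residual| < 0.5` persons).
#' @examples
#' calibrate_incidence(target = 5166, baseline = 2650, size = 55199,
#'                     mean_age = 34, mortality = 0.0207)
#' @export
calibrate_incidence <- function(target, baseline, size, mean_age, mortality,
                                n_cycles = 10, decay = 0.01,
                                old_young_ratio = 1, age_threshold = 50,
                                update_rule = "at_risk",
                                tol = 1e-10, max_iter = 200) {
  if (baseline < 0 || baseline > size) {
    abort("baseline must satisfy 0 <= baseline <= size",
          class = "plwhcost_validation_error")
  }
  forward <- function(inc_young) {
    inc_old <- min(1, inc_young * old_young_ratio)
    P <- baseline
    N <- size
    for (t in seq_len(n_cycles)) {
      i_t <- incidence_at(inc_young, inc_old, age_threshold, decay,
                          mean_age = mean_age + (t - 1),
                          years_since_base = t - 1)
      pool <- if (update_rule == "at_risk") N - P else N
      P <- min((P + i_t * pool) * (1 - mortality), N * (1 - mortality))
      N <- N * (1 - mortality)
    }
    P
  }
  f_lo <- forward(0)
  f_hi <- forward(1)
  if (target < f_lo - 0.5) {
    abort(sprintf(
      "infeasible target: %s is below the zero-incidence projection %.3f",
      format(target), f_lo
    ), class = "plwhcost_calibration_error")
  }
  if (target > f_hi + 0.5) {
    abort(sprintf(
      "infeasible target: %s exceeds the maximum attainable count %.3f",
      format(target), f_hi
    ), class = "plwhcost_calibration_error")
  }
  lo <- 0
  hi <- 1
  iter <- 0L
  while (hi - lo > tol && iter < max_iter) {
    mid <- (lo + hi) / 2
    if (forward(mid) < target) lo <- mid else hi <- mid
    iter <- iter + 1L
  }
  if (hi - lo > tol) {
    abort(sprintf(
      "calibration did not converge in %d iterations; bracket [%.12g, %.12g]",
      max_iter, lo, hi
    ), class = "plwhcost_calibration_error")
  }
  est <- (lo + hi) / 2
  achieved <- forward(est)
  tibble::tibble(
    incidence_young = est,
    incidence_old = min(1, est * old_young_ratio),
    achieved = achieved,
    residual = achieved - target,
    iterations = iter,
    converged = abs(achieved - target) < 0.5
  )
}

# Documented synthetic parameter ranges (not hidden magic): cohort sizes
# 1e3-1e5 persons, baseline prevalence 0-0.3, annual incidence 0-0.05,
# mortality 0-0.05, incidence decay 0-0.02, resource quantities 0-10
# events/patient-year, unit costs 20-6000 EUR, discount rate 0-0.05,
# scenario deltas 0-5 percentage points.
synthetic_ranges <- list(
  size = c(1e3, 1e5), prevalence = c(0, 0.3), incidence = c(0, 0.05),
  mortality = c(0, 0.05), decay = c(0, 0.02), quantity = c(0, 10),
  unit_cost = c(20, 6000), discount = c(0, 0.05), delta_pp = c(0, 5),
  mean_age_recent = c(30, 40), mean_age_longstanding = c(44, 54)
)

#' Generate a seeded synthetic parameter bundle
#'
#' Draws a complete, schema-valid model configuration from documented
#' parameter ranges (see `plwhcost:::synthetic_ranges`): two cohorts, four
#' comorbidities, all six resource categories, a five-year CPI series, and
#' one random counterfactual scenario. The generating truth (the drawn
#' epidemiology, mortality, and per-patient quantities) is attached as
#' `attr(cfg, "truth")` so recovery tests can compare fitted against
#' generating values. The draw is deterministic given `seed`, and the
#' caller's RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @param update_rule Update rule written into the bundle.
#' @return A validated [bia_config] with a `truth` attribute.
#' @examples
#' cfg <- generate_synthetic_params(42)
#' attr(cfg, "truth")$mortality
#' @export
generate_synthetic_params <- function(seed, update_rule = "at_risk") {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("seed must be a single number", class = "plwhcost_validation_error")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  r <- synthetic_ranges
  draw <- function(range, n = 1) runif(n, range[1], range[2])

  mortality <- draw(r$mortality)
  sizes <- draw(r$size, 2)
  cohorts <- tibble::tibble(
    cohort = cohort_levels,
    size_baseline = sizes,
    mean_age_baseline = c(draw(r$mean_age_recent), draw(r$mean_age_longstanding))
  )
  # Back-solve national parameters so derive_population() reproduces the
  # drawn cohort sizes exactly.
  hiv_prevalence <- runif(1, 0.001, 0.01)
  diagnosed_fraction <- runif(1, 0.8, 1)
  population <- tibble::tibble(
    national_population = sum(sizes) / (hiv_prevalence * diagnosed_fraction),
    hiv_prevalence = hiv_prevalence,
    diagnosed_fraction = diagnosed_fraction,
    recent_fraction = sizes[1] / sum(sizes),
    annual_mortality = mortality
  )
  epi <- tidyr::expand_grid(comorbidity = comorbidity_levels,
                            cohort = cohort_levels) |>
    dplyr::mutate(
      baseline_prevalence = draw(r$prevalence, dplyr::n()),
      incidence_young = draw(r$incidence, dplyr::n()),
      incidence_old = draw(r$incidence, dplyr::n()),
      age_threshold = 50,
      annual_incidence_reduction = draw(r$decay)
    )
  resource_use <- tidyr::expand_grid(comorbidity = comorbidity_levels,
                                     resource = resource_levels) |>
    dplyr::mutate(quantity = draw(r$quantity, dplyr::n()))
  base_year <- 2024
  unit_costs <- tibble::tibble(
    resource = resource_levels,
    unit_cost = draw(r$unit_cost, length(resource_levels)),
    origin_year = sample(seq(base_year - 5, base_year), length(resource_levels),
                         replace = TRUE)
  )
  cpi <- tibble::tibble(
    year = seq(base_year - 5, base_year),
    index = 100 * cumprod(c(1, 1 + runif(5, 0, 0.05)))
  )
  econ <- tibble::tibble(
    discount_rate = draw(r$discount),
    base_year = base_year, horizon_start = base_year,
    horizon_end = base_year + 10
  )
  scenarios <- tidyr::expand_grid(
    scenario = "synthetic_regimen", source = "expert",
    comorbidity = comorbidity_levels, cohort = cohort_levels
  ) |>
    dplyr::mutate(delta_pp = draw(r$delta_pp, dplyr::n()))

  cfg <- bia_config(population, cohorts, epi, resource_use, unit_costs, cpi,
                    econ, scenarios, update_rule = update_rule)
  attr(cfg, "truth") <- list(seed = seed, mortality = mortality, epi = epi)
  cfg
}

# Printed base-case inputs for the Spanish 2024-2034 analysis: cohort sizes
# and per-comorbidity prevalent counts in 2024 and 2034, resource-use
# quantities (events per patient-year) and 2024 unit costs. The national
# population is back-solved from the 139 390 diagnosed PLWH total.
spain_inputs <- local({
  counts <- tibble::tribble(
    ~comorbidity,       ~cohort,        ~count_2024, ~count_2034,
    "cardiovascular",   "recent",        2650,        5166,
    "cardiovascular",   "longstanding", 14397,       28389,
    "renal",            "recent",        1270,        2583,
    "renal",            "longstanding",  6483,       12808,
    "bone",             "recent",        3809,        8241,
    "bone",             "longstanding", 13892,       25709,
    "neuropsychiatric", "recent",        2484,        5606,
    "neuropsychiatric", "longstanding", 13723,       21782
  )
  resource_use <- tibble::tribble(
    ~resource,             ~cardiovascular, ~renal, ~bone, ~neuropsychiatric,
    "hospital_admissions", 0.63,            0.84,   0.32,  0.83,
    "diagnostic_tests",    3.88,            4.60,   3.23,  4.24,
    "ed_visits",           1.31,            1.98,   0.80,  1.95,
    "outpatient_visits",   1.62,            1.72,   1.30,  1.67,
    "hiv_visits",          3.21,            3.06,   2.90,  3.02,
    "blood_tests",         9.20,            8.64,   7.85,  8.43
  ) |>
    tidyr::pivot_longer(-"resource", names_to = "comorbidity",
                        values_to = "quantity") |>
    dplyr::select("comorbidity", "resource", "quantity") |>
    dplyr::arrange(.data$comorbidity)
  unit_costs <- tibble::tibble(
    resource = resource_levels,
    unit_cost = c(4669.00, 157.23, 225.93, 158.21, 158.21, 30.96),
    origin_year = 2024
  )
  scenarios <- tibble::tribble(
    ~scenario,                                  ~source,      ~cohort,        ~comorbidity,       ~delta_pp,
    "cardiovascular_darunavir",                 "expert",     "recent",       "cardiovascular",   1.13,
    "cardiovascular_darunavir",                 "expert",     "longstanding", "cardiovascular",   1.88,
    "renal_tenofovir_disoproxil",               "expert",     "recent",       "renal",            2.93,
    "renal_tenofovir_disoproxil",               "expert",     "longstanding", "renal",            7.23,
    "bone_tenofovir_disoproxil",                "expert",     "recent",       "bone",             2.38,
    "bone_tenofovir_disoproxil",                "expert",     "longstanding", "bone",             4.66,
    "neuropsychiatric_dolutegravir_expert",     "expert",     "recent",       "neuropsychiatric", 1.88,
    "neuropsychiatric_dolutegravir_expert",     "expert",     "longstanding", "neuropsychiatric", 2.05,
    "neuropsychiatric_bictegravir_expert",      "expert",     "recent",       "neuropsychiatric", 1.25,
    "neuropsychiatric_bictegravir_expert",      "expert",     "longstanding", "neuropsychiatric", 2.00,
    "neuropsychiatric_dolutegravir_literature", "literature", "recent",       "neuropsychiatric", 2.58,
    "neuropsychiatric_dolutegravir_literature", "literature", "longstanding", "neuropsychiatric", 2.58,
    "neuropsychiatric_bictegravir_literature",  "literature", "recent",       "neuropsychiatric", 0.70,
    "neuropsychiatric_bictegravir_literature",  "literature", "longstanding", "neuropsychiatric", 0.70
  )
  list(
    total_diagnosed = 139390,
    printed_sizes = c(recent = 55199, longstanding = 84192),
    mean_ages = c(recent = 34, longstanding = 48),
    hiv_prevalence = 0.0031, diagnosed_fraction = 0.925,
    recent_fraction = 0.396, annual_mortality = 0.0207,
    age_threshold = 50, annual_incidence_reduction = 0.01,
    discount_rate = 0.03, base_year = 2024, horizon_end = 2034,
    counts = counts, resource_use = resource_use, unit_costs = unit_costs,
    scenarios = scenarios
  )
})

#' Spanish 2024–2034 base-case parameter bundle
#'
#' Assembles the full configuration for the Spanish budget-impact analysis:
#' national epidemiological parameters (0.31% HIV prevalence, 92.5%
#' diagnosed, 39.6% diagnosed <10 years ago, 20.7/1000 annual mortality,
#' cohort mean ages 34 and 48 years), the six-category resource-use and
#' 2024 unit-cost grid, a 3% annual discount rate, and the seven
#' regimen-toxicity scenarios (darunavir, tenofovir disoproxil renal and
#' bone, and dolutegravir/bictegravir neuropsychiatric deltas from expert
#' and literature sources).
#'
#' The national population is back-solved so the diagnosed total equals
#' 139 390 persons. Baseline prevalences are the published 2024 prevalent
#' counts divided by the published cohort sizes, and the unpublished
#' incidence schedules are recovered by [calibrate_incidence()] so the
#' forward projection reproduces each published 2034 prevalent count to
#' within 0.5 persons. The calibration report is attached as
#' `attr(cfg, "calibration")`. The fixture is fully deterministic:
#' rebuilding it yields identical calibrated rates.
#'
#' @param update_rule Update rule used both for calibration and projection.
#' @param old_young_ratio Old-band incidence as a multiple of the young
#'   band in the calibration (default 1; the endpoint data cannot identify
#'   the two bands separately).
#' @return A validated [bia_config].
#' @examples
#' cfg <- spain_fixture()
#' attr(cfg, "calibration")
#' @export
spain_fixture <- function(update_rule = "at_risk", old_young_ratio = 1) {
  si <- spain_inputs
  population <- tibble::tibble(
    national_population = si$total_diagnosed /
      (si$hiv_prevalence * si$diagnosed_fraction),
    hiv_prevalence = si$hiv_prevalence,
    diagnosed_fraction = si$diagnosed_fraction,
    recent_fraction = si$recent_fraction,
    annual_mortality = si$annual_mortality
  )
  derived <- derive_population(population)
  cohorts <- tibble::tibble(
    cohort = cohort_levels,
    size_baseline = c(derived$recent, derived$longstanding),
    mean_age_baseline = unname(si$mean_ages[cohort_levels])
  )
  epi <- si$counts |>
    dplyr::mutate(
      baseline_prevalence = derive_baseline_prevalence(
        .data$count_2024, unname(si$printed_sizes[.data$cohort])
      )
    ) |>
    dplyr::left_join(cohorts, by = "cohort")
  calib <- epi |>
    dplyr::mutate(fit = purrr::pmap(
      list(.data$count_2034, .data$baseline_prevalence, .data$size_baseline,
           .data$mean_age_baseline),
      function(target, prev, size, age) {
        calibrate_incidence(
          target = target, baseline = prev * size, size = size,
          mean_age = age, mortality = si$annual_mortality,
          n_cycles = si$horizon_end - si$base_year,
          decay = si$annual_incidence_reduction,
          old_young_ratio = old_young_ratio,
          age_threshold = si$age_threshold, update_rule = update_rule
        )
      }
    )) |>
    tidyr::unnest("fit")
  econ <- tibble::tibble(
    discount_rate = si$discount_rate, base_year = si$base_year,
    horizon_start = si$base_year, horizon_end = si$horizon_end
  )
  cfg <- bia_config(
    population = population,
    cohorts = cohorts,
    epi = calib |>
      dplyr::mutate(age_threshold = si$age_threshold,
                    annual_incidence_reduction = si$annual_incidence_reduction) |>
      dplyr::select("comorbidity", "cohort", "baseline_prevalence",
                    "incidence_young", "incidence_old", "age_threshold",
                    "annual_incidence_reduction"),
    resource_use = si$resource_use,
    unit_costs = si$unit_costs,
    cpi = tibble::tibble(year = si$base_year, index = 100),
    econ = econ,
    scenarios = si$scenarios,
    update_rule = update_rule
  )
  attr(cfg, "calibration") <- calib |>
    dplyr::select("comorbidity", "cohort", "incidence_young", "incidence_old",
                  "achieved", "residual", "iterations", "converged")
  cfg
}
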