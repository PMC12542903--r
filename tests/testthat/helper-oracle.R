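# Independent per-cycle loop oracle: recomputes the prevalent-count
# trajectory one series at a time with scalar base-R arithmetic, sharing no
# code with the package's vectorized engine.
oracle_counts <- function(cfg, baseline_counts = NULL) {
  years <- cfg$econ$horizon_start:cfg$econ$horizon_end
  m <- cfg$population$annual_mortality
  rows <- list()
  for (ci in seq_len(nrow(cfg$epi))) {
    e <- as.list(cfg$epi[ci, ])
    coh <- as.list(cfg$cohorts[cfg$cohorts$cohort == e$cohort, ])
    P <- e$baseline_prevalence * coh$size_baseline
    if (!is.null(baseline_counts)) {
      hit <- baseline_counts$comorbidity == e$comorbidity &
        baseline_counts$cohort == e$cohort
      if (any(hit)) P <- baseline_counts$count[hit]
    }
    N <- coh$size_baseline
    for (k in seq_along(years)) {
      rows[[length(rows) + 1L]] <- data.frame(
        cohort = e$cohort, comorbidity = e$comorbidity, year = years[k],
        alive = N, prevalent = P
      )
      age <- coh$mean_age_baseline + (k - 1)
      band <- if (age >= e$age_threshold) e$incidence_old else e$incidence_young
      i <- band * (1 - e$annual_incidence_reduction)^(k - 1)
      P <- if (cfg$update_rule == "at_risk") {
        (P + i * (N - P)) * (1 - m)
      } else {
        min((P + i * N) * (1 - m), N * (1 - m))
      }
      N <- N * (1 - m)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$cohort, out$comorbidity, out$year), ]
}

# Small hand-buildable configuration: two cohorts, two comorbidities,
# flat CPI, parameters overridable per test.
tiny_config <- function(mortality = 0.02, discount = 0.03,
                        incidence_young = 0.05, incidence_old = 0.05,
                        prevalence = 0.1, decay = 0.01,
                        update_rule = "at_risk", horizon_end = 2034,
                        scenarios = NULL) {
  sizes <- c(1000, 2000)
  bia_config(
    population = tibble::tibble(
      national_population = sum(sizes) / (0.005 * 0.9),
      hiv_prevalence = 0.005, diagnosed_fraction = 0.9,
      recent_fraction = sizes[1] / sum(sizes), annual_mortality = mortality
    ),
    cohorts = tibble::tibble(cohort = c("recent", "longstanding"),
                             size_baseline = sizes,
                             mean_age_baseline = c(34, 48)),
    epi = tidyr::expand_grid(comorbidity = c("cardiovascular", "renal"),
                             cohort = c("recent", "longstanding")) |>
      dplyr::mutate(baseline_prevalence = prevalence,
                    incidence_young = incidence_young,
                    incidence_old = incidence_old,
                    age_threshold = 50,
                    annual_incidence_reduction = decay),
    resource_use = tidyr::expand_grid(
      comorbidity = c("cardiovascular", "renal"),
      resource = c("hospital_admissions", "diagnostic_tests", "ed_visits",
                   "outpatient_visits", "hiv_visits", "blood_tests")
    ) |>
      dplyr::mutate(quantity = 1),
    unit_costs = tibble::tibble(
      resource = c("hospital_admissions", "diagnostic_tests", "ed_visits",
                   "outpatient_visits", "hiv_visits", "blood_tests"),
      unit_cost = c(4000, 150, 220, 160, 160, 30), origin_year = 2024
    ),
    cpi = tibble::tibble(year = 2024, index = 100),
    econ = tibble::tibble(discount_rate = discount, base_year = 2024,
                          horizon_start = 2024, horizon_end = horizon_end),
    scenarios = scenarios,
    update_rule = update_rule
  )
}

expect_trajectories_equal <- function(engine, oracle, tol = 1e-9) {
  engine <- engine[order(engine$cohort, engine$comorbidity, engine$year), ]
  expect_equal(engine$prevalent, oracle$prevalent, tolerance = tol)
  expect_equal(engine$alive, oracle$alive, tolerance = tol)
}
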