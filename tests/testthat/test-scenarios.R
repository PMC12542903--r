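scenario_tbl <- function(delta_recent, delta_long = delta_recent,
                         comorbidity = "cardiovascular") {
  tibble::tibble(scenario = "test_regimen", source = "expert",
                 comorbidity = comorbidity,
                 cohort = c("recent", "longstanding"),
                 delta_pp = c(delta_recent, delta_long))
}

test_that("prevalence deltas shift only the baseline stock, capped at 1", {
  cfg <- tiny_config(scenarios = scenario_tbl(5, 10))
  shifted <- apply_prevalence_delta(cfg, "test_regimen")
  cv <- dplyr::filter(shifted$epi, comorbidity == "cardiovascular")
  expect_equal(cv$baseline_prevalence[cv$cohort == "recent"], 0.15)
  expect_equal(cv$baseline_prevalence[cv$cohort == "longstanding"], 0.20)
  # untouched comorbidity and all incidence schedules identical
  expect_equal(dplyr::filter(shifted$epi, comorbidity == "renal"),
               dplyr::filter(cfg$epi, comorbidity == "renal"))
  expect_equal(shifted$epi$incidence_young, cfg$epi$incidence_young)

  # capping at unity
  cfg99 <- tiny_config(prevalence = 0.99, scenarios = scenario_tbl(5))
  capped <- apply_prevalence_delta(cfg99, "test_regimen")
  expect_equal(
    dplyr::filter(capped$epi, comorbidity == "cardiovascular")$baseline_prevalence,
    c(1, 1)
  )

  expect_error(apply_prevalence_delta(cfg, "missing_regimen"), "available",
               class = "plwhcost_validation_error")
  expect_error(tiny_config(scenarios = scenario_tbl(-1)), "delta_pp",
               class = "plwhcost_validation_error")
})

test_that("a zero-delta scenario reproduces the current scenario bit-for-bit", {
  cfg <- tiny_config(scenarios = scenario_tbl(0, 0))
  cmp <- run_scenario_comparison(cfg, "test_regimen")
  expect_identical(cmp$current_py, cmp$scenario_py)
  expect_identical(cmp$current_cost, cmp$scenario_cost)
  expect_true(all(cmp$py_increase_pct == 0))
  expect_true(all(cmp$incremental_cost == 0))
  # the shifted configuration itself is numerically identical
  shifted <- apply_prevalence_delta(cfg, "test_regimen")
  expect_identical(as.data.frame(shifted$epi), as.data.frame(cfg$epi))
})

test_that("the Spanish darunavir scenario shifts the 2024 stock as printed", {
  cfg <- spain_fixture()
  shifted <- apply_prevalence_delta(cfg, "cardiovascular_darunavir")
  counts <- project_counts(shifted)
  cv24 <- dplyr::filter(counts, comorbidity == "cardiovascular", year == 2024)
  recent <- cv24$prevalent[cv24$cohort == "recent"]
  # 2650/55199 + 1.13 pp applied to the derived cohort size
  expect_equal(recent, (2650 / 55199 + 0.0113) * cfg$cohorts$size_baseline[1],
               tolerance = 1e-12)
  expect_equal(recent, 3271, tolerance = 0.005)
})

test_that("scenario PY and cost monotonicity and zero-discount equivalence", {
  small <- run_scenario_comparison(tiny_config(scenarios = scenario_tbl(1, 2)),
                                   "test_regimen")
  large <- run_scenario_comparison(tiny_config(scenarios = scenario_tbl(3, 6)),
                                   "test_regimen")
  expect_true(all(small$scenario_py >= small$current_py))
  expect_true(all(large$scenario_py >= small$scenario_py))
  expect_true(all(large$scenario_cost >= small$scenario_cost - 1e-9))

  # zero discounting with constant per-patient cost: the two percentage
  # bases coincide exactly
  cmp0 <- run_scenario_comparison(
    tiny_config(discount = 0, scenarios = scenario_tbl(2, 3)), "test_regimen"
  )
  expect_equal(cmp0$cost_increase_pct, cmp0$py_increase_pct)
  # with discounting they differ for the affected comorbidity
  cmp3 <- run_scenario_comparison(tiny_config(scenarios = scenario_tbl(2, 3)),
                                  "test_regimen")
  cv <- dplyr::filter(cmp3, comorbidity == "cardiovascular")
  expect_gt(abs(cv$cost_increase_pct - cv$py_increase_pct), 1e-6)
})

test_that("scenario-minus-current difference decays by (1-i)(1-m) per cycle", {
  cfg <- tiny_config(mortality = 0.03, incidence_young = 0.04,
                     incidence_old = 0.06, decay = 0.01,
                     scenarios = scenario_tbl(2, 4))
  shifted <- apply_prevalence_delta(cfg, "test_regimen")
  cur <- oracle_counts(cfg)
  alt <- oracle_counts(shifted)
  for (coh in c("recent", "longstanding")) {
    d <- alt$prevalent[alt$comorbidity == "cardiovascular" & alt$cohort == coh] -
      cur$prevalent[cur$comorbidity == "cardiovascular" & cur$cohort == coh]
    epi <- dplyr::filter(cfg$epi, comorbidity == "cardiovascular", cohort == coh)
    age0 <- cfg$cohorts$mean_age_baseline[cfg$cohorts$cohort == coh]
    i_t <- incidence_at(epi$incidence_young, epi$incidence_old,
                        epi$age_threshold, epi$annual_incidence_reduction,
                        mean_age = age0 + 0:9, years_since_base = 0:9)
    expected <- d[1] * cumprod(c(1, (1 - i_t) * (1 - 0.03)))
    expect_equal(d, expected, tolerance = 1e-9)
    # engine agrees with the loop oracle on both arms
    expect_trajectories_equal(project_counts(shifted), alt)
  }
})

test_that("sensitivity swaps rebuild selected cohorts and flag gaps", {
  cfg <- tiny_config()

  # identity swap: zero difference everywhere
  same <- cfg$epi |>
    dplyr::select(comorbidity, cohort, prevalence = baseline_prevalence)
  cmp_id <- run_sensitivity_swap(cfg, same)
  expect_true(all(cmp_id$incremental_cost == 0))
  expect_true(all(cmp_id$evaluated))

  # halving one cohort prevalence matches an independent two-run subtraction
  repl <- tibble::tibble(comorbidity = "cardiovascular", cohort = "recent",
                         prevalence = 0.05)
  cmp <- run_sensitivity_swap(cfg, repl)
  swapped_cfg <- cfg
  swapped_cfg$epi$baseline_prevalence[
    swapped_cfg$epi$comorbidity == "cardiovascular" &
      swapped_cfg$epi$cohort == "recent"] <- 0.05
  by_hand <- sum(run_model(swapped_cfg)$costs$cost_discounted[
    run_model(swapped_cfg)$costs$comorbidity == "cardiovascular"]) -
    sum(run_model(cfg)$costs$cost_discounted[
      run_model(cfg)$costs$comorbidity == "cardiovascular"])
  cv <- dplyr::filter(cmp, comorbidity == "cardiovascular")
  expect_equal(cv$incremental_cost, by_hand, tolerance = 1e-9)
  expect_lt(cv$incremental_cost, 0)

  # a replacement set omitting a comorbidity flags it as not evaluated
  expect_false(dplyr::filter(cmp, comorbidity == "renal")$evaluated)
  expect_equal(dplyr::filter(cmp, comorbidity == "renal")$incremental_cost, 0)

  expect_error(
    run_sensitivity_swap(cfg, dplyr::mutate(repl, prevalence = 1.2)),
    "replacement prevalence", class = "plwhcost_validation_error"
  )
  # only the selected cohort moves even if replacements name both
  both <- tibble::tibble(comorbidity = "cardiovascular",
                         cohort = c("recent", "longstanding"),
                         prevalence = c(0.05, 0.05))
  only_recent <- run_sensitivity_swap(cfg, both, cohorts = "recent")
  expect_equal(dplyr::filter(only_recent, comorbidity == "cardiovascular")$incremental_cost,
               cv$incremental_cost, tolerance = 1e-9)
})
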