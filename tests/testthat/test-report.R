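test_that("presentation layouts have the documented shape and rounding", {
  fit <- run_model(spain_fixture())
  t3 <- export_tables(fit, "table3")
  expect_equal(nrow(t3), 4)
  expect_named(t3, c("comorbidity", "count_first_recent", "count_last_recent",
                     "person_years_recent", "count_first_longstanding",
                     "count_last_longstanding", "person_years_longstanding",
                     "total_person_years"))
  # totals are rounded from the exact sum, so rounded parts may differ by 1
  expect_true(all(abs(t3$total_person_years -
                        (t3$person_years_recent + t3$person_years_longstanding)) <= 1))
  expect_true(all(vapply(t3[-1], function(x) all(x == floor(x)), logical(1))))
  # display rounding is half-up on the endpoint counts
  cv <- dplyr::filter(t3, comorbidity == "cardiovascular")
  expect_equal(cv$count_last_recent, 5166)
  expect_equal(cv$count_last_longstanding, 28389)

  f1 <- export_tables(fit, "figure1_series")
  expect_equal(nrow(f1), 4 * 11)
  expect_true(all(table(f1$comorbidity) == 11))
  # cumulative series are non-decreasing
  expect_true(all(unlist(tapply(f1$cum_discounted, f1$comorbidity, diff)) >= 0))

  t4 <- export_tables(fit, "table4")
  expect_equal(nrow(t4), 7) # one affected-comorbidity row per scenario
  expect_setequal(unique(t4$scenario), unique(fit$config$scenarios$scenario))

  f2 <- export_tables(fit, "figure2_series")
  expect_equal(nrow(f2), 7 * 11)
  expect_true(all(f2$incremental >= -1e-9))

  expect_error(export_tables(fit, "table5"))
  no_scen <- run_model(tiny_config())
  expect_error(export_tables(no_scen, "table4"), "no scenarios",
               class = "plwhcost_validation_error")
})

test_that("tidy export re-aggregates to the wide layout cell-for-cell", {
  fit <- run_model(spain_fixture())
  tidy_tbl <- export_tables(fit, "tidy")
  horizon <- c(2024, 2034)
  rebuilt <- tidy_tbl |>
    dplyr::summarise(
      count_first = prevalent[year == horizon[1]],
      count_last = prevalent[year == horizon[2]],
      person_years = sum(prevalent),
      .by = c("cohort", "comorbidity")
    ) |>
    tidyr::pivot_wider(names_from = cohort,
                       values_from = c(count_first, count_last, person_years)) |>
    dplyr::mutate(total_person_years = person_years_recent +
                    person_years_longstanding) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                function(x) floor(x + 0.5)))
  t3 <- export_tables(fit, "table3")
  expect_equal(as.data.frame(rebuilt[order(rebuilt$comorbidity), names(t3)]),
               as.data.frame(t3[order(t3$comorbidity), ]))
  # full-precision export feeds back into identical in-memory results
  path <- withr::local_tempfile(fileext = ".csv")
  export_tables(fit, "tidy", path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$cost_discounted, fit$costs$cost_discounted,
               tolerance = 1e-12)
})

test_that("model objects support tidy, glance, print, and autoplot", {
  fit <- run_model(tiny_config(scenarios = tibble::tibble(
    scenario = "s1", source = "expert", comorbidity = "renal",
    cohort = "recent", delta_pp = 2
  )))
  td <- tidy(fit)
  expect_true(all(c("cohort", "comorbidity", "year", "prevalent", "cost",
                    "cost_discounted", "cum_discounted") %in% names(td)))
  g <- glance(fit)
  expect_equal(g$total_person_years, sum(td$prevalent))
  expect_output(print(fit), "bia_model")
  expect_s3_class(autoplot(fit), "ggplot")

  cmp <- run_scenario_comparison(fit$config, "s1")
  expect_output(print(cmp), "bia_comparison")
  expect_s3_class(autoplot(cmp), "ggplot")
  expect_equal(glance(cmp)$total_incremental_cost, sum(cmp$incremental_cost))
})

test_that("the CLI runs end-to-end, deterministically, and fails loudly", {
  cfg_path <- system.file("extdata", "spain_base_case.yaml", package = "plwhcost")
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  status <- run_model_cli(c("--config", cfg_path, "--out", out1, "--quiet"))
  expect_identical(status, 0L)
  written <- list.files(out1)
  expect_true(all(c("population.csv", "costs_tidy.csv", "table3.csv",
                    "figure1_series.csv", "table4.csv", "figure2_series.csv",
                    "manifest.json") %in% written))
  expect_length(grep("^comparison_", written), 7)

  manifest <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_identical(manifest$package, "plwhcost")
  expect_identical(manifest$update_rule, "at_risk")
  expect_length(manifest$scenarios, 7)
  expect_identical(manifest$config_digest,
                   unname(unlist(tools::md5sum(cfg_path))))

  # identical config -> byte-identical data files (timestamp only in manifest)
  run_model_cli(c("--config", cfg_path, "--out", out2, "--quiet"))
  for (f in setdiff(written, "manifest.json")) {
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))), label = f)
  }

  # error paths: missing config and unknown scenario
  expect_identical(
    suppressMessages(run_model_cli(c("--config", tempfile("gone"), "--quiet"))),
    1L
  )
  expect_identical(
    suppressMessages(run_model_cli(c("--config", cfg_path, "--scenario",
                                     "warp_drive", "--quiet"))),
    1L
  )
  expect_identical(suppressMessages(run_model_cli(c("--quiet"))), 1L)
})

test_that("CLI overrides and synthetic mode are honoured", {
  out <- withr::local_tempdir()
  status <- run_model_cli(c("--seed", "3", "--scenario", "none",
                            "--update-rule", "whole_cohort",
                            "--discount", "0", "--out", out, "--quiet"))
  expect_identical(status, 0L)
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_identical(manifest$update_rule, "whole_cohort")
  expect_identical(manifest$seed, 3L)
  costs <- readr::read_csv(file.path(out, "costs_tidy.csv"),
                           show_col_types = FALSE)
  expect_equal(costs$cost, costs$cost_discounted) # discount overridden to 0
  expect_false(file.exists(file.path(out, "table4.csv")))
})
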