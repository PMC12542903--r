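round_half_up <- function(x) floor(x + 0.5)

summarise_cells <- function(costs, horizon) {
  costs |>
    dplyr::summarise(
      count_first = .data$prevalent[.data$year == horizon[1]],
      count_last = .data$prevalent[.data$year == horizon[2]],
      person_years = sum(.data$prevalent),
      .by = c("cohort", "comorbidity")
    )
}

wide_count_layout <- function(cells) {
  cells |>
    tidyr::pivot_wider(names_from = "cohort",
                       values_from = c("count_first", "count_last",
                                       "person_years")) |>
    dplyr::mutate(total_person_years = .data$person_years_recent +
                    .data$person_years_longstanding) |>
    dplyr::select("comorbidity",
                  "count_first_recent", "count_last_recent", "person_years_recent",
                  "count_first_longstanding", "count_last_longstanding",
                  "person_years_longstanding", "total_person_years") |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric), round_half_up))
}

#' Export model results in report layouts
#'
#' Produces the standard report tables for a fitted model: `"tidy"` (one
#' row per cohort, comorbidity, and year, at full precision), `"table3"`
#' (per-comorbidity prevalent counts in the first and last year plus
#' person-year totals per cohort and overall, display-rounded half-up to
#' whole persons), `"table4"` (the same layout for every configured
#' counterfactual scenario, one block row per scenario), `"figure1_series"`
#' (cumulative discounted cost per comorbidity and year, summed over
#' cohorts), and `"figure2_series"` (per scenario and year, current and
#' scenario cumulative discounted cost and their difference). Display
#' rounding never feeds back into computation: only the two presentation
#' layouts round, and the tidy export reproduces in-memory results exactly.
#'
#' @param model A `bia_model` from [run_model()] (its configuration supplies
#'   the scenarios for the `table4` and `figure2_series` layouts).
#' @param layout One of `"tidy"`, `"table3"`, `"table4"`,
#'   `"figure1_series"`, `"figure2_series"`.
#' @param path Optional CSV output path.
#' @return The layout tibble (invisibly when `path` is given).
#' @examples
#' export_tables(run_model(spain_fixture()), "table3")
#' @export
export_tables <- function(model, layout = c("tidy", "table3", "table4",
                                            "figure1_series", "figure2_series"),
                          path = NULL) {
  layout <- rlang::arg_match(layout)
  horizon <- c(model$config$econ$horizon_start, model$config$econ$horizon_end)
  out <- switch(
    layout,
    tidy = model$costs,
    table3 = wide_count_layout(summarise_cells(model$costs, horizon)),
    figure1_series = model$costs |>
      dplyr::summarise(cost_discounted = sum(.data$cost_discounted),
                       .by = c("comorbidity", "year")) |>
      dplyr::arrange(.data$comorbidity, .data$year) |>
      dplyr::mutate(cum_discounted = cumsum(.data$cost_discounted),
                    .by = "comorbidity"),
    table4 = {
      scen_names <- unique(model$config$scenarios$scenario)
      if (length(scen_names) == 0) {
        abort("configuration defines no scenarios for the table4 layout",
              class = "plwhcost_validation_error")
      }
      purrr::map(scen_names, function(s) {
        shifted <- apply_prevalence_delta(model$config, s)
        fit <- run_model(shifted)
        affected <- model$config$scenarios |>
          dplyr::filter(.data$scenario == s, .data$delta_pp > 0) |>
          dplyr::pull("comorbidity") |>
          unique()
        wide_count_layout(summarise_cells(fit$costs, horizon)) |>
          dplyr::filter(.data$comorbidity %in% affected) |>
          dplyr::mutate(scenario = s, .before = 1)
      }) |>
        purrr::list_rbind()
    },
    figure2_series = {
      scen_names <- unique(model$config$scenarios$scenario)
      if (length(scen_names) == 0) {
        abort("configuration defines no scenarios for the figure2_series layout",
              class = "plwhcost_validation_error")
      }
      current <- model$costs |>
        dplyr::summarise(current_discounted = sum(.data$cost_discounted),
                         .by = "year")
      purrr::map(scen_names, function(s) {
        fit <- run_model(apply_prevalence_delta(model$config, s))
        fit$costs |>
          dplyr::summarise(scenario_discounted = sum(.data$cost_discounted),
                           .by = "year") |>
          dplyr::left_join(current, by = "year") |>
          dplyr::arrange(.data$year) |>
          dplyr::mutate(
            scenario = s,
            incremental = .data$scenario_discounted - .data$current_discounted,
            cum_incremental = cumsum(.data$incremental)
          ) |>
          dplyr::select("scenario", "year", "current_discounted",
                        "scenario_discounted", "incremental", "cum_incremental")
      }) |>
        purrr::list_rbind()
    }
  )
  if (!is.null(path)) {
    readr::write_csv(out, path)
    return(invisible(out))
  }
  out
}

config_digest <- function(config, path = NULL) {
  if (!is.null(path) && file.exists(path)) {
    unname(tools::md5sum(path))
  } else {
    rlang::hash(lapply(unclass(config), function(x)
      if (is.data.frame(x)) as.data.frame(x) else x))
  }
}

cli_spec <- function() {
  list(
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "Path to a YAML model configuration"),
    optparse::make_option("--scenario", type = "character", default = "all",
                          help = "Scenario name, 'all', or 'none' [default %default]"),
    optparse::make_option("--update-rule", type = "character", default = NULL,
                          dest = "update_rule",
                          help = "Override update rule: at_risk or whole_cohort"),
    optparse::make_option("--discount", type = "double", default = NULL,
                          help = "Override annual discount rate (proportion)"),
    optparse::make_option("--out", type = "character", default = "plwhcost-output",
                          help = "Output directory [default %default]"),
    optparse::make_option("--seed", type = "integer", default = NULL,
                          help = "Generate a synthetic bundle with this seed instead of reading --config"),
    optparse::make_option("--quiet", action = "store_true", default = FALSE,
                          help = "Suppress progress messages")
  )
}

#' Command-line model runner
#'
#' Orchestrates load, projection, costing, scenario comparison, and export
#' for shell use: reads a YAML configuration (or generates a seeded
#' synthetic bundle with `--seed`), runs the model, writes tidy and
#' presentation CSVs plus per-scenario comparisons, and records a JSON run
#' manifest (config digest, package version, timestamp, selected scenarios,
#' update rule, file list). Data files contain no wall-clock content, so two
#' runs on identical configuration are byte-identical; the timestamp lives
#' only in the manifest. Invoked by `scripts/run_model.R`.
#'
#' @param args Character vector of command-line arguments (default: the
#'   process arguments).
#' @return Integer exit status, invisibly: 0 on success, 1 on any error
#'   (with the reason logged to stderr).
#' @export
run_model_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    parser <- optparse::OptionParser(
      option_list = cli_spec(),
      description = "Closed-cohort budget-impact model of comorbidity costs in PLWH"
    )
    opts <- optparse::parse_args(parser, args = args)
    log_info <- function(...) if (!opts$quiet) message(sprintf(...))

    if (is.null(opts$config) && is.null(opts$seed)) {
      abort("either --config or --seed is required", class = "plwhcost_io_error")
    }
    cfg <- if (!is.null(opts$config)) {
      log_info("loading configuration: %s", opts$config)
      load_model_config(opts$config)
    } else {
      log_info("generating synthetic bundle (seed %d)", opts$seed)
      generate_synthetic_params(opts$seed)
    }
    if (!is.null(opts$update_rule)) {
      cfg$update_rule <- opts$update_rule
      cfg <- validate_config(cfg)
    }
    if (!is.null(opts$discount)) {
      cfg$econ$discount_rate <- opts$discount
      cfg <- validate_config(cfg)
    }

    available <- unique(cfg$scenarios$scenario)
    scen_names <- if (identical(opts$scenario, "all")) available
      else if (identical(opts$scenario, "none")) character(0)
      else opts$scenario
    unknown <- setdiff(scen_names, available)
    if (length(unknown) > 0) {
      abort(sprintf("unknown scenario '%s'; available: %s",
                    paste(unknown, collapse = ", "),
                    paste(available, collapse = ", ")),
            class = "plwhcost_validation_error")
    }

    if (!dir.exists(opts$out)) dir.create(opts$out, recursive = TRUE)
    fit <- run_model(cfg)
    g <- glance(fit)
    log_info("projected %.0f comorbidity person-years, EUR %.1fM discounted",
             g$total_person_years, g$total_cost_discounted / 1e6)

    files <- c(
      population = file.path(opts$out, "population.csv"),
      costs_tidy = file.path(opts$out, "costs_tidy.csv"),
      table3 = file.path(opts$out, "table3.csv"),
      figure1_series = file.path(opts$out, "figure1_series.csv")
    )
    readr::write_csv(fit$population, files[["population"]])
    export_tables(fit, "tidy", files[["costs_tidy"]])
    export_tables(fit, "table3", files[["table3"]])
    export_tables(fit, "figure1_series", files[["figure1_series"]])

    if (length(scen_names) > 0) {
      for (s in scen_names) {
        cmp <- run_scenario_comparison(cfg, s)
        p <- file.path(opts$out, paste0("comparison_", s, ".csv"))
        readr::write_csv(tibble::as_tibble(cmp), p)
        files[paste0("comparison_", s)] <- p
        log_info("scenario %s: +EUR %.1fM incremental discounted cost",
                 s, sum(cmp$incremental_cost) / 1e6)
      }
      cfg_scen <- cfg
      cfg_scen$scenarios <- dplyr::filter(cfg$scenarios,
                                          .data$scenario %in% scen_names)
      fit_scen <- fit
      fit_scen$config <- cfg_scen
      files["table4"] <- file.path(opts$out, "table4.csv")
      files["figure2_series"] <- file.path(opts$out, "figure2_series.csv")
      export_tables(fit_scen, "table4", files[["table4"]])
      export_tables(fit_scen, "figure2_series", files[["figure2_series"]])
    }

    manifest <- list(
      package = "plwhcost",
      version = as.character(utils::packageVersion("plwhcost")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config_digest = config_digest(cfg, opts$config),
      config_path = opts$config,
      seed = opts$seed,
      update_rule = cfg$update_rule,
      scenarios = as.list(scen_names),
      outputs = as.list(unname(files))
    )
    manifest_path <- file.path(opts$out, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, null = "null")
    log_info("wrote %d files to %s", length(files) + 1L, opts$out)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
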