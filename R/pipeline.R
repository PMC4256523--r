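#' Summarise MMR and institutional-delivery changes
#'
#' State-level and per-district first-to-last-year percent changes in the
#' posterior-median MMR and percentage-point changes in institutional
#' delivery. Headline (state) MMR declines are rounded to the nearest
#' integer, district figures to one decimal.
#'
#' @param mmr_summary Tibble `district_id, year, median` (e.g. the output
#'   CSV of the estimation stage read back in).
#' @param exposure_panel Tibble with `district_id, year, inst_prop`.
#' @param live_births Optional `district_id, year, live_births` used to
#'   weight districts when aggregating MMR to the state; equal weights
#'   otherwise.
#' @return A list with `state` (one-row tibble) and `districts` (per-district
#'   tibble of MMR percent declines and institutional-delivery changes).
#' @export
summarize_changes <- function(mmr_summary, exposure_panel, live_births = NULL) {
  years <- range(intersect(mmr_summary$year, exposure_panel$year))
  first <- years[1]; last <- years[2]
  if (first == last) stop_config("need at least two common years")

  m <- mmr_summary[mmr_summary$year %in% c(first, last), ]
  if (!is.null(live_births)) {
    m <- dplyr::inner_join(m, live_births, by = c("district_id", "year"))
  } else {
    m$live_births <- 1
  }
  state <- m |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(mmr = sum(.data$median * .data$live_births) /
                       sum(.data$live_births), .groups = "drop")
  inst <- exposure_panel |>
    dplyr::filter(.data$year %in% c(first, last)) |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(inst_prop = mean(.data$inst_prop), .groups = "drop")

  state_tbl <- tibble::tibble(
    year_start = first, year_end = last,
    mmr_start = state$mmr[state$year == first],
    mmr_end = state$mmr[state$year == last],
    mmr_decline_pct = percent_change(state$mmr[state$year == first],
                                     state$mmr[state$year == last]),
    inst_start_pct = round(100 * inst$inst_prop[inst$year == first], 1),
    inst_end_pct = round(100 * inst$inst_prop[inst$year == last], 1)
  )

  districts <- mmr_summary |>
    dplyr::filter(.data$year %in% c(first, last)) |>
    dplyr::select("district_id", "year", "median") |>
    tidyr::pivot_wider(names_from = "year", values_from = "median",
                       names_prefix = "mmr_") |>
    dplyr::mutate(mmr_decline_pct = percent_change(
      .data[[paste0("mmr_", first)]], .data[[paste0("mmr_", last)]], digits = 1)) |>
    dplyr::left_join(
      exposure_panel |>
        dplyr::filter(.data$year %in% c(first, last)) |>
        dplyr::select("district_id", "year", "inst_prop") |>
        tidyr::pivot_wider(names_from = "year", values_from = "inst_prop",
                           names_prefix = "inst_") |>
        dplyr::mutate(inst_change_pp = round(
          100 * (.data[[paste0("inst_", last)]] - .data[[paste0("inst_", first)]]), 1)),
      by = "district_id")

  list(state = state_tbl, districts = districts)
}

collect_warnings <- function(expr) {
  warnings <- character(0)
  value <- withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(value = value, warnings = warnings)
}

pipeline_stage <- function(stage, log, expr) {
  res <- tryCatch(collect_warnings(expr), error = function(e) {
    stop_config(sprintf("pipeline stage '%s' failed: %s", stage,
                        conditionMessage(e)))
  })
  if (length(res$warnings)) {
    log$warnings <- c(log$warnings,
                      stats::setNames(res$warnings,
                                      rep(stage, length(res$warnings))))
  }
  res$value
}

#' Run the full pipeline on a synthetic scenario
#'
#' Executes simulate -> harmonize (correction factors + optional envelope
#' benchmarking of district count sources against a state-level count
#' source) -> estimate MMR -> optionally compare model specifications ->
#' assess impact for the requested exposures -> report. All intermediate
#' and final tables are CSV files under `out_dir`, and a JSON manifest
#' records the configuration hash, seeds, input digests, package version
#' and every warning raised by any stage. Reruns with identical
#' configuration and seeds reproduce all coefficient tables byte-for-byte.
#'
#' @param config A [scenario_config()].
#' @param out_dir Output directory.
#' @param stage1 A [stage1_spec()].
#' @param exposures Exposures to assess (`"jsy_prop"`, `"expenditure"`).
#' @param n_draws Posterior surfaces propagated into stage 2.
#' @param benchmark Benchmark district count sources to the state envelope
#'   before fitting?
#' @param compare_specs Optional list of [stage1_spec()]s to rank by CPO.
#' @return Invisibly, a list with the fitted objects and the manifest.
#' @export
run_pipeline <- function(config = scenario_config(), out_dir,
                         stage1 = stage1_spec(draws = 500, warmup = 300,
                                              seed = config$seed),
                         exposures = c("jsy_prop", "expenditure"),
                         n_draws = 200, benchmark = TRUE,
                         compare_specs = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- new.env()
  log$warnings <- character(0)

  scenario <- pipeline_stage("simulate", log, {
    sc <- simulate_scenario(config)
    write_scenario(sc, file.path(out_dir, "inputs"))
    sc
  })
  res <- run_pipeline_from_inputs(
    file.path(out_dir, "inputs"), out_dir, stage1 = stage1,
    exposures = exposures, n_draws = n_draws, benchmark = benchmark,
    compare_specs = compare_specs, stillbirth_rate = config$stillbirth_rate,
    seed = config$seed, config_hash = unname(config_hash(config)),
    extra_warnings = log$warnings)
  res$scenario <- scenario
  invisible(res)
}

#' Run the estimation and impact stages from an inputs directory
#'
#' Same as [run_pipeline()] but starting from CSV inputs already on disk
#' (`observations.csv`, `covariates.csv`, `program_panel.csv`,
#' `survey_benchmark.csv` in the [write_scenario()] schemas) — the entry
#' point for data that did not come from the simulator.
#'
#' @param inputs_dir Directory containing the input CSV files.
#' @param out_dir Output directory.
#' @inheritParams run_pipeline
#' @param stillbirth_rate Stillbirths per 1,000 births for the live-birth
#'   derivation.
#' @param seed Master seed for the draw-selection and impact stages.
#' @param config_hash,extra_warnings Internal, used by [run_pipeline()].
#' @return Invisibly, a list with the fitted objects and the manifest.
#' @export
run_pipeline_from_inputs <- function(inputs_dir, out_dir,
                                     stage1 = stage1_spec(draws = 500,
                                                          warmup = 300,
                                                          seed = seed),
                                     exposures = c("jsy_prop", "expenditure"),
                                     n_draws = 200, benchmark = TRUE,
                                     compare_specs = NULL,
                                     stillbirth_rate = 15, seed = 1L,
                                     config_hash = NA_character_,
                                     extra_warnings = character(0)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- new.env()
  log$warnings <- extra_warnings

  obs <- pipeline_stage("read", log,
                        read_observations(file.path(inputs_dir, "observations.csv")))
  covs <- pipeline_stage("read", log,
                         read_covariates(file.path(inputs_dir, "covariates.csv")))
  panel <- pipeline_stage("read", log,
                          read_program_panel(file.path(inputs_dir, "program_panel.csv")))
  survey <- pipeline_stage("read", log,
                           readr::read_csv(file.path(inputs_dir, "survey_benchmark.csv"),
                                           col_types = "cid", progress = FALSE))
  membership <- covs[, c("district_id", "division_id")]

  harmonized <- pipeline_stage("harmonize", log, {
    factors <- derive_correction_factors(panel, survey)
    readr::write_csv(factors, file.path(out_dir, "correction_factors.csv"))
    corrected <- apply_correction(panel, factors)
    exposure_panel <- build_exposure_panel(corrected)
    readr::write_csv(exposure_panel, file.path(out_dir, "exposure_panel.csv"))

    obs2 <- obs
    if (benchmark) {
      state_counts <- obs[obs$level == "state" & !is.na(obs$deaths), ]
      if (nrow(state_counts)) {
        envelope <- state_counts |>
          dplyr::group_by(year) |>
          dplyr::summarise(deaths = mean(.data$deaths), .groups = "drop") |>
          dplyr::mutate(unit_id = "state")
        state_map <- tibble::tibble(district_id = membership$district_id,
                                    unit_id = "state")
        for (s in unique(obs$source_id[obs$level == "district"])) {
          sel <- obs2$level == "district" & obs2$source_id == s & !is.na(obs2$deaths)
          if (!any(sel)) next
          adj <- benchmark_to_envelope(
            dplyr::rename(obs2[sel, c("unit_id", "year", "deaths")],
                          district_id = "unit_id"),
            envelope, state_map)
          obs2$deaths[sel] <- adj$deaths
        }
      }
    }
    list(exposure_panel = exposure_panel, observations = obs2)
  })

  lb <- panel |>
    dplyr::transmute(.data$district_id, .data$year,
                     live_births = derive_live_births(.data$total_deliveries,
                                                      stillbirth_rate))

  fit <- pipeline_stage("estimate-mmr", log,
                        fit_stage1(harmonized$observations, covs, lb,
                                   membership, stage1))
  posterior <- predict_mmr(fit)
  readr::write_csv(posterior, file.path(out_dir, "mmr_summary.csv"))

  ranking <- NULL
  if (!is.null(compare_specs)) {
    ranking <- pipeline_stage("evaluate-models", log,
                              compare_models(compare_specs,
                                             harmonized$observations, covs,
                                             lb, membership))
    readr::write_csv(ranking, file.path(out_dir, "model_ranking.csv"))
  }

  draws <- sample_mmr_draws(fit, n = n_draws,
                            seed = sub_seed(seed, "draws"))
  readr::write_csv(tibble::as_tibble(draws), file.path(out_dir, "mmr_draws.csv"))

  impacts <- list()
  for (exposure in exposures) {
    impacts[[exposure]] <- pipeline_stage(paste0("assess-impact-", exposure), log, {
      sp <- stage2_spec(exposure = exposure, n_draws = n_draws,
                        seed = sub_seed(seed, "stage2"))
      res <- fit_impact(draws, covs, harmonized$exposure_panel, sp)
      readr::write_csv(res$coefficients,
                       file.path(out_dir, sprintf("coefficients_%s.csv", exposure)))
      readr::write_csv(res$per_draw,
                       file.path(out_dir, sprintf("per_draw_%s.csv", exposure)))
      readr::write_csv(district_slope_report(res),
                       file.path(out_dir, sprintf("district_slopes_%s.csv", exposure)))
      res
    })
  }

  report <- pipeline_stage("report", log, report_from_dir(out_dir))

  manifest <- list(
    package_version = as.character(utils::packageVersion("jsyimpact")),
    created = format(Sys.time(), tz = "UTC"),
    seed = seed,
    stage1_seed = stage1$seed,
    config_hash = config_hash,
    input_digests = as.list(tools::md5sum(list.files(inputs_dir, full.names = TRUE))),
    n_draws = n_draws,
    converged = fit$converged,
    warnings = as.list(log$warnings)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(fit = fit, posterior = posterior,
                 impacts = impacts, ranking = ranking, report = report,
                 manifest = manifest, out_dir = out_dir))
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  tools::md5sum(f)
}

#' Rebuild the summary report from a pipeline output directory
#'
#' Reads `mmr_summary.csv` and `exposure_panel.csv` back from disk and
#' recomputes the state and district change summaries, writing
#' `report_state.csv` and `report_districts.csv`. Report numbers therefore
#' always reflect the written CSVs.
#'
#' @param out_dir A directory produced by [run_pipeline()].
#' @return The [summarize_changes()] list, invisibly.
#' @export
report_from_dir <- function(out_dir) {
  mmr_summary <- readr::read_csv(file.path(out_dir, "mmr_summary.csv"),
                                 col_types = "ciddd", progress = FALSE)
  exposure_panel <- readr::read_csv(file.path(out_dir, "exposure_panel.csv"),
                                    col_types = "ciddddd", progress = FALSE)
  report <- summarize_changes(mmr_summary, exposure_panel)
  readr::write_csv(report$state, file.path(out_dir, "report_state.csv"))
  readr::write_csv(report$districts, file.path(out_dir, "report_districts.csv"))
  invisible(report)
}
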