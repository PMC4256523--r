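# shared fixtures for the suite: everything is generated in code

# small scenario used by several stage-1 tests: 6 districts, 2 divisions
small_config <- function(seed = 1, ...) {
  scenario_config(n_districts = 6, n_divisions = 2, seed = seed, ...)
}

# a bulletin with no over-reporting, so panel-derived exposures equal truth
clean_bulletin <- list(factor_range = c(1, 1), factor_shape = c(1, 1),
                       benchmark_year = NULL)

lb_table <- function(truth) {
  dplyr::transmute(truth$mmr, district_id = .data$district_id,
                   year = .data$year, live_births = .data$live_births)
}

quiet_fit <- function(...) suppressWarnings(fit_stage1(...))

# one draw-propagated impact analysis on generator-made posterior surfaces
# with controlled spread; used by calibration / power / monotonicity checks
calibration_impact <- function(seed, program_effect, spread, n_draws = 50,
                               n_districts = 12, n_divisions = 3,
                               exposure = "jsy_prop") {
  cfg <- scenario_config(seed = seed, n_districts = n_districts,
                         n_divisions = n_divisions,
                         program_effect = program_effect,
                         bulletin = clean_bulletin)
  truth <- generate_truth(cfg)
  panel <- generate_program_panel(truth, cfg)$panel
  ep <- build_exposure_panel(panel)
  draws <- simulate_posterior_surfaces(truth, n = n_draws, spread = spread,
                                       seed = seed + 7)
  fit_impact(draws, truth$covariates, ep,
             stage2_spec(exposure = exposure, n_draws = n_draws, seed = seed))
}

coef_row <- function(result, term) {
  result$coefficients[result$coefficients$term == term, ]
}

# deterministic 3-district, 4-year design used by the OLS-limit checks
ols_fixture <- function() {
  districts <- c("d01", "d02", "d03")
  years <- 2005:2008
  grid <- tidyr::expand_grid(district_id = districts, year = years)
  covs <- tibble::tibble(district_id = districts,
                         division_id = "div1",
                         tfr = c(2.8, 3.2, 3.6), hdi = c(0.6, 0.5, 0.45),
                         urban = c(45, 28, 15), literacy = c(70, 55, 40))
  # deterministic wiggles keep the 6-column design full-rank
  ep <- grid |>
    dplyr::mutate(
      row = dplyr::row_number(),
      jsy_prop = 0.05 + 0.08 * (year - 2005) +
        0.03 * (match(district_id, districts) - 1) + 0.02 * sin(3 * row),
      njsy_prop = 0.15 + 0.01 * (year - 2005) -
        0.02 * (match(district_id, districts) - 1) + 0.015 * cos(2 * row),
      inst_prop = jsy_prop + njsy_prop,
      expenditure = 900 * jsy_prop + 10 * match(district_id, districts),
      anc3 = 35 + 3 * (year - 2005) + 2 * match(district_id, districts) +
        1.5 * sin(5 * row)) |>
    dplyr::select(-"row")
  surface <- grid |>
    dplyr::left_join(covs, by = "district_id") |>
    dplyr::left_join(ep, by = c("district_id", "year")) |>
    dplyr::mutate(log_mmr = 6.7 - 0.015 * urban - 0.005 * literacy -
                    0.3 * jsy_prop - 0.1 * njsy_prop - 0.002 * anc3 +
                    0.01 * sin(seq_len(dplyr::n()))) |>   # fixed 'noise'
    dplyr::select("district_id", "year", "log_mmr")
  list(surface = surface, covariates = covs, exposure_panel = ep)
}

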