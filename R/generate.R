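#' Generate the ground truth of a synthetic scenario
#'
#' Draws the latent state of the scenario: district covariates, district and
#' division intercepts and linear log-MMR trends, a smooth non-linear
#' perturbation (second-order random walk residualised against each
#' district's own linear trend), the true program-uptake curves, and the
#' implied true MMR and live-birth tables. Everything is deterministic given
#' `config$seed`; the truth uses its own seed substream so adding sources or
#' panel options downstream never changes these tables.
#'
#' @param config A [scenario_config()].
#' @return A `synthetic_truth` list with tibbles `mmr` (district, year, mmr,
#'   log_mmr, live_births, total_deliveries, deaths, jsy_prop, inst_prop),
#'   `covariates`, `membership` (district -> division), named `betas`
#'   (including the program effect), `source_biases`, and the per-district
#'   `alpha`, `zeta`, `xi` components.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  D <- config$n_districts
  V <- config$n_divisions
  years <- config$years
  Tn <- length(years)
  district_id <- sprintf("d%02d", seq_len(D))
  division_id <- sprintf("div%d", rep_len(seq_len(V), D))
  membership <- tibble::tibble(district_id = district_id, division_id = division_id)

  with_seed(sub_seed(config$seed, "truth"), {
    tfr <- pmax(0.8, stats::rnorm(D, 3.1, 0.4))
    hdi <- pmin(0.95, pmax(0.15, stats::rnorm(D, 0.55, 0.06)))
    urban <- pmin(85, pmax(5, 30 + 150 * (hdi - 0.55) + stats::rnorm(D, 0, 8)))
    literacy <- pmin(95, pmax(10, 55 + 80 * (hdi - 0.55) + stats::rnorm(D, 0, 7)))

    alpha_div <- stats::rnorm(V, 0, config$intercept_sd$division)
    alpha_d <- alpha_div[rep_len(seq_len(V), D)] +
      stats::rnorm(D, 0, config$intercept_sd$district)
    slope_component_sd <- config$trend$slope_sd / sqrt(2)
    zeta_div <- stats::rnorm(V, config$trend$slope_mean, slope_component_sd)
    zeta_d <- zeta_div[rep_len(seq_len(V), D)] +
      stats::rnorm(D, 0, slope_component_sd)

    xi <- matrix(0, D, Tn)
    if (config$trend$nonlinear_scale > 0 && Tn >= 3) {
      tt <- seq_len(Tn)
      for (d in seq_len(D)) {
        innov <- c(0, 0, stats::rnorm(Tn - 2, 0, config$trend$nonlinear_scale))
        raw <- cumsum(cumsum(innov))
        # keep xi purely non-linear: remove its own intercept + linear part
        xi[d, ] <- stats::residuals(stats::lm(raw ~ tt))
      }
    }

    uptake_offset <- stats::rnorm(D, 0, config$uptake$district_sd)
  })

  clamp_p <- function(p) pmin(1 - 1e-9, pmax(1e-9, p))
  logit_seq <- function(from, to) {
    seq(stats::qlogis(clamp_p(from)), stats::qlogis(clamp_p(to)), length.out = Tn)
  }
  inst_logit <- logit_seq(config$uptake$inst_start, config$uptake$inst_end)
  share_logit <- logit_seq(config$uptake$jsy_share_start, config$uptake$jsy_share_end)

  total_deliveries <- round(config$population_per_district *
                              config$crude_birth_rate / 1000)
  live_births <- derive_live_births(total_deliveries, config$stillbirth_rate)
  tc <- years - mean(years)

  grid <- tidyr::expand_grid(d = seq_len(D), t = seq_len(Tn))
  inst_prop <- stats::plogis(inst_logit[grid$t] + uptake_offset[grid$d])
  jsy_share <- stats::plogis(share_logit[grid$t] + uptake_offset[grid$d] / 2)
  jsy_prop <- inst_prop * jsy_share
  log_mmr <- config$baseline_log_mmr_mean +
    config$covariate_effects[["tfr"]] * (tfr[grid$d] - mean(tfr)) +
    config$covariate_effects[["hdi"]] * (hdi[grid$d] - mean(hdi)) +
    alpha_d[grid$d] + zeta_d[grid$d] * tc[grid$t] + xi[cbind(grid$d, grid$t)] +
    config$program_effect * jsy_prop

  mmr_tbl <- tibble::tibble(
    district_id = district_id[grid$d],
    year = years[grid$t],
    log_mmr = log_mmr,
    mmr = exp(log_mmr),
    total_deliveries = total_deliveries,
    live_births = live_births,
    deaths = exp(log_mmr) * live_births / 1e5,
    inst_prop = inst_prop,
    jsy_share = jsy_share,
    jsy_prop = jsy_prop
  )

  covariates <- tibble::tibble(
    district_id = district_id, tfr = tfr, hdi = hdi,
    urban = urban, literacy = literacy
  )

  structure(
    list(mmr = mmr_tbl,
         covariates = covariates,
         membership = membership,
         betas = c(baseline = config$baseline_log_mmr_mean,
                   tfr = unname(config$covariate_effects[["tfr"]]),
                   hdi = unname(config$covariate_effects[["hdi"]]),
                   program = config$program_effect),
         source_biases = stats::setNames(
           vapply(config$source_specs, `[[`, 0, "bias"),
           vapply(config$source_specs, `[[`, "", "source_id")),
         alpha = stats::setNames(alpha_d, district_id),
         zeta = stats::setNames(zeta_d, district_id),
         xi = xi,
         config = config),
    class = "synthetic_truth"
  )
}

# aggregate true deaths/live births to a source's reporting level
aggregate_truth <- function(truth, level) {
  tab <- dplyr::left_join(truth$mmr, truth$membership, by = "district_id")
  key <- switch(level,
    district = "district_id",
    division = "division_id",
    state = NULL
  )
  if (is.null(key)) {
    tab$unit_id <- "state"
  } else {
    tab$unit_id <- tab[[key]]
  }
  tab |>
    dplyr::group_by(.data$unit_id, .data$year) |>
    dplyr::summarise(expected_deaths = sum(.data$deaths),
                     live_births = sum(.data$live_births),
                     .groups = "drop")
}

#' Generate multi-source mortality observations
#'
#' For each configured source, aggregates the true expected deaths to the
#' source's geographic level, applies the source's multiplicative reporting
#' bias, draws reported deaths from a negative-binomial distribution with
#' the scenario's overdispersion, and drops unit-years independently with
#' probability `1 - coverage`. Sources flagged `reports_mmr_directly` report
#' the implied MMR instead of counts. Each source has its own seed
#' substream, so adding a source leaves the others' records unchanged.
#'
#' @param truth A `synthetic_truth` from [generate_truth()].
#' @param config The same [scenario_config()].
#' @return A tibble of observations with columns `unit_id`, `level`, `year`,
#'   `source_id`, `deaths`, `live_births`, `mmr` (counts and `mmr` mutually
#'   exclusive per row).
#' @export
generate_observations <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "synthetic_truth"))
  out <- purrr::imap(config$source_specs, function(src, i) {
    agg <- aggregate_truth(truth, src$level)
    with_seed(sub_seed(config$seed, "observations", i), {
      keep <- stats::runif(nrow(agg)) <= src$coverage
      mu <- src$bias * agg$expected_deaths
      drawn <- stats::rnbinom(nrow(agg), mu = mu,
                              size = src$dispersion %||% config$overdispersion)
      agg |>
        dplyr::mutate(
          level = src$level, source_id = src$source_id,
          deaths = drawn,
          mmr = .data$deaths / .data$live_births * 1e5
        ) |>
        dplyr::filter(keep)
    })
  })
  dplyr::bind_rows(out) |>
    dplyr::select("unit_id", "level", "year", "source_id",
                  "deaths", "live_births", "mmr") |>
    finalize_observation_columns(config)
}

source_reports_mmr <- function(config, source_id) {
  spec <- purrr::detect(config$source_specs, ~ .x$source_id == source_id)
  if (is.null(spec)) FALSE else spec$reports_mmr_directly
}

# enforce the XOR convention: direct-MMR sources carry mmr only, count
# sources carry deaths + live_births only
finalize_observation_columns <- function(obs, config) {
  direct <- vapply(obs$source_id, function(s) source_reports_mmr(config, s),
                   TRUE, USE.NAMES = FALSE)
  obs$deaths <- ifelse(direct, NA_real_, obs$deaths)
  obs$live_births <- ifelse(direct, NA_real_, obs$live_births)
  obs$mmr <- ifelse(direct, obs$mmr, NA_real_)
  obs
}

#' Generate the JSY program panel and a survey benchmark
#'
#' Emulates the Health-Bulletin-style district program panel: true
#' institutional-delivery proportions are inflated by a fixed per-district
#' over-reporting factor (the reciprocal of a survey/bulletin correction
#' factor drawn from a Beta distribution rescaled to the configured range;
#' defaults give mean 0.61), JSY-supported deliveries follow the uptake
#' curve within reported institutional deliveries, expenditure (in lakh) is
#' proportional to JSY deliveries with lognormal noise, and a survey
#' benchmark reports the *true* institutional proportion for the designated
#' benchmark year.
#'
#' @inheritParams generate_observations
#' @return A list with `panel` (one `ProgramRecord` row per district-year:
#'   deliveries, expenditure, anc3), `survey` (district, year, inst_prop),
#'   and `true_factors` (district-level survey/bulletin correction factors).
#' @export
generate_program_panel <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "synthetic_truth"))
  D <- config$n_districts
  districts <- truth$covariates$district_id
  with_seed(sub_seed(config$seed, "panel"), {
    rng <- config$bulletin$factor_range
    shp <- config$bulletin$factor_shape
    factors <- rng[1] + diff(rng) * stats::rbeta(D, shp[1], shp[2])
    anc3_offset <- stats::rnorm(D, 0, 6)
    expnoise <- stats::rnorm(nrow(truth$mmr), 0, config$expenditure$noise_sd)
  })
  names(factors) <- districts

  panel <- truth$mmr |>
    dplyr::mutate(
      factor = factors[.data$district_id],
      inst_prop_reported = pmin(0.97, .data$inst_prop / .data$factor),
      institutional_deliveries = round(.data$inst_prop_reported * .data$total_deliveries),
      jsy_deliveries = round(.data$jsy_share * .data$institutional_deliveries),
      home_deliveries = .data$total_deliveries - .data$institutional_deliveries,
      year_index = .data$year - min(.data$year),
      anc3 = pmin(100, pmax(0, 35 + 4 * .data$year_index + anc3_offset[match(.data$district_id, districts)])),
      expenditure = .data$jsy_deliveries * config$expenditure$per_delivery_lakh *
        config$expenditure$overhead * exp(expnoise)
    ) |>
    dplyr::transmute(
      district_id = .data$district_id, year = .data$year,
      jsy_deliveries = .data$jsy_deliveries,
      institutional_deliveries = .data$institutional_deliveries,
      home_deliveries = .data$home_deliveries,
      total_deliveries = .data$total_deliveries,
      expenditure = .data$expenditure,
      anc3 = .data$anc3
    )

  survey <- truth$mmr |>
    dplyr::filter(.data$year == config$bulletin$benchmark_year) |>
    dplyr::transmute(district_id = .data$district_id, year = .data$year,
                     inst_prop = .data$inst_prop)

  list(panel = panel, survey = survey, true_factors = factors)
}

#' Simulate a full scenario
#'
#' Convenience wrapper running [generate_truth()], [generate_observations()]
#' and [generate_program_panel()] for one configuration.
#'
#' @param config A [scenario_config()].
#' @return A `jsy_scenario` list: `truth`, `observations`, `covariates`,
#'   `membership`, `program_panel`, `survey_benchmark`, `true_factors`.
#' @export
simulate_scenario <- function(config = scenario_config()) {
  truth <- generate_truth(config)
  obs <- generate_observations(truth, config)
  prog <- generate_program_panel(truth, config)
  structure(
    list(truth = truth,
         observations = obs,
         covariates = truth$covariates,
         membership = truth$membership,
         program_panel = prog$panel,
         survey_benchmark = prog$survey,
         true_factors = prog$true_factors,
         config = config),
    class = "jsy_scenario"
  )
}

#' Simulate posterior-style MMR surfaces around a known truth
#'
#' Produces `n` complete (district, year) MMR surfaces by multiplying the
#' true surface with lognormal noise of a given log-scale spread. Used for
#' calibration studies of the draw-propagated impact regression where the
#' posterior spread must be controlled exactly, independent of any sampler.
#'
#' @param truth A `synthetic_truth`.
#' @param n Number of surfaces.
#' @param spread Log-scale standard deviation of the noise.
#' @param seed Integer seed.
#' @return A matrix with `n` rows and one column per district-year, column
#'   names `"<district_id>::<year>"`, on the MMR scale.
#' @export
simulate_posterior_surfaces <- function(truth, n = 50, spread = 0.1, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"), n >= 1)
  key <- paste(truth$mmr$district_id, truth$mmr$year, sep = "::")
  with_seed(seed, {
    noise <- matrix(stats::rnorm(n * nrow(truth$mmr), 0, spread), nrow = n)
  })
  out <- exp(sweep(noise, 2, truth$mmr$log_mmr, `+`))
  colnames(out) <- key
  out
}
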