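#' Describe one reporting source in a simulation scenario
#'
#' A source is an administrative or survey system that reports maternal
#' deaths (or direct MMR estimates) at some geographic level, with its own
#' multiplicative reporting bias and incomplete coverage — the structure of
#' Indian vital-statistics, health-bulletin and survey systems.
#'
#' @param source_id Character label, e.g. `"vital_stats"`.
#' @param level Geographic level the source reports at: `"district"`,
#'   `"division"` or `"state"`.
#' @param bias Multiplicative factor on the expected number of reported
#'   deaths relative to truth (`< 1` = under-reporting). Must be positive.
#' @param coverage Probability that a unit-year is observed at all, in
#'   (0, 1].
#' @param reports_mmr_directly If `TRUE` the source reports an MMR estimate
#'   (deaths per 100,000 live births) instead of death and live-birth counts,
#'   as national surveys do.
#' @param dispersion Optional source-specific negative-binomial size
#'   parameter overriding the scenario's; survey-class envelope sources are
#'   close to Poisson (large size) at their aggregate scale, administrative
#'   sources much noisier.
#'
#' @return A `source_spec` list.
#' @export
source_spec <- function(source_id, level = c("district", "division", "state"),
                        bias = 1, coverage = 1, reports_mmr_directly = FALSE,
                        dispersion = NULL) {
  level <- match.arg(level)
  if (!is.character(source_id) || length(source_id) != 1L || !nzchar(source_id)) {
    stop_config("source_id must be a non-empty string")
  }
  if (!is.numeric(bias) || bias <= 0) stop_config("source bias must be > 0")
  if (!is.numeric(coverage) || coverage <= 0 || coverage > 1) {
    stop_config("source coverage must be in (0, 1]")
  }
  if (!is.null(dispersion) && (!is.numeric(dispersion) || dispersion <= 0)) {
    stop_config("source dispersion must be > 0")
  }
  structure(
    list(source_id = source_id, level = level, bias = bias,
         coverage = coverage, reports_mmr_directly = isTRUE(reports_mmr_directly),
         dispersion = dispersion),
    class = "source_spec"
  )
}

default_sources <- function() {
  list(
    # district administrative vital statistics: undercounts maternal deaths
    source_spec("vital_stats", "district", bias = 0.85, coverage = 0.90),
    # health-department reports: stronger undercount, near-complete panel
    source_spec("health_dept", "district", bias = 0.70, coverage = 0.95),
    # survey-class state envelope, treated as unbiased gold standard;
    # near-Poisson at the state aggregate
    source_spec("srs", "state", bias = 1.0, coverage = 1.0, dispersion = 500)
  )
}

#' Configure a synthetic multi-source mortality scenario
#'
#' Defines the ground-truth generative model for a state made of districts
#' nested in divisions, observed by several biased sources over a span of
#' years, together with a district program panel (JSY-supported deliveries
#' and expenditure). Defaults emulate a scaled-down Madhya Pradesh
#' 2005–2010: state MMR near 371 falling ~12% over the period, institutional
#' delivery rising from about 24% to 56% of births, the JSY share of
#' institutional deliveries rising from 14% to 80%, and health-bulletin
#' delivery proportions over-reported so that survey/bulletin correction
#' factors average 0.61.
#'
#' On the log scale the true MMR of district d in year t is
#' `baseline + beta_tfr*(TFR_d - mean TFR) + beta_hdi*(HDI_d - mean HDI) +
#'  alpha_d + zeta_d*(t - midyear) + xi_{d,t} + program_effect * JSY_{d,t}`
#' where `alpha_d` and `zeta_d` are district intercepts/slopes drawn around
#' division means, `xi` is a smooth second-order random-walk perturbation
#' (residualised against each district's linear trend so it stays a purely
#' non-linear component), and `JSY_{d,t}` is the true proportion of all
#' deliveries that are JSY-supported institutional deliveries.
#'
#' @param n_districts,n_divisions Counts; districts are assigned to divisions
#'   round-robin. `n_districts >= n_divisions >= 1`.
#' @param years Inclusive integer vector of calendar years (span >= 3).
#' @param population_per_district Persons per district.
#' @param crude_birth_rate Births per 1,000 persons per year.
#' @param baseline_log_mmr_mean Log of deaths per 100,000 live births at the
#'   state level, mid-period, before the program term.
#' @param covariate_effects Named numeric, coefficients of centred TFR and
#'   HDI on log-MMR: `c(tfr = ..., hdi = ...)`.
#' @param trend List: `slope_mean`, `slope_sd` (district linear log-trend per
#'   year, drawn around division means with sd split evenly), and
#'   `nonlinear_scale` (innovation sd of the RW2 perturbation; 0 disables).
#' @param program_effect True coefficient of the JSY delivery proportion on
#'   log-MMR.
#' @param intercept_sd List with `district` and `division` sds of the
#'   log-MMR intercepts.
#' @param source_specs List of [source_spec()] objects.
#' @param overdispersion Negative-binomial size parameter of reported death
#'   counts (larger = closer to Poisson). Must be positive.
#' @param uptake List describing program growth: `inst_start`, `inst_end`
#'   (institutional share of deliveries in first/last year), `jsy_share_start`,
#'   `jsy_share_end` (JSY share of institutional deliveries), `district_sd`
#'   (logit-scale district heterogeneity of uptake).
#' @param bulletin List: `factor_range` (range of true survey/bulletin
#'   correction factors) and `factor_shape` (Beta(a, b) shape over that
#'   range; defaults give mean factor 0.61), `benchmark_year` (survey year).
#' @param expenditure List: `per_delivery_lakh` (JSY outlay per supported
#'   delivery, in lakh), `overhead` multiplier, `noise_sd` (lognormal sd).
#' @param stillbirth_rate Stillbirths per 1,000 total births, used when
#'   deriving live births from deliveries.
#' @param seed Master integer seed; per-purpose substreams are derived from
#'   it so that, e.g., adding a source never changes the truth tables.
#'
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(n_districts = 12,
                            n_divisions = 3,
                            years = 2005:2010,
                            population_per_district = 1.5e6,
                            crude_birth_rate = 26,
                            baseline_log_mmr_mean = log(350),
                            covariate_effects = c(tfr = 0.08, hdi = -1.2),
                            trend = list(slope_mean = -0.007, slope_sd = 0.012,
                                         nonlinear_scale = 0.01),
                            program_effect = -0.223,
                            intercept_sd = list(district = 0.12, division = 0.08),
                            source_specs = default_sources(),
                            overdispersion = 30,
                            uptake = list(inst_start = 0.239, inst_end = 0.559,
                                          jsy_share_start = 0.14, jsy_share_end = 0.80,
                                          district_sd = 0.25),
                            bulletin = list(factor_range = c(0.34, 0.97),
                                            factor_shape = c(3, 4),
                                            benchmark_year = NULL),
                            expenditure = list(per_delivery_lakh = 0.014,
                                               overhead = 1.3, noise_sd = 0.05),
                            stillbirth_rate = 15,
                            seed = 1L) {
  years <- sort(as.integer(years))
  if (n_districts < 1 || n_divisions < 1 || n_districts < n_divisions) {
    stop_config("need n_districts >= n_divisions >= 1")
  }
  if (length(years) < 3) stop_config("years must span at least 3 years")
  if (!all(diff(years) == 1L)) stop_config("years must be consecutive")
  if (population_per_district <= 0) stop_config("population must be positive")
  if (crude_birth_rate <= 0) stop_config("crude_birth_rate must be positive")
  if (overdispersion <= 0) stop_config("overdispersion must be positive")
  if (!all(c("tfr", "hdi") %in% names(covariate_effects))) {
    stop_config("covariate_effects needs named entries 'tfr' and 'hdi'")
  }
  if (!length(source_specs) || !all(vapply(source_specs, inherits, TRUE, "source_spec"))) {
    stop_config("source_specs must be a non-empty list of source_spec objects")
  }
  ids <- vapply(source_specs, `[[`, "", "source_id")
  if (anyDuplicated(ids)) stop_config("duplicate source_id in source_specs")
  if (is.null(bulletin$benchmark_year)) {
    bulletin$benchmark_year <- years[max(1L, length(years) - 3L)]
  }
  if (!bulletin$benchmark_year %in% years) {
    stop_config("bulletin benchmark_year must be one of the scenario years")
  }
  if (stillbirth_rate < 0 || stillbirth_rate >= 1000) {
    stop_config("stillbirth_rate must be in [0, 1000)")
  }
  structure(
    list(n_districts = as.integer(n_districts),
         n_divisions = as.integer(n_divisions),
         years = years,
         population_per_district = population_per_district,
         crude_birth_rate = crude_birth_rate,
         baseline_log_mmr_mean = baseline_log_mmr_mean,
         covariate_effects = covariate_effects,
         trend = trend,
         program_effect = program_effect,
         intercept_sd = intercept_sd,
         source_specs = source_specs,
         overdispersion = overdispersion,
         uptake = uptake,
         bulletin = bulletin,
         expenditure = expenditure,
         stillbirth_rate = stillbirth_rate,
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' Read a scenario configuration from a YAML or JSON file
#'
#' The file holds the arguments of [scenario_config()] by name; sources are
#' given under `source_specs` as a list of mappings with the fields of
#' [source_spec()]. Omitted fields keep their defaults.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file path.
#' @return A validated `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$source_specs)) {
    raw$source_specs <- lapply(raw$source_specs, function(sp) {
      do.call(source_spec, sp)
    })
  }
  if (!is.null(raw$covariate_effects)) {
    raw$covariate_effects <- unlist(raw$covariate_effects)
  }
  unknown <- setdiff(names(raw), names(formals(scenario_config)))
  if (length(unknown)) {
    stop_config("unknown scenario fields: ", paste(unknown, collapse = ", "))
  }
  do.call(scenario_config, raw)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  %d districts in %d divisions, years %d-%d\n",
              x$n_districts, x$n_divisions, min(x$years), max(x$years)))
  cat(sprintf("  baseline MMR %.0f, program effect %.3f, NB size %.1f\n",
              exp(x$baseline_log_mmr_mean), x$program_effect, x$overdispersion))
  cat(sprintf("  sources: %s\n",
              paste(vapply(x$source_specs, function(s)
                sprintf("%s(%s, bias %.2f)", s$source_id, s$level, s$bias), ""),
                collapse = ", ")))
  invisible(x)
}
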