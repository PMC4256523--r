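#' Benchmark district death counts to a higher-level envelope
#'
#' Proportional raking: within each (envelope unit, year), district counts
#' are scaled by a common factor so that their sum equals the envelope
#' count, which is treated as the more reliable total. When the district sum
#' is zero but the envelope is positive, the envelope is split equally among
#' member districts (a deterministic fallback) and a warning is raised.
#'
#' @param district_deaths Tibble with columns `district_id`, `year`,
#'   `deaths`.
#' @param envelope Tibble with columns `unit_id`, `year`, `deaths` holding
#'   the trusted higher-level totals.
#' @param membership Tibble mapping `district_id` to `unit_id`; every
#'   district must map to exactly one envelope unit.
#' @return The input district table with `deaths` replaced by the adjusted
#'   values; after adjustment district sums equal the envelope exactly for
#'   every (unit, year) present in the envelope.
#' @export
benchmark_to_envelope <- function(district_deaths, envelope, membership) {
  need <- setdiff(c("district_id", "year", "deaths"), names(district_deaths))
  if (length(need)) stop_config("district_deaths missing columns: ",
                                paste(need, collapse = ", "))
  if (anyDuplicated(membership$district_id)) {
    stop_config("membership maps a district to more than one envelope unit")
  }
  unmapped <- setdiff(unique(district_deaths$district_id), membership$district_id)
  if (length(unmapped)) {
    stop_config("districts missing from membership: ",
                paste(unmapped, collapse = ", "))
  }
  df <- district_deaths |>
    dplyr::left_join(membership[, c("district_id", "unit_id")], by = "district_id") |>
    dplyr::left_join(dplyr::rename(envelope, envelope_deaths = "deaths"),
                     by = c("unit_id", "year"))
  zero_groups <- df |>
    dplyr::group_by(.data$unit_id, .data$year) |>
    dplyr::summarise(sum_d = sum(.data$deaths),
                     env = .data$envelope_deaths[1], .groups = "drop") |>
    dplyr::filter(!is.na(.data$env) & .data$sum_d == 0 & .data$env > 0)
  if (nrow(zero_groups)) {
    warning(sprintf(
      "equal-split fallback applied to %d zero-sum envelope group(s)",
      nrow(zero_groups)), call. = FALSE)
  }
  out <- df |>
    dplyr::group_by(.data$unit_id, .data$year) |>
    dplyr::mutate(deaths = dplyr::case_when(
      is.na(.data$envelope_deaths) ~ .data$deaths,
      sum(.data$deaths) > 0 ~ .data$deaths * .data$envelope_deaths[1] / sum(.data$deaths),
      TRUE ~ .data$envelope_deaths[1] / dplyr::n()
    )) |>
    dplyr::ungroup()
  out[, names(district_deaths)]
}

#' Derive a district's survey/bulletin correction factor
#'
#' The over-reporting of institutional deliveries in administrative bulletin
#' data is corrected by the ratio of the survey-reported to the
#' bulletin-reported institutional-delivery proportion in a benchmark year;
#' the bias is assumed constant across years within a district.
#'
#' @param bulletin_prop Bulletin institutional-delivery proportion in the
#'   benchmark year, in (0, 1].
#' @param survey_prop Survey proportion for the same district-year, in
#'   (0, 1].
#' @param district_id District label.
#' @param benchmark_year Survey year.
#' @return One-row tibble: `district_id`, `factor`, `benchmark_year`,
#'   `above_one` flag. Factors above 1 (survey exceeding bulletin) are
#'   allowed but flagged with a warning.
#' @export
derive_correction_factor <- function(bulletin_prop, survey_prop,
                                     district_id, benchmark_year) {
  if (any(bulletin_prop <= 0)) stop_config("bulletin_prop must be > 0")
  if (any(bulletin_prop > 1) || any(survey_prop <= 0) || any(survey_prop > 1)) {
    stop_config("proportions must lie in (0, 1]")
  }
  factor <- survey_prop / bulletin_prop
  above <- factor > 1
  if (any(above)) {
    warning(sprintf(
      "correction factor > 1 for district(s): %s (survey exceeds bulletin)",
      paste(district_id[above], collapse = ", ")), call. = FALSE)
  }
  tibble::tibble(district_id = district_id, factor = factor,
                 benchmark_year = as.integer(benchmark_year),
                 above_one = above)
}

#' Derive correction factors for all districts of a panel
#'
#' Convenience wrapper over [derive_correction_factor()]: computes each
#' district's bulletin institutional proportion in the survey's benchmark
#' year and divides the survey proportion by it.
#'
#' @param panel Program panel tibble (see [read_program_panel()]).
#' @param survey Survey benchmark tibble: `district_id`, `year`,
#'   `inst_prop`.
#' @return Correction-factor tibble, one row per district.
#' @export
derive_correction_factors <- function(panel, survey) {
  benchmark_year <- unique(survey$year)
  if (length(benchmark_year) != 1L) {
    stop_config("survey benchmark must cover exactly one year")
  }
  bench <- panel |>
    dplyr::filter(.data$year == benchmark_year) |>
    dplyr::mutate(bulletin_prop = .data$institutional_deliveries / .data$total_deliveries) |>
    dplyr::inner_join(survey[, c("district_id", "inst_prop")], by = "district_id")
  if (nrow(bench) == 0) stop_config("no districts shared between panel and survey")
  derive_correction_factor(bench$bulletin_prop, bench$inst_prop,
                           bench$district_id, benchmark_year)
}

#' Apply correction factors to a program panel
#'
#' Multiplies each district's institutional-delivery proportion (and,
#' proportionally, its JSY-supported deliveries) by the district's single
#' correction factor in every year — the relative bias is assumed constant
#' over time. Home deliveries absorb the difference so total deliveries are
#' unchanged. Corrected proportions above 1 are clipped to 1 with a
#' warning.
#'
#' @param panel Program panel tibble.
#' @param factors Correction-factor tibble from
#'   [derive_correction_factors()]; every district in the panel must have a
#'   factor.
#' @return The corrected panel (same columns, rescaled counts).
#' @export
apply_correction <- function(panel, factors) {
  missing_d <- setdiff(unique(panel$district_id), factors$district_id)
  if (length(missing_d)) {
    stop_config("no correction factor for district(s): ",
                paste(missing_d, collapse = ", "))
  }
  out <- panel |>
    dplyr::left_join(factors[, c("district_id", "factor")], by = "district_id") |>
    dplyr::mutate(
      inst_prop = .data$institutional_deliveries / .data$total_deliveries,
      corrected_prop = .data$inst_prop * .data$factor
    )
  if (any(out$corrected_prop > 1)) {
    warning(sprintf("corrected institutional proportion > 1 clipped for %d district-year(s)",
                    sum(out$corrected_prop > 1)), call. = FALSE)
    out$corrected_prop <- pmin(1, out$corrected_prop)
  }
  out |>
    dplyr::mutate(
      jsy_share = ifelse(.data$institutional_deliveries > 0,
                         .data$jsy_deliveries / .data$institutional_deliveries, 0),
      institutional_deliveries = .data$corrected_prop * .data$total_deliveries,
      jsy_deliveries = .data$jsy_share * .data$institutional_deliveries,
      home_deliveries = .data$total_deliveries - .data$institutional_deliveries
    ) |>
    dplyr::select(dplyr::all_of(names(panel)))
}

#' Build the exposure panel for the impact regression
#'
#' Derives the JSY and non-JSY institutional-delivery proportions of all
#' deliveries: `jsy_prop = jsy_deliveries / total_deliveries` and
#' `njsy_prop = (institutional_deliveries - jsy_deliveries) /
#' total_deliveries`, carrying expenditure and ANC3 through.
#'
#' @param panel A (corrected) program panel tibble with positive
#'   `total_deliveries`.
#' @return Tibble: `district_id`, `year`, `jsy_prop`, `njsy_prop`,
#'   `inst_prop`, `expenditure`, `anc3`.
#' @export
build_exposure_panel <- function(panel) {
  if (any(panel$total_deliveries <= 0)) {
    stop_config("total_deliveries must be positive")
  }
  bad <- panel$jsy_deliveries > panel$institutional_deliveries + 1e-9
  if (any(bad)) {
    off <- panel[bad, c("district_id", "year")]
    stop_config("jsy_deliveries exceed institutional_deliveries for: ",
                paste(sprintf("%s/%d", off$district_id, off$year), collapse = ", "))
  }
  panel |>
    dplyr::transmute(
      district_id = .data$district_id, year = .data$year,
      jsy_prop = .data$jsy_deliveries / .data$total_deliveries,
      njsy_prop = (.data$institutional_deliveries - .data$jsy_deliveries) /
        .data$total_deliveries,
      inst_prop = .data$institutional_deliveries / .data$total_deliveries,
      expenditure = .data$expenditure,
      anc3 = .data$anc3
    )
}
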