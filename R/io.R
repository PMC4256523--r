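#' Derive live births from total deliveries
#'
#' Live births are approximated by removing stillbirths from total
#' deliveries, with the stillbirth rate expressed per 1,000 total births
#' (deliveries and total births are treated as equal; multiple births are
#' ignored).
#'
#' @param total_deliveries Non-negative delivery count(s).
#' @param stillbirth_rate Stillbirths per 1,000 total births, below 1,000.
#' @return Integer live-birth count(s), rounded to the nearest integer.
#' @examples
#' derive_live_births(10000, 20) # 9800
#' @export
derive_live_births <- function(total_deliveries, stillbirth_rate) {
  if (any(total_deliveries < 0)) stop_config("total_deliveries must be >= 0")
  if (any(stillbirth_rate < 0) || any(stillbirth_rate >= 1000)) {
    stop_config("stillbirth_rate must be in [0, 1000)")
  }
  round(total_deliveries * (1 - stillbirth_rate / 1000))
}

#' Compute the maternal mortality ratio
#'
#' @param deaths Maternal death count(s).
#' @param live_births Live-birth count(s); must be positive.
#' @return Deaths per 100,000 live births.
#' @examples
#' compute_mmr(100, 50000) # 200
#' @export
compute_mmr <- function(deaths, live_births) {
  if (any(live_births <= 0)) {
    stop_config("live_births must be positive; flag and fix zero-denominator records")
  }
  deaths / live_births * 100000
}

observation_columns <- c("unit_id", "level", "year", "source_id",
                         "deaths", "live_births", "mmr")

validate_observations <- function(df, year_range = NULL) {
  has_counts <- !is.na(df$deaths) & !is.na(df$live_births)
  has_partial <- xor(is.na(df$deaths), is.na(df$live_births))
  has_mmr <- !is.na(df$mmr)
  bad <- (has_counts & has_mmr) | (has_partial) | (!has_counts & !has_mmr)
  bad <- bad |
    (!df$level %in% c("district", "division", "state")) |
    (!is.na(df$deaths) & df$deaths < 0) |
    (!is.na(df$live_births) & df$live_births <= 0) |
    (!is.na(df$mmr) & df$mmr < 0)
  if (!is.null(year_range)) {
    bad <- bad | df$year < min(year_range) | df$year > max(year_range)
  }
  bad
}

#' Read mortality observations from CSV
#'
#' Expects a header with columns `unit_id, level, year, source_id, deaths,
#' live_births, mmr`; empty fields encode missing values. Each row must
#' carry either both counts (`deaths`, `live_births`) or a direct `mmr`,
#' never both and never a lone count. Rows violating the invariants are
#' quarantined — returned in a `rejects` attribute (with their line numbers
#' and reported via warning), never silently dropped.
#'
#' @param path CSV file path.
#' @param year_range Optional inclusive year range for validation.
#' @return A tibble of valid observations; attribute `rejects` holds the
#'   offending rows with a `line` column.
#' @export
read_observations <- function(path, year_range = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(
    unit_id = readr::col_character(),
    level = readr::col_character(),
    year = readr::col_integer(),
    source_id = readr::col_character(),
    deaths = readr::col_double(),
    live_births = readr::col_double(),
    mmr = readr::col_double()
  ), progress = FALSE)
  missing_cols <- setdiff(observation_columns, names(df))
  if (length(missing_cols)) {
    stop_config("observations file missing required columns: ",
                paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) {
    warning("observations file has a valid header but no rows", call. = FALSE)
    out <- tibble::as_tibble(df)
    attr(out, "rejects") <- df
    return(out)
  }
  bad <- validate_observations(df, year_range)
  rejects <- df[bad, , drop = FALSE]
  rejects$line <- which(bad) + 1L  # header is line 1
  if (nrow(rejects)) {
    warning(sprintf(
      "%d observation row(s) rejected (invariant violations) at line(s): %s",
      nrow(rejects), paste(rejects$line, collapse = ", ")), call. = FALSE)
  }
  out <- tibble::as_tibble(df[!bad, , drop = FALSE])
  attr(out, "rejects") <- rejects
  out
}

#' Write mortality observations to CSV
#'
#' @param obs Observation tibble (see [read_observations()] for the schema).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  readr::write_csv(obs[, observation_columns], path, na = "")
  invisible(path)
}

#' Read district covariates from CSV
#'
#' Columns: `district_id, division_id, tfr, hdi, urban, literacy` (urban and
#' literacy as percentages 0-100, hdi on the unit interval, tfr in children per woman).
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_covariates <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    district_id = readr::col_character(),
    division_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  need <- c("district_id", "tfr", "hdi", "urban", "literacy")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_config("covariates file missing required columns: ",
                paste(missing_cols, collapse = ", "))
  }
  ok <- df$tfr > 0 & df$hdi >= 0 & df$hdi <= 1 &
    df$urban >= 0 & df$urban <= 100 & df$literacy >= 0 & df$literacy <= 100
  if (any(!ok)) {
    stop_config("covariate rows out of range at line(s): ",
                paste(which(!ok) + 1L, collapse = ", "))
  }
  tibble::as_tibble(df)
}

#' Read the district-year program panel from CSV
#'
#' Columns: `district_id, year, jsy_deliveries, institutional_deliveries,
#' home_deliveries, total_deliveries, expenditure, anc3` (expenditure in
#' lakh; anc3 as a percentage 0–100). Enforces
#' `jsy <= institutional <= total` and `total = institutional + home`.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_program_panel <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    district_id = readr::col_character(),
    year = readr::col_integer(),
    .default = readr::col_double()
  ), progress = FALSE)
  need <- c("district_id", "year", "jsy_deliveries", "institutional_deliveries",
            "home_deliveries", "total_deliveries", "expenditure", "anc3")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_config("program panel missing required columns: ",
                paste(missing_cols, collapse = ", "))
  }
  bad <- df$jsy_deliveries > df$institutional_deliveries |
    df$institutional_deliveries > df$total_deliveries |
    abs(df$institutional_deliveries + df$home_deliveries - df$total_deliveries) > 0.5 |
    df$anc3 < 0 | df$anc3 > 100
  if (any(bad)) {
    stop_config("program panel invariant violations at line(s): ",
                paste(which(bad) + 1L, collapse = ", "))
  }
  tibble::as_tibble(df)
}

#' Write a scenario's inputs to a directory of CSV files
#'
#' Emits `observations.csv`, `covariates.csv` (with division membership),
#' `program_panel.csv` and `survey_benchmark.csv` in the schemas consumed by
#' the read functions, plus `truth_mmr.csv` with the generator's ground
#' truth for later validation.
#'
#' @param scenario A `jsy_scenario` from [simulate_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "jsy_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_observations(scenario$observations, file.path(dir, "observations.csv"))
  covs <- dplyr::left_join(scenario$covariates, scenario$membership,
                           by = "district_id")
  readr::write_csv(covs, file.path(dir, "covariates.csv"), na = "")
  readr::write_csv(scenario$program_panel, file.path(dir, "program_panel.csv"), na = "")
  readr::write_csv(scenario$survey_benchmark,
                   file.path(dir, "survey_benchmark.csv"), na = "")
  readr::write_csv(
    scenario$truth$mmr[, c("district_id", "year", "mmr", "live_births")],
    file.path(dir, "truth_mmr.csv"), na = "")
  invisible(dir)
}
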