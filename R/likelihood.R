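#' Negative-binomial log-likelihood in mean–dispersion form
#'
#' Log probability mass of observing `deaths` maternal deaths when the
#' expected count is `expected_deaths` and counts are negative-binomially
#' distributed with size (dispersion) parameter `dispersion`:
#' `Var = mu + mu^2 / dispersion`. As `dispersion -> Inf` the mass
#' approaches the Poisson. The expected count for a district-year is
#' `MMR * live_births / 100000`.
#'
#' The mass is coded directly from the Gamma-function form
#' `log Gamma(y + r) - log Gamma(r) - log y! + r log(r/(r+mu)) +
#'  y log(mu/(r+mu))` rather than delegated, so it can serve as the
#' likelihood kernel for the sampler-independent CPO computations.
#'
#' @param deaths Non-negative integer count(s).
#' @param expected_deaths Positive expected count(s) (`mu`).
#' @param dispersion Positive size parameter (`r`).
#' @return Log probability mass (vectorised).
#' @export
nb_log_likelihood <- function(deaths, expected_deaths, dispersion) {
  if (any(deaths < 0) || any(abs(deaths - round(deaths)) > 1e-8)) {
    stop_config("deaths must be non-negative integers")
  }
  if (any(expected_deaths <= 0)) stop_config("expected_deaths must be positive")
  if (any(dispersion <= 0)) stop_config("dispersion must be positive")
  y <- round(deaths)
  r <- dispersion
  mu <- expected_deaths
  lgamma(y + r) - lgamma(r) - lfactorial(y) +
    r * (log(r) - log(r + mu)) + y * (log(mu) - log(r + mu))
}
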