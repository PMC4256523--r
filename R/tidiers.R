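#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the structural parameters of a stage-1 fit
#'
#' Posterior means, standard deviations and central 95% intervals of every
#' monitored structural parameter (intercept, covariate effects, district
#' intercepts/slopes, source effects, dispersion, hierarchical sds) — the
#' latent log-MMR surface is excluded; use [predict_mmr()] for that.
#'
#' @param x A `stage1_fit`.
#' @param ... Unused.
#' @return A tibble: `term, estimate, std.error, conf.low, conf.high`.
#' @export
tidy.stage1_fit <- function(x, ...) {
  keep <- !grepl("^log_mmr\\[", colnames(x$draws))
  d <- x$draws[, keep, drop = FALSE]
  tibble::tibble(
    term = colnames(d),
    estimate = colMeans(d),
    std.error = apply(d, 2, stats::sd),
    conf.low = apply(d, 2, stats::quantile, 0.025, names = FALSE),
    conf.high = apply(d, 2, stats::quantile, 0.975, names = FALSE)
  )
}

#' One-row summary of a stage-1 fit
#'
#' @param x A `stage1_fit`.
#' @param ... Unused.
#' @return A tibble with dimensions, draw count, worst R-hat and the
#'   convergence flag.
#' @export
glance.stage1_fit <- function(x, ...) {
  tibble::tibble(
    n_districts = length(x$districts),
    n_years = length(x$years),
    n_sources = length(x$sources),
    n_draws = nrow(x$draws),
    max_rhat = if (nrow(x$diagnostics)) max(x$diagnostics$rhat) else NA_real_,
    converged = x$converged
  )
}

#' Tidy the pooled coefficients of an impact analysis
#'
#' @param x An `impact_result`.
#' @param ... Unused.
#' @return A tibble: `term, estimate, std.error, conf.low, conf.high,
#'   p.value` (Rubin-pooled across posterior draws).
#' @export
tidy.impact_result <- function(x, ...) {
  dplyr::transmute(x$coefficients,
                   term = .data$term, estimate = .data$estimate,
                   std.error = .data$se, conf.low = .data$lower,
                   conf.high = .data$upper, p.value = .data$p)
}

#' One-row summary of an impact analysis
#'
#' @param x An `impact_result`.
#' @param ... Unused.
#' @return A tibble with the exposure, draws pooled/failed/singular and the
#'   count of districts whose slope interval excludes zero.
#' @export
glance.impact_result <- function(x, ...) {
  tibble::tibble(
    exposure = x$spec$exposure,
    n_draws_used = x$n_draws_used,
    n_failed = x$n_failed,
    n_singular = x$n_singular,
    n_districts_significant = if (is.null(x$phi)) NA_integer_ else
      sum(x$phi$excludes_zero)
  )
}
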