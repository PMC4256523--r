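#' Specify the multilevel impact regression
#'
#' The impact model regresses district-year log-MMR on district demography
#' (percent urban, percent female literacy), health-system access (ANC3,
#' percent), the non-JSY institutional-delivery proportion, and the program
#' exposure — either the JSY-supported delivery proportion of all
#' deliveries (`jsy_prop`, 0–1) or annual JSY expenditure in lakh
#' (`expenditure`). Random effects: a year intercept, a district intercept
#' and a district-specific random slope on the exposure (independent of the
#' intercept by default). Percentages stay on the 0–100 scale and
#' proportions on 0–1, so coefficient magnitudes are directly comparable
#' across terms; expenditure is never rescaled, which is why its
#' coefficients come out on the 1e-06 scale for realistic (hundreds to
#' thousands of lakh) budgets.
#'
#' @param exposure `"jsy_prop"` or `"expenditure"`.
#' @param fixed_terms Character vector of fixed-effect terms besides the
#'   intercept; the exposure must be among them.
#' @param random_terms Subset of `c("year_intercept", "district_intercept",
#'   "district_exposure_slope")`; empty means ordinary least squares.
#' @param n_draws Number of posterior MMR surfaces to propagate (default
#'   1000).
#' @param seed Integer seed for draw selection.
#' @return A `stage2_spec` list.
#' @export
stage2_spec <- function(exposure = c("jsy_prop", "expenditure"),
                        fixed_terms = c("urban", "literacy", "anc3",
                                        "njsy_prop", exposure),
                        random_terms = c("year_intercept", "district_intercept",
                                         "district_exposure_slope"),
                        n_draws = 1000, seed = 1L) {
  exposure <- match.arg(exposure)
  fixed_terms <- unique(fixed_terms)
  if (!exposure %in% fixed_terms) {
    stop_config("the exposure must be one of the fixed terms")
  }
  bad <- setdiff(random_terms,
                 c("year_intercept", "district_intercept", "district_exposure_slope"))
  if (length(bad)) stop_config("unknown random terms: ", paste(bad, collapse = ", "))
  if (n_draws < 1) stop_config("n_draws must be >= 1")
  structure(
    list(exposure = exposure, fixed_terms = fixed_terms,
         random_terms = random_terms, n_draws = as.integer(n_draws),
         seed = as.integer(seed)),
    class = "stage2_spec"
  )
}

# assemble the regression frame for one MMR surface
stage2_frame <- function(log_mmr_surface, covariates, exposure_panel, spec) {
  df <- exposure_panel |>
    dplyr::inner_join(covariates, by = "district_id") |>
    dplyr::inner_join(log_mmr_surface, by = c("district_id", "year"))
  if (!nrow(df)) stop_config("no overlapping district-years between panel and surface")
  if (length(unique(df$year)) < 2 || length(unique(df$district_id)) < 3) {
    stop_config("need at least 2 years and 3 districts")
  }
  for (term in c(spec$fixed_terms)) {
    if (!term %in% names(df)) stop_config("missing model term: ", term)
    if (stats::var(df[[term]]) < 1e-12) {
      stop_config("term '", term, "' is constant across the design; ",
                  "its coefficient is inestimable")
    }
  }
  df$district_id <- factor(df$district_id)
  df$year_f <- factor(df$year)
  df
}

stage2_formula <- function(spec) {
  fixed <- paste(spec$fixed_terms, collapse = " + ")
  ran <- c()
  if ("year_intercept" %in% spec$random_terms) ran <- c(ran, "(1 | year_f)")
  if ("district_intercept" %in% spec$random_terms &&
      "district_exposure_slope" %in% spec$random_terms) {
    ran <- c(ran, sprintf("(1 | district_id) + (0 + %s | district_id)", spec$exposure))
  } else if ("district_intercept" %in% spec$random_terms) {
    ran <- c(ran, "(1 | district_id)")
  } else if ("district_exposure_slope" %in% spec$random_terms) {
    ran <- c(ran, sprintf("(0 + %s | district_id)", spec$exposure))
  }
  stats::as.formula(paste("log_mmr ~", paste(c(fixed, ran), collapse = " + ")))
}

#' Fit the impact regression to a single MMR surface
#'
#' One mixed-model (REML) fit of log-MMR on the spec's fixed terms with the
#' spec's random effects, for one complete (district, year) MMR surface.
#' With no random terms the model reduces to ordinary least squares. The
#' optimizer and starting values are fixed, so the fit is deterministic
#' given its inputs. Singular variance components are retained at the
#' boundary (zero) and flagged.
#'
#' @param log_mmr_surface Tibble `district_id, year, log_mmr`.
#' @param covariates District covariates (`urban`, `literacy`, ...).
#' @param exposure_panel Exposure panel from [build_exposure_panel()].
#' @param spec A [stage2_spec()].
#' @return An `impact_fit`: `coefficients` tibble (term, estimate, se),
#'   `variance_components`, `phi` (per-district total exposure slope
#'   `fixed + random`, with approximate se), `singular`, `model`.
#' @export
fit_impact_single <- function(log_mmr_surface, covariates, exposure_panel,
                              spec = stage2_spec()) {
  stopifnot(inherits(spec, "stage2_spec"))
  df <- stage2_frame(log_mmr_surface, covariates, exposure_panel, spec)
  form <- stage2_formula(spec)
  districts <- levels(df$district_id)

  if (!length(spec$random_terms)) {
    fit <- stats::lm(form, data = df)
    sm <- summary(fit)
    coefs <- tibble::tibble(term = rownames(sm$coefficients),
                            estimate = unname(sm$coefficients[, 1]),
                            se = unname(sm$coefficients[, 2]))
    vc <- tibble::tibble(component = "residual", variance = sm$sigma^2)
    phi <- NULL
    singular <- FALSE
  } else {
    fit <- suppressMessages(lme4::lmer(
      form, data = df, REML = TRUE,
      control = lme4::lmerControl(optimizer = "bobyqa",
                                  calc.derivs = FALSE,
                                  check.conv.singular = "ignore",
                                  # exposures keep their native units (lakh
                                  # spans 1e2-1e4); the scale nag is expected
                                  check.scaleX = "ignore")))
    sm <- summary(fit)
    coefs <- tibble::tibble(term = rownames(sm$coefficients),
                            estimate = unname(sm$coefficients[, 1]),
                            se = unname(sm$coefficients[, 2]))
    vcd <- as.data.frame(lme4::VarCorr(fit))
    vc <- tibble::tibble(
      component = ifelse(is.na(vcd$var1), vcd$grp, paste(vcd$grp, vcd$var1)),
      variance = vcd$vcov)
    singular <- lme4::isSingular(fit, tol = 1e-5)
    phi <- NULL
    if ("district_exposure_slope" %in% spec$random_terms) {
      re <- lme4::ranef(fit, condVar = TRUE)
      slope_re <- NULL
      for (nm in names(re)) {
        if (spec$exposure %in% colnames(re[[nm]])) {
          pv <- attr(re[[nm]], "postVar")
          cond_var <- if (is.list(pv)) {
            pv_ix <- match(spec$exposure, colnames(re[[nm]]))
            pv[[pv_ix]][1, 1, ]
          } else {
            pv[match(spec$exposure, colnames(re[[nm]])),
               match(spec$exposure, colnames(re[[nm]])), ]
          }
          slope_re <- tibble::tibble(district_id = rownames(re[[nm]]),
                                     blup = re[[nm]][[spec$exposure]],
                                     cond_var = cond_var)
        }
      }
      b5 <- coefs[coefs$term == spec$exposure, ]
      phi <- slope_re |>
        dplyr::mutate(estimate = .data$blup + b5$estimate,
                      se = sqrt(.data$cond_var + b5$se^2)) |>
        dplyr::select("district_id", "estimate", "se") |>
        dplyr::arrange(match(.data$district_id, districts))
    }
  }

  structure(
    list(coefficients = coefs, variance_components = vc, phi = phi,
         singular = singular, spec = spec, n_obs = nrow(df), model = fit),
    class = "impact_fit"
  )
}

#' Fit the impact regression across posterior MMR draws
#'
#' Fits [fit_impact_single()] to each of `n` posterior MMR surfaces and
#' pools the per-draw estimates with Rubin-style rules: pooled estimate =
#' mean of per-draw estimates; pooled variance = mean within-draw variance
#' + (1 + 1/n) x between-draw variance; intervals and p-values from the
#' normal reference distribution. Empirical 2.5/97.5 percentiles of the
#' per-draw estimates are reported alongside. Per-district total exposure
#' slopes are pooled identically. Aborts if more than 5% of the draws fail.
#'
#' @param mmr_draws Matrix of MMR surfaces (rows = draws, columns
#'   `"<district>::<year>"`), e.g. from [sample_mmr_draws()].
#' @param covariates,exposure_panel,spec As in [fit_impact_single()].
#' @return An `impact_result`: `coefficients` (term, estimate, se, lower,
#'   upper, p, emp_lower, emp_upper), `phi` (same layout per district, plus
#'   `excludes_zero`), `variance_components` (means across draws),
#'   `n_draws_used`, `n_failed`, `n_singular`, `per_draw` (per-draw
#'   coefficient archive).
#' @export
fit_impact <- function(mmr_draws, covariates, exposure_panel,
                       spec = stage2_spec()) {
  stopifnot(is.matrix(mmr_draws), inherits(spec, "stage2_spec"))
  n <- min(spec$n_draws, nrow(mmr_draws))
  if (n < spec$n_draws) {
    warning(sprintf("only %d draws available; using all of them", n), call. = FALSE)
  }
  parts <- strsplit(colnames(mmr_draws), "::", fixed = TRUE)
  base <- tibble::tibble(district_id = vapply(parts, `[`, "", 1),
                         year = as.integer(vapply(parts, `[`, "", 2)))

  fits <- vector("list", n)
  failures <- character(0)
  for (k in seq_len(n)) {
    surface <- dplyr::mutate(base, log_mmr = log(mmr_draws[k, ]))
    res <- try(fit_impact_single(surface, covariates, exposure_panel, spec),
               silent = TRUE)
    if (inherits(res, "try-error")) {
      failures <- c(failures, conditionMessage(attr(res, "condition")))
    } else {
      fits[[k]] <- res
    }
  }
  fits <- fits[!vapply(fits, is.null, TRUE)]
  n_failed <- n - length(fits)
  if (n_failed > 0.05 * n) {
    stop_config(sprintf(
      "%d of %d draw fits failed (> 5%%); first error: %s",
      n_failed, n, failures[1]))
  }

  per_draw <- purrr::imap_dfr(fits, function(f, k) {
    dplyr::mutate(f$coefficients, draw = k)
  })
  coefficients <- pool_rubin(per_draw, key = "term")

  phi <- NULL
  if (!is.null(fits[[1]]$phi)) {
    per_draw_phi <- purrr::imap_dfr(fits, function(f, k) {
      dplyr::mutate(f$phi, draw = k)
    })
    phi <- pool_rubin(per_draw_phi, key = "district_id") |>
      dplyr::mutate(excludes_zero = .data$lower > 0 | .data$upper < 0)
  }

  vc <- purrr::map_dfr(fits, "variance_components") |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(variance = mean(.data$variance), .groups = "drop")

  structure(
    list(coefficients = coefficients, phi = phi, variance_components = vc,
         n_draws_used = length(fits), n_failed = n_failed,
         n_singular = sum(vapply(fits, `[[`, TRUE, "singular")),
         per_draw = per_draw, spec = spec),
    class = "impact_result"
  )
}

# Rubin-style pooling of per-draw (estimate, se) rows grouped by `key`
pool_rubin <- function(per_draw, key) {
  m <- length(unique(per_draw$draw))
  per_draw |>
    dplyr::group_by(.data[[key]]) |>
    dplyr::summarise(
      qbar = mean(.data$estimate),
      w = mean(.data$se^2),
      b = if (m > 1) stats::var(.data$estimate) else 0,
      emp_lower = unname(stats::quantile(.data$estimate, 0.025)),
      emp_upper = unname(stats::quantile(.data$estimate, 0.975)),
      .groups = "drop") |>
    dplyr::mutate(
      se = sqrt(.data$w + (1 + 1 / m) * .data$b),
      lower = .data$qbar - stats::qnorm(0.975) * .data$se,
      upper = .data$qbar + stats::qnorm(0.975) * .data$se,
      p = 2 * stats::pnorm(-abs(.data$qbar / .data$se))) |>
    dplyr::select(dplyr::all_of(key), estimate = "qbar", "se",
                  "lower", "upper", "p", "emp_lower", "emp_upper")
}

#' Per-district exposure-slope report
#'
#' Pools each district's total exposure slope (fixed effect + district
#' random slope) and flags districts whose 95% interval excludes zero —
#' the analog of the district random-slope interval display.
#'
#' @param result An `impact_result` fitted with a district exposure slope.
#' @return Tibble `district_id, estimate, lower, upper, excludes_zero`,
#'   with a summary attribute `n_significant`.
#' @export
district_slope_report <- function(result) {
  stopifnot(inherits(result, "impact_result"))
  if (is.null(result$phi)) {
    stop_config("the fitted spec has no district exposure slope; ",
                "add 'district_exposure_slope' to random_terms")
  }
  out <- result$phi[, c("district_id", "estimate", "lower", "upper", "excludes_zero")]
  attr(out, "n_significant") <- sum(out$excludes_zero)
  out
}

#' Format the pooled coefficient table
#'
#' Rows ordered Intercept, Literacy, Urban, ANC3, NJSY, exposure; estimates
#' to 3 decimals; interval bounds to 3 decimals except values that would
#' round to zero, which are printed in scientific notation; p-values to 3
#' decimals with exact-zero rounding printed as `"0"`.
#'
#' @param result An `impact_result`.
#' @return Tibble of formatted strings: `term, estimate, ci, p`.
#' @export
make_coefficient_table <- function(result) {
  stopifnot(inherits(result, "impact_result"))
  labels <- c("(Intercept)" = "Intercept",
              literacy = "Literacy",
              urban = "Urban",
              anc3 = ">=3 Antenatal care visits",
              njsy_prop = "Non-JSY institutional deliveries",
              jsy_prop = "JSY-supported institutional deliveries",
              expenditure = "JSY total annual expenditures (in lakh)")
  ord <- c("(Intercept)", "literacy", "urban", "anc3", "njsy_prop",
           result$spec$exposure)
  tab <- result$coefficients |>
    dplyr::filter(.data$term %in% ord) |>
    dplyr::arrange(match(.data$term, ord))
  tibble::tibble(
    term = unname(labels[tab$term]),
    estimate = vapply(tab$estimate, format_coef, ""),
    ci = sprintf("(%s, %s)",
                 vapply(tab$lower, format_bound, ""),
                 vapply(tab$upper, format_bound, "")),
    p = vapply(tab$p, format_p, "")
  )
}

#' @export
print.impact_result <- function(x, ...) {
  cat("<impact_result>\n")
  cat(sprintf("  exposure: %s; %d draws pooled (%d failed, %d singular)\n",
              x$spec$exposure, x$n_draws_used, x$n_failed, x$n_singular))
  print(make_coefficient_table(x), n = Inf)
  if (!is.null(x$phi)) {
    cat(sprintf("  district slopes: %d of %d exclude zero\n",
                sum(x$phi$excludes_zero), nrow(x$phi)))
  }
  invisible(x)
}
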