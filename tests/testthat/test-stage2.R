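test_that("with no random terms the fit equals brute-force least squares", {
  fx <- ols_fixture()
  spec <- stage2_spec(random_terms = character(0), n_draws = 1)
  fit <- fit_impact_single(fx$surface, fx$covariates, fx$exposure_panel, spec)

  df <- fx$surface |>
    dplyr::left_join(fx$covariates, by = "district_id") |>
    dplyr::left_join(fx$exposure_panel, by = c("district_id", "year"))
  X <- cbind(1, df$urban, df$literacy, df$anc3, df$njsy_prop, df$jsy_prop)
  beta_hat <- solve(t(X) %*% X, t(X) %*% df$log_mmr)[, 1]
  ours <- fit$coefficients$estimate[match(
    c("(Intercept)", "urban", "literacy", "anc3", "njsy_prop", "jsy_prop"),
    fit$coefficients$term)]
  expect_equal(unname(ours), unname(beta_hat), tolerance = 1e-8)
})

test_that("a known program effect is recovered from a noiseless surface", {
  cfg <- scenario_config(
    seed = 51, program_effect = -0.3,
    intercept_sd = list(district = 0.02, division = 0),
    trend = list(slope_mean = 0, slope_sd = 0, nonlinear_scale = 0),
    bulletin = clean_bulletin)
  truth <- generate_truth(cfg)
  ep <- build_exposure_panel(generate_program_panel(truth, cfg)$panel)
  surface <- dplyr::transmute(truth$mmr, district_id = .data$district_id,
                              year = .data$year, log_mmr = .data$log_mmr)
  fit <- fit_impact_single(surface, truth$covariates, ep, stage2_spec(n_draws = 1))
  b5 <- fit$coefficients[fit$coefficients$term == "jsy_prop", ]
  expect_lt(abs(b5$estimate - (-0.3)), 2 * b5$se)
})

test_that("a constant exposure is rejected as inestimable", {
  fx <- ols_fixture()
  ep <- dplyr::mutate(fx$exposure_panel, jsy_prop = 0.4)
  expect_error(
    fit_impact_single(fx$surface, fx$covariates, ep, stage2_spec(n_draws = 1)),
    "jsy_prop.*inestimable")
})

test_that("pooling is the mean of per-draw estimates, exactly", {
  truth <- generate_truth(small_config(seed = 52, bulletin = clean_bulletin))
  ep <- build_exposure_panel(generate_program_panel(truth, truth$config)$panel)
  draws <- simulate_posterior_surfaces(truth, n = 12, spread = 0.05, seed = 1)
  res <- fit_impact(draws, truth$covariates, ep, stage2_spec(n_draws = 12, seed = 2))
  per_draw_means <- res$per_draw |>
    dplyr::group_by(term) |>
    dplyr::summarise(m = mean(estimate))
  expect_equal(res$coefficients$estimate[match(per_draw_means$term,
                                               res$coefficients$term)],
               per_draw_means$m)
  expect_equal(res$n_draws_used, 12)
})

test_that("identical draws degenerate to the single fit", {
  truth <- generate_truth(small_config(seed = 53, bulletin = clean_bulletin))
  ep <- build_exposure_panel(generate_program_panel(truth, truth$config)$panel)
  one <- simulate_posterior_surfaces(truth, n = 1, spread = 0.03, seed = 9)
  same <- one[rep(1, 10), , drop = FALSE]
  res <- fit_impact(same, truth$covariates, ep, stage2_spec(n_draws = 10, seed = 1))
  surface <- tibble::tibble(
    district_id = sub("::.*", "", colnames(one)),
    year = as.integer(sub(".*::", "", colnames(one))),
    log_mmr = log(one[1, ]))
  single <- fit_impact_single(surface, truth$covariates, ep,
                              stage2_spec(n_draws = 1))
  expect_equal(res$coefficients$estimate[match(single$coefficients$term,
                                               res$coefficients$term)],
               single$coefficients$estimate)
  # between-draw variance is zero, so pooled se equals the within-draw se
  expect_equal(res$coefficients$se[match(single$coefficients$term,
                                         res$coefficients$term)],
               single$coefficients$se, tolerance = 1e-8)
})

test_that("a strongly deviating district slope is flagged, null districts are not", {
  truth <- generate_truth(scenario_config(
    seed = 54, program_effect = -0.2,
    intercept_sd = list(district = 0.03, division = 0.02),
    trend = list(slope_mean = 0, slope_sd = 0.001, nonlinear_scale = 0),
    bulletin = clean_bulletin))
  ep <- build_exposure_panel(generate_program_panel(truth, truth$config)$panel)
  # inject an extra slope of -1.0 for district d05 on top of the shared effect
  mm <- truth$mmr
  inject <- mm$district_id == "d05"
  mm$log_mmr[inject] <- mm$log_mmr[inject] - 1.0 * mm$jsy_prop[inject]
  truth$mmr <- mm
  draws <- simulate_posterior_surfaces(truth, n = 30, spread = 0.01, seed = 2)
  res <- fit_impact(draws, truth$covariates, ep, stage2_spec(n_draws = 30, seed = 3))
  rep_tbl <- district_slope_report(res)
  expect_true(rep_tbl$excludes_zero[rep_tbl$district_id == "d05"])
  expect_lt(rep_tbl$estimate[rep_tbl$district_id == "d05"], 0)

  # without a random slope in the spec the report is an informative error
  res2 <- fit_impact(draws, truth$covariates, ep,
                     stage2_spec(random_terms = c("year_intercept",
                                                  "district_intercept"),
                                 n_draws = 5, seed = 3))
  expect_error(district_slope_report(res2), "district_exposure_slope")
})

test_that("expenditure in lakh keeps its native scale in the coefficients", {
  truth <- generate_truth(scenario_config(seed = 55, bulletin = clean_bulletin))
  panel <- generate_program_panel(truth, truth$config)$panel
  ep <- build_exposure_panel(panel)
  expect_true(stats::median(ep$expenditure) > 1e2 &&
                stats::median(ep$expenditure) < 1e4)
  draws <- simulate_posterior_surfaces(truth, n = 20, spread = 0.02, seed = 4)
  res <- fit_impact(draws, truth$covariates, ep,
                    stage2_spec(exposure = "expenditure", n_draws = 20, seed = 5))
  b5 <- coef_row(res, "expenditure")
  # per-lakh coefficients live on the 1e-6..1e-4 scale for realistic budgets;
  # anything near unity would mean the module silently rescaled the exposure
  expect_lt(abs(b5$estimate), 1e-3)
  expect_lt(b5$se, 1e-3)
  expect_gt(b5$se, 1e-9)
})

test_that("coefficient tables follow the mixed precision formatting rules", {
  fake <- structure(list(
    coefficients = tibble::tibble(
      term = c("(Intercept)", "literacy", "urban", "anc3", "njsy_prop",
               "expenditure"),
      estimate = c(6.752, -0.2231, -0.016, -0.004, -0.219, 1.2e-7),
      se = 0.1,
      lower = c(6.518, -0.44, -0.0199, -0.007, -0.537, -2.488e-6),
      upper = c(6.942, 0.063, -0.012, 0.001, 0.131, 1.682e-6),
      p = c(0.0004, 0.016, 0, 0.078, 0.194, 0.486),
      emp_lower = NA_real_, emp_upper = NA_real_),
    spec = stage2_spec(exposure = "expenditure", n_draws = 1)),
    class = "impact_result")
  tab <- make_coefficient_table(fake)
  expect_equal(tab$term[1], "Intercept")
  expect_equal(tab$estimate[2], "-0.223")
  expect_equal(tab$p[1], "0")                       # 0.0004 prints as "0"
  expect_equal(tab$p[2], "0.016")
  expect_equal(tab$estimate[6], "0.000")            # 1.2e-7 rounds to zero
  expect_match(tab$ci[6], "e-06")                   # bounds go scientific
  expect_equal(tab$ci[1], "(6.518, 6.942)")
})

test_that("power is non-decreasing in the effect size", {
  sizes <- c(0, -0.15, -0.3, -0.6)
  detect <- vapply(sizes, function(b5) {
    hits <- vapply(1:6, function(i) {
      r <- calibration_impact(700 + 13 * i, b5, spread = 0.02, n_draws = 15,
                              n_districts = 50, n_divisions = 10)
      co <- coef_row(r, "jsy_prop")
      co$upper < 0
    }, TRUE)
    mean(hits)
  }, 0)
  expect_lte(detect[1], detect[4])
  # allow one-step Monte-Carlo wiggle at 6 replicates per grid point
  expect_true(all(diff(detect) >= -0.2))
})
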