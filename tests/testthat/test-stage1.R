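test_that("posterior medians track truth in a no-trend single-source scenario", {
  cfg <- scenario_config(
    seed = 31,
    trend = list(slope_mean = 0, slope_sd = 0, nonlinear_scale = 0),
    program_effect = 0,
    source_specs = list(source_spec("vs", "district", bias = 1, coverage = 1,
                                    dispersion = 200)))
  sc <- simulate_scenario(cfg)
  fit <- quiet_fit(sc$observations, sc$covariates, lb_table(sc$truth),
                   sc$membership,
                   stage1_spec(source_effects = FALSE, trend = "linear_only",
                               draws = 500, warmup = 500, seed = 31))
  post <- predict_mmr(fit)
  comp <- dplyr::inner_join(post, sc$truth$mmr[, c("district_id", "year", "mmr")],
                            by = c("district_id", "year"))
  expect_gte(mean(abs(comp$median - comp$mmr) / comp$mmr <= 0.10), 0.9)
})

test_that("an injected source bias is recovered by the source effect", {
  cfg <- small_config(seed = 21, source_specs = list(
    source_spec("ref", "district", bias = 1.0, coverage = 1.0, dispersion = 200),
    source_spec("infl", "district", bias = 1.5, coverage = 1.0)))
  sc <- simulate_scenario(cfg)
  fit <- quiet_fit(sc$observations, sc$covariates, lb_table(sc$truth),
                   sc$membership,
                   stage1_spec(draws = 600, warmup = 400, seed = 3,
                               reference_source = "ref"))
  d2 <- tidy(fit)
  d2 <- d2[d2$term == "delta[2]", ]
  expect_lt(abs(d2$estimate - log(1.5)), 3 * d2$std.error)
})

test_that("a single district's interval covers the conjugate-style shrinkage oracle", {
  lb <- 40000
  years <- 2005:2008
  obs <- tibble::tibble(unit_id = "d01", level = "district", year = years,
                        source_id = "vs", deaths = c(115, 131, 120, 125),
                        live_births = lb, mmr = NA_real_)
  covs <- tibble::tibble(district_id = "d01", division_id = "div1",
                         tfr = 3, hdi = 0.5, urban = 30, literacy = 55)
  lbt <- tibble::tibble(district_id = "d01", year = years, live_births = lb)
  mem <- covs[, c("district_id", "division_id")]
  spec <- stage1_spec(covariates = character(0), trend = "linear_only",
                      source_effects = FALSE, draws = 1500, warmup = 1000,
                      seed = 5)
  fit <- quiet_fit(obs, covs, lbt, mem, spec)

  # brute-force oracle: constant log-MMR c with the spec's own normal prior,
  # negative-binomial likelihood at the true dispersion, 1-D quadrature
  cgrid <- seq(log(50), log(1500), length.out = 4001)
  loglik <- vapply(cgrid, function(cc) {
    sum(nb_log_likelihood(obs$deaths, exp(cc) * lb / 1e5, 30))
  }, 0)
  logpost <- loglik + stats::dnorm(cgrid, spec$priors$b0_mean,
                                   spec$priors$b0_sd, log = TRUE)
  w <- exp(logpost - max(logpost))
  oracle_mmr <- sum(exp(cgrid) * w) / sum(w)

  post <- predict_mmr(fit)
  expect_true(all(post$lower <= oracle_mmr & oracle_mmr <= post$upper))
  expect_lt(abs(stats::median(post$median) - oracle_mmr) / oracle_mmr, 0.15)
})

test_that("sparse districts shrink toward their division", {
  # five fully observed districts around MMR 300 and one district with a
  # single, wildly high observation: the posterior must pull it toward the
  # division mean by more than it trusts the raw rate
  years <- 2005:2007
  lb <- 40000
  full <- tidyr::expand_grid(unit_id = sprintf("d%02d", 2:6), year = years) |>
    dplyr::mutate(level = "district", source_id = "vs",
                  deaths = 120, live_births = lb, mmr = NA_real_)
  sparse <- tibble::tibble(unit_id = "d01", level = "district", year = 2006,
                           source_id = "vs", deaths = 240, live_births = lb,
                           mmr = NA_real_)
  obs <- dplyr::bind_rows(full, sparse)
  covs <- tibble::tibble(district_id = sprintf("d%02d", 1:6),
                         division_id = rep(c("div1", "div2"), each = 3),
                         tfr = 3, hdi = 0.5, urban = 30, literacy = 55)
  lbt <- tidyr::expand_grid(district_id = sprintf("d%02d", 1:6), year = years) |>
    dplyr::mutate(live_births = lb)
  fit <- quiet_fit(obs, covs, lbt, covs[, c("district_id", "division_id")],
                   stage1_spec(covariates = character(0), trend = "linear_only",
                               source_effects = FALSE, draws = 800,
                               warmup = 800, seed = 6))
  post <- predict_mmr(fit)
  raw <- compute_mmr(240, lb)           # 600
  division_mean <- 300
  est <- post$median[post$district_id == "d01" & post$year == 2006]
  expect_lt(abs(est - division_mean), abs(raw - division_mean))
})

test_that("quantile summaries follow the draws exactly", {
  fake <- structure(list(log_mmr_draws = matrix(log(200), 50, 2,
                                                dimnames = list(NULL, c("d01::2005", "d01::2006")))),
                    class = "stage1_fit")
  post <- predict_mmr(fake)
  expect_equal(post$median, c(200, 200))
  expect_equal(post$lower, post$upper)

  draws <- matrix(log(c(rep(100, 975), rep(500, 25))), ncol = 1,
                  dimnames = list(NULL, "d01::2005"))
  fake2 <- structure(list(log_mmr_draws = draws), class = "stage1_fit")
  post2 <- predict_mmr(fake2)
  oracle_upper <- exp(stats::quantile(log(c(rep(100, 975), rep(500, 25))),
                                      0.975, names = FALSE))
  expect_equal(post2$upper, oracle_upper)
  # monotone-transform invariance of the quantile rule
  expect_equal(post2$median,
               exp(stats::quantile(draws[, 1], 0.5, names = FALSE)))
})

test_that("posterior surface draws are joint, seeded and consistent", {
  sc <- simulate_scenario(small_config(seed = 33))
  fit <- quiet_fit(sc$observations, sc$covariates, lb_table(sc$truth),
                   sc$membership, stage1_spec(draws = 300, warmup = 300, seed = 2))
  all_draws <- sample_mmr_draws(fit, n = nrow(fit$log_mmr_draws))
  expect_equal(all_draws, exp(fit$log_mmr_draws))   # identity at full size
  a <- sample_mmr_draws(fit, n = 100, seed = 4)
  b <- sample_mmr_draws(fit, n = 100, seed = 4)
  expect_identical(a, b)
  big <- sample_mmr_draws(fit, n = 2000, seed = 4)  # resample w/ replacement
  expect_equal(nrow(big), 2000)
  expect_lt(max(abs(colMeans(log(big)) - colMeans(fit$log_mmr_draws))),
            4 * max(apply(fit$log_mmr_draws, 2, stats::sd)) / sqrt(2000) * 3)
  expect_error(sample_mmr_draws(fit, n = 0), "positive")
})

test_that("the full fit is reproducible given a seed", {
  sc <- simulate_scenario(small_config(seed = 35))
  spec <- stage1_spec(draws = 150, warmup = 150, seed = 77)
  f1 <- quiet_fit(sc$observations, sc$covariates, lb_table(sc$truth),
                  sc$membership, spec)
  f2 <- quiet_fit(sc$observations, sc$covariates, lb_table(sc$truth),
                  sc$membership, spec)
  expect_identical(f1$draws, f2$draws)
})

test_that("percent change uses the decline-positive convention", {
  expect_equal(percent_change(371, 327), 12)
  expect_equal(percent_change(200, 200), 0)
  expect_equal(percent_change(100, 130), -30)
  expect_equal(percent_change(300, 190.3, digits = 1), 36.6)
  expect_error(percent_change(0, 100), "positive")
})

test_that("single-source data demand source effects off", {
  sc <- simulate_scenario(small_config(
    seed = 36, source_specs = list(source_spec("only", "district"))))
  expect_error(
    fit_stage1(sc$observations, sc$covariates, lb_table(sc$truth),
               sc$membership, stage1_spec(seed = 1)),
    "at least 2 sources")
})
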