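test_that("degenerate generator collapses to a constant surface", {
  cfg <- scenario_config(
    covariate_effects = c(tfr = 0, hdi = 0),
    trend = list(slope_mean = 0, slope_sd = 0, nonlinear_scale = 0),
    program_effect = 0,
    intercept_sd = list(district = 0, division = 0),
    seed = 4)
  truth <- generate_truth(cfg)
  expect_equal(truth$mmr$mmr,
               rep(exp(cfg$baseline_log_mmr_mean), nrow(truth$mmr)))
})

test_that("program term enters the mean function with the configured slope", {
  # exposure stepping 0 -> 0.8 with every other term frozen: the first-to-last
  # log-MMR difference must equal program_effect * 0.8
  cfg <- scenario_config(
    covariate_effects = c(tfr = 0, hdi = 0),
    trend = list(slope_mean = 0, slope_sd = 0, nonlinear_scale = 0),
    program_effect = -0.3,
    intercept_sd = list(district = 0, division = 0),
    uptake = list(inst_start = 0, inst_end = 0.8,
                  jsy_share_start = 1, jsy_share_end = 1, district_sd = 0),
    seed = 4)
  truth <- generate_truth(cfg)
  d1 <- truth$mmr[truth$mmr$district_id == "d01", ]
  expect_equal(d1$log_mmr[d1$year == 2010] - d1$log_mmr[d1$year == 2005],
               -0.24, tolerance = 1e-6)
})

test_that("generation is deterministic given the seed and uses substreams", {
  cfg <- scenario_config(seed = 11)
  s1 <- simulate_scenario(cfg)
  s2 <- simulate_scenario(cfg)
  expect_identical(s1$truth$mmr, s2$truth$mmr)
  expect_identical(s1$observations, s2$observations)
  expect_identical(s1$program_panel, s2$program_panel)

  # adding a source must not perturb the truth or other sources' records
  cfg_extra <- scenario_config(seed = 11, source_specs = c(
    cfg$source_specs, list(source_spec("extra", "division", bias = 1.2))))
  s3 <- simulate_scenario(cfg_extra)
  expect_identical(s1$truth$mmr, s3$truth$mmr)
  expect_identical(
    s1$observations[s1$observations$source_id == "vital_stats", ],
    s3$observations[s3$observations$source_id == "vital_stats", ])
})

test_that("an unbiased full-coverage near-Poisson source reproduces truth on average", {
  cfg <- scenario_config(
    seed = 2,
    source_specs = list(source_spec("s", "district", bias = 1, coverage = 1,
                                    dispersion = 1e6)))
  truth <- generate_truth(cfg)
  reps <- 200
  per_rep <- vapply(seq_len(reps), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- 5000L + i
    obs <- generate_observations(truth, cfg_i)
    obs <- obs[order(obs$unit_id, obs$year), ]
    obs$deaths
  }, numeric(nrow(truth$mmr)))
  truth_sorted <- truth$mmr[order(truth$mmr$district_id, truth$mmr$year), ]
  mean_obs <- rowMeans(per_rep)
  mc_se <- apply(per_rep, 1, stats::sd) / sqrt(reps)
  z <- abs(mean_obs - truth_sorted$deaths) / mc_se
  # 72 simultaneous cells: allow the expected handful of 3-sigma excursions
  # but no gross ones, and demand the pooled total agree to 3 SE
  expect_gt(mean(z <= 3), 0.95)
  expect_true(all(z <= 5))
  pooled_se <- stats::sd(colSums(per_rep)) / sqrt(reps)
  expect_lt(abs(mean(colSums(per_rep)) - sum(truth_sorted$deaths)),
            3 * pooled_se)
})

test_that("higher-level sources aggregate member districts before biasing", {
  cfg <- scenario_config(seed = 3)
  truth <- generate_truth(cfg)
  obs <- generate_observations(truth, cfg)
  state <- obs[obs$level == "state", ]
  expect_equal(nrow(state), length(cfg$years))           # one record per year
  # expectation identity, checked by averaging replicate draws
  reps <- 200
  draws <- vapply(seq_len(reps), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- 6000L + i
    o <- generate_observations(truth, cfg_i)
    o$deaths[o$level == "state" & o$year == 2007]
  }, 0)
  expected <- sum(truth$mmr$deaths[truth$mmr$year == 2007])  # srs bias is 1
  expect_lt(abs(mean(draws) - expected), 3 * stats::sd(draws) / sqrt(reps))
})

test_that("coverage thins unit-years binomially", {
  cfg <- scenario_config(
    n_districts = 50, n_divisions = 10, seed = 8,
    source_specs = list(source_spec("s", "district", coverage = 0.5)))
  truth <- generate_truth(cfg)
  n <- nrow(generate_observations(truth, cfg))
  # binomial(300, 0.5): mean 150, sd sqrt(75)
  expect_lt(abs(n - 150), 3 * sqrt(300 * 0.25))
})

test_that("bulletin over-reporting follows the configured inflation", {
  # all correction factors pinned at 0.61: reported proportion = true / 0.61
  cfg <- scenario_config(
    seed = 5,
    bulletin = list(factor_range = c(0.61, 0.61), factor_shape = c(1, 1),
                    benchmark_year = NULL))
  truth <- generate_truth(cfg)
  prog <- generate_program_panel(truth, cfg)
  reported <- prog$panel$institutional_deliveries / prog$panel$total_deliveries
  expected <- pmin(0.97, truth$mmr$inst_prop / 0.61)
  expect_equal(reported, expected, tolerance = 1e-4)  # count rounding only
  # direct arithmetic of the configured inflation
  expect_equal(0.40 / 0.61, 0.656, tolerance = 1e-3)

  # inflation factor 1: the panel reports the truth
  cfg1 <- scenario_config(seed = 5, bulletin = clean_bulletin)
  prog1 <- generate_program_panel(generate_truth(cfg1), cfg1)
  rep1 <- prog1$panel$institutional_deliveries / prog1$panel$total_deliveries
  expect_equal(rep1, truth$mmr$inst_prop, tolerance = 1e-4)
})

test_that("the JSY share of institutional deliveries rises monotonically", {
  cfg <- scenario_config(seed = 6)
  truth <- generate_truth(cfg)
  prog <- generate_program_panel(truth, cfg)
  shares <- prog$panel |>
    dplyr::mutate(share = ifelse(institutional_deliveries > 0,
                                 jsy_deliveries / institutional_deliveries, 0)) |>
    dplyr::arrange(district_id, year)
  for (d in unique(shares$district_id)) {
    expect_true(all(diff(shares$share[shares$district_id == d]) > -1e-3))
  }
  # default scenario spans the documented uptake range
  expect_lt(mean(truth$mmr$jsy_share[truth$mmr$year == 2005]), 0.2)
  expect_gt(mean(truth$mmr$jsy_share[truth$mmr$year == 2010]), 0.7)
})

test_that("invalid configurations are rejected", {
  expect_error(scenario_config(n_districts = 2, n_divisions = 3), "n_districts")
  expect_error(scenario_config(years = 2005:2006), "3 years")
  expect_error(scenario_config(overdispersion = 0), "overdispersion")
  expect_error(source_spec("x", bias = -1), "bias")
  expect_error(source_spec("x", coverage = 0), "coverage")
})

test_that("synthetic posterior surfaces are seeded and centred on truth", {
  truth <- generate_truth(small_config(seed = 2))
  a <- simulate_posterior_surfaces(truth, n = 400, spread = 0.1, seed = 3)
  b <- simulate_posterior_surfaces(truth, n = 400, spread = 0.1, seed = 3)
  expect_identical(a, b)
  log_means <- colMeans(log(a))
  expect_lt(max(abs(log_means - truth$mmr$log_mmr)), 4 * 0.1 / sqrt(400))
})
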