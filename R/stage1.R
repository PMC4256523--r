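#' Specify the hierarchical MMR estimation model
#'
#' Configures the Bayesian negative-binomial model of district-level MMR:
#' `log(MMR[d,t]) = b0 + X[d] beta + alpha[d] + zeta[d] * (t - midyear) +
#' xi[d,t]`, with reported death counts from source `s` distributed
#' negative-binomially around `exp(delta[s]) *` (true expected deaths
#' aggregated to the source's level). District intercepts `alpha` and linear
#' slopes `zeta` are nested in division-level effects which shrink toward
#' state-level means; the non-linear component `xi` is a second-order
#' random walk over years anchored at zero for the first two years so it
#' cannot absorb the intercept or linear trend. One designated reference
#' source has `delta = 0` for identifiability. Sources that report MMR
#' directly enter through a lognormal observation model with a
#' source-specific residual sd.
#'
#' @param covariates Character subset of `c("tfr", "hdi")` (may be empty).
#' @param trend `"linear_plus_nonlinear"` (default) or `"linear_only"`.
#' @param source_effects Logical; estimate source effects `delta`?
#' @param reference_source Optional source_id to pin at `delta = 0`;
#'   defaults to the source reporting at the highest geographic level.
#' @param priors Named list of hyperprior settings (see defaults in the
#'   function signature): normal prior mean/sd of the intercept `b0`, the
#'   normal sd of covariate and source effects, upper bounds of the uniform
#'   priors on hierarchical sds, and the Gamma(shape, rate) prior of the
#'   negative-binomial dispersion.
#' @param draws Posterior draws kept per chain after warmup.
#' @param warmup Burn-in iterations per chain (adaptation uses half).
#' @param chains Number of MCMC chains (2+ enables Gelman–Rubin
#'   diagnostics).
#' @param seed Integer seed controlling all chains' RNG.
#' @param label Optional label used in model-comparison tables.
#' @return A `stage1_spec` list.
#' @export
stage1_spec <- function(covariates = c("tfr", "hdi"),
                        trend = c("linear_plus_nonlinear", "linear_only"),
                        source_effects = TRUE,
                        reference_source = NULL,
                        priors = list(),
                        draws = 1000, warmup = 500, chains = 2,
                        seed = 1L, label = NULL) {
  trend <- match.arg(trend)
  covariates <- intersect(covariates, c("tfr", "hdi"))
  defaults <- list(b0_mean = log(300), b0_sd = 1, beta_sd = 2,
                   zeta0_sd = 0.2, sd_upper = 1, xi_sd_upper = 0.3,
                   delta_sd = 1, dispersion_shape = 2, dispersion_rate = 0.1,
                   direct_sd_upper = 1)
  priors <- utils::modifyList(defaults, priors)
  if (draws < 1 || warmup < 0 || chains < 1) stop_config("invalid sampler settings")
  structure(
    list(covariates = covariates, trend = trend,
         source_effects = isTRUE(source_effects),
         reference_source = reference_source, priors = priors,
         draws = as.integer(draws), warmup = as.integer(warmup),
         chains = as.integer(chains), seed = as.integer(seed),
         label = label %||% paste0(
           "cov:", if (length(covariates)) paste(covariates, collapse = "+") else "none",
           "|", trend, "|delta:", if (isTRUE(source_effects)) "on" else "off")),
    class = "stage1_spec"
  )
}

# Assemble the JAGS data list and model string for a spec + data set.
# Returns everything fit_stage1 and the CPO refits need.
build_stage1_inputs <- function(observations, covariates, live_births,
                                membership, spec, drop_obs = NULL) {
  obs <- observations
  if (!is.null(drop_obs)) obs <- obs[-drop_obs, , drop = FALSE]
  districts <- sort(unique(membership$district_id))
  divisions <- sort(unique(membership$division_id))
  years <- sort(unique(live_births$year))
  D <- length(districts); V <- length(divisions); Tn <- length(years)
  if (Tn < 3) stop_config("need at least 3 years of exposure data")
  div_of <- match(membership$division_id[match(districts, membership$district_id)],
                  divisions)

  lb <- matrix(NA_real_, D, Tn)
  idx <- cbind(match(live_births$district_id, districts),
               match(live_births$year, years))
  lb[idx] <- live_births$live_births
  if (anyNA(lb)) stop_config("live_births must cover every district-year")

  K <- length(spec$covariates)
  X <- matrix(0, D, max(1L, K))
  if (K > 0) {
    cv <- covariates[match(districts, covariates$district_id), , drop = FALSE]
    if (anyNA(cv$district_id)) stop_config("covariates missing for some districts")
    for (k in seq_len(K)) {
      v <- cv[[spec$covariates[k]]]
      X[, k] <- v - mean(v)
    }
  }

  sources <- sort(unique(obs$source_id))
  ref <- spec$reference_source
  if (is.null(ref)) {
    lv <- vapply(sources, function(s) {
      l <- unique(obs$level[obs$source_id == s])[1]
      match(l, c("district", "division", "state"))
    }, 0L)
    ref <- sources[which.max(lv)]
  }
  if (!ref %in% sources) stop_config("reference source not present in data: ", ref)
  sources <- c(ref, setdiff(sources, ref))
  S <- length(sources)
  if (S < 2 && spec$source_effects) {
    stop_config("source_effects require at least 2 sources; ",
                "set source_effects = FALSE for single-source data")
  }

  member_row <- function(level, unit_id) {
    switch(level,
      district = as.numeric(districts == unit_id),
      division = as.numeric(div_of == match(unit_id, divisions)),
      state = rep(1, D),
      stop_config("unknown level: ", level))
  }

  is_direct <- !is.na(obs$mmr)
  cobs <- obs[!is_direct, , drop = FALSE]
  dobs <- obs[is_direct, , drop = FALSE]
  if (any(dobs$mmr <= 0)) stop_config("direct-MMR observations must be positive")

  Mmat <- if (nrow(cobs)) {
    matrix(t(vapply(seq_len(nrow(cobs)),
                    function(i) member_row(cobs$level[i], cobs$unit_id[i]),
                    numeric(D))), nrow = nrow(cobs))
  } else {
    matrix(0, 0, D)
  }
  data <- list(
    D = D, V = V, T = Tn, lb = lb, tc = years - mean(years), div = div_of,
    b0_mean = spec$priors$b0_mean, b0_prec = spec$priors$b0_sd^-2,
    zeta0_prec = spec$priors$zeta0_sd^-2,
    sd_upper = spec$priors$sd_upper,
    disp_shape = spec$priors$dispersion_shape,
    disp_rate = spec$priors$dispersion_rate
  )
  if (K > 0) {
    data$K <- K; data$X <- X
    data$beta_prec <- spec$priors$beta_sd^-2
  }
  use_delta <- spec$source_effects && S >= 2
  if (nrow(cobs)) {
    data$Nobs <- nrow(cobs)
    data$deaths <- round(cobs$deaths)
    if (use_delta) data$src <- match(cobs$source_id, sources)
    data$tt <- match(cobs$year, years)
    data$M <- Mmat
  }
  if (nrow(dobs)) {
    data$Ndir <- nrow(dobs)
    data$log_mmr_obs <- log(dobs$mmr)
    if (use_delta) data$srcd <- match(dobs$source_id, sources)
    data$ttd <- match(dobs$year, years)
    data$Md <- t(vapply(seq_len(nrow(dobs)),
                        function(j) member_row(dobs$level[j], dobs$unit_id[j]),
                        numeric(D)))
    data$direct_sd_upper <- spec$priors$direct_sd_upper
  }
  if (spec$source_effects && S >= 2) {
    data$S <- S
    data$delta_prec <- spec$priors$delta_sd^-2
  }
  if (spec$trend == "linear_plus_nonlinear") {
    data$xi_sd_upper <- spec$priors$xi_sd_upper
  }

  list(data = data, model = stage1_model_string(spec, data),
       districts = districts, divisions = divisions, years = years,
       sources = sources, cobs = cobs, dobs = dobs,
       spec = spec, lb = lb, Mmat = Mmat,
       covariates_tbl = covariates, live_births_tbl = live_births,
       membership_tbl = membership)
}

stage1_model_string <- function(spec, data) {
  K <- data$K %||% 0
  has_counts <- !is.null(data$Nobs)
  has_direct <- !is.null(data$Ndir)
  has_delta <- !is.null(data$S)
  nonlinear <- spec$trend == "linear_plus_nonlinear"

  latent <- paste(
    "  for (d in 1:D) { for (t in 1:T) {",
    # hierarchically centred: b0 enters through the division means, which
    # removes the additive redundancy between the intercept and the
    # random-effect locations and mixes far better
    if (K > 0) {
      "    log_mmr[d,t] <- inprod(X[d,], beta) + alpha[d] + zeta[d]*tc[t] + xi[d,t]"
    } else {
      "    log_mmr[d,t] <- alpha[d] + zeta[d]*tc[t] + xi[d,t]"
    },
    "    td[d,t] <- exp(log_mmr[d,t]) * lb[d,t] * 1.0E-5",
    "  }}",
    sep = "\n")

  hierarchy <- paste(
    "  for (v in 1:V) {",
    "    a_div[v] ~ dnorm(b0, tau_a_div)",
    "    z_div[v] ~ dnorm(zeta0, tau_z_div)",
    "  }",
    "  for (d in 1:D) {",
    "    alpha[d] ~ dnorm(a_div[div[d]], tau_a_dist)",
    "    zeta[d] ~ dnorm(z_div[div[d]], tau_z_dist)",
    "  }",
    "  b0 ~ dnorm(b0_mean, b0_prec)",
    "  zeta0 ~ dnorm(0, zeta0_prec)",
    if (K > 0) "  for (k in 1:K) { beta[k] ~ dnorm(0, beta_prec) }" else NULL,
    "  sd_a_div ~ dunif(0, sd_upper); tau_a_div <- pow(sd_a_div, -2)",
    "  sd_a_dist ~ dunif(0, sd_upper); tau_a_dist <- pow(sd_a_dist, -2)",
    "  sd_z_div ~ dunif(0, sd_upper / 5); tau_z_div <- pow(sd_z_div, -2)",
    "  sd_z_dist ~ dunif(0, sd_upper / 5); tau_z_dist <- pow(sd_z_dist, -2)",
    sep = "\n")

  xi_block <- if (nonlinear) {
    paste(
      "  for (d in 1:D) {",
      "    xi[d,1] <- 0",
      "    xi[d,2] <- 0",
      "    for (t in 3:T) { xi[d,t] ~ dnorm(2*xi[d,t-1] - xi[d,t-2], tau_xi) }",
      "  }",
      "  sd_xi ~ dunif(0, xi_sd_upper); tau_xi <- pow(sd_xi, -2)",
      sep = "\n")
  } else {
    "  for (d in 1:D) { for (t in 1:T) { xi[d,t] <- 0 } }"
  }

  delta_block <- if (has_delta) {
    paste("  delta[1] <- 0",
          "  for (s in 2:S) { delta[s] ~ dnorm(0, delta_prec) }",
          sep = "\n")
  } else {
    NULL
  }
  delta_of <- function(ix) if (has_delta) sprintf("delta[%s]", ix) else "0"

  count_block <- if (has_counts) {
    paste(
      "  for (i in 1:Nobs) {",
      sprintf("    mu[i] <- exp(%s) * inprod(M[i,], td[, tt[i]])", delta_of("src[i]")),
      "    rho[i] ~ dgamma(r, r / mu[i])",
      "    deaths[i] ~ dpois(rho[i])",
      "  }",
      sep = "\n")
  } else {
    NULL
  }

  direct_block <- if (has_direct) {
    paste(
      "  for (j in 1:Ndir) {",
      "    mmr_pred[j] <- inprod(Md[j,], td[, ttd[j]]) / inprod(Md[j,], lb[, ttd[j]]) * 1.0E5",
      sprintf("    log_mmr_obs[j] ~ dnorm(log(mmr_pred[j]) + %s, tau_dir)", delta_of("srcd[j]")),
      "  }",
      "  sd_dir ~ dunif(0, direct_sd_upper); tau_dir <- pow(sd_dir, -2)",
      sep = "\n")
  } else {
    NULL
  }

  paste(c("model {", latent, hierarchy, xi_block, delta_block,
          "  r ~ dgamma(disp_shape, disp_rate)",
          count_block, direct_block, "}"), collapse = "\n")
}

#' Fit the hierarchical MMR model
#'
#' Builds and samples the model described in [stage1_spec()] with JAGS,
#' returning posterior draws of the full latent log-MMR surface together
#' with all structural parameters and convergence diagnostics. Draws are
#' reproducible given the spec's seed and sampler settings.
#'
#' @param observations Observation tibble (schema of [read_observations()]).
#' @param covariates District covariate tibble ([read_covariates()]).
#' @param live_births Tibble `district_id, year, live_births` covering every
#'   district-year (the model's exposure).
#' @param membership Tibble `district_id, division_id`.
#' @param spec A [stage1_spec()].
#' @return A `stage1_fit` with elements `draws` (matrix, all monitored
#'   parameters), `log_mmr_draws` (draws x district-year matrix, columns
#'   `"<district>::<year>"`), `districts`, `years`, `sources`, `diagnostics`
#'   (tibble of split-chain Gelman–Rubin R-hat values) and `converged`.
#'   Non-convergence flags the fit; it never fails silently.
#' @export
fit_stage1 <- function(observations, covariates, live_births, membership,
                       spec = stage1_spec()) {
  stopifnot(inherits(spec, "stage1_spec"))
  inp <- build_stage1_inputs(observations, covariates, live_births,
                             membership, spec)
  monitors <- c("log_mmr", "b0", "alpha", "zeta", "r",
                "sd_a_div", "sd_a_dist", "sd_z_div", "sd_z_dist")
  if (!is.null(inp$data$K)) monitors <- c(monitors, "beta")
  if (!is.null(inp$data$S)) monitors <- c(monitors, "delta")
  if (spec$trend == "linear_plus_nonlinear") monitors <- c(monitors, "sd_xi")
  if (!is.null(inp$data$Ndir)) monitors <- c(monitors, "sd_dir")

  inits <- lapply(seq_len(spec$chains), function(ch) {
    list(.RNG.name = "base::Wichmann-Hill",
         .RNG.seed = sub_seed(spec$seed, "stage1", ch),
         b0 = spec$priors$b0_mean)
  })
  model <- rjags::jags.model(textConnection(inp$model), data = inp$data,
                             inits = inits, n.chains = spec$chains,
                             n.adapt = max(100L, spec$warmup %/% 2L),
                             quiet = TRUE)
  stats::update(model, n.iter = spec$warmup, progress.bar = "none")
  samp <- rjags::coda.samples(model, variable.names = monitors,
                              n.iter = spec$draws, progress.bar = "none")

  draws <- do.call(rbind, lapply(samp, as.matrix))
  lm_cols <- grep("^log_mmr\\[", colnames(draws), value = TRUE)
  idx <- do.call(rbind, lapply(strsplit(gsub("log_mmr\\[|\\]", "", lm_cols), ","),
                               as.integer))
  key <- paste(inp$districts[idx[, 1]], inp$years[idx[, 2]], sep = "::")
  log_mmr_draws <- draws[, lm_cols, drop = FALSE]
  colnames(log_mmr_draws) <- key
  ord <- order(idx[, 1], idx[, 2])
  log_mmr_draws <- log_mmr_draws[, ord, drop = FALSE]

  diag_pars <- intersect(c("b0", "r", grep("^beta", colnames(draws), value = TRUE),
                           grep("^delta\\[", colnames(draws), value = TRUE),
                           "sd_a_dist", "sd_z_dist"),
                         colnames(draws))
  diagnostics <- stage1_rhat(samp, diag_pars)
  converged <- all(is.finite(diagnostics$rhat)) && max(diagnostics$rhat) < 1.1
  if (!converged) {
    warning("stage-1 fit flagged: max split R-hat = ",
            round(max(diagnostics$rhat, na.rm = TRUE), 3), call. = FALSE)
  }

  structure(
    list(draws = draws, log_mmr_draws = log_mmr_draws,
         districts = inp$districts, divisions = inp$divisions,
         years = inp$years, sources = inp$sources,
         spec = spec, inputs = inp,
         diagnostics = diagnostics, converged = converged),
    class = "stage1_fit"
  )
}

# split-chain Gelman-Rubin diagnostic; falls back to splitting a single
# chain in two so a point estimate exists even for chains = 1
stage1_rhat <- function(samp, pars) {
  pars <- pars[vapply(pars, function(p) {
    stats::var(as.matrix(samp[[1]])[, p]) > 1e-12
  }, TRUE)]
  if (!length(pars)) {
    return(tibble::tibble(parameter = character(), rhat = numeric()))
  }
  chains <- lapply(samp, function(ch) as.matrix(ch)[, pars, drop = FALSE])
  if (length(chains) == 1L) {
    n <- nrow(chains[[1]])
    chains <- list(chains[[1]][seq_len(n %/% 2), , drop = FALSE],
                   chains[[1]][(n %/% 2 + 1):n, , drop = FALSE])
  }
  ml <- coda::mcmc.list(lapply(chains, coda::mcmc))
  gd <- try(coda::gelman.diag(ml, autoburnin = FALSE, multivariate = FALSE),
            silent = TRUE)
  if (inherits(gd, "try-error")) {
    return(tibble::tibble(parameter = pars, rhat = NA_real_))
  }
  tibble::tibble(parameter = rownames(gd$psrf), rhat = gd$psrf[, 1])
}

#' @export
print.stage1_fit <- function(x, ...) {
  cat("<stage1_fit>\n")
  cat(sprintf("  %d districts x %d years, %d sources; %d draws (%d chains)\n",
              length(x$districts), length(x$years), length(x$sources),
              nrow(x$draws), x$spec$chains))
  cat(sprintf("  trend: %s, source effects: %s, converged: %s\n",
              x$spec$trend, x$spec$source_effects, x$converged))
  invisible(x)
}

#' Summarise the posterior MMR surface
#'
#' Medians and central 95% uncertainty intervals (2.5th–97.5th posterior
#' quantiles) of the latent MMR for every district-year. Quantiles are
#' computed on the log scale and exponentiated, so the summaries commute
#' exactly with the log/MMR transform. Source effects are part of the
#' observation model only, so these are estimates of the latent "true"
#' MMR, not of any single source's reported level.
#'
#' @param fit A `stage1_fit`.
#' @return An `mmr_posterior` tibble: `district_id`, `year`, `median`,
#'   `lower`, `upper`, with the draw matrix attached as attribute `draws`.
#' @export
predict_mmr <- function(fit) {
  stopifnot(inherits(fit, "stage1_fit"))
  mmr_draws <- exp(fit$log_mmr_draws)
  qs <- exp(t(apply(fit$log_mmr_draws, 2, stats::quantile,
                    probs = c(0.5, 0.025, 0.975), names = FALSE)))
  rownames(qs) <- NULL
  parts <- strsplit(colnames(mmr_draws), "::", fixed = TRUE)
  out <- tibble::tibble(
    district_id = vapply(parts, `[`, "", 1),
    year = as.integer(vapply(parts, `[`, "", 2)),
    median = qs[, 1], lower = qs[, 2], upper = qs[, 3]
  )
  attr(out, "draws") <- mmr_draws
  class(out) <- c("mmr_posterior", class(out))
  out
}

#' Sample complete MMR surfaces from the posterior
#'
#' Draws `n` complete (district x year) MMR surfaces jointly — whole rows of
#' the posterior draw matrix — so cross-district-year posterior correlation
#' is preserved for downstream propagation. If `n` equals the number of
#' stored draws the fit's own draws are returned unchanged; fewer are
#' subsampled without replacement; more are resampled with replacement.
#'
#' @param fit A `stage1_fit`.
#' @param n Number of surfaces (default 1000).
#' @param seed Integer seed.
#' @return Matrix `n` x district-years on the MMR scale, columns
#'   `"<district>::<year>"`.
#' @export
sample_mmr_draws <- function(fit, n = 1000, seed = 1L) {
  stopifnot(inherits(fit, "stage1_fit"))
  if (n <= 0) stop_config("n must be positive")
  total <- nrow(fit$log_mmr_draws)
  rows <- if (n == total) {
    seq_len(total)
  } else {
    with_seed(seed, sample.int(total, n, replace = n > total))
  }
  exp(fit$log_mmr_draws[rows, , drop = FALSE])
}

#' Percent change between two MMR levels
#'
#' Declines are positive: `(start - end) / start * 100`. Headline summaries
#' are rounded to the nearest integer; district tables use one decimal.
#'
#' @param mmr_start,mmr_end MMR values; `mmr_start` must be positive.
#' @param digits Rounding digits (0 for headline figures).
#' @return Rounded percent change (vectorised).
#' @examples
#' percent_change(371, 327) # 12
#' @export
percent_change <- function(mmr_start, mmr_end, digits = 0) {
  if (any(mmr_start <= 0)) stop_config("mmr_start must be positive")
  round((mmr_start - mmr_end) / mmr_start * 100, digits)
}
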