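# per-observation likelihood of each posterior draw, computed in R from the
# monitored draws (not by the sampler), so both CPO methods share one kernel
stage1_obs_likelihood <- function(fit, drop_obs = NULL) {
  inp <- fit$inputs
  draws <- fit$draws
  n_draws <- nrow(draws)
  lm <- fit$log_mmr_draws                     # draws x (D*T), district-major
  D <- length(fit$districts); Tn <- length(fit$years)
  r <- draws[, "r"]
  has_delta <- any(grepl("^delta\\[", colnames(draws)))
  delta <- if (has_delta) {
    draws[, sprintf("delta[%d]", seq_along(fit$sources)), drop = FALSE]
  } else {
    matrix(0, n_draws, length(fit$sources))
  }

  lb_vec <- as.vector(t(inp$lb))              # district-major (d1 y1..yT, d2 ...)
  td <- exp(lm) * rep(lb_vec, each = n_draws) / 1e5  # expected deaths per cell

  col_of <- function(d, t) (d - 1L) * Tn + t
  out <- list()
  if (nrow(inp$cobs)) {
    ll <- matrix(NA_real_, n_draws, nrow(inp$cobs))
    for (i in seq_len(nrow(inp$cobs))) {
      members <- which(inp$Mmat[i, ] > 0)
      t_i <- match(inp$cobs$year[i], fit$years)
      mu <- rowSums(td[, col_of(members, t_i), drop = FALSE]) *
        exp(delta[, match(inp$cobs$source_id[i], fit$sources)])
      ll[, i] <- nb_log_likelihood(inp$cobs$deaths[i], mu, r)
    }
    out$count <- ll
  }
  if (nrow(inp$dobs)) {
    sd_dir <- draws[, "sd_dir"]
    ll <- matrix(NA_real_, n_draws, nrow(inp$dobs))
    for (j in seq_len(nrow(inp$dobs))) {
      members <- which(inp$data$Md[j, ] > 0)
      t_j <- match(inp$dobs$year[j], fit$years)
      mmr_pred <- rowSums(td[, col_of(members, t_j), drop = FALSE]) /
        sum(inp$lb[members, t_j]) * 1e5
      mean_j <- log(mmr_pred) + delta[, match(inp$dobs$source_id[j], fit$sources)]
      ll[, j] <- stats::dnorm(log(inp$dobs$mmr[j]), mean_j, sd_dir, log = TRUE)
    }
    out$direct <- ll
  }
  ll <- cbind(out$count, out$direct)
  obs_tbl <- dplyr::bind_rows(inp$cobs, inp$dobs)
  list(log_lik = ll, observations = obs_tbl)
}

#' Conditional predictive ordinates for a fitted MMR model
#'
#' The CPO of observation i is its leave-one-out posterior-predictive
#' density: the probability of the held-out record under the model fitted
#' to all other records. Two methods are provided. `importance_weighted`
#' uses the harmonic-mean identity `CPO_i = 1 / E_post[1 / p(y_i | theta)]`
#' on the full-fit draws, with an effective-sample-size guard flagging
#' observations whose importance weights are degenerate.
#' `exact_refit` refits the model without each observation and averages the
#' held-out likelihood over the refit's draws — the gold standard, at
#' one-refit-per-observation cost.
#'
#' @param fit A converged `stage1_fit`.
#' @param method `"importance_weighted"` (default) or `"exact_refit"`.
#' @param ess_threshold Minimum importance-weight effective sample size
#'   before an observation is flagged unstable.
#' @param ess_frac Minimum effective sample size as a fraction of the total
#'   draw count; the inverse-likelihood weights of an extreme observation
#'   have heavy tails, so a low ESS *fraction* signals a degenerate
#'   harmonic mean even when the absolute ESS looks comfortable.
#' @param tail_k_threshold Pareto tail-index cutoff: the shape of the upper
#'   tail of the inverse-likelihood weights is estimated (Hill estimator on
#'   the largest weights) and the observation is flagged when it exceeds
#'   this value — the standard 0.7 rule for unreliable importance-sampling
#'   estimates. This catches heavy tails that still produce a
#'   respectable-looking ESS.
#' @param fallback For the importance-weighted method, recompute flagged
#'   observations by exact refit (default `TRUE`) — the harmonic-mean
#'   estimator is known to be unstable when the held-out likelihood has
#'   heavy inverse tails.
#' @return A `cpo_result` tibble (one row per observation: `unit_id`,
#'   `source_id`, `year`, `cpo`, `log_cpo`, `ess`, `flagged`,
#'   `obs_method`) with attributes `sum_log_cpo` and `method`.
#' @export
compute_cpo <- function(fit, method = c("importance_weighted", "exact_refit"),
                        ess_threshold = 100, ess_frac = 0.025,
                        tail_k_threshold = 0.7, fallback = TRUE) {
  stopifnot(inherits(fit, "stage1_fit"))
  method <- match.arg(method)
  ol <- stage1_obs_likelihood(fit)
  n_obs <- ncol(ol$log_lik)
  obs_all <- dplyr::bind_rows(fit$inputs$cobs, fit$inputs$dobs)

  if (method == "importance_weighted") {
    cpo <- numeric(n_obs); ess <- numeric(n_obs); tail_k <- numeric(n_obs)
    for (i in seq_len(n_obs)) {
      # stabilised harmonic mean: shift by the max inverse-likelihood
      neg <- -ol$log_lik[, i]
      m <- max(neg)
      w <- exp(neg - m)
      cpo[i] <- exp(-(m + log(mean(w))))
      ess[i] <- sum(w)^2 / sum(w^2)
      tail_k[i] <- hill_tail_index(neg)
    }
    flagged <- ess < ess_threshold | ess < ess_frac * nrow(ol$log_lik) |
      tail_k > tail_k_threshold
    obs_method <- rep("importance", n_obs)
    if (fallback && any(flagged)) {
      for (i in which(flagged)) {
        cpo[i] <- exact_cpo_for(fit, obs_all, i)
        obs_method[i] <- "exact_fallback"
      }
    }
  } else {
    cpo <- vapply(seq_len(n_obs), function(i) exact_cpo_for(fit, obs_all, i), 0)
    ess <- rep(NA_real_, n_obs)
    tail_k <- rep(NA_real_, n_obs)
    flagged <- rep(FALSE, n_obs)
    obs_method <- rep("exact", n_obs)
  }

  out <- ol$observations |>
    dplyr::transmute(.data$unit_id, .data$source_id, .data$year) |>
    dplyr::mutate(cpo = cpo, log_cpo = log(cpo), ess = ess, tail_k = tail_k,
                  flagged = flagged, obs_method = obs_method)
  attr(out, "sum_log_cpo") <- sum(out$log_cpo)
  attr(out, "method") <- method
  class(out) <- c("cpo_result", class(out))
  out
}

# Hill estimator of the Pareto tail index of importance weights, given on
# the log scale; uses the canonical ~3*sqrt(S) largest weights. Values
# above ~0.7 mean the weight distribution is too heavy-tailed for the
# harmonic-mean estimator to be trusted.
hill_tail_index <- function(log_w) {
  n <- length(log_w)
  m <- max(5L, min(floor(0.2 * n), ceiling(3 * sqrt(n))))
  top <- sort(log_w, decreasing = TRUE)[seq_len(m + 1L)]
  mean(top[seq_len(m)]) - top[m + 1L]
}

# leave-one-out predictive mass of observation i: refit without it, then
# average the held-out likelihood kernel over the refit's posterior
exact_cpo_for <- function(fit, obs_all, i) {
  refit <- fit_stage1(obs_all[-i, , drop = FALSE],
                      fit$inputs$covariates_tbl,
                      live_births = fit$inputs$live_births_tbl,
                      membership = fit$inputs$membership_tbl,
                      spec = refit_spec(fit$spec, i))
  mean(exp(stage1_obs_likelihood_for(refit, obs_all[i, , drop = FALSE])))
}

refit_spec <- function(spec, i) {
  s <- spec
  s$seed <- sub_seed(spec$seed, "stage1", 1000L + i)
  s
}

# likelihood of an arbitrary held-out observation under an existing fit
stage1_obs_likelihood_for <- function(fit, obs_row) {
  draws <- fit$draws
  Tn <- length(fit$years); r <- draws[, "r"]
  lb_vec <- as.vector(t(fit$inputs$lb))
  td <- exp(fit$log_mmr_draws) * rep(lb_vec, each = nrow(draws)) / 1e5
  members <- switch(obs_row$level,
    district = match(obs_row$unit_id, fit$districts),
    division = which(fit$inputs$data$div == match(obs_row$unit_id, fit$divisions)),
    state = seq_along(fit$districts))
  t_i <- match(obs_row$year, fit$years)
  cols <- (members - 1L) * Tn + t_i
  agg <- rowSums(td[, cols, drop = FALSE])
  s_ix <- match(obs_row$source_id, fit$sources)
  has_delta <- any(grepl("^delta\\[", colnames(draws)))
  dlt <- if (has_delta && !is.na(s_ix) && s_ix > 1) {
    draws[, sprintf("delta[%d]", s_ix)]
  } else {
    0
  }
  if (!is.na(obs_row$mmr)) {
    mmr_pred <- agg / sum(fit$inputs$lb[members, t_i]) * 1e5
    stats::dnorm(log(obs_row$mmr), log(mmr_pred) + dlt, draws[, "sd_dir"], log = TRUE)
  } else {
    nb_log_likelihood(obs_row$deaths, agg * exp(dlt), r)
  }
}

#' Compare competing model specifications by predictive validity
#'
#' Fits each specification to the same data, scores it by the sum of log
#' CPO values (larger is better), and ranks the specifications. Fits whose
#' convergence diagnostics fail are excluded from the ranking with the
#' reason recorded.
#'
#' @param specs List of [stage1_spec()] objects (>= 2).
#' @inheritParams fit_stage1
#' @param method CPO method passed to [compute_cpo()].
#' @return Tibble: `label`, `sum_log_cpo`, `n_flagged`, `converged`,
#'   `rank` (NA for excluded fits), with the per-spec `cpo_result`s in
#'   attribute `details`.
#' @export
compare_models <- function(specs, observations, covariates, live_births,
                           membership, method = "importance_weighted") {
  if (length(specs) < 2) stop_config("need at least 2 specifications to compare")
  rows <- purrr::map(specs, function(sp) {
    fit <- fit_stage1(observations, covariates, live_births, membership, sp)
    # for ranking, unstable observations keep their harmonic-mean value and
    # are counted in n_flagged instead of triggering per-observation refits
    cpo <- compute_cpo(fit, method = method, fallback = FALSE)
    tibble::tibble(label = sp$label,
                   sum_log_cpo = attr(cpo, "sum_log_cpo"),
                   n_flagged = sum(cpo$flagged),
                   converged = fit$converged,
                   details = list(cpo))
  })
  out <- dplyr::bind_rows(rows)
  out$rank <- NA_integer_
  ok <- which(out$converged & is.finite(out$sum_log_cpo))
  out$rank[ok] <- rank(-out$sum_log_cpo[ok], ties.method = "first")
  details <- out$details
  out$details <- NULL
  attr(out, "details") <- details
  dplyr::arrange(out, dplyr::desc(.data$converged), dplyr::desc(.data$sum_log_cpo))
}
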