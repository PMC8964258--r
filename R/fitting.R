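#' Hierarchical prior specification
#'
#' Group-level laws and hyperpriors for the hierarchical fits: learning rates
#' and belief probabilities are drawn from group beta distributions whose two
#' hyperparameters have gamma(1, 1) hyperpriors; the inverse temperature is
#' drawn from a group gamma distribution (shape and rate, each gamma(1, 1));
#' stickiness is drawn from a group normal truncated to `[-1, 1]`, with mean
#' prior N(0, 10) and spread prior half-normal(0, 10).
#'
#' @param beta_hyper_shape,beta_hyper_rate Gamma hyperprior for the beta-law
#'   hyperparameters.
#' @param gamma_hyper_shape,gamma_hyper_rate Gamma hyperprior for the
#'   inverse-temperature group law.
#' @param st_mu_sd Prior SD of the stickiness group mean.
#' @param st_sigma_sd Half-normal scale of the stickiness group SD.
#' @return An object of class `hier_prior_spec`.
#' @export
hier_prior_spec <- function(beta_hyper_shape = 1, beta_hyper_rate = 1,
                            gamma_hyper_shape = 1, gamma_hyper_rate = 1,
                            st_mu_sd = 10, st_sigma_sd = 10) {
  structure(list(beta_hyper_shape = beta_hyper_shape,
                 beta_hyper_rate = beta_hyper_rate,
                 gamma_hyper_shape = gamma_hyper_shape,
                 gamma_hyper_rate = gamma_hyper_rate,
                 st_mu_sd = st_mu_sd, st_sigma_sd = st_sigma_sd),
            class = "hier_prior_spec")
}

#' MCMC settings
#'
#' Defaults follow the full fitting protocol: 4 chains of 5,000 iterations
#' each, the first 1,000 discarded as warm-up. Tests and desk-scale analyses
#' use scaled-down chains (2 chains, 1,000 iterations, 500 warm-up) with the
#' same diagnostic thresholds.
#'
#' @param n_chains Number of chains.
#' @param n_warmup Warm-up iterations per chain (discarded).
#' @param n_iter Total iterations per chain (retained draws =
#'   `n_iter - n_warmup`).
#' @param seed Sampler seed.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 4L, n_warmup = 1000L, n_iter = 5000L,
                          seed = 1L) {
  if (n_iter <= n_warmup) stop("n_iter must exceed n_warmup")
  if (n_chains < 1L) stop("need at least one chain")
  structure(list(n_chains = as.integer(n_chains),
                 n_warmup = as.integer(n_warmup),
                 n_iter = as.integer(n_iter),
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

# Univariate slice sampler (stepping out + shrinkage, Neal 2003). `logf` is
# the log conditional density up to a constant; `w` the initial bracket
# width; the support is clipped to [lower, upper].
slice_sample1 <- function(x0, logf, w, lower = -Inf, upper = Inf,
                          max_step = 20L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started at a zero-density point")
  y <- f0 - stats::rexp(1)
  L <- x0 - stats::runif(1) * w
  R <- L + w
  j <- floor(stats::runif(1) * max_step)
  k <- max_step - 1L - j
  while (j > 0L && L > lower && logf(L) > y) { L <- L - w; j <- j - 1L }
  while (k > 0L && R < upper && logf(R) > y) { R <- R + w; k <- k - 1L }
  L <- max(L, lower); R <- min(R, upper)
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

# Log-densities of the group laws under the (mean, concentration) /
# (mean, shape) reparameterization, with the exact gamma(1,1) hyperpriors on
# the natural hyperparameters mapped through the Jacobian.
logp_group_beta <- function(v, mu, kap) {
  sum(stats::dbeta(v, mu * kap, (1 - mu) * kap, log = TRUE))
}
logprior_beta_hyper <- function(mu, kap, pr) {
  stats::dgamma(mu * kap, pr$beta_hyper_shape, pr$beta_hyper_rate, log = TRUE) +
    stats::dgamma((1 - mu) * kap, pr$beta_hyper_shape, pr$beta_hyper_rate,
                  log = TRUE) + log(kap)
}
logp_group_gamma <- function(v, m, k) {
  sum(stats::dgamma(v, shape = k, rate = k / m, log = TRUE))
}
logprior_gamma_hyper <- function(m, k, pr) {
  stats::dgamma(k, pr$gamma_hyper_shape, pr$gamma_hyper_rate, log = TRUE) +
    stats::dgamma(k / m, pr$gamma_hyper_shape, pr$gamma_hyper_rate,
                  log = TRUE) + log(k) - 2 * log(m)
}
logp_group_st <- function(v, mu, sig) sum(dtnorm(v, mu, sig, -1, 1, log = TRUE))
logprior_st_hyper <- function(mu, sig, pr) {
  stats::dnorm(mu, 0, pr$st_mu_sd, log = TRUE) +
    stats::dnorm(sig, 0, pr$st_sigma_sd, log = TRUE)
}

# Parameter layout for a model + restrictions: which subject-level parameters
# are sampled, their supports, slice widths, and group-law types.
model_layout <- function(model, restrictions) {
  eps <- 1e-9
  if (model == "rl") {
    defs <- list(
      alpha_pos = list(type = "beta", lo = eps, hi = 1 - eps, w = 0.15,
                       init = c(0.3, 0.8)),
      alpha_neg = list(type = "beta", lo = eps, hi = 1 - eps, w = 0.15,
                       init = c(0.2, 0.7)),
      beta = list(type = "gamma", lo = eps, hi = Inf, w = 1.5,
                  init = c(2, 8)),
      st = list(type = "st", lo = -1 + eps, hi = 1 - eps, w = 0.25,
                init = c(-0.1, 0.3)))
    if ("shared_alpha" %in% restrictions) defs$alpha_neg <- NULL
    if ("no_stickiness" %in% restrictions) defs$st <- NULL
  } else {
    defs <- list(
      p_reward = list(type = "beta", lo = eps, hi = 1 - eps, w = 0.1,
                      init = c(0.6, 0.9)),
      p_switch = list(type = "beta", lo = eps, hi = 1 - eps, w = 0.08,
                      init = c(0.03, 0.3)),
      beta = list(type = "gamma", lo = eps, hi = Inf, w = 1.5,
                  init = c(2, 8)),
      st = list(type = "st", lo = -1 + eps, hi = 1 - eps, w = 0.25,
                init = c(-0.1, 0.3)))
  }
  defs
}

# Subject log-likelihood dispatcher; th is the named list of that subject's
# current parameter values with restrictions already resolved.
make_subject_loglik <- function(model, restrictions, blocks) {
  counterfactual <- !("no_counterfactual" %in% restrictions)
  shared <- "shared_alpha" %in% restrictions
  no_st <- "no_stickiness" %in% restrictions
  if (model == "rl") {
    function(j, th) {
      .rl_loglik_cpp(blocks[[j]], th$alpha_pos,
                     if (shared) th$alpha_pos else th$alpha_neg,
                     th$beta, if (no_st) 0 else th$st,
                     counterfactual, FALSE)[1]
    }
  } else {
    function(j, th) {
      .bi_loglik_cpp(blocks[[j]], th$p_reward, th$p_switch, th$beta, th$st,
                     1e-4, FALSE)[1]
    }
  }
}

# One MCMC chain. Data preparation, initialization and column naming live
# here; the sampling kernel itself (random-direction slice moves over subject
# parameters in transformed coordinates, componentwise hyper updates, and
# reparameterized translation/scale group moves) is compiled C++
# (src/sampler.cpp), driven by R's RNG so the chain seed fixes every draw.
run_chain <- function(blocks, model, restrictions, priors, n_iter, n_warmup,
                      chain_seed) {
  defs <- model_layout(model, restrictions)
  n <- length(blocks)
  pn <- names(defs)
  types <- vapply(pn, function(p) switch(defs[[p]]$type,
                                         beta = 0L, gamma = 1L, st = 2L), 0L)
  full_order <- if (model == "rl") c("alpha_pos", "alpha_neg", "beta", "st")
                else c("p_reward", "p_switch", "beta", "st")
  pmap <- match(full_order, pn) - 1L
  pmap[is.na(pmap)] <- -1L
  subjects <- lapply(blocks, function(bl) {
    ch <- lapply(bl, `[[`, "choice")
    list(choice = as.integer(unlist(ch, use.names = FALSE)),
         reward = as.integer(unlist(lapply(bl, `[[`, "reward"),
                                    use.names = FALSE)),
         block_start = as.integer(c(0L, cumsum(lengths(ch)))))
  })
  # random-direction step scales in transformed coordinates, by law type
  dir_scale <- c(1.0, 0.3, 0.4)[types + 1L]
  prior_consts <- c(priors$beta_hyper_shape, priors$beta_hyper_rate,
                    priors$gamma_hyper_shape, priors$gamma_hyper_rate,
                    priors$st_mu_sd, priors$st_sigma_sd)

  col_names <- c(unlist(lapply(pn, function(p) paste0(p, "[", seq_len(n), "]"))),
                 unlist(lapply(pn, function(p) {
                   switch(defs[[p]]$type,
                          beta = paste0(c("mu_", "kappa_"), p),
                          gamma = c("mean_beta", "shape_beta"),
                          st = c("mu_st", "sigma_st"))
                 })))

  with_local_seed(chain_seed, {
    theta0 <- vapply(defs, function(d) stats::runif(n, d$init[1], d$init[2]),
                     numeric(n))
    if (n == 1L) theta0 <- matrix(theta0, nrow = 1L)
    hyper0 <- unlist(lapply(pn, function(p) {
      switch(defs[[p]]$type,
             beta = c(clip(mean(theta0[, p]), 0.05, 0.95), 5),
             gamma = c(mean(theta0[, p]), 3),
             st = c(mean(theta0[, p]), 0.4))
    }), use.names = FALSE)
    draws <- .hier_chain_cpp(subjects, if (model == "rl") 0L else 1L,
                             !("no_counterfactual" %in% restrictions),
                             unname(types), pmap, prior_consts,
                             theta0, hyper0, dir_scale,
                             as.integer(n_iter), as.integer(n_warmup), 6L, 6L)
    dimnames(draws) <- list(NULL, col_names)
    draws
  })
}

split_sequences <- function(chains, col) {
  out <- list()
  for (m in chains) {
    x <- m[, col]
    n2 <- floor(length(x) / 2)
    out <- c(out, list(x[seq_len(n2)], x[(length(x) - n2 + 1):length(x)]))
  }
  out
}

#' Split-Rhat convergence diagnostic
#'
#' Potential scale reduction factor computed over split chains (each chain
#' halved), the standard between/within-chain variance ratio.
#'
#' @param chains List of draw matrices (one per chain, same columns) or a
#'   list of numeric vectors for a single parameter.
#' @return Named vector of Rhat values (one per parameter).
#' @export
split_rhat <- function(chains) {
  if (is.numeric(chains[[1]]) && is.null(dim(chains[[1]]))) {
    chains <- lapply(chains, function(x) matrix(x, ncol = 1,
                                                dimnames = list(NULL, "x")))
  }
  cols <- colnames(chains[[1]])
  vapply(cols, function(cl) {
    seqs <- split_sequences(chains, cl)
    n <- length(seqs[[1]])
    means <- vapply(seqs, mean, 0)
    vars <- vapply(seqs, stats::var, 0)
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, 0)
}

#' Effective sample size
#'
#' Stan-style effective sample size over split chains: combined lag
#' autocorrelations from per-chain autocovariances, truncated by Geyer's
#' initial positive-pair rule.
#'
#' @inheritParams split_rhat
#' @return Named vector of ESS values.
#' @export
effective_sample_size <- function(chains) {
  if (is.numeric(chains[[1]]) && is.null(dim(chains[[1]]))) {
    chains <- lapply(chains, function(x) matrix(x, ncol = 1,
                                                dimnames = list(NULL, "x")))
  }
  cols <- colnames(chains[[1]])
  vapply(cols, function(cl) {
    seqs <- split_sequences(chains, cl)
    n <- length(seqs[[1]])
    m <- length(seqs)
    vars <- vapply(seqs, stats::var, 0)
    means <- vapply(seqs, mean, 0)
    W <- mean(vars)
    B <- n * stats::var(means)
    var_plus <- (n - 1) / n * W + B / n
    if (var_plus == 0 || W == 0) return(m * n)
    acov <- vapply(seqs, function(x) {
      stats::acf(x, lag.max = n - 1, type = "covariance",
                 plot = FALSE)$acf[, 1, 1] * (n - 1) / n
    }, numeric(n))
    rho <- 1 - (W - rowMeans(acov)[-1]) / var_plus  # lags 1 .. n-1
    tau <- 1
    t <- 1
    while (t + 1 <= length(rho)) {
      pair <- rho[t] + rho[t + 1]
      if (!is.finite(pair) || pair < 0) break
      tau <- tau + 2 * pair
      t <- t + 2
    }
    max(m * n / tau, 1)
  }, 0)
}

# Pointwise per-trial log-likelihood draws for WAIC; rows = (thinned)
# posterior draws across all chains, columns = responded trials in subject
# then trial order.
pointwise_loglik_matrix <- function(chains, model, restrictions, blocks,
                                    subject_ids, max_draws = 1000L) {
  all_draws <- do.call(rbind, chains)
  S <- nrow(all_draws)
  keep <- if (S > max_draws) round(seq(1, S, length.out = max_draws)) else seq_len(S)
  defs <- model_layout(model, restrictions)
  pn <- names(defs)
  counterfactual <- !("no_counterfactual" %in% restrictions)
  shared <- "shared_alpha" %in% restrictions
  no_st <- "no_stickiness" %in% restrictions
  n_trials <- vapply(blocks, function(b) sum(vapply(b, function(x)
    length(x$choice), 0L)), 0L)
  out <- matrix(NA_real_, length(keep), sum(n_trials))
  for (s in seq_along(keep)) {
    row <- all_draws[keep[s], ]
    off <- 0L
    for (j in seq_along(blocks)) {
      th <- lapply(pn, function(p) row[[paste0(p, "[", j, "]")]])
      names(th) <- pn
      ll <- if (model == "rl") {
        .rl_loglik_cpp(blocks[[j]], th$alpha_pos,
                       if (shared) th$alpha_pos else th$alpha_neg,
                       th$beta, if (no_st) 0 else th$st,
                       counterfactual, TRUE)
      } else {
        .bi_loglik_cpp(blocks[[j]], th$p_reward, th$p_switch, th$beta,
                       th$st, 1e-4, TRUE)
      }
      out[s, off + seq_along(ll)] <- ll
      off <- off + length(ll)
    }
  }
  out
}

#' Fit a hierarchical choice model by MCMC
#'
#' Hierarchical Bayesian estimation of the RL or BI model: subject-level
#' parameters are drawn from group-level distributions (beta for rates and
#' probabilities, gamma for the inverse temperature, truncated normal for
#' stickiness) whose hyperparameters carry the [hier_prior_spec()]
#' hyperpriors. Sampling is slice-within-Gibbs over all subject- and
#' group-level parameters, with the session likelihoods evaluated in
#' compiled code. Convergence is assessed by split-Rhat and effective sample
#' size per parameter; a fit is flagged converged when max Rhat < 1.01 and
#' min ESS > 40 (slice sampling has no divergent-transition failure mode, so
#' the divergence count is structurally zero).
#'
#' @param logs A `trial_log` covering two or more participants.
#' @param model `"rl"` or `"bi"`.
#' @param priors A [hier_prior_spec()].
#' @param settings An [mcmc_settings()].
#' @param restrictions RL nested variants: any of `"shared_alpha"`,
#'   `"no_stickiness"`, `"no_counterfactual"`.
#' @param max_pointwise_draws Cap on posterior draws retained for the
#'   pointwise WAIC log-likelihood matrix (evenly thinned).
#' @return An object of class `hier_fit`: per-chain draw matrices,
#'   per-subject posterior-mean estimates, a diagnostics table, the
#'   pointwise log-likelihood draws, and the WAIC inputs.
#' @export
fit_hierarchical <- function(logs, model = c("rl", "bi"),
                             priors = hier_prior_spec(),
                             settings = mcmc_settings(),
                             restrictions = character(0),
                             max_pointwise_draws = 1000L) {
  model <- match.arg(model)
  validate_trial_log(logs, warn_reward_incorrect = FALSE)
  ids <- unique(logs$participant_id)
  blocks <- list()
  kept <- character()
  for (pid in ids) {
    bl <- log_to_blocks(logs[logs$participant_id == pid, ], warn = FALSE)
    bl <- Filter(function(b) length(b$choice) > 0L, bl)
    if (!length(bl)) {
      warning("participant ", pid, " has no responded trials; excluded")
    } else {
      blocks[[pid]] <- bl
      kept <- c(kept, pid)
    }
  }
  if (length(kept) < 2L) stop("need at least 2 participants with responses")

  chains <- lapply(seq_len(settings$n_chains), function(cc) {
    run_chain(blocks, model, restrictions, priors,
              settings$n_iter, settings$n_warmup,
              derive_seed(settings$seed, "chain", cc))
  })

  rhat <- split_rhat(chains)
  ess <- effective_sample_size(chains)
  diagnostics <- tibble::tibble(parameter = names(rhat),
                                rhat = unname(rhat), ess = unname(ess))
  all_draws <- do.call(rbind, chains)
  post_mean <- colMeans(all_draws)

  defs <- model_layout(model, restrictions)
  est <- tibble::tibble(participant_id = kept)
  for (p in names(defs)) {
    est[[p]] <- unname(post_mean[paste0(p, "[", seq_along(kept), "]")])
  }
  if (model == "rl") {  # restricted parameters on their implied values
    if ("shared_alpha" %in% restrictions) est$alpha_neg <- est$alpha_pos
    if ("no_stickiness" %in% restrictions) est$st <- 0
    est <- est[, c("participant_id", "alpha_pos", "alpha_neg", "beta", "st")]
  }
  pw <- pointwise_loglik_matrix(chains, model, restrictions, blocks, kept,
                                max_pointwise_draws)
  structure(list(model = model,
                 restrictions = restrictions,
                 chains = chains,
                 estimates = est,
                 group_means = post_mean[setdiff(names(post_mean),
                                                 grep("\\[", names(post_mean),
                                                      value = TRUE))],
                 diagnostics = diagnostics,
                 n_divergent = 0L,
                 converged = max(rhat) < 1.01 && min(ess) > 40,
                 pointwise_loglik = pw,
                 participant_ids = kept,
                 settings = settings,
                 priors = priors),
            class = "hier_fit")
}

#' @export
print.hier_fit <- function(x, ...) {
  cat("<hier_fit> ", toupper(x$model), " model",
      if (length(x$restrictions)) paste0(" [", paste(x$restrictions,
                                                     collapse = ", "), "]"),
      ": ", length(x$participant_ids), " participants, ",
      length(x$chains), " chains x ",
      nrow(x$chains[[1]]), " retained draws\n", sep = "")
  cat(sprintf("max Rhat = %.4f, min ESS = %.1f, divergences = %d -> %s\n",
              max(x$diagnostics$rhat), min(x$diagnostics$ess), x$n_divergent,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Watanabe-Akaike information criterion
#'
#' Computed from pointwise posterior log-likelihood draws, averaging over the
#' posterior rather than conditioning on a point estimate: per observation
#' `lppd_i = log mean_s exp(ll_si)` and `p_i = Var_s(ll_si)`;
#' `WAIC = -2 * sum(lppd_i - p_i)` with standard error
#' `sqrt(N * Var_i(waic_i))`.
#'
#' @param x A `hier_fit`, or a draws-by-observations matrix of pointwise
#'   log-likelihoods.
#' @return List of class `waic_result` with `waic`, `se`, `lppd`, `p_waic`,
#'   `elpd` and the pointwise contributions.
#' @export
compute_waic <- function(x) {
  ll <- if (inherits(x, "hier_fit")) x$pointwise_loglik else as.matrix(x)
  if (is.null(ll) || !nrow(ll)) stop("pointwise log-likelihood draws required")
  mx <- apply(ll, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(ll, 2, mx))))
  p_i <- apply(ll, 2, stats::var)
  waic_i <- -2 * (lppd_i - p_i)
  structure(list(waic = sum(waic_i),
                 se = sqrt(length(waic_i) * stats::var(waic_i)),
                 lppd = sum(lppd_i), p_waic = sum(p_i),
                 elpd = sum(lppd_i - p_i),
                 pointwise = tibble::tibble(lppd = lppd_i, p = p_i,
                                            waic = waic_i)),
            class = "waic_result")
}

#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("WAIC = %.2f (SE %.2f); lppd = %.2f, p_waic = %.2f\n",
              x$waic, x$se, x$lppd, x$p_waic))
  invisible(x)
}

#' Generate-and-recover harness
#'
#' Simulates a cohort from known group laws, refits the model, and reports
#' the truth-versus-estimate correlation for every subject-level parameter —
#' the standard check that model parameters are recoverable at the design's
#' trial counts.
#'
#' @param model `"rl"` or `"bi"`.
#' @param n_participants,blocks_per Cohort design.
#' @param seed Seed driving both generation and fitting.
#' @param group_laws Generating group laws (defaults to
#'   [default_group_laws()]).
#' @param settings [mcmc_settings()] for the refit (scaled-down default).
#' @param restrictions Passed to [fit_hierarchical()].
#' @return List of class `recovery_report`: `comparison` (tibble of truth and
#'   estimates), `correlations` (named vector), and the underlying `fit`.
#' @export
generate_and_recover <- function(model = c("rl", "bi"), n_participants = 20L,
                                 blocks_per = 2L, seed = 1L,
                                 group_laws = NULL,
                                 settings = mcmc_settings(2L, 500L, 1000L,
                                                          seed = seed),
                                 restrictions = character(0)) {
  model <- match.arg(model)
  spec <- cohort_spec(n_participants = n_participants,
                      blocks_per_participant = blocks_per,
                      generating_model = model,
                      group_laws = group_laws,
                      seed = derive_seed(seed, "gen"))
  cohort <- generate_cohort(spec)
  fit <- fit_hierarchical(cohort$trial_log, model, settings = settings,
                          restrictions = restrictions)
  truth <- cohort$params
  est <- fit$estimates
  pn <- setdiff(names(truth), "participant_id")
  comparison <- dplyr::left_join(truth, est, by = "participant_id",
                                 suffix = c("_true", "_est"))
  correlations <- vapply(pn, function(p) {
    e <- est[[p]][match(truth$participant_id, est$participant_id)]
    if (stats::sd(e) == 0 || stats::sd(truth[[p]]) == 0) return(NA_real_)
    stats::cor(truth[[p]], e)
  }, 0)
  structure(list(comparison = comparison, correlations = correlations,
                 fit = fit, cohort = cohort),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> truth-estimate correlations:\n")
  print(round(x$correlations, 3))
  invisible(x)
}

#' Posterior predictive check
#'
#' Simulates fresh sessions for every fitted participant using their
#' posterior-mean point estimates, then computes the model-free behavioral
#' summaries (switch-aligned accuracy, 3-back stay table, 1-back stay
#' probability after no reward, per-participant performance) for the real and
#' simulated data side by side.
#'
#' @param fit A `hier_fit`.
#' @param logs The `trial_log` the model was fitted to.
#' @param config Task configuration for the fresh sessions.
#' @param seed Simulation seed.
#' @return List of class `ppc` with elements `real` and `simulated`, each a
#'   list of behavioral summaries.
#' @export
posterior_predictive_check <- function(fit, logs, config = task_config(),
                                       seed = 1L) {
  est <- fit$estimates
  n_blocks <- vapply(est$participant_id, function(pid) {
    length(unique(logs$block_id[logs$participant_id == pid]))
  }, 0L)
  sim_logs <- with_local_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(est))) {
      params <- if (fit$model == "rl") {
        rl_params(est$alpha_pos[i], est$alpha_neg[i], est$beta[i], est$st[i])
      } else {
        bi_params(est$p_reward[i], est$p_switch[i], est$beta[i], est$st[i])
      }
      policy <- agent_policy(params)
      for (b in seq_len(n_blocks[i])) {
        version <- ((i + b - 2L) %% config$n_sequence_versions) + 1L
        out[[length(out) + 1L]] <- run_session(
          build_block_schedule(config, version), config, policy,
          participant_id = est$participant_id[i], block_id = b)
      }
    }
    dplyr::bind_rows(out)
  })
  class(sim_logs) <- c("trial_log", class(sim_logs))
  summarize <- function(lg) {
    list(switch_curve = switch_aligned_accuracy(lg),
         table_3back = stay_table_3back(lg),
         p_stay_unrewarded = stay_probability_1back(lg, "unrewarded"),
         performance = overall_performance(lg, by_participant = TRUE))
  }
  structure(list(real = summarize(logs), simulated = summarize(sim_logs),
                 simulated_log = sim_logs),
            class = "ppc")
}
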