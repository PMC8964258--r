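# Fitting machinery: WAIC against a hand-computed table, diagnostic
# statistics on constructed chains, the slice sampler against a known
# density, restriction handling, and small smoke fits. The mandated
# 20-participant convergence/recovery runs live in test-acceptance.R.

test_that("settings and prior constructors validate", {
  s <- mcmc_settings(2, 500, 1000)
  expect_equal(s$n_iter - s$n_warmup, 500L)
  expect_error(mcmc_settings(2, 1000, 1000))
  expect_error(mcmc_settings(0, 10, 20))
  expect_s3_class(hier_prior_spec(), "hier_prior_spec")
})

test_that("WAIC matches a hand-computed 3-observation, 4-draw table", {
  ll <- matrix(c(-1.0, -1.2, -0.8, -1.1,   # obs 1 over 4 draws
                 -2.0, -1.7, -2.2, -1.9,   # obs 2
                 -0.5, -0.6, -0.4, -0.5),  # obs 3
               nrow = 4)
  # hand computation, written out long-form
  lppd1 <- log((exp(-1.0) + exp(-1.2) + exp(-0.8) + exp(-1.1)) / 4)
  lppd2 <- log((exp(-2.0) + exp(-1.7) + exp(-2.2) + exp(-1.9)) / 4)
  lppd3 <- log((exp(-0.5) + exp(-0.6) + exp(-0.4) + exp(-0.5)) / 4)
  v <- function(x) sum((x - mean(x))^2) / 3
  p1 <- v(c(-1.0, -1.2, -0.8, -1.1))
  p2 <- v(c(-2.0, -1.7, -2.2, -1.9))
  p3 <- v(c(-0.5, -0.6, -0.4, -0.5))
  by_hand <- -2 * ((lppd1 - p1) + (lppd2 - p2) + (lppd3 - p3))
  w <- compute_waic(ll)
  expect_equal(w$waic, by_hand, tolerance = 1e-10)
  expect_equal(w$lppd, lppd1 + lppd2 + lppd3, tolerance = 1e-10)
  expect_equal(w$p_waic, p1 + p2 + p3, tolerance = 1e-10)
  pointwise_waic <- -2 * (c(lppd1, lppd2, lppd3) - c(p1, p2, p3))
  expect_equal(w$se, sqrt(3 * stats::var(pointwise_waic)), tolerance = 1e-10)
  # identical draws -> identical WAIC (determinism given draws)
  expect_identical(compute_waic(ll)$waic, w$waic)
})

test_that("WAIC equals the independent long-way oracle on random tables", {
  set.seed(41)
  ll <- matrix(-rexp(50 * 12), nrow = 50)
  w <- compute_waic(ll)
  ora <- oracle_waic(ll)
  expect_equal(w$waic, ora$waic, tolerance = 1e-10)
  expect_equal(w$se, ora$se, tolerance = 1e-10)
  expect_equal(w$lppd, ora$lppd, tolerance = 1e-10)
  expect_equal(w$p_waic, ora$p_waic, tolerance = 1e-10)
})

test_that("split-Rhat separates mixed from unmixed chains", {
  set.seed(42)
  a <- rnorm(2000); b <- rnorm(2000)
  expect_lt(split_rhat(list(a, b))[["x"]], 1.01)
  # chains exploring different regions
  expect_gt(split_rhat(list(a, b + 3))[["x"]], 1.5)
  # within-chain drift is caught by the split
  drifting <- c(rnorm(1000, 0), rnorm(1000, 3))
  expect_gt(split_rhat(list(drifting, drifting))[["x"]], 1.5)
  # matrix interface keeps parameter names
  m1 <- cbind(p1 = a, p2 = b)
  m2 <- cbind(p1 = rnorm(2000), p2 = rnorm(2000))
  r <- split_rhat(list(m1, m2))
  expect_named(r, c("p1", "p2"))
})

test_that("effective sample size reflects autocorrelation", {
  set.seed(43)
  iid <- list(rnorm(1000), rnorm(1000))
  e_iid <- effective_sample_size(iid)[["x"]]
  expect_gt(e_iid, 1200)  # near the nominal 2000
  ar <- function(n, phi) {
    x <- numeric(n)
    for (t in 2:n) x[t] <- phi * x[t - 1] + rnorm(1)
    x
  }
  e_ar <- effective_sample_size(list(ar(1000, 0.95), ar(1000, 0.95)))[["x"]]
  expect_lt(e_ar, e_iid / 5)
  expect_gte(e_ar, 1)
})

test_that("the slice sampler samples a known density correctly", {
  set.seed(44)
  x <- 0.3
  draws <- numeric(4000)
  for (i in seq_along(draws)) {
    x <- probswitch:::slice_sample1(x, function(z) -z^2 / 2, w = 1)
    draws[i] <- x
  }
  expect_lt(abs(mean(draws)), 0.08)
  expect_lt(abs(stats::sd(draws) - 1), 0.08)
  # bounded support is respected
  x <- 0.5
  b <- replicate(500, {
    x <<- probswitch:::slice_sample1(x, function(z) 0, w = 0.5,
                                     lower = 0, upper = 1)
    x
  })
  expect_true(all(b >= 0 & b <= 1))
  expect_error(probswitch:::slice_sample1(0, function(z) -Inf, w = 1),
               "zero-density")
})

test_that("model layout honors restrictions", {
  full <- probswitch:::model_layout("rl", character(0))
  expect_named(full, c("alpha_pos", "alpha_neg", "beta", "st"))
  expect_named(probswitch:::model_layout("rl", "shared_alpha"),
               c("alpha_pos", "beta", "st"))
  expect_named(probswitch:::model_layout("rl", "no_stickiness"),
               c("alpha_pos", "alpha_neg", "beta"))
  expect_named(probswitch:::model_layout("bi", character(0)),
               c("p_reward", "p_switch", "beta", "st"))
})

test_that("restricted subject likelihoods collapse to the right model", {
  set.seed(45)
  ch <- sample(0:1, 20, replace = TRUE)
  rw <- sample(0:1, 20, replace = TRUE)
  log <- make_hand_log(ch, rw)
  blocks <- list(s1 = probswitch:::log_to_blocks(log))
  th <- list(alpha_pos = 0.6, alpha_neg = 0.99, beta = 4, st = 0.4)
  ll_shared <- probswitch:::make_subject_loglik("rl", "shared_alpha",
                                                blocks)(1, th)
  expect_equal(ll_shared,
               session_loglik(log, rl_params(0.6, 0.6, 4, 0.4)),
               tolerance = 1e-12)
  ll_nost <- probswitch:::make_subject_loglik("rl", "no_stickiness",
                                              blocks)(1, th)
  expect_equal(ll_nost,
               session_loglik(log, rl_params(0.6, 0.99, 4, 0)),
               tolerance = 1e-12)
  ll_nocf <- probswitch:::make_subject_loglik("rl", "no_counterfactual",
                                              blocks)(1, th)
  expect_equal(ll_nocf,
               session_loglik(log, rl_params(0.6, 0.99, 4, 0.4),
                              counterfactual = FALSE),
               tolerance = 1e-12)
})

smoke_cohort <- function(n = 4L, seed = 301L) {
  generate_cohort(cohort_spec(n_participants = n, blocks_per_participant = 1L,
                              generating_model = "rl", seed = seed))
}

test_that("a small hierarchical fit has coherent structure", {
  co <- smoke_cohort()
  fit <- fit_hierarchical(co$trial_log, "rl",
                          settings = mcmc_settings(2, 100, 250, seed = 5))
  expect_s3_class(fit, "hier_fit")
  expect_length(fit$chains, 2L)
  expect_equal(nrow(fit$chains[[1]]), 150L)
  # columns: 4 params x 4 subjects + 8 hyper columns
  expect_equal(ncol(fit$chains[[1]]), 4L * 4L + 8L)
  expect_equal(fit$estimates$participant_id, co$params$participant_id)
  expect_true(all(c("alpha_pos", "alpha_neg", "beta", "st") %in%
                    names(fit$estimates)))
  expect_true(all(fit$estimates$alpha_pos > 0 & fit$estimates$alpha_pos < 1))
  expect_equal(fit$n_divergent, 0L)
  expect_equal(nrow(fit$diagnostics), ncol(fit$chains[[1]]))
  # pointwise matrix spans every responded trial
  expect_equal(ncol(fit$pointwise_loglik), sum(co$trial_log$responded))
  expect_true(all(is.finite(fit$pointwise_loglik)))
  expect_true(all(fit$pointwise_loglik <= 0))
  expect_true(is.finite(compute_waic(fit)$waic))
  # identical settings and seed reproduce the chains bit-identically
  fit2 <- fit_hierarchical(co$trial_log, "rl",
                           settings = mcmc_settings(2, 100, 250, seed = 5))
  expect_identical(fit$chains, fit2$chains)
})

test_that("restricted fits pin the restricted parameters", {
  co <- smoke_cohort(3L, seed = 302L)
  fit <- fit_hierarchical(co$trial_log, "rl",
                          settings = mcmc_settings(1, 60, 140, seed = 6),
                          restrictions = c("shared_alpha", "no_stickiness"))
  expect_identical(fit$estimates$alpha_neg, fit$estimates$alpha_pos)
  expect_true(all(fit$estimates$st == 0))
  expect_equal(ncol(fit$chains[[1]]), 2L * 3L + 4L)
})

test_that("participants with no responses are excluded with a warning", {
  co <- smoke_cohort(3L, seed = 303L)
  idle <- co$trial_log[co$trial_log$participant_id == "p001", ]
  idle$participant_id <- "idle"
  idle$chosen_side <- NA_character_
  idle$rewarded <- NA_integer_
  idle$responded <- FALSE
  logs <- dplyr::bind_rows(co$trial_log, idle)
  class(logs) <- c("trial_log", class(tibble::tibble()))
  expect_warning(
    fit <- fit_hierarchical(logs, "rl",
                            settings = mcmc_settings(1, 40, 90, seed = 7)),
    "no responded")
  expect_false("idle" %in% fit$estimates$participant_id)
  expect_error(
    suppressWarnings(fit_hierarchical(logs[logs$participant_id %in%
                                             c("p001", "idle"), ], "rl")),
    "at least 2")
})

test_that("posterior predictive checks return paired summaries", {
  co <- smoke_cohort(3L, seed = 304L)
  fit <- fit_hierarchical(co$trial_log, "rl",
                          settings = mcmc_settings(1, 50, 120, seed = 8))
  ppc <- posterior_predictive_check(fit, co$trial_log, seed = 2L)
  expect_named(ppc$real, c("switch_curve", "table_3back",
                           "p_stay_unrewarded", "performance"))
  expect_named(ppc$simulated, names(ppc$real))
  expect_setequal(unique(ppc$simulated_log$participant_id),
                  fit$estimates$participant_id)
  expect_equal(nrow(ppc$simulated_log),
               nrow(co$trial_log))  # same design: 3 participants x 1 block
  expect_true(all(ppc$simulated$performance$accuracy >= 0 &
                    ppc$simulated$performance$accuracy <= 1))
})
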