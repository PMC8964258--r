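# Questionnaire scoring, reliability, gated correlations, history-design
# coding, GLMM recovery on known-coefficient simulations, median splits,
# and the Bonferroni gate.

raw_for_scored <- function(scored, schema = supps_schema()) {
  # invert the scoring map: raw = 5 - scored on reverse items
  raw <- scored
  raw[schema$reverse_items] <- 5L - scored[schema$reverse_items]
  raw
}

test_that("schema validation rejects malformed layouts", {
  expect_s3_class(supps_schema(), "supps_schema")
  expect_error(supps_schema(reverse_items = c(0, 3)))
  expect_error(supps_schema(subscale_map = list(a = 1:10, b = 11:20)))
  bad_map <- list(a = 1:4, b = 5:8, c = 9:12, d = 13:16, e = c(17:19, 19))
  expect_error(supps_schema(subscale_map = bad_map))
})

test_that("scoring attains the printed extremes 80 and 20", {
  hi <- raw_for_scored(rep(4L, 20))
  lo <- raw_for_scored(rep(1L, 20))
  sc <- score_supps(rbind(hi, lo))
  expect_equal(sc$total, c(80L, 20L))
  # subscales partition the total
  subs <- as.matrix(sc[, names(supps_schema()$subscale_map)])
  expect_equal(rowSums(subs), c(80, 20), ignore_attr = TRUE)
  expect_true(all(subs >= 4 & subs <= 16))
})

test_that("hand-built responses score to the hand sum", {
  schema <- supps_schema()
  # reverse items 5, 6, 7 answered "1" contribute 4 each
  raw <- rep(2L, 20)
  raw[c(5, 6, 7)] <- 1L
  scored <- raw
  scored[schema$reverse_items] <- 5L - raw[schema$reverse_items]
  expect_equal(scored[c(5, 6, 7)], c(4L, 4L, 4L))
  sc <- score_supps(matrix(raw, nrow = 1), schema)
  expect_equal(sc$total, sum(scored))
})

test_that("scoring validates inputs and z-scores the cohort", {
  expect_error(score_supps(matrix(1L, 2, 19)), "20 item")
  bad <- matrix(2L, 2, 20); bad[1, 3] <- 5L
  expect_error(score_supps(bad), "1..4", fixed = TRUE)
  bad[1, 3] <- NA
  expect_error(score_supps(bad), "missing")
  set.seed(8)
  m <- matrix(sample(1:4, 20 * 12, replace = TRUE), 12, 20)
  sc <- score_supps(m)
  expect_equal(mean(sc$z_total), 0, tolerance = 1e-12)
  expect_equal(stats::sd(sc$z_total), 1, tolerance = 1e-12)
  # data-frame input with ids
  df <- data.frame(participant_id = c("a", "b"),
                   matrix(2L, 2, 20, dimnames = list(NULL, paste0("i", 1:20))))
  expect_equal(score_supps(df)$participant_id, c("a", "b"))
})

test_that("reverse coding is an involution", {
  set.seed(9)
  m <- matrix(sample(1:4, 20 * 6, replace = TRUE), 6, 20)
  expect_equal(unname(reverse_code(reverse_code(m))), unname(m),
               ignore_attr = TRUE)
})

test_that("Cronbach's alpha matches hand computation and limits", {
  # duplicated items are perfectly consistent
  set.seed(10)
  x <- rnorm(30)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1, tolerance = 1e-12)
  # independent items, large n -> alpha near 0
  big <- matrix(rnorm(4 * 4000), ncol = 4)
  expect_lt(abs(cronbach_alpha(big)), 0.1)
  # 4-item x 5-participant hand table against the formula written out
  tab <- matrix(c(1, 2, 3, 4, 2,
                  2, 2, 4, 3, 1,
                  1, 3, 3, 4, 2,
                  2, 1, 4, 4, 3), nrow = 5)
  k <- 4
  by_hand <- (k / (k - 1)) *
    (1 - sum(apply(tab, 2, stats::var)) / stats::var(rowSums(tab)))
  expect_equal(cronbach_alpha(tab), by_hand, tolerance = 1e-12)
  expect_error(cronbach_alpha(matrix(1, 3, 3)), "zero total")
})

test_that("the normality gate picks Pearson or Spearman correctly", {
  set.seed(11)
  x <- rnorm(70); y <- 0.5 * x + rnorm(70)
  g <- gated_correlation(x, y)
  expect_equal(g$method, "pearson")
  expect_equal(g$estimate, unname(stats::cor.test(x, y)$estimate),
               tolerance = 1e-12)
  # heavy skew trips the Shapiro-Wilk gate
  ys <- exp(2 * rnorm(70))
  g2 <- gated_correlation(x, ys)
  expect_lt(stats::shapiro.test(ys)$p.value, 0.05)  # gate recomputed
  expect_equal(g2$method, "spearman")
  expect_equal(g2$estimate,
               unname(stats::cor.test(x, ys, method = "spearman",
                                      exact = FALSE)$estimate),
               tolerance = 1e-12)
  # exact linear map -> coefficient 1
  expect_equal(gated_correlation(x, 2 * x + 1)$estimate, 1, tolerance = 1e-12)
  expect_error(gated_correlation(x, rep(1, 70)), "constant")
  expect_error(gated_correlation(x[1:3], y[1:3]), "at least 4")
})

test_that("history design matrix matches hand coding on a 6-trial log", {
  #           t: 1  2  3  4  5  6
  ch <- c(0L, 1L, 1L, 0L, 1L, 0L)
  rw <- c(1L, 0L, 1L, 1L, 0L, 1L)
  log <- make_hand_log(ch, rw)
  d <- build_history_design(log)
  expect_equal(nrow(d), 3L)  # trials 4, 5, 6
  expect_equal(d$action, c(0L, 1L, 0L))
  # row for t=4: lags 1..3 are trials 3,2,1
  # t-1 = trial 3: chose right, rewarded  -> pos_1 = +1, neg_1 = 0
  # t-2 = trial 2: chose right, unrewarded -> neg_2 = +1
  # t-3 = trial 1: chose left, rewarded    -> pos_3 = -1
  expect_equal(unlist(d[1, c("pos_1", "neg_1", "pos_2", "neg_2",
                             "pos_3", "neg_3")], use.names = FALSE),
               c(1, 0, 0, 1, -1, 0))
  # row for t=6: t-1 = trial 5 (right, unrewarded), t-2 = trial 4
  # (left, rewarded), t-3 = trial 3 (right, rewarded)
  expect_equal(unlist(d[3, c("pos_1", "neg_1", "pos_2", "neg_2",
                             "pos_3", "neg_3")], use.names = FALSE),
               c(0, 1, -1, 0, 1, 0))
})

test_that("exactly one of pos_i/neg_i is nonzero per responded lag", {
  set.seed(12)
  cfg <- task_config(rng_seed = 55L)
  log <- run_session(build_block_schedule(cfg, 1), cfg,
                     agent_policy(rl_params(0.5, 0.4, 5, 0.2)))
  d <- build_history_design(log)
  for (i in 1:3) {
    expect_true(all(abs(d[[paste0("pos_", i)]]) +
                      abs(d[[paste0("neg_", i)]]) == 1))
  }
})

test_that("trait join works and missing traits error", {
  log <- make_hand_log(c(0L, 1L, 0L, 1L, 0L), c(1L, 1L, 0L, 0L, 1L),
                       participant_id = "p1")
  traits <- tibble::tibble(participant_id = "p1", z_total = 1.3)
  d <- build_history_design(log, traits = traits)
  expect_true(all(d$imp_z == 1.3))
  bad <- tibble::tibble(participant_id = "someone_else", z_total = 0)
  expect_error(build_history_design(log, traits = bad), "missing")
})

simulate_glmm_design <- function(n_id, n_per, betas, seed,
                                 gamma_int = NULL, tau = 0.5) {
  # direct simulation from the logistic model: predictors drawn with the
  # one-of-pos/neg structure, random intercepts N(0, tau^2)
  set.seed(seed)
  rows <- n_id * n_per
  d <- tibble::tibble(id = rep(sprintf("s%02d", 1:n_id), each = n_per))
  for (i in 1:3) {
    side <- sample(c(-1, 1), rows, replace = TRUE)
    rewarded <- stats::runif(rows) < 0.5
    d[[paste0("pos_", i)]] <- ifelse(rewarded, side, 0)
    d[[paste0("neg_", i)]] <- ifelse(rewarded, 0, side)
  }
  b0 <- rep(stats::rnorm(n_id, 0, tau), each = n_per)
  eta <- b0
  for (nm in names(betas)) eta <- eta + betas[[nm]] * d[[nm]]
  if (!is.null(gamma_int)) {
    imp <- rep(stats::rnorm(n_id), each = n_per)
    imp <- (imp - mean(imp)) / stats::sd(imp)
    d$imp_z <- imp
    eta <- eta + gamma_int * imp * d$neg_1
  }
  d$action <- as.integer(stats::runif(rows) < stats::plogis(eta))
  d
}

test_that("GLMM recovers known coefficients within 2 SE at 70 x 300", {
  truth <- list(pos_1 = 2.0, neg_1 = -0.4, pos_2 = 0, neg_2 = 0,
                pos_3 = 0, neg_3 = 0)
  d <- simulate_glmm_design(70, 300, truth, seed = 21)
  fit <- fit_history_glmm(d)
  co <- fit$coefficients
  for (nm in names(truth)) {
    row <- co[co$term == nm, ]
    expect_lt(abs(row$estimate - truth[[nm]]), 2 * row$se)
  }
  expect_gt(fit$tau00, 0)
  expect_true(fit$r2_conditional >= fit$r2_marginal)
  expect_true(fit$icc > 0 && fit$icc < 1)
})

test_that("a planted trait x neg_1 interaction is recovered with its sign", {
  d <- simulate_glmm_design(60, 200, list(pos_1 = 1.5, neg_1 = -0.3),
                            seed = 22, gamma_int = -0.6)
  fit <- fit_history_glmm(d)
  row <- fit$coefficients[fit$coefficients$term == "imp_z:neg_1", ]
  expect_equal(nrow(row), 1L)
  expect_lt(row$estimate, 0)
  expect_lt(row$p, 0.05)
})

test_that("all-zero predictors yield an intercept-only fit", {
  d <- tibble::tibble(id = rep(c("a", "b"), each = 40),
                      action = rep(c(0L, 1L), 40),
                      pos_1 = 0, neg_1 = 0)
  fit <- fit_history_glmm(d)
  expect_equal(fit$coefficients$term, "(Intercept)")
})

test_that("median split sends ties to the low group", {
  cohort <- tibble::tibble(total = c(30, 35, 35, 40, 50),
                           m = c(0.9, 0.8, 0.7, 0.5, 0.4))
  out <- median_split_summary(cohort, "m")
  # median 35; ties at 35 go low -> low = {30, 35, 35}, high = {40, 50}
  expect_equal(out$n[out$group == "low"], 3L)
  expect_equal(out$n[out$group == "high"], 2L)
  expect_equal(out$mean[out$group == "low"], mean(c(0.9, 0.8, 0.7)))
  expect_equal(out$mean[out$group == "high"], mean(c(0.5, 0.4)))
  expect_false(attr(out, "degenerate"))
  # planted negative association -> high group lower
  expect_lt(out$mean[out$group == "high"], out$mean[out$group == "low"])
  # degenerate split flagged
  flat <- tibble::tibble(total = c(40, 40, 40), m = 1:3)
  expect_true(attr(median_split_summary(flat, "m"), "degenerate"))
  # n = 2 distinct scores -> one per group
  two <- tibble::tibble(total = c(30, 50), m = c(1, 2))
  expect_equal(median_split_summary(two, "m")$n, c(1L, 1L))
})

test_that("Bonferroni gate reproduces the printed decisions", {
  g <- multiple_comparison_gate(c(0.0046, 0.03), family_size = 8)
  expect_equal(attr(g, "threshold"), 0.05 / 8)
  expect_true(g$significant_bonferroni[1])   # 0.0046 < 0.00625
  expect_false(g$significant_bonferroni[2])  # 0.03 > 0.00625
  expect_true(all(g$significant_raw))
  # family of one reduces to the raw threshold
  g1 <- multiple_comparison_gate(0.03, family_size = 1)
  expect_identical(g1$significant_raw, g1$significant_bonferroni)
  expect_error(multiple_comparison_gate(c(0.1, 0.2), family_size = 1))
})
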