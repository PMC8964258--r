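# Model-free behavioral statistics: exact scripted-agent values, hand
# tallies, brute-force oracle equivalence, and the structural properties
# (partition, 1-back/3-back consistency, history eligibility).

sim_fixture_log <- function(n_participants = 2, policy_maker = NULL,
                            seed = 17) {
  # <= 300-trial fixtures for oracle equivalence
  set.seed(seed)
  logs <- lapply(seq_len(n_participants), function(i) {
    cfg <- task_config(rng_seed = 900L + i)
    pol <- if (is.null(policy_maker)) {
      agent_policy(rl_params(0.6, 0.4, 5, 0.2))
    } else policy_maker()
    run_session(build_block_schedule(cfg, (i %% 4) + 1), cfg, pol,
                participant_id = sprintf("p%d", i), block_id = 1L)
  })
  out <- dplyr::bind_rows(logs)
  class(out) <- c("trial_log", class(out))
  out
}

test_that("overall performance counts responded trials only", {
  log <- make_hand_log(c(0, 1, 0, 1), c(1, 1, 0, 0),
                       responded = c(TRUE, TRUE, FALSE, TRUE),
                       correct_side = c(0, 1, 0, 0))
  # responded trials: choices 0,1,1 vs correct 0,1,0 -> 2/3
  expect_equal(overall_performance(log), 2 / 3)
  per <- overall_performance(log, by_participant = TRUE)
  expect_equal(per$n_responded, 3L)
  expect_equal(per$accuracy, 2 / 3)
  none <- make_hand_log(c(0, 1), c(0, 0), responded = c(FALSE, FALSE))
  expect_error(overall_performance(none), "no responded")
})

test_that("WSLS agent pins the 1-back stay probabilities at 1 and 0", {
  log <- sim_fixture_log(2, function() scripted_policy("wsls"))
  expect_identical(stay_probability_1back(log, "rewarded"), 1)
  expect_identical(stay_probability_1back(log, "unrewarded"), 0)
  # always-stay repeats regardless of outcome
  log2 <- sim_fixture_log(1, function() scripted_policy("always-stay"))
  expect_identical(stay_probability_1back(log2, "rewarded"), 1)
  expect_identical(stay_probability_1back(log2, "unrewarded"), 1)
})

test_that("3-back stay table matches the brute-force oracle on fixtures", {
  log <- sim_fixture_log(2)
  tab <- stay_table_3back(log)
  ora <- oracle_stay_table_3back(log)
  expect_setequal(tab$history, names(ora$p))
  for (k in tab$history) {
    expect_equal(tab$n[tab$history == k], unname(ora$n[k]))
    expect_equal(tab$p_stay[tab$history == k], unname(ora$p[k]),
                 tolerance = 1e-12)
  }
  # per-participant counts aggregate to the pooled counts
  per <- stay_table_3back(log, by_participant = TRUE)
  agg <- tapply(per$n, per$history, sum)
  expect_equal(as.vector(agg[tab$history]), as.vector(tab$n))
})

test_that("3-back table on a hand log matches a literal hand tally", {
  # 8 trials, single block: choices L L R R R L L L, rewards 1 0 0 1 1 1 0 1
  ch <- c(0, 0, 1, 1, 1, 0, 0, 0)
  rw <- c(1, 0, 0, 1, 1, 1, 0, 1)
  log <- make_hand_log(ch, rw)
  tab <- stay_table_3back(log)
  # eligible trials t = 4..8 (1-based); histories over (t-3,t-2,t-1):
  # t4: +-- stay; t5: --+ stay; t6: -++ switch; t7: +++ stay; t8: ++- stay
  get <- function(k, col) tab[[col]][tab$history == k]
  expect_equal(get("+--", "n"), 1L); expect_equal(get("+--", "p_stay"), 1)
  expect_equal(get("--+", "n"), 1L); expect_equal(get("--+", "p_stay"), 1)
  expect_equal(get("-++", "n"), 1L); expect_equal(get("-++", "p_stay"), 0)
  expect_equal(get("+++", "n"), 1L); expect_equal(get("+++", "p_stay"), 1)
  expect_equal(get("++-", "n"), 1L); expect_equal(get("++-", "p_stay"), 1)
  expect_equal(sum(tab$n), 5L)
  expect_true(all(is.na(tab$p_stay[tab$n == 0])))
})

test_that("empty conditions report NA, never zero", {
  log <- make_hand_log(rep(0L, 8), rep(1L, 8))  # all rewarded
  tab <- stay_table_3back(log)
  expect_equal(tab$n[tab$history == "+++"], 5L)
  expect_equal(tab$p_stay[tab$history == "+++"], 1)
  expect_true(all(is.na(tab$p_stay[tab$history != "+++"])))
  expect_true(all(tab$n[tab$history != "+++"] == 0L))
})

test_that("aB table matches the brute-force oracle under both conventions", {
  log <- sim_fixture_log(2)
  for (conv in c("lower_unrewarded", "upper_unrewarded")) {
    tab <- ab_table(log, convention = conv)
    ora <- oracle_ab_table(log, lower_unrewarded = conv == "lower_unrewarded")
    for (k in names(ora$p)) {
      expect_equal(tab$n[tab$history == k], unname(ora$n[k]))
      expect_equal(tab$p_a[tab$history == k], unname(ora$p[k]),
                   tolerance = 1e-12)
    }
    # keys absent from the oracle had no eligible trials
    expect_true(all(tab$n[!(tab$history %in% names(ora$n))] == 0L))
  }
})

test_that("WSLS aB values equal the rule's analytic predictions", {
  # under WSLS the trial-t action is the t-1 action iff t-1 was rewarded;
  # with lowercase = unrewarded this forces p(a) per key:
  truth <- c(aa = 0, aA = 1, ab = 1, aB = 0, Aa = 0, AA = 1, Ab = 1, AB = 0)
  log <- sim_fixture_log(2, function() scripted_policy("wsls"))
  tab <- ab_table(log)
  for (k in names(truth)) {
    n <- tab$n[tab$history == k]
    if (n > 0) expect_equal(tab$p_a[tab$history == k], unname(truth[k]))
  }
  # WSLS switches after every loss and stays after every win, so exactly
  # the keys {ab, aB, Aa, AA} are reachable; all occur over 300 trials
  expect_setequal(tab$history[tab$n > 0], c("ab", "aB", "Aa", "AA"))
})

test_that("always-stay agent populates only stay-type keys with p_a = 1", {
  log <- sim_fixture_log(1, function() scripted_policy("always-stay"))
  tab <- ab_table(log)
  stay_keys <- c("aa", "aA", "Aa", "AA")
  expect_true(all(tab$n[!(tab$history %in% stay_keys)] == 0L))
  pop <- tab$history %in% stay_keys & tab$n > 0
  expect_true(any(pop))
  expect_true(all(tab$p_a[pop] == 1))
})

test_that("history tables partition the eligible trials", {
  log <- sim_fixture_log(2)
  # independent eligibility count: responded trials with k responded
  # in-block predecessors
  count_eligible <- function(log, k) {
    tot <- 0L
    for (pid in unique(log$participant_id)) {
      for (b in unique(log$block_id[log$participant_id == pid])) {
        d <- log[log$participant_id == pid & log$block_id == b, ]
        d <- d[order(d$trial), ]
        for (t in seq_len(nrow(d))) {
          if (t > k && all(d$responded[(t - k):t])) tot <- tot + 1L
        }
      }
    }
    tot
  }
  expect_equal(sum(stay_table_3back(log)$n), count_eligible(log, 3L))
  expect_equal(sum(ab_table(log)$n), count_eligible(log, 2L))
})

test_that("1-back unrewarded marginal equals the weighted 3-back average", {
  log <- sim_fixture_log(2)
  tab <- stay_table_3back(log)
  ends_loss <- tab[substr(tab$history, 3, 3) == "-" & tab$n > 0, ]
  weighted <- sum(ends_loss$p_stay * ends_loss$n) / sum(ends_loss$n)
  expect_equal(stay_probability_1back(log, "unrewarded", n_history = 3L),
               weighted, tolerance = 1e-12)
})

test_that("non-response trials break history eligibility", {
  ch <- c(0L, 1L, 1L, 0L, 1L, 0L, 1L)
  rw <- c(1L, 0L, 1L, 0L, 1L, 1L, 0L)
  resp <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  log <- make_hand_log(ch, rw, responded = resp, correct_side = ch)
  # only trial 7 has 3 responded immediate predecessors (trials 4..6 include
  # a non-response, so trials 5 and 6 are ineligible; 7 needs 4,5,6 -> no)
  tab <- stay_table_3back(log)
  expect_equal(sum(tab$n), 0L)
  # aB needs 2 responded predecessors: eligible t = 3 and t = 7
  expect_equal(sum(ab_table(log)$n), 2L)
})

test_that("switch-aligned accuracy is exact for the lag-1 oracle policy", {
  cfg <- task_config(rng_seed = 303L)
  log <- run_session(build_block_schedule(cfg, 1), cfg,
                     scripted_policy("lag1-oracle"))
  curve <- switch_aligned_accuracy(log, window = -1:1)
  expect_gt(curve$n_participants[1], 0)
  expect_equal(curve$p_correct[curve$offset == -1], 1)
  expect_equal(curve$p_correct[curve$offset == 0], 0)
  expect_equal(curve$p_correct[curve$offset == 1], 1)
})

test_that("preprocess_sessions drops planted violations with reasons", {
  good <- sim_fixture_log(1)
  # low response rate participant
  ch <- rep(c(0L, 1L), 50)
  lazy <- make_hand_log(ch, rep(0L, 100), participant_id = "lazy",
                        responded = rep(c(TRUE, FALSE), 50),
                        correct_side = ch)
  # poor accuracy participant: always left, correct always right
  poor <- make_hand_log(rep(0L, 100), rep(0L, 100), participant_id = "poor",
                        correct_side = rep(1L, 100))
  logs <- dplyr::bind_rows(good, lazy, poor)
  class(logs) <- c("trial_log", class(tibble::tibble()))
  pp <- preprocess_sessions(logs, exclusion_criteria(min_accuracy = 0.55,
                                                     min_response_rate = 0.8))
  expect_setequal(pp$report$participant_id, c("lazy", "poor"))
  expect_match(pp$report$reason[pp$report$participant_id == "lazy"],
               "response rate")
  expect_match(pp$report$reason[pp$report$participant_id == "poor"],
               "accuracy")
  expect_false(any(pp$logs$participant_id %in% c("lazy", "poor")))
  # block-count requirement
  pp2 <- preprocess_sessions(good, exclusion_criteria(require_blocks = 2))
  expect_equal(nrow(pp2$logs), 0L)
})
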