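# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles with the slowest, most literal code
# possible; they share no logic with the package internals.

# ---- literal step-by-step RL evaluator (chosen/counterfactual updates,
# stickiness, two-option softmax), one block ----
oracle_rl_block_loglik <- function(choice, reward, alpha_pos, alpha_neg,
                                   beta, st, counterfactual = TRUE) {
  q <- c(0.5, 0.5)  # index 1 = left (code 0), 2 = right (code 1)
  last <- NA_integer_
  ll <- numeric(length(choice))
  for (t in seq_along(choice)) {
    w <- q
    if (!is.na(last)) w[last + 1] <- w[last + 1] + st
    p_left <- exp(beta * w[1]) / (exp(beta * w[1]) + exp(beta * w[2]))
    ll[t] <- log(if (choice[t] == 0) p_left else 1 - p_left)
    a <- choice[t] + 1
    u <- 3 - a
    rate <- if (reward[t] == 1) alpha_pos else alpha_neg
    q_new <- q
    q_new[a] <- q[a] + rate * (reward[t] - q[a])
    if (counterfactual) q_new[u] <- q[u] + rate * ((1 - reward[t]) - q[u])
    q <- q_new
    last <- choice[t]
  }
  ll
}

# ---- literal step-by-step BI evaluator (Bayes posterior, switch mixing) ----
oracle_bi_block_loglik <- function(choice, reward, p_reward, p_switch,
                                   beta, st, epsilon = 1e-4) {
  belief <- 0.5  # p(correct side = left)
  last <- NA_integer_
  ll <- numeric(length(choice))
  for (t in seq_along(choice)) {
    w <- c(belief, 1 - belief)
    if (!is.na(last)) w[last + 1] <- w[last + 1] + st
    p_left <- exp(beta * w[1]) / (exp(beta * w[1]) + exp(beta * w[2]))
    ll[t] <- log(if (choice[t] == 0) p_left else 1 - p_left)
    # emission p(r | C) for C = left, right
    if (choice[t] == 0) {
      lik <- if (reward[t] == 1) c(p_reward, epsilon)
             else c(1 - p_reward, 1 - epsilon)
    } else {
      lik <- if (reward[t] == 1) c(epsilon, p_reward)
             else c(1 - epsilon, 1 - p_reward)
    }
    post <- lik[1] * belief / (lik[1] * belief + lik[2] * (1 - belief))
    belief <- (1 - p_switch) * post + p_switch * (1 - post)
    last <- choice[t]
  }
  ll
}

# ---- exact marginal filtering by enumeration over all 2^T latent paths ----
# Returns the belief p(C_{t+1} = left | actions, rewards up to t) for every t,
# i.e. the same next-trial prior the BI agent tracks.
oracle_bi_enumeration_beliefs <- function(choice, reward, p_reward, p_switch,
                                          epsilon = 1e-4) {
  T_ <- length(choice)
  emit <- function(c_side, a, r) {
    if (a == c_side) { if (r == 1) p_reward else 1 - p_reward }
    else { if (r == 1) epsilon else 1 - epsilon }
  }
  beliefs <- numeric(T_)
  for (t in seq_len(T_)) {
    # enumerate latent paths C_1 .. C_{t+1} (0 = left, 1 = right)
    n_paths <- 2^(t + 1)
    num <- 0; den <- 0
    for (k in seq_len(n_paths) - 1) {
      path <- as.integer(intToBits(k))[seq_len(t + 1)]
      w <- 0.5  # p(C_1)
      for (s in seq_len(t)) {
        w <- w * emit(path[s], choice[s], reward[s])
        w <- w * (if (path[s + 1] == path[s]) 1 - p_switch else p_switch)
      }
      den <- den + w
      if (path[t + 1] == 0) num <- num + w
    }
    beliefs[t] <- num / den
  }
  beliefs
}

# ---- WAIC recomputed the long way from a pointwise log-likelihood matrix ----
oracle_waic <- function(ll) {
  S <- nrow(ll); N <- ncol(ll)
  lppd_i <- numeric(N); p_i <- numeric(N)
  for (i in seq_len(N)) {
    lppd_i[i] <- log(sum(exp(ll[, i])) / S)
    p_i[i] <- sum((ll[, i] - mean(ll[, i]))^2) / (S - 1)
  }
  list(waic = -2 * sum(lppd_i - p_i),
       se = sqrt(N * stats::var(-2 * (lppd_i - p_i))),
       lppd = sum(lppd_i), p_waic = sum(p_i))
}

# ---- brute-force behavioral tallies straight off a trial log ----
# All of these re-walk the raw rows with explicit loops.
oracle_stay_table_3back <- function(log) {
  keys <- apply(expand.grid(c("+", "-"), c("+", "-"), c("+", "-")),
                1, function(r) paste0(r[3], r[2], r[1]))
  stay <- setNames(numeric(8), sort(keys)); n <- setNames(numeric(8), sort(keys))
  for (pid in unique(log$participant_id)) {
    for (b in unique(log$block_id[log$participant_id == pid])) {
      d <- log[log$participant_id == pid & log$block_id == b, ]
      d <- d[order(d$trial), ]
      for (t in seq_len(nrow(d))) {
        if (t < 4) next
        win <- d[(t - 3):t, ]
        if (!all(win$responded)) next
        key <- paste0(ifelse(win$rewarded[1:3] == 1, "+", "-"), collapse = "")
        n[key] <- n[key] + 1
        if (win$chosen_side[4] == win$chosen_side[3]) stay[key] <- stay[key] + 1
      }
    }
  }
  p <- ifelse(n > 0, stay / n, NA_real_)
  list(p = p, n = n)
}

oracle_ab_table <- function(log, lower_unrewarded = TRUE) {
  res_n <- list(); res_a <- list()
  bump <- function(env_key, hit) {
    res_n[[env_key]] <<- (res_n[[env_key]] %||% 0) + 1
    res_a[[env_key]] <<- (res_a[[env_key]] %||% 0) + hit
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  for (pid in unique(log$participant_id)) {
    for (b in unique(log$block_id[log$participant_id == pid])) {
      d <- log[log$participant_id == pid & log$block_id == b, ]
      d <- d[order(d$trial), ]
      for (t in seq_len(nrow(d))) {
        if (t < 3) next
        win <- d[(t - 2):t, ]
        if (!all(win$responded)) next
        case1 <- if (lower_unrewarded) win$rewarded[1] == 1 else win$rewarded[1] == 0
        case2 <- if (lower_unrewarded) win$rewarded[2] == 1 else win$rewarded[2] == 0
        ch1 <- if (case1) "A" else "a"
        stay2 <- win$chosen_side[2] == win$chosen_side[1]
        ch2 <- if (stay2) "a" else "b"
        if (case2) ch2 <- toupper(ch2)
        key <- paste0(ch1, ch2)
        bump(key, as.integer(win$chosen_side[3] == win$chosen_side[1]))
      }
    }
  }
  keys <- sort(names(res_n))
  list(p = setNames(vapply(keys, function(k) res_a[[k]] / res_n[[k]], 0), keys),
       n = setNames(vapply(keys, function(k) res_n[[k]], 0), keys))
}

# ---- minimal independent event-driven task simulation (oracle policy) ----
# Used to cross-check reversal counts from the package's engine.
oracle_simulate_oracle_policy <- function(reward_flags, criteria, n_trials) {
  correct <- 0L  # 0 = left
  flag_i <- 0L; crit_i <- 1L
  rewards_on_side <- 0L
  n_reversals <- 0L
  rewarded <- integer(n_trials)
  for (t in seq_len(n_trials)) {
    # oracle picks the correct side; consume a flag
    flag_i <- flag_i + 1L
    r <- reward_flags[flag_i]
    rewarded[t] <- r
    if (r == 1L) {
      rewards_on_side <- rewards_on_side + 1L
      if (rewards_on_side == criteria[crit_i]) {
        # the reversal takes effect on the next trial; a criterion completed
        # on the final trial produces no reversal row
        if (t < n_trials) {
          correct <- 1L - correct
          n_reversals <- n_reversals + 1L
        }
        crit_i <- crit_i + 1L
        rewards_on_side <- 0L
      }
    }
  }
  list(rewarded = rewarded, n_reversals = n_reversals)
}

# ---- shared small fixtures ----
# choice/correct given as 0 = left, 1 = right codes; stored as side labels
make_hand_log <- function(choice, reward, participant_id = "p1", block_id = 1L,
                          responded = rep(TRUE, length(choice)),
                          correct_side = NULL) {
  n <- length(choice)
  if (is.null(correct_side)) correct_side <- choice  # make all correct
  side <- function(code) c("left", "right")[code + 1L]
  log <- tibble::tibble(
    participant_id = participant_id,
    block_id = as.integer(block_id),
    trial = seq_len(n) - 1L,
    correct_side = side(correct_side),
    chosen_side = ifelse(responded, side(choice), NA_character_),
    rewarded = ifelse(responded, as.integer(reward), NA_integer_),
    responded = responded,
    reversal_trial = FALSE)
  class(log) <- c("trial_log", class(log))
  log
}
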