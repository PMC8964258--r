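#' Parameters of the Q-learning choice model
#'
#' The four-parameter reinforcement learning model: separate learning rates
#' for rewarded (`alpha_pos`) and unrewarded (`alpha_neg`) outcomes, an
#' inverse temperature `beta` scaling the softmax policy, and a sticky-choice
#' parameter `st` added to the previously selected action's value before
#' choice. The unchosen action is updated simultaneously toward the opposite
#' counterfactual outcome with the same outcome-selected learning rate.
#'
#' @param alpha_pos,alpha_neg Learning rates in `[0, 1]`.
#' @param beta Inverse temperature, `>= 0`.
#' @param st Stickiness in `[-1, 1]`; positive values favor repeating the
#'   previous choice, negative values favor alternating.
#' @return An object of class `rl_params`.
#' @export
rl_params <- function(alpha_pos, alpha_neg, beta, st = 0) {
  if (alpha_pos < 0 || alpha_pos > 1 || alpha_neg < 0 || alpha_neg > 1) {
    stop("learning rates must lie in [0, 1]")
  }
  if (beta < 0) stop("beta must be >= 0")
  if (st < -1 || st > 1) stop("st must lie in [-1, 1]")
  structure(list(alpha_pos = alpha_pos, alpha_neg = alpha_neg,
                 beta = beta, st = st),
            class = "rl_params")
}

#' Parameters of the Bayesian latent-state inference model
#'
#' The agent tracks its belief that the correct box is on the left, updating
#' by Bayes' rule with emission probabilities `p_reward` (reward when choosing
#' the correct side) and `epsilon` (reward when choosing the incorrect side),
#' then propagating the posterior to the next trial's prior with switch
#' probability `p_switch`. The choice policy is the same softmax-with-
#' stickiness rule as the RL model, with beliefs in place of values.
#' `epsilon` is fixed to 0.0001 by default: the incorrect box effectively
#' never pays out, but a hard zero would make the filter degenerate.
#'
#' @param p_reward,p_switch Probabilities in `[0, 1]`.
#' @param beta Inverse temperature, `>= 0`.
#' @param st Stickiness in `[-1, 1]`.
#' @param epsilon Small fixed reward probability for the incorrect side.
#' @return An object of class `bi_params`.
#' @export
bi_params <- function(p_reward, p_switch, beta, st = 0, epsilon = 1e-4) {
  if (p_reward < 0 || p_reward > 1 || p_switch < 0 || p_switch > 1) {
    stop("p_reward and p_switch must lie in [0, 1]")
  }
  if (beta < 0) stop("beta must be >= 0")
  if (st < -1 || st > 1) stop("st must lie in [-1, 1]")
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must lie in (0, 1)")
  structure(list(p_reward = p_reward, p_switch = p_switch,
                 beta = beta, st = st, epsilon = epsilon),
            class = "bi_params")
}

#' Initial agent state
#'
#' RL agents start with both action values at 0.5 (the uninformative midpoint
#' of the binary-outcome value range); BI agents start with a flat prior
#' `p(C = left) = 0.5`. No stickiness bonus applies before the first response.
#'
#' @param model `"rl"` or `"bi"`.
#' @return An object of class `agent_state` with fields `values` (RL; named
#'   left/right) or `belief` (BI; `p(C = left)`), and `last_action`
#'   (`NA` before the first responded trial).
#' @export
agent_state <- function(model = c("rl", "bi")) {
  model <- match.arg(model)
  structure(
    if (model == "rl") list(model = model, values = c(left = 0.5, right = 0.5),
                            last_action = NA_integer_)
    else list(model = model, belief = 0.5, last_action = NA_integer_),
    class = "agent_state")
}

check_action_reward <- function(action, reward) {
  if (!(action %in% c(0L, 1L))) stop("action must be 0 (left) or 1 (right)")
  if (!(reward %in% c(0L, 1L))) stop("reward must be 0 or 1")
}

#' One Q-learning update
#'
#' Applies the dual-learning-rate delta rule with counterfactual updating:
#' the chosen action moves toward the outcome `r` and the unchosen action
#' simultaneously moves toward `1 - r`, both at rate `alpha_pos` when `r = 1`
#' and `alpha_neg` when `r = 0`, and both from the pre-update values.
#'
#' @param state An `agent_state` for model `"rl"`.
#' @param params [rl_params()].
#' @param action Chosen side, 0 = left, 1 = right.
#' @param reward Outcome, 0 or 1.
#' @param counterfactual Update the unchosen action too (the winning model
#'   does; `FALSE` gives the no-counterfactual nested variant).
#' @return The updated `agent_state`.
#' @export
rl_update <- function(state, params, action, reward, counterfactual = TRUE) {
  stopifnot(inherits(state, "agent_state"), state$model == "rl")
  check_action_reward(action, reward)
  rate <- if (reward == 1L) params$alpha_pos else params$alpha_neg
  q <- state$values
  chosen <- action + 1L
  other <- 2L - action
  q_new <- q
  q_new[chosen] <- q[chosen] + rate * (reward - q[chosen])
  if (counterfactual) q_new[other] <- q[other] + rate * ((1 - reward) - q[other])
  state$values <- q_new
  state$last_action <- as.integer(action)
  state
}

softmax_pair <- function(w_left, w_right, beta) {
  p_left <- 1 / (1 + exp(-beta * (unname(w_left) - unname(w_right))))
  c(left = p_left, right = 1 - p_left)
}

#' Softmax choice probabilities of the RL agent
#'
#' `W(a) = Q(a) + st` for the previously selected action (no bonus before the
#' first response), `W(a) = Q(a)` otherwise; probabilities are
#' `softmax(beta * W)`.
#'
#' @inheritParams rl_update
#' @return Named numeric pair `(left, right)` summing to 1.
#' @export
rl_choice_probs <- function(state, params) {
  stopifnot(inherits(state, "agent_state"), state$model == "rl")
  w <- state$values
  if (!is.na(state$last_action)) {
    w[state$last_action + 1L] <- w[state$last_action + 1L] + params$st
  }
  softmax_pair(w[1], w[2], params$beta)
}

#' One Bayesian belief update
#'
#' Computes the posterior over the correct side from the outcome likelihood
#' (`p_reward` if the choice matched the latent state, `epsilon` otherwise,
#' with complements for unrewarded outcomes), then mixes it with switch
#' probability `p_switch` to form the next trial's prior. The returned belief
#' is that next-trial prior.
#'
#' @param state An `agent_state` for model `"bi"`.
#' @param params [bi_params()].
#' @inheritParams rl_update
#' @return The updated `agent_state`.
#' @export
bi_update <- function(state, params, action, reward) {
  stopifnot(inherits(state, "agent_state"), state$model == "bi")
  check_action_reward(action, reward)
  b <- state$belief
  if (action == 0L) {
    lik_left <- if (reward == 1L) params$p_reward else 1 - params$p_reward
    lik_right <- if (reward == 1L) params$epsilon else 1 - params$epsilon
  } else {
    lik_left <- if (reward == 1L) params$epsilon else 1 - params$epsilon
    lik_right <- if (reward == 1L) params$p_reward else 1 - params$p_reward
  }
  den <- lik_left * b + lik_right * (1 - b)
  if (den <= 0) stop("degenerate belief normalizer (all-zero likelihood)")
  post <- lik_left * b / den
  state$belief <- (1 - params$p_switch) * post + params$p_switch * (1 - post)
  state$last_action <- as.integer(action)
  state
}

#' Softmax choice probabilities of the BI agent
#'
#' Identical policy to the RL model with the belief pair
#' `(p(C = left), 1 - p(C = left))` in place of action values.
#'
#' @inheritParams bi_update
#' @return Named numeric pair `(left, right)` summing to 1.
#' @export
bi_choice_probs <- function(state, params) {
  stopifnot(inherits(state, "agent_state"), state$model == "bi")
  w <- c(state$belief, 1 - state$belief)
  if (!is.na(state$last_action)) {
    w[state$last_action + 1L] <- w[state$last_action + 1L] + params$st
  }
  softmax_pair(w[1], w[2], params$beta)
}

# Convert a single-participant trial_log into per-block lists of responded
# choices/rewards (integer codes), the form the compiled likelihoods consume.
# Non-response trials are dropped: they contribute no action-outcome pair and
# leave agent state (including the stickiness reference action) unchanged.
log_to_blocks <- function(log, warn = TRUE) {
  validate_trial_log(log, warn_reward_incorrect = warn)
  if (length(unique(log$participant_id)) > 1L) {
    stop("expected a trial log for a single participant")
  }
  lapply(split(log, log$block_id), function(blk) {
    blk <- blk[order(blk$trial), ]
    keep <- blk$responded
    list(choice = side_to_code(blk$chosen_side[keep]),
         reward = as.integer(blk$rewarded[keep]))
  })
}

#' Session log-likelihood under a generative choice model
#'
#' Sequentially applies the model's choice rule and update rule over a
#' single participant's trial log (one or more blocks, each an independent
#' sequence with agent state reset at block start), accumulating the log
#' probability of each observed action. Non-response trials are skipped for
#' both the likelihood and the internal update.
#'
#' @param log A `trial_log` for one participant.
#' @param params [rl_params()] or [bi_params()] matching `model`.
#' @param model `"rl"` or `"bi"`; defaults to the class of `params`.
#' @param pointwise Return the per-trial log-likelihood vector (in trial
#'   order, responded trials only) instead of the total.
#' @param counterfactual RL only: include counterfactual updating.
#' @return Total log-likelihood (scalar) or per-trial vector.
#' @export
session_loglik <- function(log, params, model = NULL, pointwise = FALSE,
                           counterfactual = TRUE) {
  if (is.null(model)) {
    model <- if (inherits(params, "rl_params")) "rl"
             else if (inherits(params, "bi_params")) "bi"
             else stop("params must be rl_params or bi_params")
  }
  blocks <- log_to_blocks(log)
  out <- if (model == "rl") {
    .rl_loglik_cpp(blocks, params$alpha_pos, params$alpha_neg, params$beta,
                   params$st, counterfactual, pointwise)
  } else {
    .bi_loglik_cpp(blocks, params$p_reward, params$p_switch, params$beta,
                   params$st, params$epsilon, pointwise)
  }
  if (pointwise) out else out[[1]]
}
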