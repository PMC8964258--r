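#' Scripted choice policies for testing and benchmarking
#'
#' Returns a choice-producing callback implementing a named deterministic or
#' seeded heuristic rule. These serve as analytic oracles for the behavioral
#' statistics (e.g., a win-stay/lose-switch agent pins the 1-back stay
#' probabilities at 0 and 1 exactly) and as baseline agents.
#'
#' Available policies:
#' * `"wsls"` — win-stay/lose-switch: repeat the last responded choice if it
#'   was rewarded, otherwise take the other side; first choice is left.
#' * `"always-stay"` — repeat the last responded choice (first choice left).
#' * `"always-switch"` — alternate away from the last responded choice.
#' * `"random"` — choose each side with probability 1/2 (uses the session RNG).
#' * `"oracle"` — always choose the currently correct side (privileged
#'   information; a testing construct).
#' * `"lag1-oracle"` — choose the side that was correct on the previous trial.
#'
#' @param name Policy tag.
#' @return A function usable as the `policy` argument of [run_session()].
#' @export
scripted_policy <- function(name = c("wsls", "always-stay", "always-switch",
                                     "random", "oracle", "lag1-oracle")) {
  name <- match.arg(name)
  last_responded <- function(v) {
    idx <- which(v$responded)
    if (!length(idx)) return(NULL)
    i <- idx[length(idx)]
    list(chosen = v$chosen[i], rewarded = v$rewarded[i])
  }
  switch(name,
    "wsls" = function(v) {
      lr <- last_responded(v)
      if (is.null(lr)) return("left")
      if (lr$rewarded == 1L) code_to_side(lr$chosen)
      else code_to_side(1L - lr$chosen)
    },
    "always-stay" = function(v) {
      lr <- last_responded(v)
      if (is.null(lr)) "left" else code_to_side(lr$chosen)
    },
    "always-switch" = function(v) {
      lr <- last_responded(v)
      if (is.null(lr)) "left" else code_to_side(1L - lr$chosen)
    },
    "random" = function(v) if (stats::runif(1) < 0.5) "left" else "right",
    "oracle" = function(v) code_to_side(v$correct_now),
    "lag1-oracle" = function(v) {
      if (v$trial == 0L) "left" else code_to_side(v$correct[length(v$correct)])
    })
}

#' Generative agent policies from model parameters
#'
#' Wraps an [rl_params()] or [bi_params()] parameter vector as a stateful
#' choice policy for [run_session()]. On each call the agent first replays any
#' feedback it has not yet processed (responded trials only; non-responses
#' leave the internal state and the stickiness reference action untouched),
#' then samples an action from its softmax policy using the session RNG.
#'
#' @param params An [rl_params()] or [bi_params()] object.
#' @return A policy function.
#' @export
agent_policy <- function(params) {
  is_rl <- inherits(params, "rl_params")
  if (!is_rl && !inherits(params, "bi_params")) {
    stop("params must be rl_params or bi_params")
  }
  state <- agent_state(if (is_rl) "rl" else "bi")
  processed <- 0L
  function(v) {
    n_prev <- length(v$responded)
    if (n_prev < processed) {  # new session started: reset learning state
      state <<- agent_state(if (is_rl) "rl" else "bi")
      processed <<- 0L
    }
    if (processed < n_prev) {
      for (i in (processed + 1L):n_prev) {
        if (v$responded[i]) {
          act <- v$chosen[i]
          rew <- v$rewarded[i]
          state <<- if (is_rl) rl_update(state, params, act, rew)
                    else bi_update(state, params, act, rew)
        }
      }
      processed <<- n_prev
    }
    p <- if (is_rl) rl_choice_probs(state, params)
         else bi_choice_probs(state, params)
    if (stats::runif(1) < p[1]) "left" else "right"
  }
}
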