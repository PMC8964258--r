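#' Task configuration for the probabilistic switching task
#'
#' Defines one block of the two-box probabilistic reversal learning task. The
#' defaults reproduce the study design: 150 trials per block, the correct box
#' rewarded 75% of the time and the incorrect box never, the correct side
#' starting on the left, and a reversal scheduled after a uniformly sampled
#' 5--15 rewarded trials on the current correct side.
#'
#' @param n_trials Trials per block.
#' @param p_reward_correct Probability that a correct choice is rewarded.
#' @param p_reward_incorrect Probability that an incorrect choice is rewarded.
#' @param criterion_min,criterion_max Inclusive bounds on the number of
#'   rewarded trials required before the correct side switches.
#' @param first_correct_side Side on which the correct box starts
#'   (`"left"` or `"right"`).
#' @param n_sequence_versions Number of pre-randomized sequence versions.
#' @param rng_seed Base seed for schedule construction.
#' @return An object of class `task_config`.
#' @examples
#' cfg <- task_config()
#' sched <- build_block_schedule(cfg, version = 1)
#' @export
task_config <- function(n_trials = 150L,
                        p_reward_correct = 0.75,
                        p_reward_incorrect = 0,
                        criterion_min = 5L,
                        criterion_max = 15L,
                        first_correct_side = c("left", "right"),
                        n_sequence_versions = 4L,
                        rng_seed = 1L) {
  first_correct_side <- match.arg(first_correct_side)
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) stop("n_trials must be a positive integer")
  if (p_reward_incorrect < 0 || p_reward_correct > 1 ||
      p_reward_incorrect > p_reward_correct) {
    stop("require 0 <= p_reward_incorrect <= p_reward_correct <= 1")
  }
  criterion_min <- as.integer(criterion_min)
  criterion_max <- as.integer(criterion_max)
  if (criterion_min < 1L || criterion_min > criterion_max) {
    stop("require 1 <= criterion_min <= criterion_max")
  }
  structure(
    list(n_trials = n_trials,
         p_reward_correct = p_reward_correct,
         p_reward_incorrect = p_reward_incorrect,
         criterion_min = criterion_min,
         criterion_max = criterion_max,
         first_correct_side = first_correct_side,
         n_sequence_versions = as.integer(n_sequence_versions),
         rng_seed = as.integer(rng_seed)),
    class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config> ", x$n_trials, " trials; p(reward|correct)=",
      x$p_reward_correct, ", p(reward|incorrect)=", x$p_reward_incorrect,
      "; switch criterion U{", x$criterion_min, ",...,", x$criterion_max,
      "}; first correct side: ", x$first_correct_side, "\n", sep = "")
  invisible(x)
}

# Pre-randomized reward flags are built in fixed-proportion chunks so that the
# realized reward rate on correct choices matches p_reward_correct exactly over
# every full chunk, while each chunk's internal order is shuffled. Chunk size
# is the smallest length for which p_reward_correct is an exact proportion
# (20 for the default 0.75), capped at 100.
reward_flag_chunk_size <- function(p) {
  for (k in 1:100) {
    if (abs(p * k - round(p * k)) < 1e-9) return(as.integer(k))
  }
  100L
}

make_reward_flags <- function(config, version, chunk_index, n_chunks = 1L) {
  k <- reward_flag_chunk_size(config$p_reward_correct)
  n_ones <- as.integer(round(config$p_reward_correct * k))
  unlist(lapply(seq_len(n_chunks), function(i) {
    seed <- derive_seed(config$rng_seed, "flags", version, chunk_index + i - 1L)
    with_local_seed(seed, sample(c(rep(1L, n_ones), rep(0L, k - n_ones))))
  }))
}

# Uniform integer draw on [lo, hi] that is safe when lo == hi (plain
# sample(lo:hi) would fall into R's scalar-`sample` behavior there).
sample_int_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

make_switch_criteria <- function(config, version, chunk_index, n = 40L) {
  seed <- derive_seed(config$rng_seed, "criteria", version, chunk_index)
  with_local_seed(seed, sample_int_range(config$criterion_min,
                                         config$criterion_max, n))
}

#' Draw switch criteria with the default uniform sampler
#'
#' Samples reversal criteria (rewarded trials required before the correct side
#' switches) i.i.d. uniformly on the inclusive integer range
#' `[criterion_min, criterion_max]`.
#'
#' @param n Number of criteria to draw.
#' @param config A [task_config()].
#' @param seed Seed for the draw.
#' @return Integer vector of length `n`.
#' @export
sample_switch_criteria <- function(n, config = task_config(), seed = 1L) {
  with_local_seed(seed, sample_int_range(config$criterion_min,
                                         config$criterion_max, n))
}

#' Build a pre-randomized block schedule
#'
#' Constructs the outcome sequence and switch-criterion sequence for one block,
#' mirroring how the task loads both at block start rather than sampling
#' online: reward flags for correct choices come from a seeded fixed-proportion
#' shuffle (so the realized rate matches `p_reward_correct` exactly over full
#' chunks) and switch criteria are i.i.d. uniform on the configured range.
#' Sequences are long enough for any play pattern over `n_trials` and are
#' extended deterministically if exhausted.
#'
#' @param config A [task_config()].
#' @param version Sequence version, an integer in
#'   `1..config$n_sequence_versions`.
#' @return An object of class `block_schedule` with elements `reward_flags`,
#'   `switch_criteria` and `version_id`.
#' @export
build_block_schedule <- function(config, version = 1L) {
  stopifnot(inherits(config, "task_config"))
  version <- as.integer(version)
  if (version < 1L || version > config$n_sequence_versions) {
    stop("version must be in 1..", config$n_sequence_versions)
  }
  k <- reward_flag_chunk_size(config$p_reward_correct)
  n_chunks <- max(2L, ceiling(config$n_trials / k) + 1L)
  structure(
    list(reward_flags = make_reward_flags(config, version, 1L, n_chunks),
         switch_criteria = make_switch_criteria(config, version, 1L,
                                                n = max(40L, config$n_trials %/%
                                                          config$criterion_min + 5L)),
         version_id = version,
         config = config,
         n_flag_chunks = n_chunks),
    class = "block_schedule")
}

#' @export
print.block_schedule <- function(x, ...) {
  cat("<block_schedule> version ", x$version_id, ": ",
      length(x$reward_flags), " reward flags (",
      round(100 * mean(x$reward_flags), 1), "% rewarded), ",
      length(x$switch_criteria), " switch criteria in [",
      min(x$switch_criteria), ",", max(x$switch_criteria), "]\n", sep = "")
  invisible(x)
}

#' Run one session of the probabilistic switching task
#'
#' Executes a block against a choice-producing policy. The correct side starts
#' at `config$first_correct_side`; each time the accumulated rewarded choices
#' on the current correct side reach the active criterion, the correct side
#' switches on the trial immediately after that rewarded choice, and
#' `reversal_trial` marks the first trial under the new contingency (t = 0 for
#' switch-aligned analyses). Correct choices consume the pre-randomized reward
#' flags; incorrect choices are rewarded with probability
#' `p_reward_incorrect` (never, under the default configuration). A policy may
#' return `"none"` (response timeout): the trial is logged with
#' `responded = FALSE`, consumes no reward flag and does not advance the
#' reward-accumulation count.
#'
#' @param schedule A [build_block_schedule()] result.
#' @param config The [task_config()] used to build the schedule.
#' @param policy A function called once per trial with a list holding the
#'   visible history (`trial`, vectors `chosen`, `rewarded`, `responded`) plus
#'   privileged fields for oracle test policies (`correct`, `correct_now`).
#'   Must return `"left"`, `"right"` or `"none"`.
#' @param participant_id,block_id Identifiers stamped on every trial record.
#' @return A tibble of class `trial_log`, one row per trial.
#' @export
run_session <- function(schedule, config, policy,
                        participant_id = "p1", block_id = 1L) {
  stopifnot(inherits(schedule, "block_schedule"), inherits(config, "task_config"))
  n <- config$n_trials
  chosen <- rep(NA_integer_, n)
  rewarded <- rep(NA_integer_, n)
  responded <- rep(FALSE, n)
  correct <- rep(NA_integer_, n)
  reversal <- rep(FALSE, n)

  flags <- schedule$reward_flags
  crits <- schedule$switch_criteria
  flag_chunks <- schedule$n_flag_chunks
  crit_chunks <- 1L
  flag_i <- 0L
  crit_i <- 1L
  cur <- if (config$first_correct_side == "left") 0L else 1L
  criterion <- crits[crit_i]
  n_rewarded <- 0L
  switch_next <- FALSE

  for (t in seq_len(n)) {
    if (switch_next) {
      cur <- 1L - cur
      reversal[t] <- TRUE
      n_rewarded <- 0L
      crit_i <- crit_i + 1L
      if (crit_i > length(crits)) {  # deterministic seeded extension
        crit_chunks <- crit_chunks + 1L
        crits <- c(crits, make_switch_criteria(config, schedule$version_id,
                                               crit_chunks))
      }
      criterion <- crits[crit_i]
      switch_next <- FALSE
    }
    correct[t] <- cur
    visible <- list(trial = t - 1L,
                    chosen = chosen[seq_len(t - 1L)],
                    rewarded = rewarded[seq_len(t - 1L)],
                    responded = responded[seq_len(t - 1L)],
                    correct = correct[seq_len(t - 1L)],
                    correct_now = cur)
    side <- policy(visible)
    if (!is.character(side) || length(side) != 1L ||
        !(side %in% c("left", "right", "none"))) {
      stop("policy must return \"left\", \"right\" or \"none\"")
    }
    if (side == "none") next
    responded[t] <- TRUE
    chosen[t] <- side_to_code(side)
    if (chosen[t] == cur) {
      flag_i <- flag_i + 1L
      if (flag_i > length(flags)) {
        flags <- c(flags, make_reward_flags(config, schedule$version_id,
                                            flag_chunks + 1L))
        flag_chunks <- flag_chunks + 1L
      }
      rewarded[t] <- flags[flag_i]
      if (rewarded[t] == 1L) {
        n_rewarded <- n_rewarded + 1L
        if (n_rewarded >= criterion) switch_next <- TRUE
      }
    } else {
      rewarded[t] <- if (config$p_reward_incorrect > 0) {
        stats::rbinom(1L, 1L, config$p_reward_incorrect)
      } else 0L
    }
  }

  log <- tibble::tibble(
    participant_id = as.character(participant_id),
    block_id = as.integer(block_id),
    trial = 0:(n - 1L),
    correct_side = code_to_side(correct),
    chosen_side = ifelse(responded, code_to_side(chosen), NA_character_),
    rewarded = rewarded,
    responded = responded,
    reversal_trial = reversal)
  class(log) <- c("trial_log", class(log))
  log
}

# light structural validation used by readers and metrics
validate_trial_log <- function(log, warn_reward_incorrect = TRUE) {
  need <- c("participant_id", "block_id", "trial", "correct_side",
            "chosen_side", "rewarded", "responded", "reversal_trial")
  miss <- setdiff(need, names(log))
  if (length(miss)) stop("trial log missing columns: ", paste(miss, collapse = ", "))
  bad <- which(is.na(log$rewarded) != !log$responded)
  if (length(bad)) {
    stop("rewarded must be missing iff responded is FALSE (rows ",
         paste(utils::head(bad, 5), collapse = ", "), ")")
  }
  odd <- which(log$responded & log$rewarded == 1L &
                 log$chosen_side != log$correct_side)
  if (length(odd) && warn_reward_incorrect) {
    warning("rewarded incorrect choice(s) at rows ",
            paste(utils::head(odd, 5), collapse = ", "),
            " (unexpected under the default task configuration)")
  }
  invisible(log)
}
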