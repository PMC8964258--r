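#' Overall task performance
#'
#' Fraction of correct choices among responded trials (non-responses excluded
#' from numerator and denominator).
#'
#' @param log A `trial_log` (one or several participants).
#' @param by_participant Return a per-participant tibble instead of the
#'   pooled fraction.
#' @return A fraction, or a tibble with columns `participant_id`,
#'   `n_responded`, `accuracy`.
#' @export
overall_performance <- function(log, by_participant = FALSE) {
  validate_trial_log(log, warn_reward_incorrect = FALSE)
  resp <- log[log$responded, ]
  if (by_participant) {
    out <- dplyr::summarise(
      dplyr::group_by(resp, .data$participant_id),
      n_responded = dplyr::n(),
      accuracy = mean(.data$chosen_side == .data$correct_side),
      .groups = "drop")
    return(out)
  }
  if (nrow(resp) == 0L) stop("no responded trials: performance undefined")
  mean(resp$chosen_side == resp$correct_side)
}

#' Switch-aligned accuracy curve
#'
#' Probability of selecting the correct box at trial offsets around a
#' reversal, where t = 0 is the first trial under the new contingency.
#' Offsets never cross block boundaries. Accuracy is first averaged over
#' reversal events within participant, then summarized across participants
#' (mean and standard error of the mean).
#'
#' @param logs A `trial_log`.
#' @param window Integer offsets relative to the reversal trial.
#' @return Tibble with columns `offset`, `p_correct`, `se`, `n_participants`.
#' @export
switch_aligned_accuracy <- function(logs, window = -4:5) {
  validate_trial_log(logs, warn_reward_incorrect = FALSE)
  rows <- list()
  for (key in unique(paste(logs$participant_id, logs$block_id, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    blk <- logs[logs$participant_id == parts[1] &
                  logs$block_id == as.integer(parts[2]), ]
    blk <- blk[order(blk$trial), ]
    rev_idx <- which(blk$reversal_trial)
    if (!length(rev_idx)) next
    for (r in rev_idx) {
      idx <- r + window
      ok <- idx >= 1L & idx <= nrow(blk)
      acc <- rep(NA_real_, length(window))
      sel <- idx[ok]
      resp <- blk$responded[sel]
      acc[ok] <- ifelse(resp, as.numeric(blk$chosen_side[sel] ==
                                           blk$correct_side[sel]), NA_real_)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant_id = parts[1], offset = window, correct = acc)
    }
  }
  if (!length(rows)) {
    warning("no reversals found in logs")
    return(tibble::tibble(offset = window, p_correct = NA_real_,
                          se = NA_real_, n_participants = 0L))
  }
  ev <- dplyr::bind_rows(rows)
  per_part <- dplyr::summarise(
    dplyr::group_by(ev, .data$participant_id, .data$offset),
    acc = mean(.data$correct, na.rm = TRUE), .groups = "drop")
  dplyr::summarise(
    dplyr::group_by(per_part, .data$offset),
    p_correct = mean(.data$acc, na.rm = TRUE),
    se = stats::sd(.data$acc, na.rm = TRUE) /
      sqrt(sum(!is.na(.data$acc))),
    n_participants = sum(!is.na(.data$acc)),
    .groups = "drop")
}

# Build the per-trial eligibility frame used by the history tables: for each
# responded trial with `n_back` responded in-block predecessors, the outcome
# symbols and stay indicators of those predecessors.
history_frame <- function(logs, n_back) {
  validate_trial_log(logs, warn_reward_incorrect = FALSE)
  out <- list()
  grp <- split(logs, list(logs$participant_id, logs$block_id), drop = TRUE)
  for (blk in grp) {
    blk <- blk[order(blk$trial), ]
    n <- nrow(blk)
    if (n <= n_back) next
    ch <- side_to_code(blk$chosen_side)
    rew <- blk$rewarded
    resp <- blk$responded
    for (t in (n_back + 1L):n) {
      if (!resp[t]) next
      lags <- (t - n_back):(t - 1L)
      if (!all(resp[lags])) next  # a non-response breaks history eligibility
      out[[length(out) + 1L]] <- list(
        participant_id = blk$participant_id[t],
        choice = ch[t],
        prev_choices = ch[lags],
        prev_rewards = rew[lags])
    }
  }
  out
}

history_key3 <- function(rewards) {
  paste(ifelse(rewards == 1L, "+", "-"), collapse = "")
}

all_history_keys3 <- function() {
  apply(expand.grid(c("-", "+"), c("-", "+"), c("-", "+"))[, 3:1], 1, paste,
        collapse = "")
}

#' Three-back stay-probability table
#'
#' Probability of repeating the previous trial's choice as a function of the
#' rewarded/unrewarded pattern of the last three trials. Keys are strings of
#' `+` (rewarded) and `-` (unrewarded) ordered (t-3, t-2, t-1). Histories
#' never cross block boundaries and any history containing a non-response is
#' discarded. Conditions with no eligible trials report `NA`, not zero.
#'
#' @param logs A `trial_log`.
#' @param by_participant Return per-participant tables (needed for the
#'   trait-correlation analyses).
#' @return Tibble with columns (`participant_id`,) `history`, `n`, `p_stay`.
#' @export
stay_table_3back <- function(logs, by_participant = FALSE) {
  hf <- history_frame(logs, 3L)
  keys <- all_history_keys3()
  rows <- if (length(hf)) {
    tibble::tibble(
      participant_id = vapply(hf, `[[`, "", "participant_id"),
      history = vapply(hf, function(h) history_key3(h$prev_rewards), ""),
      stay = vapply(hf, function(h) {
        as.numeric(h$choice == h$prev_choices[3])
      }, 0))
  } else {
    tibble::tibble(participant_id = character(), history = character(),
                   stay = numeric())
  }
  summarise_keyed(rows, keys, by_participant, value_name = "p_stay")
}

#' One-back stay probability
#'
#' Probability of repeating the previous choice conditioned on the previous
#' trial's outcome. `n_history` sets how many responded in-block predecessors
#' a trial needs to be eligible; `n_history = 3` restricts to the same trials
#' as [stay_table_3back()], so its unrewarded marginal equals the
#' count-weighted average of the four 3-back conditions ending `-`.
#'
#' @param logs A `trial_log`.
#' @param outcome Condition on a `"rewarded"` or `"unrewarded"` previous trial.
#' @param by_participant Per-participant output.
#' @param n_history Required responded predecessors (default 1).
#' @return A fraction, or a tibble with `participant_id`, `n`, `p_stay`.
#' @export
stay_probability_1back <- function(logs, outcome = c("unrewarded", "rewarded"),
                                   by_participant = FALSE, n_history = 1L) {
  outcome <- match.arg(outcome)
  want <- if (outcome == "rewarded") 1L else 0L
  hf <- history_frame(logs, as.integer(n_history))
  hf <- Filter(function(h) h$prev_rewards[length(h$prev_rewards)] == want, hf)
  if (!length(hf)) {
    if (by_participant) {
      return(tibble::tibble(participant_id = character(), n = integer(),
                            p_stay = numeric()))
    }
    return(NA_real_)
  }
  tab <- tibble::tibble(
    participant_id = vapply(hf, `[[`, "", "participant_id"),
    stay = vapply(hf, function(h) {
      as.numeric(h$choice == h$prev_choices[length(h$prev_choices)])
    }, 0))
  if (by_participant) {
    dplyr::summarise(dplyr::group_by(tab, .data$participant_id),
                     n = dplyr::n(), p_stay = mean(.data$stay),
                     .groups = "drop")
  } else {
    mean(tab$stay)
  }
}

ab_keys <- function() c("aa", "ab", "aA", "aB", "Aa", "Ab", "AA", "AB")

#' Action-conditioned two-back (aB) analysis
#'
#' For every trial with two responded in-block predecessors, classifies the
#' two-trial history into one of eight categories coded over (t-2, t-1): the
#' first character is always the reference action `a` (the action at t-2),
#' the second is `a` if the agent stayed at t-1 and `b` if it switched, and
#' letter case encodes the outcome. Under the default convention LOWERCASE =
#' unrewarded and UPPERCASE = rewarded, so `"ab"` reads "unrewarded a, then
#' an unrewarded switch to b". `p_a` is the probability of selecting the
#' reference action (the t-2 action) on trial t.
#'
#' @param logs A `trial_log`.
#' @param by_participant Per-participant tables.
#' @param convention `"lower_unrewarded"` (default) or `"upper_unrewarded"`;
#'   flips the case coding of outcomes.
#' @return Tibble with columns (`participant_id`,) `history`, `n`, `p_a`.
#' @export
ab_table <- function(logs, by_participant = FALSE,
                     convention = c("lower_unrewarded", "upper_unrewarded")) {
  convention <- match.arg(convention)
  hf <- history_frame(logs, 2L)
  case_of <- function(ch, rewarded) {
    up <- if (convention == "lower_unrewarded") rewarded == 1L else rewarded == 0L
    ifelse(up, toupper(ch), ch)
  }
  rows <- if (length(hf)) {
    tibble::tibble(
      participant_id = vapply(hf, `[[`, "", "participant_id"),
      history = vapply(hf, function(h) {
        first <- case_of("a", h$prev_rewards[1])
        stayed <- h$prev_choices[2] == h$prev_choices[1]
        second <- case_of(if (stayed) "a" else "b", h$prev_rewards[2])
        paste0(first, second)
      }, ""),
      stay = vapply(hf, function(h) as.numeric(h$choice == h$prev_choices[1]),
                    0))
  } else {
    tibble::tibble(participant_id = character(), history = character(),
                   stay = numeric())
  }
  summarise_keyed(rows, ab_keys(), by_participant, value_name = "p_a")
}

summarise_keyed <- function(rows, keys, by_participant, value_name) {
  template <- tibble::tibble(history = keys)
  if (by_participant) {
    ids <- unique(rows$participant_id)
    full <- dplyr::cross_join(tibble::tibble(participant_id = ids), template)
    agg <- dplyr::summarise(
      dplyr::group_by(rows, .data$participant_id, .data$history),
      n = dplyr::n(), value = mean(.data$stay), .groups = "drop")
    out <- dplyr::left_join(full, agg, by = c("participant_id", "history"))
  } else {
    agg <- dplyr::summarise(dplyr::group_by(rows, .data$history),
                            n = dplyr::n(), value = mean(.data$stay),
                            .groups = "drop")
    out <- dplyr::left_join(template, agg, by = "history")
  }
  out$n[is.na(out$n)] <- 0L
  names(out)[names(out) == "value"] <- value_name
  out
}

#' Exclusion criteria for session preprocessing
#'
#' @param min_accuracy Minimum overall accuracy among responded trials; the
#'   original performance criterion is unspecified, so the default (0.55,
#'   modestly above chance) is a documented, configurable choice.
#' @param min_response_rate Minimum fraction of trials with a response.
#' @param require_blocks If not `NULL`, participants must have at least this
#'   many blocks (analyses over both blocks jointly use 2).
#' @return A list of class `exclusion_criteria`.
#' @export
exclusion_criteria <- function(min_accuracy = 0.55, min_response_rate = 0.8,
                               require_blocks = NULL) {
  structure(list(min_accuracy = min_accuracy,
                 min_response_rate = min_response_rate,
                 require_blocks = require_blocks),
            class = "exclusion_criteria")
}

#' Filter participants by completeness and performance
#'
#' Drops participants who responded too rarely, performed below the accuracy
#' criterion, or (optionally) did not complete the required number of blocks,
#' and reports who was dropped and why.
#'
#' @param logs A `trial_log`.
#' @param criteria An [exclusion_criteria()] object.
#' @return List with `logs` (filtered) and `report` (tibble
#'   `participant_id`, `reason`).
#' @export
preprocess_sessions <- function(logs, criteria = exclusion_criteria()) {
  validate_trial_log(logs, warn_reward_incorrect = FALSE)
  report <- tibble::tibble(participant_id = character(), reason = character())
  drop <- character()
  for (pid in unique(logs$participant_id)) {
    pl <- logs[logs$participant_id == pid, ]
    rate <- mean(pl$responded)
    reason <- NULL
    if (rate < criteria$min_response_rate) {
      reason <- sprintf("response rate %.2f below %.2f", rate,
                        criteria$min_response_rate)
    } else if (mean(pl$chosen_side[pl$responded] ==
                      pl$correct_side[pl$responded]) < criteria$min_accuracy) {
      reason <- sprintf("accuracy below criterion %.2f", criteria$min_accuracy)
    } else if (!is.null(criteria$require_blocks) &&
               length(unique(pl$block_id)) < criteria$require_blocks) {
      reason <- sprintf("completed %d block(s), %d required",
                        length(unique(pl$block_id)), criteria$require_blocks)
    }
    if (!is.null(reason)) {
      drop <- c(drop, pid)
      report <- dplyr::bind_rows(report, tibble::tibble(
        participant_id = pid, reason = reason))
    }
  }
  list(logs = logs[!(logs$participant_id %in% drop), ], report = report)
}
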