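#' Default group-level parameter laws for synthetic cohorts
#'
#' Plausible moderate group distributions used when generating synthetic
#' participants. No published group-level values exist for this task, so the
#' defaults are documented choices: learning/accuracy parameters spread over
#' the identifiable part of their supports (under counterfactual updating the
#' two action values mirror each other, so behavior depends on a single value
#' difference that saturates for large reward learning rates; the positive
#' rate is therefore spread over the unit interval rather than concentrated
#' near saturation), an inverse temperature around 6 (fairly deterministic at
#' belief differences of ~0.5), a mildly positive stickiness, and a switch
#' belief near the task's true hazard rate.
#'
#' @param model `"rl"` or `"bi"`.
#' @return Named list of distribution settings.
#' @export
default_group_laws <- function(model = c("rl", "bi")) {
  model <- match.arg(model)
  if (model == "rl") {
    list(alpha_pos = list(dist = "beta", shape1 = 2, shape2 = 2),
         alpha_neg = list(dist = "beta", shape1 = 4, shape2 = 4),
         beta = list(dist = "gamma", shape = 12, rate = 2),
         st = list(dist = "tnorm", mean = 0.2, sd = 0.2, lo = -1, hi = 1))
  } else {
    list(p_reward = list(dist = "beta", shape1 = 6, shape2 = 2),
         p_switch = list(dist = "beta", shape1 = 2, shape2 = 18),
         beta = list(dist = "gamma", shape = 12, rate = 2),
         st = list(dist = "tnorm", mean = 0.2, sd = 0.2, lo = -1, hi = 1))
  }
}

law_quantile <- function(law, p) {
  switch(law$dist,
         beta = stats::qbeta(p, law$shape1, law$shape2),
         gamma = stats::qgamma(p, shape = law$shape, rate = law$rate),
         tnorm = qtnorm(p, law$mean, law$sd, law$lo, law$hi),
         stop("unknown distribution tag: ", law$dist))
}

plant_aliases <- c(stay_tendency = "st", loss_sensitivity = "alpha_neg")

#' Specification of a synthetic cohort
#'
#' Describes a complete synthetic dataset: participants playing one or two
#' blocks of the switching task with choices generated by a model-based agent
#' (or a scripted policy), trait questionnaire responses, and an optional
#' planted correlation between the trait total and a generating parameter.
#' Behavioral-tendency plants are expressed through a monotonically related
#' model parameter (`"stay_tendency"` maps to the stickiness `st`,
#' `"loss_sensitivity"` to the negative learning rate), preserving generative
#' coherence rather than rejection-sampling behavior.
#'
#' @param n_participants Number of participants.
#' @param blocks_per_participant 1 or 2 blocks each.
#' @param generating_model `"rl"`, `"bi"`, or a scripted policy tag
#'   accepted by [scripted_policy()].
#' @param group_laws Per-parameter group distributions (model-based agents).
#' @param plant Optional `list(target = <parameter or tendency>, rho = <r>)`
#'   with `rho` in `[-1, 1]`.
#' @param trait_law Marginal law of the trait total: a normal law matched to
#'   the observed spread of total impulsivity scores (mean 40, SD 8, clipped
#'   to 26--63), discretized to integers.
#' @param task A [task_config()].
#' @param seed Cohort seed; identical spec + seed reproduce the cohort
#'   bit-identically.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 70L,
                        blocks_per_participant = 2L,
                        generating_model = "rl",
                        group_laws = NULL,
                        plant = NULL,
                        trait_law = list(mean = 40, sd = 8, min = 26, max = 63),
                        task = task_config(),
                        seed = 1L) {
  n_participants <- as.integer(n_participants)
  if (n_participants < 1L) stop("n_participants must be >= 1")
  if (!blocks_per_participant %in% c(1L, 2L)) {
    stop("blocks_per_participant must be 1 or 2")
  }
  model_based <- generating_model %in% c("rl", "bi")
  if (model_based && is.null(group_laws)) {
    group_laws <- default_group_laws(generating_model)
  }
  if (!is.null(plant)) {
    if (is.null(plant$target) || is.null(plant$rho)) {
      stop("plant must be list(target = , rho = )")
    }
    if (abs(plant$rho) > 1) stop("planted rho must lie in [-1, 1]")
    if (!model_based) stop("plants require a model-based generating agent")
    target <- plant_aliases[plant$target]
    plant$target_param <- if (!is.na(target)) unname(target) else plant$target
    if (!plant$target_param %in% names(group_laws)) {
      stop("unknown plant target: ", plant$target)
    }
  }
  structure(list(n_participants = n_participants,
                 blocks_per_participant = as.integer(blocks_per_participant),
                 generating_model = generating_model,
                 group_laws = group_laws,
                 plant = plant,
                 trait_law = trait_law,
                 task = task,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Draw per-participant generating parameters and trait totals. The plant is a
# Gaussian copula: (z1, z2) bivariate standard normal with correlation rho,
# z1 mapped through the target parameter's quantile function and z2 through
# the trait marginal.
draw_cohort_params <- function(spec) {
  n <- spec$n_participants
  z_trait <- stats::rnorm(n)
  params <- NULL
  if (spec$generating_model %in% c("rl", "bi")) {
    params <- list()
    for (pn in names(spec$group_laws)) {
      z <- if (!is.null(spec$plant) && pn == spec$plant$target_param) {
        rho <- spec$plant$rho
        rho * z_trait + sqrt(1 - rho^2) * stats::rnorm(n)
      } else stats::rnorm(n)
      params[[pn]] <- law_quantile(spec$group_laws[[pn]], stats::pnorm(z))
    }
    params <- tibble::as_tibble(params)
  }
  tl <- spec$trait_law
  total <- as.integer(round(clip(tl$mean + tl$sd * z_trait, tl$min, tl$max)))
  list(params = params, trait_total = total)
}

# Distribute a total score over 20 items (scored scale, each 1..4) and
# un-reverse to raw responses; re-scoring returns the total exactly.
allocate_items <- function(total, schema) {
  scored <- rep(1L, schema$n_items)
  need <- total - schema$n_items
  while (need > 0L) {
    open <- which(scored < 4L)
    pick <- open[sample.int(length(open), 1L)]
    scored[pick] <- scored[pick] + 1L
    need <- need - 1L
  }
  raw <- scored
  raw[schema$reverse_items] <- 5L - scored[schema$reverse_items]
  raw
}

#' Generate a complete synthetic cohort
#'
#' Draws generating parameters from the group laws (with the optional plant),
#' simulates every participant's sessions through the task engine, assigns
#' trait totals, and reverse-engineers item responses so that re-scoring
#' through [score_supps()] returns the assigned totals exactly.
#'
#' @param spec A [cohort_spec()].
#' @param schema A [supps_schema()] for item allocation.
#' @return An object of class `cohort`: a list with `trial_log`, `params`
#'   (generating ground truth, `NULL` for scripted agents), `items`,
#'   `traits` ([score_supps()] output), `table` (per-participant summary)
#'   and `spec`.
#' @export
generate_cohort <- function(spec, schema = supps_schema()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_local_seed(spec$seed, {
    drawn <- draw_cohort_params(spec)
    ids <- sprintf("p%03d", seq_len(spec$n_participants))
    logs <- vector("list", spec$n_participants * spec$blocks_per_participant)
    k <- 0L
    for (i in seq_len(spec$n_participants)) {
      policy <- if (spec$generating_model %in% c("rl", "bi")) {
        p <- drawn$params[i, ]
        if (spec$generating_model == "rl") {
          agent_policy(rl_params(p$alpha_pos, p$alpha_neg, p$beta, p$st))
        } else {
          agent_policy(bi_params(p$p_reward, p$p_switch, p$beta, p$st))
        }
      } else {
        scripted_policy(spec$generating_model)
      }
      for (b in seq_len(spec$blocks_per_participant)) {
        version <- ((i + b - 2L) %% spec$task$n_sequence_versions) + 1L
        sched <- build_block_schedule(spec$task, version)
        logs[[k <- k + 1L]] <- run_session(sched, spec$task, policy,
                                           participant_id = ids[i],
                                           block_id = b)
      }
    }
    items <- t(vapply(drawn$trait_total, allocate_items, integer(20L),
                      schema = schema))
    colnames(items) <- paste0("item_", 1:20)
    items_tbl <- tibble::tibble(participant_id = ids,
                                tibble::as_tibble(items))
    traits <- score_supps(items_tbl, schema)
    params <- if (!is.null(drawn$params)) {
      tibble::tibble(participant_id = ids, drawn$params)
    } else NULL
    log <- dplyr::bind_rows(logs)
    class(log) <- c("trial_log", class(log))
    tab <- traits
    if (!is.null(params)) tab <- dplyr::left_join(params, tab, "participant_id")
    tab$n_blocks <- spec$blocks_per_participant
    structure(list(trial_log = log, params = params, items = items_tbl,
                   traits = traits, table = tab, spec = spec),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", x$spec$n_participants, " participants x ",
      x$spec$blocks_per_participant, " block(s), generator: ",
      x$spec$generating_model, sep = "")
  if (!is.null(x$spec$plant)) {
    cat(sprintf(" [plant: trait ~ %s, rho = %.2f]",
                x$spec$plant$target_param, x$spec$plant$rho))
  }
  cat("\n", nrow(x$trial_log), " trial rows; trait totals ",
      min(x$traits$total), "-", max(x$traits$total), "\n", sep = "")
  invisible(x)
}
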