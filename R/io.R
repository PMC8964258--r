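#' Write a trial log to delimited text
#'
#' One row per trial with the standard columns; missing values (chosen side
#' and reward on non-response trials) are written as empty fields.
#'
#' @param log A `trial_log`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(log, path) {
  validate_trial_log(log, warn_reward_incorrect = FALSE)
  utils::write.csv(as.data.frame(log), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trial log from delimited text
#'
#' Parses and validates a CSV trial log written by [write_trial_log()] (or
#' produced externally with the same header). Structural violations abort
#' with the offending line numbers; a rewarded incorrect choice — impossible
#' under the default task configuration — is retained but warned about.
#'
#' @param path Input CSV path.
#' @return A `trial_log` tibble.
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                  na.strings = ""),
                  error = function(e) stop("could not parse ", path, ": ",
                                           conditionMessage(e)))
  if (nrow(raw) == 0L) stop("empty trial log: ", path)
  need <- c("participant_id", "block_id", "trial", "correct_side",
            "chosen_side", "rewarded", "responded", "reversal_trial")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  bad_side <- which(!is.na(raw$chosen_side) &
                      !(raw$chosen_side %in% c("left", "right")))
  if (length(bad_side)) {
    stop("invalid chosen_side at line(s) ",
         paste(utils::head(bad_side + 1L, 5), collapse = ", "))
  }
  log <- tibble::tibble(
    participant_id = as.character(raw$participant_id),
    block_id = as.integer(raw$block_id),
    trial = as.integer(raw$trial),
    correct_side = as.character(raw$correct_side),
    chosen_side = as.character(raw$chosen_side),
    rewarded = as.integer(raw$rewarded),
    responded = as.logical(raw$responded),
    reversal_trial = as.logical(raw$reversal_trial))
  class(log) <- c("trial_log", class(log))
  validate_trial_log(log)
  log
}

#' Assemble or load a pipeline run configuration
#'
#' A run configuration groups the blocks consumed by [run_pipeline()]:
#' `task` (task design), `cohort` (synthetic cohort settings), `fitting`
#' (model tag and MCMC settings), `analysis` (exclusion criteria plus the
#' `exclude_ab_outliers` flag governing the p(a|ab) = 0 outlier rule in the
#' trait-correlation stage), `traits`,
#' plus a top-level `seed` and `out_dir`. Unknown top-level keys are rejected
#' by name.
#'
#' @param x Path to a YAML file, or a named list.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(x = list()) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  known <- c("task", "cohort", "fitting", "analysis", "traits", "seed",
             "out_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  task_args <- cfg$task %||% list()
  cfg$task_config <- do.call(task_config, task_args)
  structure(cfg, class = "run_config")
}

stage_file <- function(out_dir, name) file.path(out_dir, name)

require_artifact <- function(path, stage_needed, producing_stage) {
  if (!file.exists(path)) {
    stop("stage '", stage_needed, "' needs ", basename(path),
         ", which is produced by stage '", producing_stage,
         "'; run that stage first")
  }
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order against a shared output directory:
#' `simulate` (synthetic cohort to CSV/JSON), `analyze` (model-free
#' behavioral tables), `fit` (hierarchical model fit, estimates +
#' diagnostics + WAIC), `traits` (questionnaire scoring and gated
#' trait-behavior correlations plus the history GLMM), and `recover`
#' (generate-and-recover summary). Each run writes a manifest recording the
#' configuration hash, seed, stage timings and package version. A stage
#' whose upstream artifact is missing aborts with the name of the producing
#' stage.
#'
#' @param config A [run_config()] (or list/path coercible to one).
#' @param stages Ordered subset of
#'   `c("simulate", "analyze", "fit", "traits", "recover")`.
#' @param out_dir Output directory (created if absent); defaults to
#'   `config$out_dir`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "analyze", "fit", "traits",
                                    "recover"),
                         out_dir = NULL) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  valid <- c("simulate", "analyze", "fit", "traits", "recover")
  bad <- setdiff(stages, valid)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  out_dir <- out_dir %||% config$out_dir %||% stop("no out_dir configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  manifest_stages <- character()

  model_tag <- (config$fitting$model %||% config$cohort$generating_model) %||% "rl"

  for (stage in stages) {
    t0 <- Sys.time()
    if (stage == "simulate") {
      co <- config$cohort %||% list()
      spec <- cohort_spec(
        n_participants = co$n_participants %||% 20L,
        blocks_per_participant = co$blocks_per_participant %||% 2L,
        generating_model = co$generating_model %||% "rl",
        plant = co$plant,
        task = config$task_config,
        seed = config$seed)
      cohort <- generate_cohort(spec)
      write_trial_log(cohort$trial_log, stage_file(out_dir, "trial_log.csv"))
      utils::write.csv(as.data.frame(cohort$items),
                       stage_file(out_dir, "questionnaire.csv"),
                       row.names = FALSE)
      truth <- list(seed = config$seed,
                    generating_model = spec$generating_model,
                    plant = spec$plant)
      if (!is.null(cohort$params)) truth$params <- cohort$params
      jsonlite::write_json(truth, stage_file(out_dir, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
    } else if (stage == "analyze") {
      logs <- read_trial_log(require_artifact(
        stage_file(out_dir, "trial_log.csv"), "analyze", "simulate"))
      exc_args <- config$analysis %||% list()
      exc_args$exclude_ab_outliers <- NULL
      pp <- preprocess_sessions(logs, do.call(exclusion_criteria, exc_args))
      utils::write.csv(as.data.frame(pp$report),
                       stage_file(out_dir, "exclusions.csv"), row.names = FALSE)
      utils::write.csv(as.data.frame(switch_aligned_accuracy(pp$logs)),
                       stage_file(out_dir, "switch_curve.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(
        stay_table_3back(pp$logs, by_participant = TRUE)),
        stage_file(out_dir, "stay_3back.csv"), row.names = FALSE)
      utils::write.csv(as.data.frame(ab_table(pp$logs, by_participant = TRUE)),
                       stage_file(out_dir, "ab_table.csv"), row.names = FALSE)
      utils::write.csv(as.data.frame(
        overall_performance(pp$logs, by_participant = TRUE)),
        stage_file(out_dir, "performance.csv"), row.names = FALSE)
    } else if (stage == "fit") {
      logs <- read_trial_log(require_artifact(
        stage_file(out_dir, "trial_log.csv"), "fit", "simulate"))
      fs <- config$fitting %||% list()
      settings <- mcmc_settings(fs$n_chains %||% 2L, fs$n_warmup %||% 500L,
                                fs$n_iter %||% 1000L, seed = config$seed)
      fit <- fit_hierarchical(logs, model_tag, settings = settings)
      utils::write.csv(as.data.frame(fit$estimates),
                       stage_file(out_dir, "estimates.csv"), row.names = FALSE)
      utils::write.csv(as.data.frame(fit$diagnostics),
                       stage_file(out_dir, "diagnostics.csv"),
                       row.names = FALSE)
      w <- compute_waic(fit)
      jsonlite::write_json(list(model = model_tag, waic = w$waic, se = w$se,
                                converged = fit$converged),
                           stage_file(out_dir, "waic.json"),
                           auto_unbox = TRUE, digits = NA)
    } else if (stage == "traits") {
      logs <- read_trial_log(require_artifact(
        stage_file(out_dir, "trial_log.csv"), "traits", "simulate"))
      items <- utils::read.csv(require_artifact(
        stage_file(out_dir, "questionnaire.csv"), "traits", "simulate"))
      traits <- score_supps(items)
      utils::write.csv(as.data.frame(traits),
                       stage_file(out_dir, "trait_scores.csv"),
                       row.names = FALSE)
      tab3 <- stay_table_3back(logs, by_participant = TRUE)
      loss3 <- tab3[tab3$history == "---", ]
      perf <- overall_performance(logs, by_participant = TRUE)
      m <- match(traits$participant_id, perf$participant_id)
      cors <- list(performance = gated_correlation(traits$total,
                                                   perf$accuracy[m]))
      m3 <- match(traits$participant_id, loss3$participant_id)
      if (sum(!is.na(loss3$p_stay[m3])) >= 4) {
        cors$p_stay_3loss <- gated_correlation(traits$total,
                                               loss3$p_stay[m3])
      }
      # p(a|ab) correlation with the outlier rule: participants with
      # p(a|ab) = 0 are excluded from this correlation by default
      # (analysis$exclude_ab_outliers = FALSE retains them)
      ab <- ab_table(logs, by_participant = TRUE)
      pab <- ab[ab$history == "ab", ]
      p_ab <- pab$p_a[match(traits$participant_id, pab$participant_id)]
      use_rule <- config$analysis$exclude_ab_outliers %||% TRUE
      keep <- !is.na(p_ab) & (!use_rule | p_ab > 0)
      if (sum(keep) >= 4 && stats::sd(p_ab[keep]) > 0 &&
          stats::sd(traits$total[keep]) > 0) {
        cors$p_a_ab <- gated_correlation(traits$total[keep], p_ab[keep])
      }
      cor_tbl <- dplyr::bind_rows(lapply(names(cors), function(nm) {
        g <- cors[[nm]]
        tibble::tibble(measure = nm, method = g$method,
                       estimate = g$estimate, p_value = g$p_value, n = g$n)
      }))
      utils::write.csv(as.data.frame(cor_tbl),
                       stage_file(out_dir, "trait_correlations.csv"),
                       row.names = FALSE)
      design <- build_history_design(logs, traits = traits)
      glmm <- fit_history_glmm(design)
      utils::write.csv(as.data.frame(glmm$coefficients),
                       stage_file(out_dir, "glmm_coefficients.csv"),
                       row.names = FALSE)
    } else if (stage == "recover") {
      fs <- config$fitting %||% list()
      rec <- generate_and_recover(
        model = model_tag,
        n_participants = (config$cohort$n_participants %||% 20L),
        blocks_per = (config$cohort$blocks_per_participant %||% 2L),
        seed = config$seed,
        settings = mcmc_settings(fs$n_chains %||% 2L, fs$n_warmup %||% 500L,
                                 fs$n_iter %||% 1000L, seed = config$seed))
      utils::write.csv(as.data.frame(rec$comparison),
                       stage_file(out_dir, "recovery_comparison.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(parameter = names(rec$correlations),
                                  correlation = unname(rec$correlations)),
                       stage_file(out_dir, "recovery_correlations.csv"),
                       row.names = FALSE)
    }
    timings[[stage]] <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    manifest_stages <- c(manifest_stages, stage)
  }

  hash_cfg <- config
  hash_cfg$out_dir <- NULL  # location must not change the identity hash
  manifest <- list(
    config_hash = rlang::hash(hash_cfg),
    seed = config$seed,
    stages = manifest_stages,
    timings_sec = timings,
    package_version = as.character(utils::packageVersion("probswitch")),
    r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, stage_file(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
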