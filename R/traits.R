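#' S-UPPS-P questionnaire schema
#'
#' Structural layout of the short UPPS-P impulsive behavior scale: 20 items
#' rated 1 (strongly agree) to 4 (strongly disagree), five subscales of four
#' items each (Negative Urgency, lack of Premeditation, lack of Perseverance,
#' Sensation Seeking, Positive Urgency), and 12 reverse-scored items so that
#' higher scores always reflect more impulsivity. The published instrument
#' does not enumerate its item-to-subscale layout alongside the scoring rule,
#' so the default layout here is a documented placeholder (items 1-4, 5-8,
#' ... by subscale; items 5-16 reverse-scored): every analysis depends only
#' on the schema's structure, and both maps are configurable.
#'
#' @param reverse_items Integer indices of reverse-scored items.
#' @param subscale_map Named list of 5 subscales, each with 4 item indices.
#' @return An object of class `supps_schema`.
#' @export
supps_schema <- function(reverse_items = 5:16,
                         subscale_map = list(
                           negative_urgency = 1:4,
                           premeditation = 5:8,
                           perseverance = 9:12,
                           sensation_seeking = 13:16,
                           positive_urgency = 17:20)) {
  items <- sort(unlist(subscale_map, use.names = FALSE))
  if (!identical(items, 1:20)) {
    stop("subscale_map must assign each of items 1..20 to exactly one subscale")
  }
  if (length(subscale_map) != 5L || any(lengths(subscale_map) != 4L)) {
    stop("expected 5 subscales of 4 items each")
  }
  reverse_items <- as.integer(reverse_items)
  if (any(reverse_items < 1L | reverse_items > 20L)) {
    stop("reverse_items must index items 1..20")
  }
  structure(list(n_items = 20L, response_range = c(1L, 4L),
                 reverse_items = reverse_items, subscale_map = subscale_map),
            class = "supps_schema")
}

item_matrix <- function(items) {
  if (is.data.frame(items)) {
    id_col <- intersect(c("participant_id", "id"), names(items))
    ids <- if (length(id_col)) as.character(items[[id_col[1]]])
           else as.character(seq_len(nrow(items)))
    m <- as.matrix(items[, setdiff(names(items), id_col), drop = FALSE])
    rownames(m) <- ids
  } else {
    m <- as.matrix(items)
    if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  }
  storage.mode(m) <- "integer"
  m
}

#' Score the S-UPPS-P questionnaire
#'
#' Applies reverse coding (`r -> 5 - r`) to the schema's reverse items, sums
#' items into subscale scores and the total (possible range 20--80), and
#' z-scores the total over the scored cohort.
#'
#' @param items Participant-by-item table: a data frame with an optional
#'   `participant_id` column plus 20 item columns, or a numeric matrix.
#' @param schema A [supps_schema()].
#' @return Tibble with `participant_id`, `total`, one column per subscale,
#'   and `z_total`.
#' @export
score_supps <- function(items, schema = supps_schema()) {
  m <- item_matrix(items)
  if (ncol(m) != schema$n_items) {
    stop("expected ", schema$n_items, " item columns, got ", ncol(m))
  }
  if (anyNA(m)) stop("missing item responses (no imputation policy set)")
  if (any(m < schema$response_range[1] | m > schema$response_range[2])) {
    stop("item responses must lie in ", schema$response_range[1], "..",
         schema$response_range[2])
  }
  scored <- m
  scored[, schema$reverse_items] <- 5L - m[, schema$reverse_items]
  total <- rowSums(scored)
  out <- tibble::tibble(participant_id = rownames(m), total = as.integer(total))
  for (sc in names(schema$subscale_map)) {
    out[[sc]] <- as.integer(rowSums(scored[, schema$subscale_map[[sc]],
                                           drop = FALSE]))
  }
  out$z_total <- if (length(total) > 1L && stats::sd(total) > 0) {
    as.numeric(scale(total))
  } else rep(0, length(total))
  out
}

#' Reverse-code questionnaire responses
#'
#' Maps responses `r -> 5 - r` on the schema's reverse items; applying it
#' twice returns the raw responses.
#'
#' @inheritParams score_supps
#' @return Matrix of the same shape.
#' @export
reverse_code <- function(items, schema = supps_schema()) {
  m <- item_matrix(items)
  m[, schema$reverse_items] <- 5L - m[, schema$reverse_items]
  m
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a scale:
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total score))`.
#'
#' @param items Participant-by-item responses for one scale (matrix or data
#'   frame of numeric columns).
#' @return Alpha as a single number.
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  if (ncol(m) < 2L || nrow(m) < 2L) stop("need >= 2 items and >= 2 participants")
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) stop("zero total-score variance: alpha undefined")
  k <- ncol(m)
  (k / (k - 1)) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Normality-gated correlation
#'
#' Correlates two per-participant measures using Pearson correlation unless
#' either variable fails the Shapiro-Wilk normality test at `alpha_norm`, in
#' which case Spearman correlation is used. The report names the method.
#'
#' @param x,y Paired numeric vectors.
#' @param alpha_norm Significance level of the normality gate.
#' @return List of class `gated_cor` with `method`, `estimate`, `p_value`,
#'   `n`, and the two Shapiro-Wilk p-values.
#' @export
gated_correlation <- function(x, y, alpha_norm = 0.05) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined")
  }
  sw_x <- stats::shapiro.test(x)$p.value
  sw_y <- stats::shapiro.test(y)$p.value
  method <- if (sw_x > alpha_norm && sw_y > alpha_norm) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  structure(list(method = method, estimate = unname(ct$estimate),
                 p_value = ct$p.value, n = length(x),
                 shapiro_p_x = sw_x, shapiro_p_y = sw_y),
            class = "gated_cor")
}

#' @export
print.gated_cor <- function(x, ...) {
  cat(sprintf("<gated_cor> %s %s = %.3f, p = %.4g (n = %d; Shapiro-Wilk p: %.3g, %.3g)\n",
              x$method, if (x$method == "pearson") "r" else "rho",
              x$estimate, x$p_value, x$n, x$shapiro_p_x, x$shapiro_p_y))
  invisible(x)
}

#' Build the lagged-outcome design matrix for the history regression
#'
#' One row per responded trial with three responded in-block predecessors.
#' The response `action` is 0 for left and 1 for right. For lag `i`, `pos_i`
#' is -1 if the left box was rewarded on trial t-i, +1 if the right box was
#' rewarded, and 0 if no positive outcome occurred then; `neg_i` is coded the
#' same way for unrewarded outcomes. A responded lag therefore has exactly
#' one of `pos_i`/`neg_i` nonzero.
#'
#' @param logs A `trial_log`.
#' @param traits Optional [score_supps()] table; when supplied, the z-scored
#'   total is joined as `imp_z` (for the impulsivity-interaction model).
#' @param n_back Number of lags (default 3).
#' @return Tibble with `id`, `action`, `pos_1..pos_n`, `neg_1..neg_n` and
#'   optionally `imp_z`.
#' @export
build_history_design <- function(logs, traits = NULL, n_back = 3L) {
  hf <- history_frame(logs, n_back)
  if (!length(hf)) stop("no eligible trials for the history design")
  n <- length(hf)
  id <- vapply(hf, `[[`, "", "participant_id")
  action <- vapply(hf, `[[`, 0L, "choice")
  out <- tibble::tibble(id = id, action = as.integer(action))
  # prev vectors are ordered (t-n_back .. t-1); lag i counts back from t
  for (i in seq_len(n_back)) {
    pos_i <- neg_i <- numeric(n)
    for (r in seq_len(n)) {
      h <- hf[[r]]
      j <- n_back - i + 1L
      signed <- if (h$prev_choices[j] == 0L) -1 else 1
      if (h$prev_rewards[j] == 1L) pos_i[r] <- signed else neg_i[r] <- signed
    }
    out[[paste0("pos_", i)]] <- pos_i
    out[[paste0("neg_", i)]] <- neg_i
  }
  if (!is.null(traits)) {
    miss <- setdiff(unique(id), traits$participant_id)
    if (length(miss)) {
      stop("trait scores missing for participant(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
    }
    out$imp_z <- traits$z_total[match(out$id, traits$participant_id)]
  }
  out
}

#' Fit the random-intercept logistic history regression
#'
#' Fits `action ~ pos_1 + neg_1 + ... + (1 | id)` by `lme4::glmer`, adding a
#' main effect of the z-scored impulsivity total and its interaction with
#' every lagged predictor when the design carries `imp_z`. Reports the fixed
#' effect table (estimate, SE, z, p), the random-intercept variance, and
#' marginal/conditional pseudo-R-squared (latent-scale variance partition
#' with logistic residual variance pi^2/3).
#'
#' @param design A [build_history_design()] tibble.
#' @return List of class `history_glmm`: `coefficients` (tibble), `tau00`,
#'   `icc`, `r2_marginal`, `r2_conditional`, `n_obs`, `n_id`, `converged`,
#'   and the underlying `model`.
#' @export
fit_history_glmm <- function(design) {
  if (length(unique(design$id)) < 2L) stop("need >= 2 participants")
  preds <- grep("^(pos|neg)_", names(design), value = TRUE)
  keep <- preds[vapply(design[preds], function(v) stats::sd(v) > 0, TRUE)]
  rhs <- if (!length(keep)) "1" else paste(keep, collapse = " + ")
  if ("imp_z" %in% names(design) && length(keep)) {
    rhs <- paste0("imp_z + ", rhs, " + imp_z:(", paste(keep, collapse = " + "), ")")
  }
  f <- stats::as.formula(paste0("action ~ ", rhs, " + (1 | id)"))
  messages <- character()
  fit <- withCallingHandlers(
    lme4::glmer(f, data = design, family = stats::binomial()),
    warning = function(w) {
      messages <<- c(messages, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  coef_tbl <- tibble::tibble(term = rownames(co),
                             estimate = co[, "Estimate"],
                             se = co[, "Std. Error"],
                             z = co[, "z value"],
                             p = co[, "Pr(>|z|)"])
  tau00 <- as.numeric(lme4::VarCorr(fit)$id[1, 1])
  var_resid <- pi^2 / 3
  var_fixed <- stats::var(as.numeric(stats::model.matrix(fit) %*%
                                       lme4::fixef(fit)))
  denom <- var_fixed + tau00 + var_resid
  structure(list(coefficients = coef_tbl,
                 tau00 = tau00,
                 icc = tau00 / (tau00 + var_resid),
                 r2_marginal = var_fixed / denom,
                 r2_conditional = (var_fixed + tau00) / denom,
                 n_obs = nrow(design),
                 n_id = length(unique(design$id)),
                 converged = length(messages) == 0L,
                 messages = messages,
                 model = fit),
            class = "history_glmm")
}

#' @export
print.history_glmm <- function(x, ...) {
  cat("<history_glmm> random-intercept logistic regression:",
      x$n_obs, "trials,", x$n_id, "participants\n")
  print(as.data.frame(x$coefficients), digits = 3)
  cat(sprintf("tau00(id) = %.3f  ICC = %.3f  R2 marginal/conditional = %.3f/%.3f%s\n",
              x$tau00, x$icc, x$r2_marginal, x$r2_conditional,
              if (!x$converged) "  [convergence flagged]" else ""))
  invisible(x)
}

#' Median-split summary of a behavioral measure
#'
#' Splits participants into low/high impulsivity groups at the sample median
#' of the total score (ties at the median go to the low group) and summarizes
#' a behavioral measure per group.
#'
#' @param cohort Tibble with `total` and the measure column, one row per
#'   participant.
#' @param measure Name of the measure column.
#' @return Tibble with `group`, `n`, `mean`, `se`; a degenerate split (all
#'   scores identical) is flagged via the `degenerate` attribute.
#' @export
median_split_summary <- function(cohort, measure) {
  stopifnot(measure %in% names(cohort), "total" %in% names(cohort))
  if (nrow(cohort) < 2L) stop("need >= 2 participants")
  med <- stats::median(cohort$total)
  grp <- ifelse(cohort$total <= med, "low", "high")
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(group = factor(grp, c("low", "high")),
                                   value = cohort[[measure]]),
                    .data$group, .drop = FALSE),
    n = sum(!is.na(.data$value)),
    mean = mean(.data$value, na.rm = TRUE),
    se = stats::sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
    .groups = "drop")
  attr(out, "degenerate") <- length(unique(cohort$total)) == 1L
  out
}

#' Bonferroni multiple-comparison gate
#'
#' Family-wise error control by Bonferroni: a p-value is significant after
#' correction iff `p < level / family_size`. Reports both raw and adjusted
#' decisions.
#'
#' @param p_values Numeric vector of raw p-values.
#' @param family_size Number of analyses in the family
#'   (`>= length(p_values)`).
#' @param level Family-wise significance level.
#' @return Tibble with `p`, `significant_raw`, `significant_bonferroni`, and
#'   the adjusted threshold as attribute `threshold`.
#' @export
multiple_comparison_gate <- function(p_values, family_size, level = 0.05) {
  if (family_size < length(p_values)) {
    stop("family_size must be >= the number of p-values")
  }
  thr <- level / family_size
  out <- tibble::tibble(p = p_values,
                        significant_raw = p_values < level,
                        significant_bonferroni = p_values < thr)
  attr(out, "threshold") <- thr
  out
}
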