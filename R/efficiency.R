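#' Balanced integration score (BIS)
#'
#' Per-trial communication efficiency: standardized accuracy minus
#' standardized response time, z-scored within each interaction so that
#' different dyads are mapped onto a common scale. Accuracy is z-scored as
#' its raw 0/1 values. Trials flagged as timeouts are excluded (the score is
#' response-time based). With `scope = "balanced_prepost_16"` the z-scoring
#' set is restricted to the balanced 16 pre- and post-phase trials, guarding
#' against artifacts from the 3:1 imbalance of repeated vs. control trials.
#'
#' @param trials Trial tibble (see [interaction_record()]); may pool several
#'   dyads — z-scoring is always within `dyad_id` (or `participant_id` if
#'   present and `dyad_id` absent).
#' @param scope `"all_within_interaction"` (default) or
#'   `"balanced_prepost_16"`.
#' @return The in-scope trials with `z_accuracy`, `z_rt` and `bis` columns
#'   and a `scope` column recording the z-scoring set. If every in-scope
#'   trial of an interaction has the same accuracy, its `z_accuracy` is set
#'   to 0 with a warning; constant response times are an error.
#' @export
compute_bis <- function(trials, scope = c("all_within_interaction",
                                          "balanced_prepost_16")) {
  scope <- match.arg(scope)
  unit <- if ("dyad_id" %in% names(trials)) "dyad_id" else "participant_id"
  if (!unit %in% names(trials)) abort("trials need a dyad_id or participant_id column")
  tr <- trials
  if ("timeout" %in% names(tr)) tr <- tr[!as.logical(tr$timeout), ]
  if (scope == "balanced_prepost_16") tr <- tr[tr$phase %in% c("pre", "post"), ]

  out <- lapply(split(tr, tr[[unit]]), function(g) {
    if (nrow(g) < 2) abort("need >= 2 in-scope trials per interaction")
    if (sd(g$rt_sec) == 0) {
      abort(sprintf("interaction %s: zero variance in rt_sec; BIS undefined",
                    g[[unit]][1]))
    }
    if (sd(g$accuracy) == 0) {
      warn(sprintf("interaction %s: accuracy has zero variance; z_accuracy set to 0",
                   g[[unit]][1]))
      g$z_accuracy <- 0
    } else {
      g$z_accuracy <- as.numeric(scale(g$accuracy))
    }
    g$z_rt <- as.numeric(scale(g$rt_sec))
    g$bis <- g$z_accuracy - g$z_rt
    g
  })
  out <- dplyr::bind_rows(out)
  out$scope <- scope
  out
}

new_trend_fit <- function(term, estimate, statistic, df, p_value, method,
                          converged, coefs = NULL, model = NULL) {
  structure(list(term = term, estimate = estimate, statistic = statistic,
                 df = df, p_value = p_value, method = method,
                 converged = converged, coefs = coefs, model = model),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit %s: b = %.4g, %s = %.3g, p = %.3g [%s%s]>\n",
              x$term, x$estimate,
              if (grepl("logistic", x$method)) "z" else "t",
              x$statistic, x$p_value, x$method,
              if (isTRUE(x$converged)) "" else ", fallback/non-converged"))
  invisible(x)
}

# try a sequence of mixed-model formulas, falling back to simpler random
# effects when a fit errors out or fails to converge; mirrors the common
# practice of pruning a maximal random-effects structure. Boundary
# (singular) fits are valid maximum-likelihood estimates whose variance
# components sit at 0 -- they are kept, not pruned: discarding them in
# favor of a simpler structure silently trades dyad-level degrees of
# freedom for observation-level ones and makes slope tests anticonservative.
fit_lmm_chain <- function(formulas, data, binomial = FALSE) {
  for (fi in seq_along(formulas)) {
    f <- formulas[[fi]]
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        if (binomial) {
          lme4::glmer(f, data = data, family = stats::binomial)
        } else {
          lmerTest::lmer(f, data = data)
        }
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    msgs <- fit@optinfo$conv$lme4$messages %||% character()
    msgs <- msgs[!grepl("boundary \\(singular\\)", msgs)]
    conv_ok <- length(msgs) == 0
    if (conv_ok || fi == length(formulas)) {
      return(list(fit = fit, formula = f, converged = conv_ok, maximal = fi == 1))
    }
  }
  NULL
}

extract_term <- function(fit_info, term, binomial = FALSE) {
  sm <- suppressWarnings(summary(fit_info$fit))
  co <- stats::coef(sm)
  if (!term %in% rownames(co)) {
    abort(sprintf("term '%s' absent from fitted model", term))
  }
  row <- co[term, ]
  if (binomial) {
    new_trend_fit(term, row[["Estimate"]], row[["z value"]], NA_real_,
                  row[["Pr(>|z|)"]],
                  paste0("glmer logistic: ", deparse1(fit_info$formula)),
                  fit_info$converged, coefs = co, model = fit_info$fit)
  } else {
    new_trend_fit(term, row[["Estimate"]], row[["t value"]], row[["df"]],
                  row[["Pr(>|t|)"]],
                  paste0("lmer: ", deparse1(fit_info$formula)),
                  fit_info$converged, coefs = co, model = fit_info$fit)
  }
}

#' Repetition trend in communicative efficiency
#'
#' Fits the repetition trajectory of an outcome over the eight appearances
#' of the repeated objects: the appearance index enters as a continuous
#' linear predictor (integers 1-8) together with its orthogonalized
#' quadratic, with random intercepts and linear slopes per dyad. Continuous
#' outcomes are first averaged within dyad x appearance cells (a balanced
#' two-stage summary: trial-level BIS mixes a binary and a lognormal
#' component, and the cell means stabilize its distribution without changing
#' the slope's expectation); set `aggregate = FALSE` for a trial-level fit.
#' Accuracy is analyzed by trial-level mixed logistic regression with the
#' same fixed effects. If no mixed model can be fit, the fallback estimates
#' one slope per dyad and tests them against 0 with a one-sample t test
#' (recorded in `method`).
#'
#' @param eff Output of [compute_bis()] (or any trial tibble with the
#'   outcome) carrying a `rep_idx` appearance column; only repeated-condition
#'   rows are used.
#' @param outcome One of `"bis"`, `"accuracy"`, `"rt"`, `"n_strokes"`.
#' @param aggregate Average continuous outcomes within dyad x appearance
#'   cells before fitting?
#' @return A `trend_fit` for the linear repetition term.
#' @export
fit_repetition_trend <- function(eff, outcome = c("bis", "accuracy", "rt",
                                                  "n_strokes"),
                                 aggregate = TRUE) {
  outcome <- match.arg(outcome)
  ycol <- switch(outcome, bis = "bis", accuracy = "accuracy",
                 rt = "rt_sec", n_strokes = "n_strokes")
  unit <- if ("dyad_id" %in% names(eff)) "dyad_id" else "participant_id"
  if (!"rep_idx" %in% names(eff)) {
    eff$rep_idx <- appearance_index(eff$phase, eff$repetition)
  }
  d <- eff[eff$condition == "repeated" & !is.na(eff[[ycol]]), ]
  if (length(unique(d$rep_idx)) < 2) abort("need >= 2 repetition levels")
  if (length(unique(d[[unit]])) == 1 && length(unique(d$rep_idx)) < 3) {
    abort("a single dyad needs >= 3 repetition levels")
  }
  d$y <- d[[ycol]]
  d$unit <- d[[unit]]
  binomial <- outcome == "accuracy"
  if (aggregate && !binomial) {
    d <- dplyr::summarise(dplyr::group_by(d, .data$unit, .data$rep_idx),
                          y = mean(.data$y), .groups = "drop")
  }
  d$rep_c <- as.numeric(d$rep_idx)
  d$rep_q <- poly(d$rep_idx, 2)[, 2]
  forms <- list(y ~ rep_c + rep_q + (1 + rep_c | unit),
                y ~ rep_c + rep_q + (1 | unit))
  info <- fit_lmm_chain(forms, d, binomial = binomial)
  if (!is.null(info)) return(extract_term(info, "rep_c", binomial = binomial))

  # per-dyad slope fallback
  slopes <- vapply(split(d, d$unit), function(g) {
    unname(coef(lm(y ~ rep_c, data = g))[2])
  }, 0)
  tt <- t.test(slopes)
  new_trend_fit("rep_c", mean(slopes), unname(tt$statistic),
                unname(tt$parameter), tt$p.value,
                "fallback: per-dyad slopes, one-sample t test", FALSE)
}

#' Pre/post by condition interaction in efficiency
#'
#' Tests whether efficiency improves more from the pre to the post phase for
#' repeated than for control objects: fixed effects of phase, condition and
#' their interaction, with by-dyad random effects (pruned on
#' non-convergence). Factors are coded with `pre` and `control` as reference
#' levels, so a positive interaction means a larger pre-to-post gain for
#' repeated objects.
#'
#' @param eff Output of [compute_bis()]; needs both phases and conditions.
#' @param outcome `"bis"` (linear) or `"accuracy"` (logistic).
#' @return A `trend_fit` for the `phase x condition` interaction.
#' @export
fit_prepost_interaction <- function(eff, outcome = c("bis", "accuracy")) {
  outcome <- match.arg(outcome)
  unit <- if ("dyad_id" %in% names(eff)) "dyad_id" else "participant_id"
  d <- eff[eff$phase %in% c("pre", "post"), ]
  cells <- table(d$phase, d$condition)
  want <- expand.grid(phase = c("pre", "post"),
                      condition = c("control", "repeated"))
  for (i in seq_len(nrow(want))) {
    ph <- as.character(want$phase[i]); cd <- as.character(want$condition[i])
    if (!ph %in% rownames(cells) || !cd %in% colnames(cells) ||
        cells[ph, cd] == 0) {
      abort(sprintf("empty design cell: phase=%s, condition=%s", ph, cd))
    }
  }
  d$phase <- factor(d$phase, levels = c("pre", "post"))
  d$condition <- factor(d$condition, levels = c("control", "repeated"))
  d$y <- if (outcome == "bis") d$bis else d$accuracy
  d$unit <- d[[unit]]
  binomial <- outcome == "accuracy"
  forms <- list(y ~ phase * condition + (1 + phase * condition | unit),
                y ~ phase * condition + (1 + phase + condition | unit),
                y ~ phase * condition + (1 | unit))
  info <- fit_lmm_chain(forms, d, binomial = binomial)
  if (is.null(info)) abort("all mixed fits failed for the pre/post interaction")
  extract_term(info, "phasepost:conditionrepeated", binomial = binomial)
}

#' Group by repetition interaction (yoked vs. shuffled)
#'
#' Tests whether recognition efficiency improves at different rates across
#' groups that differ in interaction-history continuity: fixed effects of
#' group, repetition number and their interaction, with per-participant
#' random intercepts and repetition slopes. The first group level is the
#' reference; a positive interaction means the second level improves faster.
#'
#' @param eff_by_group Tibble with `group`, `rep_idx`, `bis` and a
#'   `participant_id` (or `dyad_id`) column; typically [compute_bis()] output
#'   on pooled recognition trials.
#' @param group_levels Factor order of the groups (reference first).
#' @return A `trend_fit` for the `group x repetition` interaction.
#' @export
fit_group_repetition_interaction <- function(eff_by_group,
                                             group_levels = c("shuffled", "yoked")) {
  d <- eff_by_group
  unit <- if ("participant_id" %in% names(d)) "participant_id" else "dyad_id"
  if (!all(c("group", "rep_idx", "bis") %in% names(d))) {
    abort("eff_by_group needs group, rep_idx and bis columns")
  }
  for (g in unique(d$group)) {
    if (length(unique(d$rep_idx[d$group == g])) < 2) {
      abort(sprintf("group %s has a single repetition level", g))
    }
  }
  d$group <- factor(d$group, levels = group_levels)
  d$rep_c <- as.numeric(d$rep_idx)
  d$unit <- d[[unit]]
  forms <- list(bis ~ group * rep_c + (1 + rep_c | unit),
                bis ~ group * rep_c + (1 | unit))
  info <- fit_lmm_chain(forms, d)
  if (is.null(info)) abort("all mixed fits failed for the group x repetition interaction")
  extract_term(info, paste0("group", group_levels[2], ":rep_c"))
}
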