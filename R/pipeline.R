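#' Run the full analysis pipeline on a simulated cohort
#'
#' Executes every stage end to end: simulate a cohort, score communicative
#' efficiency (BIS) and fit the repetition trend, stroke-count trend and
#' pre/post-by-condition interaction (both z-scoring scopes), compute
#' within-dyad convergence and between-dyad divergence of drawing embeddings
#' with the scramble permutation null, and run the pre/post diagnosticity
#' contrast. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param n_perm Permutations for the divergence null.
#' @param cohort Optional pre-simulated cohort (skips simulation).
#' @return A list of class `sketchcomm_report` with elements `config_hash`,
#'   `package_version`, `n_dyads`, per-analysis `trend_fit`s, the
#'   permutation result, and the similarity series.
#' @export
run_pipeline <- function(config = sim_config(), n_perm = 500, cohort = NULL) {
  cohort <- cohort %||% simulate_cohort(config)
  trials <- cohort_trials(cohort)

  eff <- compute_bis(trials, scope = "all_within_interaction")
  eff16 <- compute_bis(trials, scope = "balanced_prepost_16")

  bis_trend <- fit_repetition_trend(eff, "bis")
  strokes_trend <- fit_repetition_trend(eff, "n_strokes")
  rt_trend <- fit_repetition_trend(eff, "rt")
  prepost <- fit_prepost_interaction(eff)
  prepost16 <- fit_prepost_interaction(eff16)

  dw <- cohort_drawings(cohort)
  dw_rep <- dw[dw$condition == "repeated", ]
  conv <- within_convergence(dw_rep)
  div <- between_divergence(dw_rep)
  perm <- scramble_permutation_test(dw_rep, n_perm = n_perm,
                                    seed = child_seed(config$seed, 99L))

  scores <- cohort_diagnosticity_scores(cohort)
  diag_fit <- prepost_diagnosticity_analysis(scores)

  structure(list(
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(packageVersion("sketchcomm")),
    n_dyads = length(cohort$interactions),
    mean_accuracy = mean(trials$accuracy),
    first_appearance_accuracy = mean(trials$accuracy[trials$rep_idx == 1]),
    bis_trend = bis_trend, strokes_trend = strokes_trend,
    rt_trend = rt_trend,
    prepost_interaction = prepost, prepost_interaction_balanced16 = prepost16,
    convergence = conv, divergence = div, permutation = perm,
    diagnosticity = diag_fit, diagnosticity_scores = scores
  ), class = "sketchcomm_report")
}

#' @export
print.sketchcomm_report <- function(x, ...) {
  cat("== sketchcomm pipeline report ==\n")
  cat(sprintf("dyads: %d  config: %s  version: %s\n",
              x$n_dyads, x$config_hash, x$package_version))
  cat(sprintf("viewer accuracy: %.1f%% overall, %.1f%% at first appearance\n",
              100 * x$mean_accuracy, 100 * x$first_appearance_accuracy))
  cat("efficiency (BIS) repetition trend:   "); print(x$bis_trend)
  cat("stroke-count repetition trend:       "); print(x$strokes_trend)
  cat("pre/post x condition (BIS):          "); print(x$prepost_interaction)
  cat("  ... balanced 16-trial z-scoring:   "); print(x$prepost_interaction_balanced16)
  cat("within-dyad convergence trend:       "); print(x$convergence$fit)
  cat("between-dyad divergence trend:       "); print(x$divergence$fit)
  cat("divergence permutation null:         "); print(x$permutation)
  cat("pre/post x condition diagnosticity:  "); print(x$diagnosticity)
  invisible(x)
}

report_numbers <- function(report) {
  list(
    n_dyads = report$n_dyads,
    mean_accuracy = report$mean_accuracy,
    first_appearance_accuracy = report$first_appearance_accuracy,
    bis_trend_b = report$bis_trend$estimate,
    bis_trend_p = report$bis_trend$p_value,
    strokes_trend_b = report$strokes_trend$estimate,
    rt_trend_b = report$rt_trend$estimate,
    prepost_interaction_b = report$prepost_interaction$estimate,
    prepost_interaction_balanced16_b = report$prepost_interaction_balanced16$estimate,
    convergence_slope_b = report$convergence$fit$estimate,
    divergence_slope_b = report$divergence$fit$estimate,
    divergence_perm_p = report$permutation$p_value,
    diagnosticity_interaction_b = report$diagnosticity$estimate,
    diagnosticity_interaction_p = report$diagnosticity$p_value
  )
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (all headline numbers, config hash and package
#' version) and `report.txt` (the human-readable summary) into `dir`.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the JSON path.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  payload <- c(list(config_hash = report$config_hash,
                    package_version = report$package_version),
               report_numbers(report))
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  txt_path <- file.path(dir, "report.txt")
  con <- file(txt_path, "wt"); sink(con); print(report); sink(); close(con)
  invisible(json_path)
}

#' Write a simulated cohort to disk in the package's file formats
#'
#' Writes the pooled trials CSV, the strokes JSON-lines file, grayscale PNGs
#' of each object's diagnosticity map (`{object_id}.dmap.png`) and each
#' pre/post drawing's annotation mask (`{drawing_id}.mask.png`), and a
#' `manifest.json` with the config hash and file inventory.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_session(cohort$interactions,
                file.path(dir, "trials.csv"), file.path(dir, "strokes.jsonl"))
  for (ob in cohort$world$objects) {
    write_gray_png(ob$dmap, file.path(dir, paste0(ob$object_id, ".dmap.png")))
  }
  dw <- cohort_drawings(cohort)
  dw <- dw[dw$phase %in% c("pre", "post"), ]
  for (i in seq_len(nrow(dw))) {
    mask <- drawing_annotation_mask(cohort$world, dw[i, ])
    write_gray_png(mask * 1, file.path(dir, paste0(dw$drawing_id[i], ".mask.png")))
  }
  manifest <- list(
    config_hash = rlang::hash(unclass(cohort$config)),
    package_version = as.character(packageVersion("sketchcomm")),
    n_dyads = length(cohort$interactions),
    files = list(trials = "trials.csv", strokes = "strokes.jsonl",
                 dmaps = paste0(names(cohort$world$objects), ".dmap.png"),
                 masks = paste0(dw$drawing_id, ".mask.png"))
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE)
  invisible(path)
}

#' Plot a similarity or efficiency trajectory
#'
#' Minimal ggplot helper for the series produced by the trajectory analyses.
#'
#' @param series Tibble with columns `k` and `s` (or `rep_idx` and an
#'   outcome named by `y`).
#' @param y Name of the y column.
#' @param x Name of the x column.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(series, y = "s", x = "k") {
  ggplot2::ggplot(series, ggplot2::aes(x = .data[[x]], y = .data[[y]])) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::stat_summary(fun = mean, geom = "point") +
    ggplot2::labs(x = "repetition", y = y) +
    ggplot2::theme_minimal()
}
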