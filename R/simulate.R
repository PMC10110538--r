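#' Simulate one dyadic communication interaction
#'
#' Runs the generative model of convention formation for a single dyad over
#' a 40-trial session (8 pre + 24 repetition + 8 post):
#'
#' * **Drawings.** At appearance `k` of an object, each prototype stroke is
#'   retained with probability [stroke_retention_prob()] (simplification,
#'   biased toward diagnostic parts for repeated objects). At least one
#'   stroke is always produced. The drawing's feature embedding is the object
#'   prototype pulled a fraction `1 - (1 - conv_rate)^k` toward a
#'   dyad-specific attractor (prototype + `div_spread`-scaled offset), plus
#'   isotropic `noise_sd` noise.
#' * **Viewer.** Either a uniform-random guesser over the 4-object context,
#'   or a logistic chooser whose log-odds of a correct response combine the
#'   drawing-to-prototype resemblance (Pearson correlation, centered at 1),
#'   object-specific learning `learn_rate * (k - 1)`, and general practice
#'   `practice_rate * progress` with session progress in `[0, 1]`.
#' * **Response time.** `rt_floor + rt_range * exp(-0.6 * (learn_rate *
#'   (k - 1) + practice_rate * progress))` with lognormal jitter.
#'
#' @param world A [generate_world()] result.
#' @param config A [sim_config()].
#' @param dyad_id Dyad identifier string.
#' @param seed Seed for this interaction (defaults to a child of
#'   `config$seed` derived from the dyad id).
#' @return An [interaction_record()] whose drawings carry `features`
#'   (list-column of embeddings) and stroke-level part labels.
#' @export
simulate_interaction <- function(world, config = world$config, dyad_id = "dyad_01",
                                 seed = NULL) {
  seed <- seed %||% child_seed(config$seed, sum(utf8ToInt(dyad_id)))
  repeated_ids <- world$contexts[[1]]
  pool <- c(world$contexts[[1]], world$contexts[[2]])
  design <- generate_session(child_seed(seed, 1L), pool, repeated_ids)

  withr::with_seed(child_seed(seed, 2L), {
    # dyad-specific attractors
    attractor <- lapply(world$proto_features, function(p) {
      p + config$div_spread * rnorm(config$n_features)
    })
    seen <- setNames(integer(length(pool)), pool)
    n_tr <- nrow(design)
    response <- character(n_tr); rt_sec <- numeric(n_tr)
    n_strokes <- integer(n_tr); k_slot <- integer(n_tr)
    stroke_sets <- vector("list", n_tr); feature_sets <- vector("list", n_tr)
    for (i in seq_len(n_tr)) {
      target <- design$target_id[i]
      seen[target] <- seen[target] + 1L
      # k labels the phase/repetition slot (1-8); n_seen is how often this
      # object has actually been drawn, which drives the generative model
      # (for repeated objects the two coincide; control objects are only on
      # their 2nd appearance at post)
      k <- appearance_index(design$phase[i], design$block[i])
      n_seen <- seen[[target]]
      obj <- world$objects[[target]]
      repeated <- design$condition[i] == "repeated"

      # stroke retention
      diag_vals <- vapply(obj$proto_strokes, function(s) {
        obj$parts$diag[match(s$part_id, obj$parts$part_id)]
      }, 0)
      p_keep <- stroke_retention_prob(n_seen, diag_vals, config$simplify_rate,
                                      config$diag_bias, repeated)
      keep <- runif(length(p_keep)) < p_keep
      if (!any(keep)) keep[sample.int(length(keep), 1)] <- TRUE
      strokes <- obj$proto_strokes[keep]
      for (j in seq_along(strokes)) strokes[[j]]$index <- j - 1L

      # embedding
      pull <- 1 - (1 - config$conv_rate)^n_seen
      feat <- world$proto_features[[target]] +
        pull * (attractor[[target]] - world$proto_features[[target]]) +
        config$noise_sd * rnorm(config$n_features)

      # viewer
      progress <- design$trial_index[i] / (n_tr - 1)
      context <- design$context[[i]]
      if (config$viewer == "uniform") {
        resp <- sample(context, 1)
      } else {
        res <- cor(feat, world$proto_features[[target]])
        eta <- qlogis(config$base_accuracy) +
          config$resemblance_weight * (res - 1) +
          config$learn_rate * (n_seen - 1) +
          config$practice_rate * progress
        correct <- runif(1) < plogis(eta)
        resp <- if (correct) target else sample(setdiff(context, target), 1)
      }

      rt <- config$rt_floor + config$rt_range *
        exp(-0.6 * (config$learn_rate * (n_seen - 1) + config$practice_rate * progress))
      if (config$noise_sd > 0) rt <- rt * exp(rnorm(1, 0, config$noise_sd / 2))

      response[i] <- resp; rt_sec[i] <- rt
      n_strokes[i] <- length(strokes); k_slot[i] <- k
      stroke_sets[[i]] <- strokes; feature_sets[[i]] <- feat
    }
    trials <- tibble(
      dyad_id = dyad_id, trial_index = design$trial_index,
      phase = design$phase, condition = design$condition,
      target_id = design$target_id, response_id = response,
      accuracy = as.integer(response == design$target_id), rt_sec = rt_sec,
      repetition = design$block, n_strokes = n_strokes,
      timeout = as.integer(rt_sec > 30)
    )
    drawings <- tibble(
      drawing_id = sprintf("%s_%s_k%d", dyad_id, design$target_id, k_slot),
      dyad_id = dyad_id, object_id = design$target_id, repetition = k_slot,
      phase = design$phase, condition = design$condition,
      strokes = stroke_sets, features = feature_sets
    )
    interaction_record(dyad_id, trials, drawings)
  })
}

#' Simulate a cohort of interactions
#'
#' Simulates `config$n_dyads` independent interactions in a shared
#' [generate_world()], each from its own derived seed.
#'
#' @param config A [sim_config()].
#' @param world Optional pre-built world (defaults to
#'   `generate_world(config)`).
#' @return An object of class `sketch_cohort`: list with `world`, `config`,
#'   and `interactions` (named list of [interaction_record()]s).
#' @export
simulate_cohort <- function(config = sim_config(), world = NULL) {
  world <- world %||% generate_world(config)
  ids <- sprintf("dyad_%02d", seq_len(config$n_dyads))
  interactions <- lapply(seq_along(ids), function(i) {
    simulate_interaction(world, config, ids[i], seed = child_seed(config$seed, 100L + i))
  })
  names(interactions) <- ids
  structure(list(world = world, config = config, interactions = interactions),
            class = "sketch_cohort")
}

#' @export
print.sketch_cohort <- function(x, ...) {
  cat(sprintf("<sketch_cohort: %d dyads x %d trials>\n",
              length(x$interactions),
              nrow(x$interactions[[1]]$trials)))
  invisible(x)
}

#' Pooled trial and drawing tables of a cohort
#'
#' `cohort_trials()` binds all dyads' trial tables and adds the appearance
#' index `rep_idx` (1-8); `cohort_drawings()` binds the drawing tables.
#'
#' @param cohort A [simulate_cohort()] result.
#' @return A tibble.
#' @export
cohort_trials <- function(cohort) {
  tr <- dplyr::bind_rows(lapply(cohort$interactions, `[[`, "trials"))
  tr$rep_idx <- appearance_index(tr$phase, tr$repetition)
  tr
}

#' @rdname cohort_trials
#' @export
cohort_drawings <- function(cohort) {
  dplyr::bind_rows(lapply(cohort$interactions, `[[`, "drawings"))
}

#' Annotation mask of a synthetic drawing
#'
#' Simulates a noiseless annotator: the drawn-region mask of a drawing is the
#' union of the object-image regions of the parts its retained strokes
#' depict, optionally corrupted by pixel-flip noise, then background-masked
#' against the object segmentation.
#'
#' @param world A [generate_world()] result.
#' @param drawing One row of a drawings tibble (with `object_id`, `strokes`).
#' @param flip_prob Probability of flipping each pixel (annotator noise).
#' @return A logical matrix in object-image coordinates.
#' @export
drawing_annotation_mask <- function(world, drawing, flip_prob = 0) {
  obj <- world$objects[[drawing$object_id]]
  n <- nrow(obj$image)
  mask <- matrix(FALSE, n, n)
  part_ids <- unique(vapply(drawing$strokes[[1]], `[[`, "", "part_id"))
  for (p in part_ids) {
    px <- obj$parts$pixels[[match(p, obj$parts$part_id)]]
    mask[px] <- TRUE
  }
  if (flip_prob > 0) {
    flip <- runif(length(mask)) < flip_prob
    mask[flip] <- !mask[flip]
  }
  apply_background_mask(mask, obj$segmentation) > 0
}

#' Diagnosticity scores for all pre/post drawings of a cohort
#'
#' Builds each drawing's simulated annotation mask, scores it against the
#' object's ground-truth diagnosticity map via [score_drawing()], and labels
#' the result with phase, condition, sketcher and object for
#' [prepost_diagnosticity_analysis()]. Only pre- and post-phase drawings are
#' scored (the phases the pre/post contrast uses).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param phases Phases to score.
#' @param flip_prob Annotator pixel-flip noise passed to
#'   [drawing_annotation_mask()]; seed the RNG for reproducibility when > 0.
#' @return Tibble: `drawing_id, object_id, sketcher_id, phase, condition,
#'   score, n_pixels`.
#' @export
cohort_diagnosticity_scores <- function(cohort, phases = c("pre", "post"),
                                        flip_prob = 0) {
  dw <- cohort_drawings(cohort)
  dw <- dw[dw$phase %in% phases, ]
  world <- cohort$world
  score <- numeric(nrow(dw)); n_pixels <- integer(nrow(dw))
  for (i in seq_len(nrow(dw))) {
    mask <- drawing_annotation_mask(world, dw[i, ], flip_prob = flip_prob)
    sc <- score_drawing(mask, world$objects[[dw$object_id[i]]]$dmap)
    score[i] <- sc$score; n_pixels[i] <- sc$n_pixels
  }
  tibble(drawing_id = dw$drawing_id, object_id = dw$object_id,
         sketcher_id = dw$dyad_id, phase = dw$phase, condition = dw$condition,
         score = score, n_pixels = n_pixels)
}

#' Simulate recognition participants over yoked and shuffled sequences
#'
#' Builds one yoked sequence per source interaction and one shuffled sequence
#' per participant, then simulates naive-viewer responses. Both groups share
#' the practice term; viewers of yoked sequences additionally benefit from
#' the sketcher's interaction history at the full `learn_rate`, while
#' shuffled viewers — whose sequence splices drawings from many sketchers —
#' receive only the fraction `shuffled_benefit` of it.
#'
#' @param cohort A [simulate_cohort()] result (needs >= 10 dyads for the
#'   shuffled group).
#' @param n_per_group Participants per group.
#' @param shuffled_benefit Fraction of the object-specific learning effect
#'   retained without interaction continuity.
#' @param seed Seed.
#' @return Trial tibble with `participant_id`, `group`, `rep_idx`,
#'   `accuracy`, `rt_sec` (plus the usual identifiers).
#' @export
simulate_recognition <- function(cohort, n_per_group = 10,
                                 shuffled_benefit = 0.3, seed = 1) {
  config <- cohort$config
  interactions <- cohort$interactions
  rows <- list()
  for (g in c("yoked", "shuffled")) {
    for (p in seq_len(n_per_group)) {
      pid <- sprintf("%s_%02d", g, p)
      sseed <- child_seed(seed, p + ifelse(g == "yoked", 0L, 1000L))
      seq_tbl <- if (g == "yoked") {
        yoked_sequence(interactions[[1 + (p - 1) %% length(interactions)]])
      } else {
        shuffled_sequence(interactions, sseed)
      }
      withr::with_seed(child_seed(sseed, 3L), {
        benefit <- if (g == "yoked") 1 else shuffled_benefit
        n_tr <- nrow(seq_tbl)
        progress <- (seq_len(n_tr) - 1) / (n_tr - 1)
        eta <- qlogis(config$base_accuracy) +
          benefit * config$learn_rate * (seq_tbl$repetition - 1) +
          config$practice_rate * progress
        acc <- as.integer(runif(n_tr) < plogis(eta))
        rt <- config$rt_floor + 0.4 * config$rt_range *
          exp(-0.6 * (benefit * config$learn_rate * (seq_tbl$repetition - 1) +
                        config$practice_rate * progress)) *
          exp(rnorm(n_tr, 0, config$noise_sd / 2))
        rows[[length(rows) + 1]] <- tibble(
          participant_id = pid, group = g,
          trial_index = seq_len(n_tr) - 1L,
          object_id = seq_tbl$object_id, phase = seq_tbl$phase,
          condition = seq_tbl$condition, rep_idx = seq_tbl$repetition,
          accuracy = acc, rt_sec = rt, timeout = 0L
        )
      })
    }
  }
  dplyr::bind_rows(rows)
}
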