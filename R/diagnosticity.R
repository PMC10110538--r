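#' Union of per-stroke annotation masks
#'
#' Combines the per-stroke painted regions of one drawing into its combined
#' drawn-region mask (pixelwise OR).
#'
#' @param per_stroke_masks Non-empty list of binary rasters with identical
#'   dimensions.
#' @return A logical matrix.
#' @export
union_stroke_masks <- function(per_stroke_masks) {
  if (!length(per_stroke_masks)) abort("need at least one stroke mask")
  dims <- lapply(per_stroke_masks, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1) {
    abort("stroke masks differ in dimensions")
  }
  out <- per_stroke_masks[[1]] != 0
  for (m in per_stroke_masks[-1]) out <- out | (m != 0)
  out
}

#' Zero out background pixels
#'
#' Keeps a raster's values only where the object segmentation is foreground;
#' everything on the background becomes exactly 0. This removes annotation
#' paint that fell outside the object, where diagnosticity is 0 by
#' definition.
#'
#' @param raster Numeric or logical matrix.
#' @param segmentation Binary matrix of the same dimensions (1 = object).
#' @return A matrix of `raster`'s mode with the background zeroed.
#' @export
apply_background_mask <- function(raster, segmentation) {
  if (!identical(dim(raster), dim(segmentation))) {
    abort("raster and segmentation differ in dimensions")
  }
  raster * (segmentation != 0)
}

#' Aggregate pairwise annotation maps into a diagnosticity map
#'
#' Averages target-vs-foil annotation rasters pixelwise (the mean intensity
#' across foils), then zeroes the background. The brightest pixels are those
#' marked as distinguishing the target from the most foils.
#'
#' @param pairwise_maps Non-empty list of rasters with values in `[0, 1]`,
#'   one per foil comparison (already averaged across raters, if several).
#' @param segmentation Binary object segmentation of the same dimensions.
#' @return A numeric matrix in `[0, 1]`, 0 on the background.
#' @export
build_diagnosticity_map <- function(pairwise_maps, segmentation) {
  if (!length(pairwise_maps)) abort("need at least one pairwise map")
  for (m in pairwise_maps) {
    if (!identical(dim(m), dim(segmentation))) abort("map dimensions differ from segmentation")
    if (min(m) < 0 || max(m) > 1) abort("map values must lie in [0, 1]")
  }
  acc <- Reduce(`+`, lapply(pairwise_maps, `+`, 0))
  apply_background_mask(acc / length(pairwise_maps), segmentation)
}

#' Mean diagnosticity of a drawing
#'
#' Averages the diagnosticity map over the pixels of the drawing's combined
#' stroke mask. Normalizing by the mask size controls for the overall extent
#' of the drawing, so the score measures *selectivity* for diagnostic
#' regions, not coverage. An empty mask (after background masking) is an
#' error — the score is undefined, which is distinct from a score of 0.
#'
#' @param mask Binary drawn-region mask in object-image coordinates.
#' @param dmap Diagnosticity map of the same dimensions, values in `[0, 1]`.
#' @param segmentation Optional binary segmentation applied to the mask
#'   first.
#' @return List with `score` (in `[0, 1]`) and `n_pixels` used.
#' @export
score_drawing <- function(mask, dmap, segmentation = NULL) {
  if (!identical(dim(mask), dim(dmap))) abort("mask and map differ in dimensions")
  m <- mask != 0
  if (!is.null(segmentation)) m <- apply_background_mask(m, segmentation) > 0
  n <- sum(m)
  if (n == 0) abort("empty mask after background masking: score undefined")
  list(score = mean(dmap[m]), n_pixels = n)
}

#' Pre/post by condition contrast on diagnosticity scores
#'
#' Tests whether drawings of repeated objects gain more diagnosticity from
#' the pre to the post phase than drawings of control objects: fixed effects
#' of phase, condition and their interaction, with random intercepts and
#' main effects for sketcher and for target object (pruned to intercepts, or
#' to a fixed-effects fit, when the mixed fit does not converge). Reference
#' levels are `pre` and `control`, so a positive interaction means a larger
#' diagnosticity gain for repeated objects.
#'
#' @param scores Tibble from [cohort_diagnosticity_scores()] (columns
#'   `score`, `phase`, `condition`, `sketcher_id`, `object_id`).
#' @return A `trend_fit` for the `phase x condition` interaction.
#' @export
prepost_diagnosticity_analysis <- function(scores) {
  d <- scores[scores$phase %in% c("pre", "post"), ]
  cells <- table(d$phase, d$condition)
  for (ph in c("pre", "post")) for (cd in c("control", "repeated")) {
    if (!ph %in% rownames(cells) || !cd %in% colnames(cells) || cells[ph, cd] == 0) {
      abort(sprintf("empty design cell: phase=%s, condition=%s", ph, cd))
    }
  }
  d$phase <- factor(d$phase, levels = c("pre", "post"))
  d$condition <- factor(d$condition, levels = c("control", "repeated"))
  d$y <- d$score
  forms <- list(
    y ~ phase * condition + (1 + phase + condition | sketcher_id) +
      (1 + phase + condition | object_id),
    y ~ phase * condition + (1 | sketcher_id) + (1 | object_id)
  )
  info <- fit_lmm_chain(forms, d)
  if (!is.null(info)) {
    return(extract_term(info, "phasepost:conditionrepeated"))
  }
  fit <- lm(y ~ phase * condition, data = d)
  co <- coef(summary(fit))
  term <- "phasepost:conditionrepeated"
  new_trend_fit(term, co[term, 1], co[term, 3], fit$df.residual, co[term, 4],
                "fallback: fixed-effects lm", FALSE, coefs = co)
}
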