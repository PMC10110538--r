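#' Simulation configuration
#'
#' Collects the parameters of the synthetic dyadic-communication generator.
#' Defaults are chosen to reproduce the qualitative regime of a repeated
#' reference game with human dyads: first-appearance viewer accuracy around
#' 76% rising toward ~90% by the eighth appearance, response times falling
#' from roughly 12 s to 7 s, stroke counts roughly halving, within-dyad
#' drawing convergence, and between-dyad divergence.
#'
#' @param n_dyads Number of dyads in a simulated cohort.
#' @param n_features Embedding dimension of simulated drawing features (>= 2).
#' @param conv_rate Within-dyad attractor pull per appearance, `gamma >= 0`;
#'   the drawing embedding at appearance `k` has moved a fraction
#'   `1 - (1 - gamma)^k` of the way from the object prototype toward the
#'   dyad-specific attractor.
#' @param div_spread Standard deviation `delta >= 0` of the dyad-specific
#'   attractor offsets (per embedding dimension); 0 makes all dyads share the
#'   prototype.
#' @param simplify_rate Decay rate of stroke retention per appearance: a
#'   prototype stroke survives to appearance `k` with base probability
#'   `exp(-simplify_rate * (k - 1))`.
#' @param diag_bias `beta >= 0`; for repeated objects the retention odds of a
#'   stroke are multiplied by `exp(beta * part_diagnosticity)`, preferentially
#'   preserving diagnostic parts.
#' @param learn_rate Object-specific improvement per appearance: log-odds of
#'   a correct viewer response per appearance, and (scaled) response-time
#'   decay rate.
#' @param practice_rate Condition-general improvement accrued linearly over
#'   the session (total log-odds from first to last trial).
#' @param noise_sd Standard deviation of the embedding noise; also sets the
#'   lognormal response-time jitter (at half this value).
#' @param rt_floor Minimum response time in seconds (> 0).
#' @param seed Master seed; every stochastic draw in the generator flows from
#'   it.
#' @param base_accuracy First-appearance viewer accuracy for a drawing that
#'   perfectly resembles its prototype.
#' @param rt_range Response-time range above the floor, in seconds.
#' @param resemblance_weight Log-odds weight of the (centered) drawing-to-
#'   prototype resemblance in the viewer model.
#' @param viewer `"logistic"` for the resemblance-plus-history viewer,
#'   `"uniform"` for a null viewer that guesses uniformly among the 4 context
#'   objects.
#' @param img_size Side length in pixels of the square object images.
#' @param canvas Drawing canvas `(width, height)` in pixels.
#' @param pen_width Pen width in pixels.
#' @param strokes_per_part Prototype strokes drawn for each object part.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_dyads = 20, n_features = 64, conv_rate = 0.3,
                       div_spread = 1, simplify_rate = 0.1, diag_bias = 1,
                       learn_rate = 0.12, practice_rate = 0.33,
                       noise_sd = 0.3, rt_floor = 1.5, seed = 1,
                       base_accuracy = 0.76, rt_range = 10.7,
                       resemblance_weight = 1,
                       viewer = c("logistic", "uniform"),
                       img_size = 90, canvas = c(300L, 300L), pen_width = 5,
                       strokes_per_part = 2) {
  viewer <- match.arg(viewer)
  cfg <- list(n_dyads = n_dyads, n_features = n_features,
              conv_rate = conv_rate, div_spread = div_spread,
              simplify_rate = simplify_rate, diag_bias = diag_bias,
              learn_rate = learn_rate, practice_rate = practice_rate,
              noise_sd = noise_sd, rt_floor = rt_floor, seed = seed,
              base_accuracy = base_accuracy, rt_range = rt_range,
              resemblance_weight = resemblance_weight, viewer = viewer,
              img_size = img_size, canvas = canvas, pen_width = pen_width,
              strokes_per_part = strokes_per_part)
  rates <- c("conv_rate", "div_spread", "simplify_rate", "diag_bias",
             "learn_rate", "practice_rate", "noise_sd")
  for (r in rates) if (cfg[[r]] < 0) abort(sprintf("%s must be >= 0", r))
  if (cfg$n_features < 2) abort("n_features must be >= 2")
  if (cfg$rt_floor <= 0) abort("rt_floor must be > 0")
  if (cfg$conv_rate > 1) abort("conv_rate must be in [0, 1]")
  structure(cfg, class = "sim_config")
}

#' Zero-effect simulation configuration
#'
#' A [sim_config()] in which every systematic effect is switched off
#' (convergence, divergence, simplification, diagnosticity bias, learning and
#' practice all 0), leaving only noise. Used for type-I-error calibration of
#' the trend, interaction, and permutation tests.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
null_config <- function(...) {
  sim_config(conv_rate = 0, div_spread = 0, simplify_rate = 0, diag_bias = 0,
             learn_rate = 0, practice_rate = 0, ...)
}

# Part layout of the synthetic "chair-like" objects. Each object is built
# from 6 labeled parts at fixed disjoint rectangles (fractions of the image
# side). Variant-sharing across the 4 objects of a context determines each
# part's ground-truth diagnosticity (fraction of the 3 foils the part
# distinguishes the object from).
part_slots <- function() {
  tibble(
    slot = c("backrest", "seat", "legs_left", "legs_right", "armrest", "headrest"),
    x0 = c(0.25, 0.15, 0.20, 0.62, 0.05, 0.35),
    x1 = c(0.75, 0.85, 0.34, 0.76, 0.13, 0.65),
    y0 = c(0.10, 0.42, 0.62, 0.62, 0.30, 0.02),
    y1 = c(0.38, 0.56, 0.95, 0.95, 0.40, 0.08)
  )
}

# variant assignment per slot across the 4 objects of one context; the
# patterns are chosen so that every object owns parts at >= 4 distinct
# diagnosticity levels {0, 1/3, 2/3, 1}
slot_variants <- function() {
  list(
    backrest  = c(1, 1, 1, 1),  # shared by all: diagnosticity 0
    seat      = c(1, 1, 2, 2),  # pair-shared: 2/3 for everyone
    legs_left = c(1, 1, 1, 2),  # objects 1-3: 1/3; object 4: 1
    legs_right = c(1, 2, 2, 2), # object 1: 1; objects 2-4: 1/3
    armrest   = 1:4,            # unique: 1 for everyone
    headrest  = c(1, 1, 1, 1)   # shared: 0
  )
}

#' Generate a synthetic object world
#'
#' Builds 8 procedurally drawn objects (two 4-object contexts) with known
#' ground truth: labeled part regions, per-part diagnosticity in context,
#' pixel-level diagnosticity maps (0 on the background), prototype stroke
#' sets labeled by part, and prototype feature embeddings. Deterministic
#' given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An object of class `sketch_world`: a list with `objects` (named
#'   list; each has `object_id`, `image`, `segmentation`, `dmap`, `parts`
#'   tibble and `proto_strokes`), `contexts` (list of two id vectors),
#'   `proto_features` (named list of embeddings) and `config`.
#' @export
generate_world <- function(config = sim_config()) {
  n <- config$img_size
  slots <- part_slots()
  variants <- slot_variants()
  contexts <- list(A = sprintf("chair_A%d", 1:4), B = sprintf("chair_B%d", 1:4))

  slot_pixels <- function(s) {
    rows <- max(1, round(s$y0 * n)):min(n, round(s$y1 * n))
    cols <- max(1, round(s$x0 * n)):min(n, round(s$x1 * n))
    as.vector(outer(rows, (cols - 1) * n, `+`))
  }
  pix <- lapply(seq_len(nrow(slots)), function(i) slot_pixels(slots[i, ]))
  names(pix) <- slots$slot

  objects <- list()
  proto_features <- list()
  withr::with_seed(child_seed(config$seed, 7L), {
    for (ctx_name in names(contexts)) {
      ids <- contexts[[ctx_name]]
      for (oi in 1:4) {
        id <- ids[oi]
        parts <- tibble(
          part_id = paste0(slots$slot, "_v", vapply(slots$slot, function(sl) variants[[sl]][oi], 0)),
          slot = slots$slot,
          variant = vapply(slots$slot, function(sl) variants[[sl]][oi], 0),
          pixels = unname(pix[slots$slot])
        )
        parts$diag <- vapply(seq_len(nrow(parts)), function(pi) {
          sl <- parts$slot[pi]
          foils <- setdiff(1:4, oi)
          mean(variants[[sl]][foils] != variants[[sl]][oi])
        }, 0)

        image <- matrix(0, n, n)
        seg <- matrix(FALSE, n, n)
        dmap <- matrix(0, n, n)
        for (pi in seq_len(nrow(parts))) {
          px <- parts$pixels[[pi]]
          image[px] <- 0.4 + 0.15 * parts$variant[pi]
          seg[px] <- TRUE
          dmap[px] <- parts$diag[pi]
        }

        # prototype strokes: polylines inside each part's canvas-scaled box,
        # with a deterministic per-object jitter so objects differ visually
        scale <- config$canvas[1] / n
        proto_strokes <- list()
        si <- 0L
        for (pi in seq_len(nrow(parts))) {
          s <- slots[slots$slot == parts$slot[pi], ]
          for (j in seq_len(config$strokes_per_part)) {
            jit <- runif(6, -0.02, 0.02)
            xs <- (c(s$x0 + 0.01, (s$x0 + s$x1) / 2, s$x1 - 0.01) + jit[1:3]) * n * scale
            ys <- (c(s$y0 + 0.01, (s$y0 + s$y1) / 2, s$y1 - 0.01) + jit[4:6]) * n * scale
            if (j %% 2 == 0) ys <- rev(ys)
            pts <- cbind(pmin(pmax(xs, 0), config$canvas[1]),
                         pmin(pmax(ys, 0), config$canvas[2]))
            proto_strokes[[si + 1L]] <- stroke(pts, width = config$pen_width,
                                               index = si, part_id = parts$part_id[pi])
            si <- si + 1L
          }
        }

        objects[[id]] <- list(object_id = id, image = image,
                              segmentation = seg, dmap = dmap, parts = parts,
                              proto_strokes = proto_strokes)
        proto_features[[id]] <- rnorm(config$n_features)
      }
    }
  })

  structure(list(objects = objects, contexts = unname(contexts),
                 proto_features = proto_features, config = config),
            class = "sketch_world")
}

#' @export
print.sketch_world <- function(x, ...) {
  cat(sprintf("<sketch_world: %d objects in %d contexts, %dx%d images>\n",
              length(x$objects), length(x$contexts),
              x$config$img_size, x$config$img_size))
  invisible(x)
}

#' Closed-form stroke retention probability
#'
#' Probability that a prototype stroke of part diagnosticity `diag` is
#' retained at appearance `k`: the base survival probability
#' `q = exp(-simplify_rate * (k - 1))` has its odds multiplied by
#' `exp(diag_bias * diag)` for repeated objects.
#'
#' @param k Appearance index (1-8).
#' @param diag Part diagnosticity in `[0, 1]`.
#' @param simplify_rate,diag_bias See [sim_config()].
#' @param repeated Does the diagnosticity bias apply (repeated condition)?
#' @return Retention probability in `[0, 1]`.
#' @export
stroke_retention_prob <- function(k, diag, simplify_rate, diag_bias,
                                  repeated = TRUE) {
  n <- max(length(k), length(diag))
  q <- rep_len(exp(-simplify_rate * (k - 1)), n)
  d <- rep_len(diag, n)
  bias <- if (isTRUE(repeated)) exp(diag_bias * d) else rep(1, n)
  out <- rep(1, n)
  sub <- q < 1
  odds <- q[sub] / (1 - q[sub]) * bias[sub]
  out[sub] <- odds / (1 + odds)
  out
}
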