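# Shared fixtures, all built in code at test time.

tiny_world <- function(seed = 11) {
  generate_world(sim_config(seed = seed, img_size = 30, strokes_per_part = 1))
}

# a small but complete cohort for structural tests
small_cohort <- function(n_dyads = 4, seed = 5, ...) {
  simulate_cohort(sim_config(n_dyads = n_dyads, seed = seed, ...))
}

# hand-rolled drawings tibble with explicit feature vectors
feature_drawings <- function(feats, dyads, objects, reps,
                             condition = "repeated") {
  tibble::tibble(
    drawing_id = sprintf("d%02d", seq_along(feats)),
    dyad_id = dyads, object_id = objects, repetition = as.integer(reps),
    phase = "repetition", condition = condition,
    features = feats
  )
}

# brute-force rasterization oracle: per-pixel scan of the distance to every
# polyline segment (independent of the package's bounding-box path)
brute_raster <- function(strokes, canvas, pen_width = 5) {
  w <- canvas[1]; h <- canvas[2]
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      px <- c - 0.5; py <- r - 0.5
      for (s in strokes) {
        rad <- s$width / 2
        pts <- s$points
        for (seg in seq_len(nrow(pts) - 1)) {
          p1 <- pts[seg, ]; p2 <- pts[seg + 1, ]
          d <- p2 - p1; len2 <- sum(d^2)
          tt <- if (len2 == 0) 0 else
            min(max(((px - p1[1]) * d[1] + (py - p1[2]) * d[2]) / len2, 0), 1)
          dist2 <- (px - (p1[1] + tt * d[1]))^2 + (py - (p1[2] + tt * d[2]))^2
          if (dist2 <= rad^2) out[r, c] <- TRUE
        }
      }
    }
  }
  out
}
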