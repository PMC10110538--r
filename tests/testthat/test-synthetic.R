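test_that("world generation is deterministic and maps are zero on the background", {
  w1 <- tiny_world(seed = 13)
  w2 <- tiny_world(seed = 13)
  expect_identical(w1$objects, w2$objects)
  expect_identical(w1$proto_features, w2$proto_features)
  for (ob in w1$objects) {
    expect_true(all(ob$dmap[!ob$segmentation] == 0))
    expect_true(all(ob$dmap >= 0 & ob$dmap <= 1))
    expect_gte(sum(ob$segmentation), 1)
    # >= 4 distinct diagnosticity levels among this object's parts
    expect_gte(length(unique(round(ob$parts$diag, 6))), 4)
  }
})

test_that("per-part diagnosticity equals the brute-force variant-overlap oracle", {
  w <- tiny_world(seed = 13)
  for (ctx in w$contexts) {
    # recompute each part's diagnosticity from the variant table directly
    variant_of <- function(id, slot) {
      p <- w$objects[[id]]$parts
      p$variant[p$slot == slot]
    }
    for (id in ctx) {
      parts <- w$objects[[id]]$parts
      for (i in seq_len(nrow(parts))) {
        foils <- setdiff(ctx, id)
        oracle <- mean(vapply(foils, function(f) {
          variant_of(f, parts$slot[i]) != parts$variant[i]
        }, TRUE))
        expect_equal(parts$diag[i], oracle)
        # and the pixel map carries exactly that value on the part region
        expect_true(all(w$objects[[id]]$dmap[parts$pixels[[i]]] == oracle))
      }
      # map maximum is attained on the part unique to this object
      uniq <- parts$part_id[parts$diag == 1]
      expect_gte(length(uniq), 1)
      expect_equal(max(w$objects[[id]]$dmap), 1)
    }
  }
})

test_that("a degenerate config yields identical drawings across repetitions", {
  cfg <- sim_config(n_dyads = 1, conv_rate = 0, noise_sd = 0,
                    simplify_rate = 0, seed = 3)
  co <- simulate_cohort(cfg)
  dw <- cohort_drawings(co)
  for (ob in unique(dw$object_id)) {
    g <- dw[dw$object_id == ob, ]
    feats <- g$features
    for (i in seq_along(feats)[-1]) expect_equal(feats[[i]], feats[[1]])
    ns <- vapply(g$strokes, length, 0L)
    expect_true(all(ns == ns[1]))
  }
})

test_that("stroke retention frequency matches the closed-form probability", {
  # Monte-Carlo over many simulated final-repetition drawings of one object
  cfg <- sim_config(n_dyads = 60, simplify_rate = 0.25, diag_bias = 2,
                    conv_rate = 0, div_spread = 0, seed = 77)
  co <- simulate_cohort(cfg)
  dw <- cohort_drawings(co)
  w <- co$world
  ob_id <- w$contexts[[1]][1]
  finals <- dw[dw$object_id == ob_id & dw$repetition == 8, ]
  obj <- w$objects[[ob_id]]
  # retention frequency of the highest-diagnosticity part's strokes
  hi_part <- obj$parts$part_id[which.max(obj$parts$diag)]
  kept <- vapply(finals$strokes, function(sl) {
    any(vapply(sl, function(s) identical(s$part_id, hi_part), TRUE))
  }, TRUE)
  p_stroke <- stroke_retention_prob(8, max(obj$parts$diag), 0.25, 2, TRUE)
  # drawing retains the part iff >= 1 of its strokes_per_part=2 strokes survives
  p_part <- 1 - (1 - p_stroke)^cfg$strokes_per_part
  se <- sqrt(p_part * (1 - p_part) / length(kept))
  expect_lt(abs(mean(kept) - p_part), 3.5 * se + 1e-9)
  # and high-diagnosticity strokes are retained more than low ones
  lo_part <- obj$parts$part_id[which.min(obj$parts$diag)]
  kept_lo <- vapply(finals$strokes, function(sl) {
    any(vapply(sl, function(s) identical(s$part_id, lo_part), TRUE))
  }, TRUE)
  expect_gt(mean(kept), mean(kept_lo))
})

test_that("cohorts have the right shape and masks are subsets of the segmentation", {
  co <- small_cohort(n_dyads = 3, seed = 55)
  expect_length(co$interactions, 3)
  for (rec in co$interactions) expect_equal(nrow(rec$trials), 40)
  dw <- cohort_drawings(co)
  pp <- dw[dw$phase %in% c("pre", "post"), ]
  for (i in sample(nrow(pp), 8)) {
    mask <- drawing_annotation_mask(co$world, pp[i, ])
    seg <- co$world$objects[[pp$object_id[i]]]$segmentation
    expect_true(all(!mask | seg))
    expect_gt(sum(mask), 0)
  }
})

test_that("mean stroke count decreases over repetitions when simplification is on", {
  co <- small_cohort(n_dyads = 8, seed = 66, simplify_rate = 0.15)
  tr <- cohort_trials(co)
  rep_tr <- tr[tr$condition == "repeated", ]
  means <- tapply(rep_tr$n_strokes, rep_tr$rep_idx, mean)
  slope <- coef(lm(means ~ as.numeric(names(means))))[2]
  expect_lt(slope, 0)
  # and flat when simplification is off
  co0 <- small_cohort(n_dyads = 8, seed = 66, simplify_rate = 0, diag_bias = 0)
  tr0 <- cohort_trials(co0)
  expect_true(all(tr0$n_strokes == tr0$n_strokes[1]))
})

test_that("identical dyads arise when attractor spread and noise are zero", {
  cfg <- sim_config(n_dyads = 3, div_spread = 0, noise_sd = 0, seed = 8)
  co <- simulate_cohort(cfg)
  dw <- cohort_drawings(co)
  g <- dw[dw$condition == "repeated", ]
  for (ob in unique(g$object_id)) {
    for (k in c(1, 4, 8)) {
      cell <- g[g$object_id == ob & g$repetition == k, ]
      if (nrow(cell) < 2) next
      prs <- utils::combn(nrow(cell), 2)
      for (j in seq_len(ncol(prs))) {
        expect_equal(pairwise_similarity(cell$features[[prs[1, j]]],
                                         cell$features[[prs[2, j]]]), 1)
      }
    }
  }
})

test_that("invalid configs are rejected", {
  expect_error(sim_config(conv_rate = -0.1), "conv_rate")
  expect_error(sim_config(n_features = 1), "n_features")
  expect_error(sim_config(rt_floor = 0), "rt_floor")
})
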