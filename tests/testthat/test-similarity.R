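test_that("pairwise similarity matches closed-form hand computations", {
  expect_equal(pairwise_similarity(c(1, 2, 3), c(1, 2, 4)), 0.9820, tolerance = 1e-4)
  f <- rnorm(50)
  expect_equal(pairwise_similarity(f, f), 1)
  expect_equal(pairwise_similarity(f, -f), -1)
})

test_that("pairwise similarity is symmetric, bounded, and affine-invariant", {
  withr::with_seed(42, {
    for (i in 1:20) {
      a <- rnorm(16); b <- rnorm(16)
      s <- pairwise_similarity(a, b)
      expect_equal(s, pairwise_similarity(b, a))
      expect_true(s >= -1 && s <= 1)
      expect_equal(pairwise_similarity(2.5 * a + 1, b), s, tolerance = 1e-12)
      expect_equal(pairwise_similarity(a, 0.3 * b - 7), s, tolerance = 1e-12)
    }
  })
  expect_error(pairwise_similarity(rep(1, 5), rnorm(5)), "zero-variance")
  expect_error(pairwise_similarity(rnorm(4), rnorm(5)), "length")
})

test_that("seeded projection features equal an independent dense matrix-vector product", {
  r <- matrix(runif(20 * 20) > 0.5, 20, 20)
  f <- extract_features(r, "seeded_projection", dim = 8, seed = 5)
  P <- withr::with_seed(5, matrix(rnorm(8 * 400), nrow = 8) / sqrt(400))
  expect_equal(as.numeric(f), as.numeric(P %*% as.numeric(r)), tolerance = 1e-12)
  # determinism and linearity
  expect_equal(as.numeric(extract_features(r, dim = 8, seed = 5)), as.numeric(f))
  zero <- extract_features(matrix(0, 20, 20), dim = 8, seed = 5)
  expect_equal(as.numeric(zero), rep(0, 8))
})

test_that("the pretrained CNN backend errors with backend-switch instructions", {
  r <- matrix(0, 4, 4)
  expect_error(extract_features(r, "pretrained_cnn_fc6"), "seeded_projection")
})

test_that("within-dyad convergence series counts pairs and flags degenerate data", {
  # identical drawings across repetitions: series constant at 1, slope ~ 0
  f <- rnorm(12)
  dw <- feature_drawings(rep(list(f), 8), dyads = "d1", objects = "o1", reps = 1:8)
  res <- within_convergence(dw, fit = FALSE)
  expect_equal(nrow(res$series), 7)  # (#repetitions - 1)
  expect_equal(res$series$s, rep(1, 7), tolerance = 1e-12)

  # a missing repetition is skipped with a note
  dw5 <- dw[dw$repetition != 5, ]
  expect_message(res5 <- within_convergence(dw5, fit = FALSE), "missing")
  expect_equal(nrow(res5$series), 5)
})

test_that("convergence is positive under attractor pull, flat without it", {
  co <- simulate_cohort(sim_config(n_dyads = 10, seed = 61))
  dw <- cohort_drawings(co)
  res <- within_convergence(dw[dw$condition == "repeated", ])
  expect_gt(res$fit$estimate, 0)
  expect_lt(res$fit$p_value, 0.05)
})

test_that("between-dyad divergence counts cross-dyad pairs and respects degenerate configs", {
  # delta = 0, noise 0 -> series identically 1
  co <- simulate_cohort(sim_config(n_dyads = 4, div_spread = 0, noise_sd = 0, seed = 71))
  dw <- cohort_drawings(co)
  res <- between_divergence(dw[dw$condition == "repeated", ], fit = FALSE)
  expect_true(all(abs(res$series$s - 1) < 1e-9))
  expect_true(all(res$series$n_pairs == choose(4, 2)))

  # divergence under dyad-specific attractors
  co2 <- simulate_cohort(sim_config(n_dyads = 10, seed = 72))
  dw2 <- cohort_drawings(co2)
  res2 <- between_divergence(dw2[dw2$condition == "repeated", ])
  expect_lt(res2$fit$estimate, 0)

  # single-dyad objects are excluded with a note
  solo <- dw2[dw2$dyad_id == "dyad_01" & dw2$object_id == dw2$object_id[1], ]
  keep <- dw2[dw2$object_id != dw2$object_id[1] & dw2$condition == "repeated", ]
  expect_message(between_divergence(rbind(keep, solo), fit = FALSE), "single dyad")
})

test_that("permutation p-values honor the add-one correction and are seed-reproducible", {
  co <- simulate_cohort(sim_config(n_dyads = 8, seed = 81))
  dw <- cohort_drawings(co)
  dwr <- dw[dw$condition == "repeated", ]
  r1 <- scramble_permutation_test(dwr, n_perm = 149, seed = 4)
  r2 <- scramble_permutation_test(dwr, n_perm = 149, seed = 4)
  expect_identical(r1$null_stats, r2$null_stats)
  expect_identical(r1$p_value, r2$p_value)
  expect_gt(r1$p_value, 0)
  expect_gte(r1$p_value, 1 / 150)
  expect_length(r1$null_stats, 149)
  expect_true(all(r1$ci >= min(r1$null_stats) & r1$ci <= max(r1$null_stats)))
  # strong divergence in the generating process -> observed stat extreme
  expect_lt(r1$p_value, 0.05)
  expect_lt(r1$observed_stat, 0)
})

test_that("Monte-Carlo scramble null matches exhaustive enumeration on a toy set", {
  # 2 sketchers x 1 object x 3 repetitions; statistic = slope of the
  # cross-dyad similarity over repetition
  withr::with_seed(9, {
    feats <- lapply(1:6, function(i) rnorm(10))
  })
  dw <- feature_drawings(feats, dyads = rep(c("a", "b"), each = 3),
                         objects = "o1", reps = c(1:3, 1:3))
  slope_stat <- function(d) {
    d <- d[order(d$dyad_id, d$repetition), ]
    a <- d[d$dyad_id == "a", ]; b <- d[d$dyad_id == "b", ]
    s <- vapply(1:3, function(k) {
      pairwise_similarity(a$features[[which(a$repetition == k)]],
                          b$features[[which(b$repetition == k)]])
    }, 0)
    unname(coef(lm(s ~ c(1:3)))[2])
  }
  # exhaustive oracle: all (3!)^2 = 36 label scrambles
  all_orders <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  exhaustive <- apply(as.matrix(expand.grid(1:6, 1:6)), 1, function(ij) {
    d <- dw
    d$repetition[1:3] <- all_orders[ij[1], ]
    d$repetition[4:6] <- all_orders[ij[2], ]
    slope_stat(d)
  })
  mc <- scramble_permutation_test(dw, stat_fn = slope_stat, n_perm = 400, seed = 12)
  se <- sd(exhaustive) / sqrt(400)
  expect_lt(abs(mean(mc$null_stats) - mean(exhaustive)), 2 * se)
  # Monte-Carlo draws live inside the exhaustive support
  expect_true(all(round(mc$null_stats, 10) %in% round(exhaustive, 10)))
  # observed stat is one of the scrambles (identity included conceptually)
  expect_true(round(mc$observed_stat, 10) %in% round(exhaustive, 10))
})

test_that("nothing-to-scramble inputs are rejected", {
  dw <- feature_drawings(list(rnorm(5), rnorm(5)), dyads = c("a", "b"),
                         objects = "o1", reps = c(1, 1))
  expect_error(scramble_permutation_test(dw, n_perm = 100), "nothing to scramble")
})
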