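four_trial_table <- function(acc = c(1, 1, 0, 1), rt = c(10, 8, 6, 4)) {
  tibble::tibble(
    dyad_id = "d1", trial_index = 0:3,
    phase = c("pre", "repetition", "repetition", "post"),
    condition = "repeated", target_id = "o1",
    response_id = ifelse(acc == 1, "o1", "o2"),
    accuracy = acc, rt_sec = rt,
    repetition = c(NA, 1L, 2L, NA), n_strokes = 5L, timeout = 0L
  )
}

test_that("BIS matches hand-computed z-scores on a 4-trial table", {
  tr <- four_trial_table()
  eff <- compute_bis(tr)
  # hand computation with sample (n-1) sd:
  # acc mean .75, sd .5 -> z_acc = (.5, .5, -1.5, .5)
  # rt mean 7, sd sqrt(20/3) -> z_rt = (3,1,-1,-3)/sqrt(20/3)
  z_acc <- c(0.5, 0.5, -1.5, 0.5)
  z_rt <- c(3, 1, -1, -3) / sqrt(20 / 3)
  expect_equal(eff$z_accuracy, z_acc, tolerance = 1e-12)
  expect_equal(eff$z_rt, z_rt, tolerance = 1e-12)
  expect_equal(eff$bis, z_acc - z_rt, tolerance = 1e-12)
  # trial 4 (fast and correct) is the most efficient
  expect_equal(which.max(eff$bis), 4L)
})

test_that("within-scope z means are 0 (and sds 1) to machine precision", {
  co <- small_cohort(n_dyads = 3, seed = 14)
  tr <- cohort_trials(co)
  for (scope in c("all_within_interaction", "balanced_prepost_16")) {
    eff <- suppressWarnings(compute_bis(tr, scope))
    for (g in split(eff, eff$dyad_id)) {
      expect_lt(abs(mean(g$z_rt)), 1e-9)
      expect_lt(abs(mean(g$z_accuracy)), 1e-9)
      expect_equal(sd(g$z_rt), 1, tolerance = 1e-9)
    }
    if (scope == "balanced_prepost_16") {
      expect_true(all(table(eff$dyad_id) <= 16))
      expect_true(all(eff$phase %in% c("pre", "post")))
    }
  }
})

test_that("BIS is invariant to positive affine transformations of rt", {
  tr <- four_trial_table()
  base <- compute_bis(tr)$bis
  tr2 <- tr; tr2$rt_sec <- 3.7 * tr$rt_sec + 2.2
  expect_equal(compute_bis(tr2)$bis, base, tolerance = 1e-12)
})

test_that("zero-variance rules: constant accuracy warns and zeroes, constant rt errors", {
  tr <- four_trial_table(acc = c(1, 1, 1, 1))
  expect_warning(eff <- compute_bis(tr), "zero variance")
  expect_true(all(eff$z_accuracy == 0))
  expect_equal(eff$bis, -eff$z_rt)

  tr_flat <- four_trial_table(rt = c(5, 5, 5, 5))
  expect_error(compute_bis(tr_flat), "rt_sec")

  # fully degenerate table: identical (acc, rt) pairs
  expect_error(compute_bis(four_trial_table(acc = c(1, 1, 1, 1), rt = rep(7, 4))),
               "rt_sec")
})

test_that("repetition trends recover the sign of the generating process", {
  co <- simulate_cohort(sim_config(n_dyads = 12, seed = 23))
  eff <- suppressWarnings(compute_bis(cohort_trials(co)))
  up <- fit_repetition_trend(eff, "bis")
  expect_gt(up$estimate, 0)
  expect_lt(up$p_value, 0.05)
  rt <- fit_repetition_trend(eff, "rt")
  expect_lt(rt$estimate, 0)
  ns <- fit_repetition_trend(eff, "n_strokes")
  expect_lt(ns$estimate, 0)
  expect_lt(ns$p_value, 0.05)
  acc <- fit_repetition_trend(eff, "accuracy")
  expect_gt(acc$estimate, 0)
})

test_that("the pre/post x condition interaction favors repeated objects and flips with labels", {
  co <- simulate_cohort(sim_config(n_dyads = 15, seed = 29))
  tr <- cohort_trials(co)
  eff <- suppressWarnings(compute_bis(tr))
  fit <- fit_prepost_interaction(eff)
  expect_gt(fit$estimate, 0)
  expect_lt(fit$p_value, 0.05)

  # relabeling the conditions swaps the interaction sign
  eff_sw <- eff
  eff_sw$condition <- ifelse(eff$condition == "repeated", "control", "repeated")
  fit_sw <- fit_prepost_interaction(eff_sw)
  expect_equal(fit_sw$estimate, -fit$estimate, tolerance = 0.25 * abs(fit$estimate))
  expect_lt(fit_sw$estimate, 0)

  # missing cell errors by name
  eff_miss <- eff[!(eff$phase == "post" & eff$condition == "control"), ]
  expect_error(fit_prepost_interaction(eff_miss), "phase=post, condition=control")
})

test_that("group x repetition interaction is null for identical groups, positive for yoked benefit", {
  co <- simulate_cohort(sim_config(n_dyads = 12, seed = 33))
  rec <- simulate_recognition(co, n_per_group = 12, shuffled_benefit = 0.2, seed = 2)
  eff <- suppressWarnings(compute_bis(rec))
  eff$rep_idx <- rec$rep_idx[match(paste(eff$participant_id, eff$trial_index),
                                   paste(rec$participant_id, rec$trial_index))]
  fit <- fit_group_repetition_interaction(eff[eff$condition == "repeated", ])
  expect_gt(fit$estimate, 0)

  # identical groups: relabel half of the yoked participants as shuffled
  rec_y <- simulate_recognition(co, n_per_group = 16, shuffled_benefit = 1, seed = 5)
  rec_y <- rec_y[rec_y$group == "yoked", ]
  ids <- unique(rec_y$participant_id)
  rec_y$group[rec_y$participant_id %in% ids[1:8]] <- "shuffled"
  eff_y <- suppressWarnings(compute_bis(rec_y))
  eff_y$rep_idx <- rec_y$rep_idx[match(paste(eff_y$participant_id, eff_y$trial_index),
                                       paste(rec_y$participant_id, rec_y$trial_index))]
  fit_null <- fit_group_repetition_interaction(eff_y[eff_y$condition == "repeated", ])
  expect_gt(fit_null$p_value, 0.05)

  # a group with a single repetition level errors
  one_rep <- eff[eff$condition == "repeated" & !(eff$group == "yoked" & eff$rep_idx > 1), ]
  expect_error(fit_group_repetition_interaction(one_rep), "single repetition")
})
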