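#' Extract a feature embedding from a drawing raster
#'
#' The `"seeded_projection"` backend maps the flattened raster through a
#' fixed, seeded random Gaussian linear projection to a `dim`-dimensional
#' vector; it is deterministic, needs no downloads, and is the backend used
#' throughout the test suite. The `"pretrained_cnn_fc6"` backend stands for
#' a 4096-dimensional penultimate-layer embedding from a pretrained
#' image-classification CNN; it requires an optional deep-learning runtime
#' and raises an explicit error (with instructions to switch backend) when
#' that runtime is absent — never a silent fallback.
#'
#' @param raster Binary or grayscale matrix.
#' @param backend `"seeded_projection"` or `"pretrained_cnn_fc6"`.
#' @param dim Output dimension for the seeded projection.
#' @param seed Seed of the projection matrix.
#' @return Numeric vector of length `dim` with attribute `backend_id`.
#' @export
extract_features <- function(raster, backend = c("seeded_projection",
                                                 "pretrained_cnn_fc6"),
                             dim = 64, seed = 101) {
  backend <- match.arg(backend)
  if (backend == "pretrained_cnn_fc6") {
    if (!requireNamespace("torch", quietly = TRUE)) {
      abort(paste0(
        "backend 'pretrained_cnn_fc6' needs the optional 'torch' runtime, ",
        "which is not installed; use backend = 'seeded_projection' instead"))
    }
    abort("pretrained_cnn_fc6 backend not wired to a model in this build")
  }
  P <- projection_matrix(dim, length(raster), seed)
  f <- as.numeric(P %*% as.numeric(raster))
  attr(f, "backend_id") <- sprintf("seeded_projection(dim=%d,seed=%d)", dim, seed)
  f
}

#' Seeded random projection matrix
#'
#' The fixed Gaussian matrix behind the `"seeded_projection"` feature
#' backend, scaled by `1 / sqrt(n_pixels)`; cached per (dim, n_pixels, seed).
#'
#' @param dim Number of output features.
#' @param n_pixels Number of input pixels.
#' @param seed Seed.
#' @return A `dim x n_pixels` matrix.
#' @export
projection_matrix <- function(dim, n_pixels, seed = 101) {
  key <- sprintf("proj_%d_%d_%d", dim, n_pixels, seed)
  if (is.null(the[[key]])) {
    the[[key]] <- withr::with_seed(seed, {
      matrix(rnorm(dim * n_pixels), nrow = dim) / sqrt(n_pixels)
    })
  }
  the[[key]]
}

#' Pearson similarity of two feature vectors
#'
#' `s_ij = cov(r_i, r_j) / sqrt(var(r_i) var(r_j))`, the Pearson correlation
#' between the two embeddings. Symmetric, bounded in `[-1, 1]`, and invariant
#' to positive affine transformations of either vector.
#'
#' @param f_i,f_j Numeric vectors of equal length.
#' @return Similarity in `[-1, 1]`.
#' @export
pairwise_similarity <- function(f_i, f_j) {
  if (length(f_i) != length(f_j)) abort("feature vectors differ in length")
  if (sd(f_i) == 0 || sd(f_j) == 0) {
    abort("zero-variance feature vector: Pearson similarity undefined")
  }
  cor(f_i, f_j)
}

# feature matrix (drawings x dims) for one object, plus dyad/rep index
drawings_feature_matrix <- function(dw) {
  if (!"features" %in% names(dw)) abort("drawings need a 'features' list-column")
  do.call(rbind, dw$features)
}

#' Within-interaction convergence of successive drawings
#'
#' For each dyad and repeated object, the similarity between drawings at
#' successive appearances `k` and `k + 1`; rising similarity means the dyad
#' is converging on a stable way of depicting the object. The trend is fit
#' with random intercepts/slopes for object and for sketcher (pruned on
#' non-convergence; `lm` as last resort).
#'
#' @param drawings Drawings tibble with `dyad_id`, `object_id`, `repetition`
#'   and a `features` list-column; typically [cohort_drawings()] restricted
#'   to the repeated condition.
#' @param fit Also fit the trend?
#' @return List with `series` (tibble `dyad_id, object_id, k, s`: `s` links
#'   appearances `k` and `k + 1`) and `fit` (a `trend_fit`, or `NULL`).
#' @export
within_convergence <- function(drawings, fit = TRUE) {
  dw <- if ("condition" %in% names(drawings)) {
    drawings[drawings$condition == "repeated", ]
  } else drawings
  if (!nrow(dw)) dw <- drawings
  series <- list()
  for (key in split(seq_len(nrow(dw)), paste(dw$dyad_id, dw$object_id))) {
    g <- dw[key, ]
    g <- g[order(g$repetition), ]
    ks <- g$repetition
    for (i in seq_len(nrow(g) - 1)) {
      if (ks[i + 1] != ks[i] + 1) {
        inform(sprintf("%s/%s: appearance %d missing; pair skipped",
                       g$dyad_id[1], g$object_id[1], ks[i] + 1))
        next
      }
      series[[length(series) + 1]] <- tibble(
        dyad_id = g$dyad_id[1], object_id = g$object_id[1], k = ks[i],
        s = pairwise_similarity(g$features[[i]], g$features[[i + 1]])
      )
    }
  }
  series <- dplyr::bind_rows(series)
  out <- list(series = series, fit = NULL)
  if (fit && nrow(series)) {
    d <- series
    d$k_c <- as.numeric(d$k)
    forms <- list(s ~ k_c + (1 + k_c | object_id) + (1 + k_c | dyad_id),
                  s ~ k_c + (1 | object_id) + (1 | dyad_id))
    info <- fit_lmm_chain(forms, d)
    out$fit <- if (!is.null(info)) {
      extract_term(info, "k_c")
    } else {
      lm_trend_fit(d$k_c, d$s, quadratic = FALSE)
    }
  }
  out
}

lm_trend_fit <- function(k, y, quadratic = TRUE) {
  X <- if (quadratic) trend_design(k) else cbind(1, k)
  fit <- lm(y ~ X - 1)
  sm <- summary(fit)
  co <- coef(sm)
  new_trend_fit("k_c", co[2, 1], co[2, 3], fit$df.residual, co[2, 4],
                "lm on series (fixed effects only)", TRUE, coefs = co)
}

#' Between-interaction divergence of same-object drawings
#'
#' For each repeated object and appearance index `k`, the mean pairwise
#' similarity between drawings of that object produced in *different*
#' interactions; a falling series means dyads are drifting toward
#' dyad-specific conventions. The trend over `k` includes linear and
#' orthogonalized quadratic terms, with by-object random effects when the
#' data permit.
#'
#' @inheritParams within_convergence
#' @return List with `series` (tibble `object_id, k, s, n_pairs`) and `fit`.
#' @export
between_divergence <- function(drawings, fit = TRUE) {
  dw <- if ("condition" %in% names(drawings)) {
    drawings[drawings$condition == "repeated", ]
  } else drawings
  if (!nrow(dw)) dw <- drawings
  series <- list()
  for (ob in unique(dw$object_id)) {
    g <- dw[dw$object_id == ob, ]
    if (length(unique(g$dyad_id)) < 2) {
      inform(sprintf("object %s drawn by a single dyad; excluded", ob))
      next
    }
    Fm <- drawings_feature_matrix(g)
    C <- suppressWarnings(cor(t(Fm)))
    for (k in sort(unique(g$repetition))) {
      rows <- which(g$repetition == k)
      if (length(rows) < 2) next
      pairs <- utils::combn(rows, 2)
      cross <- g$dyad_id[pairs[1, ]] != g$dyad_id[pairs[2, ]]
      if (!any(cross)) next
      sims <- C[cbind(pairs[1, cross], pairs[2, cross])]
      series[[length(series) + 1]] <- tibble(
        object_id = ob, k = k, s = mean(sims), n_pairs = sum(cross))
    }
  }
  series <- dplyr::bind_rows(series)
  out <- list(series = series, fit = NULL)
  if (fit && nrow(series)) {
    d <- series
    d$k_c <- as.numeric(d$k)
    if (length(unique(d$object_id)) > 1 && length(unique(d$k)) >= 3) {
      d$k_q <- poly(d$k, 2)[, 2]
      forms <- list(s ~ k_c + k_q + (1 + k_c | object_id),
                    s ~ k_c + k_q + (1 | object_id))
      info <- fit_lmm_chain(forms, d)
      out$fit <- if (!is.null(info)) extract_term(info, "k_c") else
        lm_trend_fit(d$k_c, d$s)
    } else {
      out$fit <- lm_trend_fit(d$k_c, d$s, quadratic = length(unique(d$k)) >= 3)
    }
  }
  out
}

# default permutation statistic: t of the linear repetition term in a
# fixed-effects fit of the between-interaction cell means (fast and
# deterministic inside the permutation loop)
divergence_cell_stat <- function(cells_k, cells_s) {
  X <- trend_design(cells_k)
  ls_coef_t(X, cells_s)
}

#' Scramble permutation test for repetition trajectories
#'
#' Builds a null distribution for a trajectory statistic by independently
#' permuting the repetition labels within every sketcher-by-object cell, so
#' any dependence of the statistic on repetition order is destroyed while
#' the drawings themselves (and their dyad/object structure) are preserved.
#' The default statistic is the t value of the linear repetition term from a
#' fixed-effects fit of the between-interaction divergence cell means. The
#' p value is two-sided with add-one correction,
#' `p = (1 + #\{|null| >= |observed|\}) / (n_perm + 1)`, and the reported
#' null interval is the 2.5-97.5 percentile range.
#'
#' @param drawings Drawings tibble with `dyad_id`, `object_id`, `repetition`
#'   and `features`.
#' @param stat_fn Optional function `drawings -> scalar`; when `NULL` the
#'   fast default divergence statistic is used.
#' @param n_perm Number of permutations (>= 100 recommended; smaller values
#'   are allowed for exhaustive toy comparisons).
#' @param seed Seed; the null sample is reproducible given it.
#' @return An object of class `permutation_result`: `observed_stat`,
#'   `null_stats`, `p_value`, `ci` (2.5/97.5 percentiles of the null),
#'   `n_perm`, `seed`, `scheme`.
#' @export
scramble_permutation_test <- function(drawings, stat_fn = NULL, n_perm = 1000,
                                      seed = 1) {
  dw <- drawings
  cell <- paste(dw$dyad_id, dw$object_id)
  if (max(table(cell)) < 2) abort("all sketcher x object cells have size 1; nothing to scramble")

  if (is.null(stat_fn)) {
    res <- scramble_default_stat(dw, n_perm, seed)
  } else {
    observed <- stat_fn(dw)
    null_stats <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        perm <- dw
        for (idx in split(seq_len(nrow(dw)), cell)) {
          perm$repetition[idx] <- sample(dw$repetition[idx])
        }
        stat_fn(perm)
      }, 0)
    })
    res <- list(observed = observed, null = null_stats)
  }
  null_stats <- res$null[is.finite(res$null)]
  p <- (1 + sum(abs(null_stats) >= abs(res$observed))) / (length(null_stats) + 1)
  structure(list(observed_stat = res$observed, null_stats = res$null,
                 p_value = p,
                 ci = unname(quantile(null_stats, c(0.025, 0.975))),
                 n_perm = n_perm, seed = seed,
                 scheme = "repetition labels scrambled within sketcher x object"),
            class = "permutation_result")
}

# fast path: precompute per-object correlation matrices once; a permutation
# only relabels repetitions, i.e. regroups precomputed pairwise similarities
scramble_default_stat <- function(dw, n_perm, seed) {
  objs <- unique(dw$object_id)
  pre <- list()
  for (ob in objs) {
    g <- dw[dw$object_id == ob, ]
    if (length(unique(g$dyad_id)) < 2) next
    Fm <- drawings_feature_matrix(g)
    pre[[ob]] <- list(C = suppressWarnings(cor(t(Fm))),
                      dyad = g$dyad_id, rep = g$repetition)
  }
  if (!length(pre)) abort("no object is drawn by >= 2 dyads")

  cell_means <- function(labels_by_obj) {
    ks <- c(); ss <- c()
    for (ob in names(pre)) {
      p <- pre[[ob]]
      lab <- labels_by_obj[[ob]]
      for (k in sort(unique(lab))) {
        rows <- which(lab == k)
        if (length(rows) < 2) next
        prs <- utils::combn(rows, 2)
        cross <- p$dyad[prs[1, ]] != p$dyad[prs[2, ]]
        if (!any(cross)) next
        ks <- c(ks, k)
        ss <- c(ss, mean(p$C[cbind(prs[1, cross], prs[2, cross])]))
      }
    }
    list(k = ks, s = ss)
  }

  obs_labels <- lapply(pre, `[[`, "rep")
  cm <- cell_means(obs_labels)
  observed <- divergence_cell_stat(cm$k, cm$s)
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      labs <- lapply(pre, function(p) {
        lab <- p$rep
        for (idx in split(seq_along(lab), p$dyad)) lab[idx] <- sample(lab[idx])
        lab
      })
      cmi <- cell_means(labs)
      divergence_cell_stat(cmi$k, cmi$s)
    }, 0)
  })
  list(observed = observed, null = null)
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result: observed = %.4g, p = %.4g (n_perm = %d), null 95%% [%.3g, %.3g]>\n",
              x$observed_stat, x$p_value, x$n_perm, x$ci[1], x$ci[2]))
  invisible(x)
}
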