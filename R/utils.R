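#' Derive a child seed from a base seed
#'
#' Deterministically maps a base seed and an index to a new seed in
#' `[0, 2^31)`, so that independent simulation streams (one per dyad, per
#' replicate, ...) can be derived from a single user-facing seed.
#'
#' @param seed Integer base seed.
#' @param index Non-negative integer stream index.
#' @return A single integer seed.
#' @export
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(index))
  # splitmix-style integer hash, kept in 32-bit signed range
  x <- (as.double(seed) * 48271 + as.double(index) * 2654435761) %% 2147483647
  as.integer(x)
}

#' Appearance index of a trial
#'
#' Maps the session phase structure onto the 1..8 "repetition number" used by
#' the trajectory analyses: the pre phase counts as appearance 1, the six
#' repetition blocks as appearances 2-7, and the post phase as appearance 8.
#' Control objects are only drawn in pre (1) and post (8).
#'
#' @param phase Character vector in `c("pre", "repetition", "post")`.
#' @param block Integer repetition-block index (1-6), `NA` outside the
#'   repetition phase.
#' @return Integer vector of appearance indices.
#' @export
appearance_index <- function(phase, block) {
  stopifnot(length(phase) == length(block) || length(block) == 1)
  out <- rep(NA_integer_, length(phase))
  out[phase == "pre"] <- 1L
  out[phase == "post"] <- 8L
  rep_i <- phase == "repetition"
  out[rep_i] <- as.integer(block[rep_i]) + 1L
  if (anyNA(out)) abort("unknown phase label or missing block index")
  out
}

# t statistic of the j-th coefficient of a least-squares fit y ~ X
# (X includes the intercept column). Fast path used inside permutation loops.
ls_coef_t <- function(X, y, j = 2L, xtx_inv = NULL) {
  if (is.null(xtx_inv)) xtx_inv <- solve(crossprod(X))
  b <- xtx_inv %*% crossprod(X, y)
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  if (df <= 0) return(NA_real_)
  s2 <- sum(res^2) / df
  as.numeric(b[j] / sqrt(s2 * xtx_inv[j, j]))
}

# linear + orthogonalized-quadratic design matrix on an index k
trend_design <- function(k) {
  if (length(unique(k)) >= 3) {
    cbind(1, k, poly(k, 2)[, 2])
  } else {
    cbind(1, k)
  }
}
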