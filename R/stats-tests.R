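#' Bonferroni correction
#'
#' `q = min(1, m * p)`, order-preserving; `m` defaults to the number of
#' p-values (one test per feature family).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param m number of comparisons (>= 1).
#' @return numeric vector of corrected q-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < 1) stopf("bmetex_param_error", "m must be >= 1")
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stopf("bmetex_param_error", "p-values must be in [0, 1]")
  }
  pmin(1, m * p)
}

#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Two-sided signed-rank test of paired differences. Zero differences are
#' dropped (classical convention; a message reports how many). With at most
#' 25 remaining pairs, the exact null distribution of the positive-rank sum
#' is computed by enumeration over all sign assignments (dynamic programming
#' over doubled midranks, so ties are handled exactly); above that, a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param before,after paired numeric vectors of equal length.
#' @return list with `p`, statistic `W` (positive-rank sum), `n_used`,
#'   `n_zero_dropped`, and `method`.
#' @export
wilcoxon_paired <- function(before, after) {
  if (length(before) != length(after)) {
    stopf("bmetex_param_error", "paired vectors must have equal length")
  }
  d <- after - before
  nz <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    rlang::warn("all differences are zero; degenerate test, p = 1")
    return(list(p = 1, W = NA_real_, n_used = 0L, n_zero_dropped = nz,
                method = "degenerate"))
  }
  if (nz > 0) message(sprintf("dropped %d zero difference(s)", nz))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25L) {
    p <- signed_rank_exact_p(r, W)
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(abs(d))
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(p = p, W = W, n_used = n, n_zero_dropped = nz, method = method)
}

# Exact two-sided p over all 2^n sign assignments: distribution of the
# doubled rank sum via generating-function convolution.
signed_rank_exact_p <- function(ranks, W) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (r in r2) {
    g <- f
    g[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] + f[1L:(total + 1L - r)]
    f <- g
  }
  f <- f / 2^length(r2)
  w2 <- as.integer(round(2 * W))
  lower <- sum(f[seq_len(w2 + 1L)])
  upper <- sum(f[(w2 + 1L):(total + 1L)])
  min(1, 2 * min(lower, upper))
}

#' Fisher's exact probability test (Freeman-Halton) for 2xC tables
#'
#' Exhaustive enumeration over all tables with the observed margins: the
#' p-value is the total probability of tables whose multivariate
#' hypergeometric probability does not exceed that of the observed table
#' (with a small numerical slack for ties). Supports 2x2 and 2x3 tables. A
#' zero row or column margin makes the test degenerate (`p = 1`).
#'
#' @param t 2xC matrix of non-negative integer counts, C in {2, 3}.
#' @return the two-sided p-value.
#' @export
fisher_exact <- function(t) {
  t <- as.matrix(t)
  if (nrow(t) != 2L || !ncol(t) %in% c(2L, 3L)) {
    stopf("bmetex_param_error", "table must be 2x2 or 2x3")
  }
  if (any(t < 0) || any(t != round(t))) {
    stopf("bmetex_param_error", "counts must be non-negative integers")
  }
  rs <- rowSums(t); cs <- colSums(t)
  if (any(rs == 0) || any(cs == 0)) {
    return(1)
  }
  tabs <- enumerate_margin_tables(rs, cs)
  lp <- vapply(tabs, function(a) table_log_prob(a, rs, cs), 0.0)
  p_obs <- table_log_prob(t[1, ], rs, cs)
  probs <- exp(lp)
  sum(probs[probs <= exp(p_obs) * (1 + 1e-7) + 1e-12])
}

# All first rows consistent with the margins of a 2xC table.
enumerate_margin_tables <- function(rs, cs) {
  C <- length(cs)
  out <- list()
  if (C == 2L) {
    for (a in max(0, rs[1] - cs[2]):min(rs[1], cs[1])) {
      out[[length(out) + 1L]] <- c(a, rs[1] - a)
    }
  } else {
    for (a1 in 0:min(rs[1], cs[1])) {
      for (a2 in 0:min(rs[1] - a1, cs[2])) {
        a3 <- rs[1] - a1 - a2
        if (a3 >= 0 && a3 <= cs[3]) {
          out[[length(out) + 1L]] <- c(a1, a2, a3)
        }
      }
    }
  }
  out
}

# log P(first row = a | margins), multivariate hypergeometric.
table_log_prob <- function(a, rs, cs) {
  sum(lchoose(cs, a)) - lchoose(sum(rs), rs[1])
}
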