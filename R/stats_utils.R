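# Shared statistical primitives: rank-sum tests (vectorised over genes),
# one-sided Fisher via the hypergeometric tail, and the adjusted Rand index.

#' Two-sided Wilcoxon rank-sum p-value, exact by enumeration when feasible
#'
#' For small problems (`choose(n, n1) <= max_enum`) the permutation null of
#' the rank-sum statistic is enumerated over all assignments of observations
#' to the first group, which handles ties exactly (and reduces to the
#' classical exact Wilcoxon distribution when there are none). Otherwise a
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param x,y numeric vectors for the two groups.
#' @param max_enum largest number of group assignments enumerated exactly.
#' @return two-sided p-value in (0, 1].
#' @export
rank_sum_test <- function(x, y, max_enum = 20000) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  stopifnot(n1 >= 1, n2 >= 1)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (choose(n, n1) <= max_enum) {
    combs <- utils::combn(n, n1)
    ws <- colSums(matrix(r[combs], nrow = n1))
    mu <- n1 * (n + 1) / 2
    # two-sided permutation p: assignments at least as extreme around the mean
    p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
    return(min(1, p))
  }
  tie_normal_p(w, n1, n2, table(r))
}

# Tie-corrected normal approximation with continuity correction for the
# rank-sum statistic w (sum of group-1 ranks).
tie_normal_p <- function(w, n1, n2, tie_tab) {
  n <- n1 + n2
  mu <- n1 * (n + 1) / 2
  ties <- as.numeric(tie_tab)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

# Vectorised rank-sum p-values, one per column of `mat`, comparing rows in
# `in_group` against the rest. Ranks are computed once per column and reused
# by every caller that tests several groups on the same sample.
rank_sum_matrix_p <- function(ranks, tiecorr, in_group, exact_ok = FALSE,
                              mat = NULL) {
  n <- nrow(ranks)
  n1 <- sum(in_group)
  n2 <- n - n1
  if (exact_ok && choose(n, n1) <= 20000 && !is.null(mat)) {
    return(vapply(seq_len(ncol(mat)), function(j) {
      rank_sum_test(mat[in_group, j], mat[!in_group, j])
    }, numeric(1)))
  }
  w <- colSums(ranks[in_group, , drop = FALSE])
  mu <- n1 * (n + 1) / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tiecorr / (n * (n - 1)))
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(pmax(sigma2, 0))
  p <- 2 * stats::pnorm(-abs(z))
  p[sigma2 <= 0] <- 1
  pmin(p, 1)
}

# Per-column ranks and tie-correction terms sum(t^3 - t) for a matrix.
column_ranks <- function(mat) {
  ranks <- apply(mat, 2L, rank)
  tiecorr <- apply(mat, 2L, function(x) {
    t <- tabulate(match(x, unique(x)))
    sum(t^3 - t)
  })
  list(ranks = ranks, tiecorr = tiecorr)
}

#' One-sided (greater) Fisher exact p-value for 2x2 tables
#'
#' Computed as the hypergeometric upper tail; vectorised over table entries.
#' The table is `[a, b; c, d]` with `a` the overlap being tested for
#' enrichment.
#'
#' @param a,b,c,d nonnegative integer vectors (recycled).
#' @return p-values in (0, 1].
#' @export
fisher_greater_p <- function(a, b, c, d) {
  stopifnot(all(c(a, b, c, d) >= 0))
  stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over [stats::p.adjust()] kept as the single correction point
#' for the package so every family uses the same procedure.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values (same length, NA preserved).
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Adjusted Rand index between two labelings
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return ARI in [-1, 1]; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxidx <- (si + sj) / 2
  if (maxidx == expected) return(1)
  (sij - expected) / (maxidx - expected)
}

# log2 fold change between two groups of normalized (log1p) expression:
# means are taken on the linear (expm1) scale with a small epsilon.
log2fc_linear <- function(norm_in, norm_out, eps = 1e-9) {
  m1 <- if (is.matrix(norm_in)) colMeans(expm1(norm_in)) else mean(expm1(norm_in))
  m0 <- if (is.matrix(norm_out)) colMeans(expm1(norm_out)) else mean(expm1(norm_out))
  log2((m1 + eps) / (m0 + eps))
}
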