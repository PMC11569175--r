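# Gene-set activity scoring with expression-bin-matched control genes,
# quantile-effect-size comparisons, and region-fraction / score correlation.

# Equal-frequency expression bins over genes, ranked by mean normalized
# expression with ties broken by gene name so the binning is invariant to
# input gene order.
expression_bins <- function(avg, gene_ids, n_bins) {
  ord <- order(avg, gene_ids)
  bin <- integer(length(avg))
  bin[ord] <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  pmin(bin, n_bins)
}

#' Score a gene set on spots with bin-matched control genes
#'
#' Genes are divided into `n_bins` equal-frequency bins by mean normalized
#' expression across spots. For every bin containing at least one set gene,
#' `ctrl_size` control genes are sampled from the bin without replacement
#' (the entire bin when it is smaller); no gene is excluded from the
#' control pool, so set genes may serve as their own controls. The score of
#' a spot is the mean normalized expression of the set genes minus the mean
#' over the pooled control genes. Deterministic given `seed`.
#'
#' @param s a normalized [st_sample()].
#' @param genes character vector: the gene set.
#' @param ctrl_size controls sampled per bin (default 50).
#' @param n_bins number of expression bins (default 25).
#' @param seed RNG seed.
#' @return numeric score per spot (class `score_vector`, with metadata
#'   attributes); all-NA with a warning when no set gene is present.
#' @export
score_gene_set <- function(s, genes, ctrl_size = 50L, n_bins = 25L,
                           seed = 0L) {
  stopifnot(inherits(s, "st_sample"))
  if (is.null(s$norm_expr)) stop("normalize_log() the sample first")
  X <- s$norm_expr
  present <- intersect(unique(genes), s$gene_ids)
  if (!length(present)) {
    warning("no gene of the set is present in sample ", s$sample_id)
    out <- rep(NA_real_, nrow(X))
    names(out) <- s$spot_ids
    return(out)
  }
  avg <- colMeans(X)
  n_bins <- min(n_bins, ncol(X))
  bins <- expression_bins(avg, s$gene_ids, n_bins)
  names(bins) <- s$gene_ids
  set.seed(seed)
  ctrl <- character(0)
  for (b in sort(unique(bins[present]))) {
    pool <- sort(s$gene_ids[bins == b])
    ctrl <- c(ctrl, if (length(pool) <= ctrl_size) pool
              else sample(pool, ctrl_size))
  }
  score <- rowMeans(X[, present, drop = FALSE]) -
    rowMeans(X[, ctrl, drop = FALSE])
  structure(score, names = s$spot_ids, class = "score_vector",
            ctrl_size = ctrl_size, n_bins = n_bins, seed = seed)
}

#' Two-group comparison with quantile effect-size stars
#'
#' Welch two-sided t-test of focal versus other scores, with effect-size
#' tiers: `***` when the other group's 90th percentile lies below the focal
#' mean, `**` for the 80th, `*` for the 70th (each additionally requires
#' p < alpha), `ns` otherwise. Tiers nest, the highest satisfied one is
#' reported.
#'
#' @param scores_focal,scores_other numeric score vectors.
#' @param alpha significance threshold for the stars.
#' @return list with `mean_focal`, `mean_other`, `t`, `p`, `stars`.
#' @export
quantile_effect_test <- function(scores_focal, scores_other,
                                 alpha = 0.05) {
  scores_focal <- scores_focal[!is.na(scores_focal)]
  scores_other <- scores_other[!is.na(scores_other)]
  stopifnot(length(scores_focal) > 0, length(scores_other) > 0)
  tt <- tryCatch(stats::t.test(scores_focal, scores_other),
                 error = function(e) NULL)
  p <- if (is.null(tt)) 1 else tt$p.value
  tstat <- if (is.null(tt)) 0 else unname(tt$statistic)
  m <- mean(scores_focal)
  q <- stats::quantile(scores_other, c(0.7, 0.8, 0.9), names = FALSE)
  stars <- "ns"
  if (p < alpha) {
    if (q[1] < m) stars <- "*"
    if (q[2] < m) stars <- "**"
    if (q[3] < m) stars <- "***"
  }
  list(mean_focal = m, mean_other = mean(scores_other), t = tstat, p = p,
       stars = stars)
}

#' Correlate per-sample focal-region fraction with a signature score
#'
#' Raw counts of all non-focal spots are pooled cohort-wide, genes
#' expressed in fewer than `min_samples_per_gene` samples are dropped, the
#' pool is renormalized (median library size + log1p) and scored, and each
#' sample is summarized by the mean score of its non-focal spots. Reported
#' is the Spearman correlation between those means and the per-sample
#' focal-region fractions.
#'
#' @param cohort an [st_cohort()] (raw counts are used).
#' @param assignment a [assign_regions()] result.
#' @param focal_region focal region label.
#' @param genes the gene set to score.
#' @param ctrl_size,n_bins,seed scoring parameters, see [score_gene_set()].
#' @param min_samples minimum samples required (error below).
#' @param min_samples_per_gene gene filter across samples.
#' @return list with `rho`, `p`, `per_sample` (data.frame of fraction and
#'   mean score).
#' @export
fraction_score_correlation <- function(cohort, assignment, focal_region,
                                       genes, ctrl_size = 50L,
                                       n_bins = 25L, seed = 0L,
                                       min_samples = 4L,
                                       min_samples_per_gene = 10L) {
  stopifnot(inherits(cohort, "st_cohort"))
  samples <- cohort$samples
  if (length(samples) < min_samples) {
    stop("fewer than ", min_samples, " samples")
  }
  min_samples_per_gene <- min(min_samples_per_gene, length(samples))
  shared <- Reduce(intersect, lapply(samples, `[[`, "gene_ids"))
  counts <- list(); sample_of <- list(); fracs <- numeric(0)
  for (s in samples) {
    lab <- assignment_for_sample(assignment, s)
    keep <- lab != focal_region & lab >= 1L
    fracs[s$sample_id] <- mean(lab == focal_region)
    counts[[s$sample_id]] <- as.matrix(s$counts[keep, shared,
                                                drop = FALSE])
    sample_of[[s$sample_id]] <- rep(s$sample_id, sum(keep))
  }
  pool <- do.call(rbind, counts)
  sample_of <- unlist(sample_of, use.names = FALSE)
  expressed <- vapply(unique(sample_of), function(sid)
    Matrix::colSums(pool[sample_of == sid, , drop = FALSE] > 0) > 0,
    logical(ncol(pool)))
  keep_gene <- rowSums(expressed) >= min_samples_per_gene
  pool <- pool[, keep_gene, drop = FALSE]
  pooled <- st_sample("pooled", "OTHER", pool,
                      gene_ids = shared[keep_gene],
                      spot_ids = paste0("p", seq_len(nrow(pool))),
                      array_coords = data.frame(
                        array_row = seq_len(nrow(pool)) * 2L,
                        array_col = seq_len(nrow(pool)) * 2L))
  pooled <- normalize_log(pooled)
  sc <- score_gene_set(pooled, genes, ctrl_size = ctrl_size,
                       n_bins = n_bins, seed = seed)
  mean_score <- tapply(as.numeric(sc), sample_of, mean)
  mean_score <- mean_score[names(fracs)]
  if (stats::sd(mean_score) == 0 || stats::sd(fracs) == 0) {
    warning("degenerate (constant) scores or fractions; rho reported as 0")
    return(list(rho = 0, p = 1,
                per_sample = data.frame(sample_id = names(fracs),
                                        fraction = unname(fracs),
                                        mean_score = unname(mean_score))))
  }
  ct <- suppressWarnings(stats::cor.test(fracs, mean_score,
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value,
       per_sample = data.frame(sample_id = names(fracs),
                               fraction = unname(fracs),
                               mean_score = unname(mean_score)))
}
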