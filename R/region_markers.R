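# Region marker derivation: per-sample one-vs-rest Wilcoxon differential
# expression, the cross-sample one-sided Fisher meta-enrichment that defines
# region-specific markers, category-wise DE inside a region, and gene-set
# overrepresentation among markers.

assignment_for_sample <- function(assignment, s) {
  sub <- assignment[assignment$sample_id == s$sample_id, , drop = FALSE]
  lab <- sub$region[match(s$spot_ids, sub$spot_id)]
  if (anyNA(lab)) stop("assignment missing spots of sample ", s$sample_id)
  lab
}

#' Per-sample one-vs-rest differential expression
#'
#' For every region with at least `min_region_size` spots in the sample,
#' each gene is tested by a two-sided Wilcoxon rank-sum test of the
#' region's spots against all other spots of the sample. Mitochondrial and
#' ribosomal genes are excluded by default. P-values are BH-adjusted per
#' region across genes; log2 fold changes are computed between linear-scale
#' means of the expm1-transformed normalized values with epsilon 1e-9.
#'
#' @param s a normalized [st_sample()].
#' @param assignment a [assign_regions()] result covering this sample.
#' @param min_region_size minimum spots for a region to be tested.
#' @param exclude_mito_ribo drop genes matching [is_mito_ribo()].
#' @param alpha,log2fc_min DE call thresholds (`p_adj < alpha` and
#'   `log2fc >= log2fc_min`).
#' @return data.frame (class `de_table`) with columns `sample_id`,
#'   `region`, `gene`, `log2fc`, `p`, `p_adj`, `is_de`.
#' @export
per_sample_de <- function(s, assignment, min_region_size = 10L,
                          exclude_mito_ribo = TRUE, alpha = 0.05,
                          log2fc_min = 1) {
  stopifnot(inherits(s, "st_sample"))
  if (is.null(s$norm_expr)) stop("normalize_log() the sample first")
  lab <- assignment_for_sample(assignment, s)
  genes <- s$gene_ids
  if (exclude_mito_ribo) genes <- genes[!is_mito_ribo(genes)]
  X <- s$norm_expr[, genes, drop = FALSE]
  regions <- sort(unique(lab[lab >= 1L]))
  regions <- regions[vapply(regions, function(r) sum(lab == r),
                            integer(1)) >= min_region_size]
  if (!length(regions)) {
    warning("no region meets the size threshold in sample ", s$sample_id)
    out <- data.frame(sample_id = character(0), region = integer(0),
                      gene = character(0), log2fc = numeric(0),
                      p = numeric(0), p_adj = numeric(0),
                      is_de = logical(0))
    class(out) <- c("de_table", "data.frame")
    return(out)
  }
  n <- nrow(X)
  need_approx <- any(vapply(regions, function(r)
    choose(n, sum(lab == r)) > 20000, logical(1)))
  cr <- if (need_approx) column_ranks(X) else NULL
  res <- lapply(regions, function(r) {
    in_r <- lab == r
    p <- if (choose(n, sum(in_r)) <= 20000) {
      vapply(seq_len(ncol(X)), function(j)
        rank_sum_test(X[in_r, j], X[!in_r, j]), numeric(1))
    } else {
      rank_sum_matrix_p(cr$ranks, cr$tiecorr, in_r)
    }
    lfc <- log2fc_linear(X[in_r, , drop = FALSE], X[!in_r, , drop = FALSE])
    p_adj <- bh_adjust(p)
    data.frame(sample_id = s$sample_id, region = r, gene = genes,
               log2fc = lfc, p = p, p_adj = p_adj,
               is_de = lfc >= log2fc_min & p_adj < alpha,
               row.names = NULL)
  })
  out <- do.call(rbind, res)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Cross-sample region-specific markers by Fisher meta-enrichment
#'
#' Instances are the (sample, region) pairs that were tested (regions
#' dropped by the size filter are untested, not non-DE). For each gene and
#' focal region the 2x2 table counts instances of the focal region where
#' the gene was / was not differentially expressed against the same counts
#' over all other regions, and a one-sided (greater) Fisher exact test asks
#' whether DE calls concentrate in the focal region. BH adjustment is
#' applied within each region across genes; a gene never tested in the
#' focal region is excluded from that region's family. A gene may be a
#' marker for several regions.
#'
#' @param tables list of [per_sample_de()] tables (or one rbind-ed table).
#' @param alpha marker threshold on the adjusted Fisher p-value.
#' @return data.frame (class `region_marker_set`) with columns `region`,
#'   `gene`, `n_de_in_region`, `n_tested_in_region`, `n_de_elsewhere`,
#'   `n_tested_elsewhere`, `fisher_p`, `fisher_p_adj`, `is_marker`.
#' @export
region_specific_markers <- function(tables, alpha = 0.05) {
  tab <- if (is.data.frame(tables)) tables else do.call(rbind, tables)
  if (!nrow(tab)) stop("no DE results supplied")
  g <- factor(tab$gene)
  r <- factor(tab$region)
  tested <- table(g, r)
  de <- stats::xtabs(is_de ~ g + r, data = data.frame(g = g, r = r,
                                                      is_de = tab$is_de))
  tot_tested <- rowSums(tested)
  tot_de <- rowSums(de)
  out <- lapply(colnames(tested), function(rr) {
    in_r <- tested[, rr] > 0
    a <- de[in_r, rr]
    nt <- tested[in_r, rr]
    c_ <- tot_de[in_r] - a
    nt_else <- tot_tested[in_r] - nt
    p <- fisher_greater_p(a, nt - a, c_, nt_else - c_)
    data.frame(region = rr, gene = rownames(tested)[in_r],
               n_de_in_region = as.integer(a),
               n_tested_in_region = as.integer(nt),
               n_de_elsewhere = as.integer(c_),
               n_tested_elsewhere = as.integer(nt_else),
               fisher_p = as.numeric(p),
               fisher_p_adj = bh_adjust(as.numeric(p)),
               row.names = NULL)
  })
  out <- do.call(rbind, out)
  out$is_marker <- out$fisher_p_adj < alpha
  class(out) <- c("region_marker_set", "data.frame")
  out
}

#' Marker gene lists per region
#'
#' @param markers a [region_specific_markers()] table.
#' @return named list of marker gene vectors.
#' @export
marker_genes <- function(markers) {
  split(markers$gene[markers$is_marker], markers$region[markers$is_marker])
}

#' Differential expression between sample categories within one region
#'
#' Region spots are pooled across samples within each category; every pair
#' of categories with at least `min_spots` pooled spots each is compared
#' gene-by-gene with a two-sided Wilcoxon rank-sum test (BH per pair).
#'
#' @param cohort an [st_cohort()] of normalized samples.
#' @param assignment a [assign_regions()] result.
#' @param region focal region label.
#' @param groups map from sample_id to group (named character vector); by
#'   default the samples' categories.
#' @param min_spots group size floor.
#' @param alpha,log2fc_min flags as in [per_sample_de()] but two-sided
#'   (`|log2fc| >= log2fc_min`).
#' @return data.frame (class `group_de_table`) with columns `region`,
#'   `group_a`, `group_b`, `gene`, `log2fc`, `p`, `p_adj`, `is_de`.
#' @export
group_de <- function(cohort, assignment, region, groups = NULL,
                     min_spots = 10L, alpha = 0.05, log2fc_min = 1) {
  stopifnot(inherits(cohort, "st_cohort"))
  if (is.null(groups)) {
    groups <- vapply(cohort$samples, function(s) s$category, character(1))
  }
  shared <- Reduce(intersect, lapply(cohort$samples, `[[`, "gene_ids"))
  pools <- list()
  for (s in cohort$samples) {
    if (is.null(s$norm_expr)) stop("normalize_log() all samples first")
    lab <- assignment_for_sample(assignment, s)
    in_r <- lab == region
    if (!any(in_r)) next
    grp <- groups[[s$sample_id]]
    pools[[grp]] <- rbind(pools[[grp]],
                          s$norm_expr[in_r, shared, drop = FALSE])
  }
  sizes <- vapply(pools, nrow, integer(1))
  out <- list()
  gs <- names(pools)
  for (a in seq_along(gs)) for (b in seq_along(gs)) {
    if (a >= b) next
    if (sizes[a] < min_spots || sizes[b] < min_spots) {
      message("group_de: skipping ", gs[a], " vs ", gs[b],
              " (group below ", min_spots, " spots)")
      next
    }
    X <- rbind(pools[[a]], pools[[b]])
    in_a <- c(rep(TRUE, sizes[a]), rep(FALSE, sizes[b]))
    cr <- column_ranks(X)
    p <- rank_sum_matrix_p(cr$ranks, cr$tiecorr, in_a,
                           exact_ok = TRUE, mat = X)
    lfc <- log2fc_linear(X[in_a, , drop = FALSE], X[!in_a, , drop = FALSE])
    p_adj <- bh_adjust(p)
    out[[length(out) + 1L]] <- data.frame(
      region = region, group_a = gs[a], group_b = gs[b], gene = shared,
      log2fc = lfc, p = p, p_adj = p_adj,
      is_de = abs(lfc) >= log2fc_min & p_adj < alpha, row.names = NULL)
  }
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(region = integer(0), group_a = character(0),
               group_b = character(0), gene = character(0),
               log2fc = numeric(0), p = numeric(0), p_adj = numeric(0),
               is_de = logical(0))
  class(out) <- c("group_de_table", "data.frame")
  out
}

#' Gene-set overrepresentation among region-specific markers
#'
#' Per region, a one-sided (greater) Fisher exact test on the 2x2 table of
#' set membership against marker status over the gene universe (by default
#' all genes tested in at least one instance). BH adjustment is applied
#' across sets within each region.
#'
#' @param markers a [region_specific_markers()] table.
#' @param gene_sets named list of gene vectors.
#' @param universe gene universe; default all genes in `markers`.
#' @return data.frame with columns `region`, `set`, `n_overlap`, `n_set`,
#'   `n_markers`, `n_universe`, `p`, `p_adj`.
#' @export
marker_set_overrepresentation <- function(markers, gene_sets,
                                          universe = NULL) {
  if (is.null(universe)) universe <- unique(markers$gene)
  out <- list()
  for (rr in unique(markers$region)) {
    mk <- markers$gene[markers$region == rr & markers$is_marker]
    mk <- intersect(mk, universe)
    ps <- numeric(length(gene_sets))
    ovs <- integer(length(gene_sets)); ns <- integer(length(gene_sets))
    for (i in seq_along(gene_sets)) {
      set <- intersect(unique(gene_sets[[i]]), universe)
      if (!length(set)) {
        warning("gene set ", names(gene_sets)[i],
                " has empty intersection with the universe")
        ps[i] <- 1; ovs[i] <- 0L; ns[i] <- 0L
        next
      }
      a <- length(intersect(set, mk))
      ps[i] <- fisher_greater_p(a, length(mk) - a, length(set) - a,
                                length(universe) - length(mk) -
                                  length(set) + a)
      ovs[i] <- a; ns[i] <- length(set)
    }
    out[[length(out) + 1L]] <- data.frame(
      region = rr, set = names(gene_sets), n_overlap = ovs, n_set = ns,
      n_markers = length(mk), n_universe = length(universe),
      p = ps, p_adj = bh_adjust(ps), row.names = NULL)
  }
  do.call(rbind, out)
}
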