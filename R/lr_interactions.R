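# Permutation ligand-receptor testing between interface spot sets and the
# cross-sample interface-specific Fisher enrichment.

#' Filter a ligand-receptor table by literature support
#'
#' @param db data.frame with columns `ligand`, `receptor`, `n_references`.
#' @param min_refs minimum reference count (default 3; pairs with fewer
#'   are discarded).
#' @return filtered data.frame (warning when empty).
#' @export
filter_lr_pairs <- function(db, min_refs = 3L) {
  out <- db[db$n_references >= min_refs, , drop = FALSE]
  if (!nrow(out)) warning("no ligand-receptor pair passes the filter")
  out
}

#' Permutation test of one ligand-receptor pair at an interface
#'
#' The pair is tested only when the ligand is detected (count > 0) in more
#' than `threshold` of the F-side interacting spots and the receptor in
#' more than `threshold` of the G-side spots; otherwise it is reported
#' untested. The statistic is the mean of the two side means of normalized
#' expression (ligand on F, receptor on G); the null permutes the side
#' assignment over the union of interacting spots. The p-value uses the
#' add-one estimator `(1 + #(null >= observed)) / (1 + n_perms)`, so the
#' smallest attainable value is `1 / (n_perms + 1)`.
#'
#' @param s a normalized [st_sample()].
#' @param f_spots,g_spots integer spot indices of the two interacting sets
#'   (disjoint).
#' @param ligand,receptor gene symbols.
#' @param threshold expression-fraction gate (default 0.01).
#' @param n_perms number of permutations (default 1000).
#' @param seed RNG seed.
#' @return list with `tested`, `p`, `mean_lig`, `mean_rec`.
#' @export
lr_permutation_test <- function(s, f_spots, g_spots, ligand, receptor,
                                threshold = 0.01, n_perms = 1000L,
                                seed = 0L) {
  stopifnot(inherits(s, "st_sample"), length(f_spots) > 0,
            length(g_spots) > 0,
            length(intersect(f_spots, g_spots)) == 0)
  if (is.null(s$norm_expr)) stop("normalize_log() the sample first")
  if (!all(c(ligand, receptor) %in% s$gene_ids)) {
    stop("ligand or receptor gene absent from sample")
  }
  lig_frac <- mean(s$counts[f_spots, ligand] > 0)
  rec_frac <- mean(s$counts[g_spots, receptor] > 0)
  if (lig_frac <= threshold || rec_frac <= threshold) {
    return(list(tested = FALSE, p = NA_real_,
                mean_lig = NA_real_, mean_rec = NA_real_))
  }
  spots <- c(f_spots, g_spots)
  lx <- s$norm_expr[spots, ligand]
  rx <- s$norm_expr[spots, receptor]
  n_f <- length(f_spots); n_u <- length(spots)
  mean_lig <- mean(lx[seq_len(n_f)])
  mean_rec <- mean(rx[-seq_len(n_f)])
  observed <- (mean_lig + mean_rec) / 2
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perms)) {
    f_idx <- sample.int(n_u, n_f)
    stat <- (mean(lx[f_idx]) + mean(rx[-f_idx])) / 2
    if (stat >= observed - 1e-12) exceed <- exceed + 1L
  }
  list(tested = TRUE, p = (1 + exceed) / (1 + n_perms),
       mean_lig = mean_lig, mean_rec = mean_rec)
}

#' Test many ligand-receptor pairs at one interface of one sample
#'
#' Runs [lr_permutation_test()] for every pair and BH-adjusts p-values
#' across the tested pairs of this (sample, interface, direction) family.
#'
#' @param s a normalized [st_sample()].
#' @param f_spots,g_spots interacting spot sets (ligand side first).
#' @param pairs data.frame with `ligand`, `receptor` columns.
#' @param interface label describing the interface (stored in the output).
#' @param direction label, e.g. "F->G".
#' @param alpha active threshold on `p_adj`.
#' @param threshold,n_perms,seed see [lr_permutation_test()].
#' @return data.frame (class `lr_result`) with one row per pair.
#' @export
lr_test_interface <- function(s, f_spots, g_spots, pairs,
                              interface = "F|G", direction = "F->G",
                              alpha = 0.05, threshold = 0.01,
                              n_perms = 1000L, seed = 0L) {
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    pr <- if (all(c(pairs$ligand[i], pairs$receptor[i]) %in% s$gene_ids)) {
      lr_permutation_test(s, f_spots, g_spots, pairs$ligand[i],
                          pairs$receptor[i], threshold = threshold,
                          n_perms = n_perms, seed = seed + i)
    } else list(tested = FALSE, p = NA_real_, mean_lig = NA_real_,
                mean_rec = NA_real_)
    data.frame(sample_id = s$sample_id, interface = interface,
               direction = direction, ligand = pairs$ligand[i],
               receptor = pairs$receptor[i], tested = pr$tested,
               mean_lig = pr$mean_lig, mean_rec = pr$mean_rec, p = pr$p)
  })
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  out$p_adj[out$tested] <- bh_adjust(out$p[out$tested])
  out$active <- !is.na(out$p_adj) & out$p_adj < alpha
  class(out) <- c("lr_result", "data.frame")
  out
}

#' Interface-specific enrichment of active ligand-receptor pairs
#'
#' Pools tested (sample, interface) instances across samples and asks, for
#' every pair and interface type, whether activity concentrates at that
#' interface type: a one-sided (greater) Fisher exact test on active vs
#' tested-not-active counts here against everywhere else, BH-adjusted
#' across pairs within each interface type. Optionally restricts to pairs
#' whose focal-side partner is among the focal region's specific markers.
#'
#' @param results rbind of [lr_test_interface()] outputs across samples
#'   and interfaces.
#' @param allowed_pairs optional data.frame of `ligand`, `receptor` rows to
#'   keep (e.g. pairs with a marker partner); NULL keeps all.
#' @param min_interfaces drop interface types tested in fewer instances
#'   (0 disables).
#' @return data.frame with per (pair, interface) counts, `fisher_p`,
#'   `fisher_p_adj`, and a `degenerate` flag for pairs tested at a single
#'   interface type.
#' @export
interface_enrichment <- function(results, allowed_pairs = NULL,
                                 min_interfaces = 0L) {
  res <- results[results$tested, , drop = FALSE]
  if (!is.null(allowed_pairs)) {
    key <- paste(res$ligand, res$receptor)
    res <- res[key %in% paste(allowed_pairs$ligand,
                              allowed_pairs$receptor), , drop = FALSE]
  }
  if (min_interfaces > 0L) {
    inst <- unique(res[, c("sample_id", "interface")])
    counts <- table(inst$interface)
    res <- res[res$interface %in% names(counts)[counts >=
                                                  min_interfaces], ,
               drop = FALSE]
  }
  if (!nrow(res)) stop("no tested ligand-receptor results")
  pair_key <- paste(res$ligand, res$receptor, sep = "|")
  out <- list()
  for (itf in unique(res$interface)) {
    here <- res$interface == itf
    for (pk in unique(pair_key[here])) {
      sel <- pair_key == pk
      a <- sum(res$active[sel & here])
      b <- sum(sel & here) - a
      c_ <- sum(res$active[sel & !here])
      d <- sum(sel & !here) - c_
      lig <- res$ligand[sel & here][1]
      rec <- res$receptor[sel & here][1]
      out[[length(out) + 1L]] <- data.frame(
        ligand = lig, receptor = rec, interface = itf,
        n_active_here = a, n_tested_here = a + b,
        n_active_elsewhere = c_, n_tested_elsewhere = c_ + d,
        fisher_p = fisher_greater_p(a, b, c_, d),
        degenerate = sum(sel & !here) == 0L)
    }
  }
  out <- do.call(rbind, out)
  out$fisher_p_adj <- NA_real_
  for (itf in unique(out$interface)) {
    sel <- out$interface == itf
    out$fisher_p_adj[sel] <- bh_adjust(out$fisher_p[sel])
  }
  out
}
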