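# SCM region calling: iterative NMF over cell-state abundances with the
# component-uniqueness stopping rule, argmax spot categorization, and
# region-fraction statistics.

#' Select the number of NMF components by top-state uniqueness
#'
#' Fits NMF to the spots-by-states abundance matrix for every component
#' count in `k_min..k_max` and inspects, for each component, which cell
#' state contributes most to its loading row. A component count is
#' admissible when every component has a distinct top state; the chosen k
#' is the largest admissible one. If no k in the range is admissible an
#' error lists the duplicated states per k.
#'
#' @param A an [abundance_matrix()].
#' @param k_min,k_max component range (defaults 5 and 12).
#' @param seed RNG seed forwarded to [nmf_fit()].
#' @param ... further arguments to [nmf_fit()].
#' @return object of class `region_model`: `k`, `W`, `H`,
#'   `top_state_per_component`, `k_range_tried`, `uniqueness_flags`,
#'   `trace` (per-k fits summary), `seed`, plus the input row metadata.
#' @export
select_k_by_uniqueness <- function(A, k_min = 5L, k_max = 12L, seed = 0L,
                                   ...) {
  stopifnot(inherits(A, "abundance_matrix"), k_min >= 1, k_min <= k_max)
  if (k_max > ncol(A$values)) {
    stop("k_max exceeds the number of cell states")
  }
  ks <- k_min:k_max
  fits <- vector("list", length(ks))
  flags <- logical(length(ks))
  tops <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    fit <- nmf_fit(A$values, ks[i], seed = seed, ...)
    top <- apply(fit$H, 1L, which.max)     # ties -> lowest state index
    fits[[i]] <- fit
    tops[[i]] <- top
    flags[i] <- !anyDuplicated(top)
  }
  if (!any(flags)) {
    dups <- vapply(seq_along(ks), function(i) {
      d <- tops[[i]][duplicated(tops[[i]])]
      sprintf("k=%d: duplicated state(s) %s", ks[i],
              paste(unique(A$state_names[d]), collapse = ","))
    }, character(1))
    stop("selection-failure error: no k in range has unique top states\n",
         paste(dups, collapse = "\n"))
  }
  best <- max(which(flags))
  fit <- fits[[best]]
  structure(list(k = ks[best], W = fit$W, H = fit$H,
                 top_state_per_component = tops[[best]],
                 k_range_tried = ks, uniqueness_flags = flags,
                 trace = list(top_states = tops,
                              objective = lapply(fits, `[[`, "objective"),
                              iterations = vapply(fits, `[[`, integer(1),
                                                  "iterations")),
                 seed = seed, state_names = A$state_names,
                 spot_ids = A$spot_ids, sample_ids = A$sample_ids),
            class = "region_model")
}

#' @method print region_model
#' @export
print.region_model <- function(x, ...) {
  cat("region_model: k =", x$k, "chosen from",
      paste(range(x$k_range_tried), collapse = ".."),
      "| top states:", paste(x$state_names[x$top_state_per_component],
                             collapse = ", "), "\n")
  invisible(x)
}

#' Assign each spot to its highest-contributing component
#'
#' Ties are broken towards the lowest component index (with a warning);
#' spots whose entire loading row is zero get the reserved label 0
#' ("unassigned") and a warning.
#'
#' @param model a [select_k_by_uniqueness()] result.
#' @return object of class `region_assignment`: data.frame with columns
#'   `spot_id`, `sample_id`, `region` (integer in 1..k, or 0).
#' @export
assign_regions <- function(model) {
  stopifnot(inherits(model, "region_model"))
  W <- model$W
  lab <- apply(W, 1L, which.max)
  zero <- rowSums(W) == 0
  if (any(zero)) {
    warning(sum(zero), " spot(s) with all-zero loadings left unassigned")
    lab[zero] <- 0L
  }
  maxes <- W[cbind(seq_len(nrow(W)), pmax(lab, 1L))]
  tied <- !zero & rowSums(W == maxes) > 1L
  if (any(tied)) {
    warning(sum(tied), " tie(s) broken towards the lowest component index")
  }
  out <- data.frame(spot_id = model$spot_ids,
                    sample_id = model$sample_ids,
                    region = as.integer(lab))
  class(out) <- c("region_assignment", "data.frame")
  attr(out, "k") <- model$k
  out
}

#' Per-sample region fraction table
#'
#' @param assignment a [assign_regions()] result (or any data.frame with
#'   `sample_id` and `region`).
#' @param k number of regions (default from the assignment attribute).
#' @return matrix samples x regions; each row sums to 1.
#' @export
region_fractions <- function(assignment, k = attr(assignment, "k")) {
  stopifnot(!is.null(k))
  keep <- assignment$region >= 1L
  tab <- table(factor(assignment$sample_id[keep],
                      levels = unique(assignment$sample_id)),
               factor(assignment$region[keep], levels = seq_len(k)))
  frac <- sweep(unclass(tab), 1L, rowSums(tab), "/")
  dimnames(frac) <- list(rownames(tab), paste0("region", seq_len(k)))
  frac
}

#' Compare region fractions across sample categories
#'
#' For each region: a Kruskal-Wallis test across all categories with at
#' least two samples, plus all pairwise two-sided Wilcoxon rank-sum tests
#' (exact by enumeration for small groups, tie-corrected normal
#' approximation otherwise).
#'
#' @param fractions samples x regions matrix from [region_fractions()].
#' @param categories category label per sample (same order as rows).
#' @return data.frame with columns `region`, `test` ("kruskal" or
#'   "groupA|groupB"), `p`.
#' @export
compare_fractions <- function(fractions, categories) {
  stopifnot(nrow(fractions) == length(categories))
  sizes <- table(categories)
  keep_cats <- names(sizes)[sizes >= 2L]
  if (length(keep_cats) < length(sizes)) {
    warning("excluding categories with fewer than 2 samples: ",
            paste(setdiff(names(sizes), keep_cats), collapse = ", "))
  }
  if (length(keep_cats) < 2L) stop("need >= 2 categories with >= 2 samples")
  keep <- categories %in% keep_cats
  fractions <- fractions[keep, , drop = FALSE]
  categories <- factor(categories[keep])
  out <- list()
  for (j in seq_len(ncol(fractions))) {
    x <- fractions[, j]
    kw <- suppressWarnings(stats::kruskal.test(x, categories)$p.value)
    if (!is.finite(kw)) kw <- 1   # all observations tied
    out[[length(out) + 1L]] <- data.frame(region = colnames(fractions)[j],
                                          test = "kruskal", p = kw)
    cats <- levels(categories)
    for (a in seq_along(cats)) for (b in seq_along(cats)) {
      if (a >= b) next
      p <- rank_sum_test(x[categories == cats[a]],
                         x[categories == cats[b]])
      out[[length(out) + 1L]] <- data.frame(
        region = colnames(fractions)[j],
        test = paste(cats[a], cats[b], sep = "|"), p = p)
    }
  }
  do.call(rbind, out)
}
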