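# Neighborhood enrichment on the hex graph and the proximal/distant and
# interface annotation rules.

#' Permutation neighborhood enrichment z-scores
#'
#' Counts, for every ordered-free region pair (i, j), the number of spot
#' pairs at ring distance <= the graph's `n_rings` that join regions i and
#' j, and compares it to the same count under `n_perms` random permutations
#' of the labels over spots. z = (observed - null mean) / null sd, with z
#' defined as 0 where the null sd is 0 (e.g. a single-region sample).
#'
#' @param labels integer region label per spot (0 = unassigned, ignored).
#' @param graph a [build_hex_graph()] for the same spots.
#' @param k number of regions (labels range over 1..k).
#' @param n_perms number of label permutations.
#' @param seed RNG seed.
#' @return k x k symmetric matrix of z-scores.
#' @export
neighborhood_enrichment <- function(labels, graph, k = max(labels),
                                    n_perms = 1000L, seed = 0L) {
  stopifnot(length(labels) == graph$n)
  edges <- graph_edges(graph)
  pair_counts <- function(lab) {
    a <- lab[edges[, 1L]]; b <- lab[edges[, 2L]]
    ok <- a >= 1L & b >= 1L
    idx <- (pmin(a[ok], b[ok]) - 1L) * k + pmax(a[ok], b[ok])
    tabulate(idx, nbins = k * k)
  }
  obs <- pair_counts(labels)
  set.seed(seed)
  null <- matrix(0, n_perms, k * k)
  for (b in seq_len(n_perms)) {
    null[b, ] <- pair_counts(sample(labels))
  }
  mu <- colMeans(null)
  sd <- apply(null, 2L, stats::sd)
  z <- (obs - mu) / sd
  z[!is.finite(z)] <- 0
  zm <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in i:k) {
    zm[i, j] <- zm[j, i] <- z[(i - 1L) * k + j]
  }
  dimnames(zm) <- list(paste0("region", 1:k), paste0("region", 1:k))
  zm
}

#' Cohort-mean neighborhood enrichment
#'
#' Averages per-sample z matrices after setting rows/columns of regions
#' missing from a sample to 0.
#'
#' @param z_list list of k x k z matrices (one per sample).
#' @param present_list list of integer vectors: regions present per sample.
#' @return k x k mean matrix.
#' @export
cohort_enrichment <- function(z_list, present_list) {
  k <- nrow(z_list[[1]])
  acc <- matrix(0, k, k)
  for (i in seq_along(z_list)) {
    z <- z_list[[i]]
    miss <- setdiff(seq_len(k), present_list[[i]])
    z[miss, ] <- 0
    z[, miss] <- 0
    acc <- acc + z
  }
  acc / length(z_list)
}

# Focal spots with at least one ring-1 neighbour of the same focal label.
anchored_spots <- function(labels, graph, focal) {
  which(vapply(seq_len(graph$n), function(i) {
    labels[i] == focal &&
      any(labels[graph_neighbors(graph, i, ring = 1L)] == focal)
  }, logical(1)))
}

#' Annotate spots by proximity to a focal region
#'
#' Focal spots are "focal-anchored" when at least one ring-1 neighbour
#' shares the focal label, else "focal-sporadic". A non-focal spot is
#' "proximal" when it lies within 3 rings of two or more anchored focal
#' spots that are adjacent to each other (`rule = "pair"`, the default) or
#' of any two anchored focal spots (`rule = "any"`); otherwise "distant".
#' Samples with fewer than `min_focal_spots` focal spots are excluded
#' (returned with `excluded = TRUE` and no statuses).
#'
#' @param labels integer region label per spot.
#' @param graph a [build_hex_graph()] with `n_rings >= 3`.
#' @param focal_region focal region label.
#' @param min_focal_spots sample inclusion floor on focal spot count.
#' @param rule adjacency reading of "two or more adjacent focal spots".
#' @return list with `excluded` (logical), `status` (character per spot:
#'   focal-anchored / focal-sporadic / proximal / distant), `n_focal`.
#' @export
annotate_proximity <- function(labels, graph, focal_region,
                               min_focal_spots = 10L,
                               rule = c("pair", "any")) {
  rule <- match.arg(rule)
  n_focal <- sum(labels == focal_region)
  if (n_focal < min_focal_spots) {
    return(list(excluded = TRUE, status = NULL, n_focal = n_focal))
  }
  anch <- anchored_spots(labels, graph, focal_region)
  status <- rep("distant", graph$n)
  status[labels == focal_region] <- "focal-sporadic"
  status[anch] <- "focal-anchored"
  nonfocal <- which(labels != focal_region)
  if (rule == "pair") {
    # adjacent anchored pairs -> spots within 3 rings of both ends
    for (u in anch) {
      vs <- intersect(graph_neighbors(graph, u, ring = 1L), anch)
      vs <- vs[vs > u]
      for (v in vs) {
        near <- intersect(graph_neighbors(graph, u, ring = 3L,
                                          within = TRUE),
                          graph_neighbors(graph, v, ring = 3L,
                                          within = TRUE))
        near <- near[labels[near] != focal_region]
        status[near] <- "proximal"
      }
    }
  } else {
    for (q in nonfocal) {
      cnt <- sum(graph_neighbors(graph, q, ring = 3L, within = TRUE)
                 %in% anch)
      if (cnt >= 2L) status[q] <- "proximal"
    }
  }
  list(excluded = FALSE, status = status, n_focal = n_focal)
}

#' Annotate an interface between two regions
#'
#' A spot of region F is "interacting" towards G when it is anchored in F
#' (has a ring-1 neighbour of its own region) and at least `min_partner`
#' spots of region G lie within 3 rings of it; symmetrically for G. The
#' (F, G) interface exists in a sample only when both interacting sets have
#' at least `min_spots` members.
#'
#' @param labels integer region label per spot.
#' @param graph a [build_hex_graph()] with `n_rings >= 3`.
#' @param region_f,region_g the two region labels.
#' @param min_spots floor on both interacting set sizes.
#' @param min_partner required partner spots within 3 rings (default 2).
#' @return list with `exists` (logical), `f_spots`, `g_spots` (integer
#'   indices of interacting spots).
#' @export
annotate_interface <- function(labels, graph, region_f, region_g,
                               min_spots = 10L, min_partner = 2L) {
  interacting <- function(a, b) {
    anch <- anchored_spots(labels, graph, a)
    keep <- vapply(anch, function(i) {
      sum(labels[graph_neighbors(graph, i, ring = 3L, within = TRUE)]
          == b) >= min_partner
    }, logical(1))
    anch[keep]
  }
  f_spots <- interacting(region_f, region_g)
  g_spots <- interacting(region_g, region_f)
  list(exists = length(f_spots) >= min_spots &&
         length(g_spots) >= min_spots,
       f_spots = f_spots, g_spots = g_spots)
}
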