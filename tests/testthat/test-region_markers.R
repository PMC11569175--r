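two_group_sample <- function() {
  # 3 region-1 spots expressing gene "up", 3 region-2 spots silent
  # equal spot totals so normalization is the identity scaling
  counts <- cbind(up = c(2, 2, 2, 0, 0, 0),
                  flat = rep(3, 6),
                  base = c(8, 8, 8, 10, 10, 10))
  rownames(counts) <- paste0("s", 1:6)
  toy_sample(counts)
}

de_assignment <- function(s, region) {
  data.frame(spot_id = s$spot_ids, sample_id = s$sample_id,
             region = region)
}

test_that("one-vs-rest DE reproduces the exact enumeration example", {
  s <- two_group_sample()
  asg <- de_assignment(s, rep(c(1L, 2L), each = 3))
  de <- per_sample_de(s, asg, min_region_size = 3L)
  up1 <- de[de$region == 1 & de$gene == "up", ]
  expect_equal(up1$p, 0.1)          # 2 of the 20 rank arrangements
  expect_gt(up1$log2fc, 5)          # near-infinite linear ratio
  flat <- de[de$region == 1 & de$gene == "flat", ]
  expect_equal(flat$p, 1)
  expect_equal(flat$log2fc, 0, tolerance = 1e-9)
  expect_false(any(de$is_de))       # p_adj can never clear 0.05 at n=6
})

test_that("small regions are skipped and mito/ribo genes excluded", {
  s <- two_group_sample()
  asg <- de_assignment(s, rep(c(1L, 2L), each = 3))
  expect_warning(empty <- per_sample_de(s, asg, min_region_size = 4L),
                 "size threshold")
  expect_equal(nrow(empty), 0L)
  counts <- cbind(`MT-CO1` = 1:6, RPL3 = 6:1, RPS9 = rep(2, 6),
                  ok = rep(3, 6))
  rownames(counts) <- paste0("s", 1:6)
  s2 <- toy_sample(counts)
  de2 <- per_sample_de(s2, de_assignment(s2, rep(c(1L, 2L), each = 3)),
                       min_region_size = 3L)
  expect_equal(unique(de2$gene), "ok")
})

test_that("DE calls are invariant to spot and gene order", {
  sim <- small_sim()
  s <- normalize_log(filter_sample(sim$cohort$samples[[1]]))
  asg <- truth_assignment(sim)
  de1 <- per_sample_de(s, asg)
  perm_g <- sample(ncol(s$counts))
  perm_s <- sample(nrow(s$counts))
  s2 <- st_sample(s$sample_id, s$category, s$counts[perm_s, perm_g],
                  gene_ids = s$gene_ids[perm_g],
                  spot_ids = s$spot_ids[perm_s],
                  array_coords = s$array_coords[perm_s, ])
  s2 <- normalize_log(s2)
  de2 <- per_sample_de(s2, asg)
  key <- function(d) d[order(d$region, d$gene), c("region", "gene", "p",
                                                  "log2fc", "is_de")]
  expect_equal(key(de1), key(de2), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("Fisher meta-enrichment counts instances and matches closed form", {
  # gene G is DE in region 1 of all 8 samples, never elsewhere (8 regions)
  tabs <- do.call(rbind, lapply(1:8, function(sid)
    do.call(rbind, lapply(1:8, function(r)
      data.frame(sample_id = paste0("s", sid), region = r,
                 gene = c("G", "H"), log2fc = 0, p = 1, p_adj = 1,
                 is_de = c(r == 1, FALSE))))))
  mk <- region_specific_markers(tabs)
  g1 <- mk[mk$region == 1 & mk$gene == "G", ]
  expect_equal(g1$n_de_in_region, 8L)
  expect_equal(g1$n_tested_elsewhere, 56L)
  expect_equal(g1$fisher_p, 1 / choose(64, 8), tolerance = 1e-9)
  expect_true(g1$is_marker)
  # no DE in the focal region cannot be enrichment
  h1 <- mk[mk$region == 2 & mk$gene == "H", ]
  expect_equal(h1$fisher_p, 1)
  # a gene never tested in a region is excluded from that family
  tabs2 <- tabs[!(tabs$gene == "H" & tabs$region == 3), ]
  mk2 <- region_specific_markers(tabs2)
  expect_false(any(mk2$region == 3 & mk2$gene == "H"))
  expect_true(any(mk2$region == 3 & mk2$gene == "G"))
})

test_that("planted markers are recovered across a synthetic cohort", {
  sim <- small_sim()
  cohort <- small_sim_norm()
  asg <- truth_assignment(sim)
  de <- do.call(rbind, lapply(cohort$samples, per_sample_de,
                              assignment = asg))
  mk <- region_specific_markers(de)
  called <- marker_genes(mk)
  sens <- numeric(0)
  for (r in seq_len(sim$config$k_true)) {
    planted <- sim$truth$markers[[r]]
    sens <- c(sens, mean(planted %in% called[[as.character(r)]]))
  }
  expect_gte(mean(sens), 0.9)
  # false-marker rate over unplanted genes
  unplanted <- setdiff(sim$cohort$samples[[1]]$gene_ids,
                       unlist(sim$truth$markers))
  fpr <- mean(unlist(lapply(called, intersect, unplanted)) %in% unplanted)
  n_false <- sum(vapply(called, function(g)
    length(intersect(g, unplanted)), integer(1)))
  expect_lte(n_false / (length(unplanted) * sim$config$k_true), 0.05)
})

test_that("category DE flags the AR-like suppression but not club markers", {
  sim <- small_sim()
  cohort <- small_sim_norm()
  asg <- truth_assignment(sim)
  club <- sim$truth$club_region
  gde <- group_de(cohort, asg, club, min_spots = 10L)
  pair <- gde[gde$group_a %in% c("TRNA", "NEADT") &
                gde$group_b %in% c("TRNA", "NEADT"), ]
  expect_gt(nrow(pair), 0)
  # orient log2fc as NEADT relative to TRNA
  sgn <- if (pair$group_a[1] == "NEADT") 1 else -1
  ar <- pair[pair$gene %in% sim$truth$gene_sets$AR_like, ]
  expect_gte(mean(ar$is_de & sgn * ar$log2fc <= -1), 0.8)
  clubmk <- pair[pair$gene %in% sim$truth$markers[[club]], ]
  expect_false(any(clubmk$is_de))
})

test_that("identical group distributions yield no DE flags", {
  s <- small_sim_norm()$samples[[1]]
  # duplicate the same sample under two categories
  s2 <- s; s2$sample_id <- "copy"; s2$category <- "NEADT"
  s2$spot_ids <- paste0("c_", s$spot_ids)
  rownames(s2$counts) <- s2$spot_ids
  rownames(s2$norm_expr) <- s2$spot_ids
  cohort <- st_cohort(list(s, s2))
  sim <- small_sim()
  tr <- truth_assignment(sim)
  tr2 <- tr[tr$sample_id == s$sample_id, ]
  tr2$sample_id <- "copy"; tr2$spot_id <- paste0("c_", tr2$spot_id)
  asg <- rbind(tr, tr2)
  gde <- group_de(cohort, asg, region = 1L, min_spots = 10L)
  expect_false(any(gde$is_de))
  expect_true(all(gde$p_adj > 0.9))
})

test_that("marker overrepresentation hits a perfectly matching set", {
  mk <- data.frame(region = 1L, gene = paste0("g", 1:1000),
                   is_marker = c(rep(TRUE, 20), rep(FALSE, 980)))
  sets <- list(exact = paste0("g", 1:20),
               disjoint = paste0("g", 900:920))
  ov <- marker_set_overrepresentation(mk, sets)
  # log-scale closed form: 1 / C(1000, 20)
  expect_equal(log(ov$p[ov$set == "exact"]),
               -lchoose(1000, 20), tolerance = 1e-6)
  expect_equal(ov$p[ov$set == "disjoint"], 1, tolerance = 1e-12)
  expect_warning(
    marker_set_overrepresentation(mk, list(empty = "absent")),
    "empty intersection")
})
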