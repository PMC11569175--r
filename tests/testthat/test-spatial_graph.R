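test_that("neighborhood enrichment separates blocks and is deterministic", {
  lat <- generate_hex_lattice(12, 12)
  g <- build_hex_graph(lat, n_rings = 3L)
  # two spatially separated blocks
  lab <- ifelse(lat$array_row < 6, 1L, 2L)
  z1 <- neighborhood_enrichment(lab, g, k = 2, n_perms = 300, seed = 5)
  expect_gt(z1[1, 1], 0); expect_gt(z1[2, 2], 0)
  expect_lt(z1[1, 2], 0)
  expect_equal(z1[1, 2], z1[2, 1])
  z2 <- neighborhood_enrichment(lab, g, k = 2, n_perms = 300, seed = 5)
  expect_identical(z1, z2)
  # single-region sample: degenerate null, all zeros off the diagonal
  z3 <- neighborhood_enrichment(rep(1L, nrow(lat)), g, k = 2,
                                n_perms = 50, seed = 1)
  expect_true(all(z3 == 0))
})

test_that("random labels give approximately standard-normal z-scores", {
  lat <- generate_hex_lattice(10, 10)
  g <- build_hex_graph(lat, n_rings = 3L)
  set.seed(77)
  zs <- replicate(30, {
    lab <- sample(1:4, nrow(lat), replace = TRUE)
    z <- neighborhood_enrichment(lab, g, k = 4, n_perms = 300,
                                 seed = sample.int(1e6, 1))
    z[upper.tri(z, diag = TRUE)]
  })
  expect_lt(abs(mean(zs)), 0.15)
  expect_gt(stats::sd(zs), 0.7)
  expect_lt(stats::sd(zs), 1.3)
})

test_that("cohort averaging zeroes missing regions before the mean", {
  z <- matrix(2, 3, 3)
  zm <- cohort_enrichment(list(z, z), list(1:3, 1:2))
  expect_equal(zm[1, 1], 2)
  expect_equal(zm[3, 3], 1)     # missing in the second sample
  expect_equal(zm[1, 3], 1)
})

test_that("proximity statuses follow the anchored-pair rule exactly", {
  lat <- generate_hex_lattice(12, 12)
  g <- build_hex_graph(lat, n_rings = 3L)
  # isolated focal spot: sporadic, creates no proximal spots
  lab <- rep(2L, nrow(lat))
  lone <- which(lat$array_row == 5 & lat$array_col == 5)
  lab[lone] <- 1L
  lab[sample(setdiff(seq_len(nrow(lat)), lone), 11)] <- 3L  # padding
  res <- annotate_proximity(lab, g, 1L, min_focal_spots = 1L)
  expect_equal(res$status[lone], "focal-sporadic")
  expect_false(any(res$status == "proximal"))
  # a domino of two adjacent focal spots: every non-focal spot within 3
  # rings of both is proximal (checked exhaustively)
  lab2 <- rep(2L, nrow(lat))
  a <- which(lat$array_row == 5 & lat$array_col == 5)
  b <- which(lat$array_row == 5 & lat$array_col == 7)
  lab2[c(a, b)] <- 1L
  res2 <- annotate_proximity(lab2, g, 1L, min_focal_spots = 2L)
  d_a <- hex_distance(lat, seq_len(nrow(lat)), rep(a, nrow(lat)))
  d_b <- hex_distance(lat, seq_len(nrow(lat)), rep(b, nrow(lat)))
  manual <- ifelse(d_a <= 3 & d_b <= 3, "proximal", "distant")
  manual[c(a, b)] <- "focal-anchored"
  expect_equal(res2$status, manual)
})

test_that("proximity and interface match the brute-force oracle", {
  lat <- generate_hex_lattice(12, 12)
  g <- build_hex_graph(lat, n_rings = 3L)
  set.seed(21)
  for (rep in 1:5) {
    lab <- sample(1:3, nrow(lat), replace = TRUE)
    res <- annotate_proximity(lab, g, 1L, min_focal_spots = 1L)
    expect_equal(res$status, brute_proximity(lat, lab, 1L))
    res_any <- annotate_proximity(lab, g, 1L, min_focal_spots = 1L,
                                  rule = "any")
    expect_equal(res_any$status, brute_proximity(lat, lab, 1L, "any"))
    itf <- annotate_interface(lab, g, 1L, 2L, min_spots = 1L)
    oracle <- brute_interface(lat, lab, 1L, 2L)
    expect_equal(itf$f_spots, oracle$f_spots)
    expect_equal(itf$g_spots, oracle$g_spots)
  }
})

test_that("samples below the focal spot floor are excluded", {
  lat <- generate_hex_lattice(12, 12)
  g <- build_hex_graph(lat, n_rings = 3L)
  lab <- rep(2L, nrow(lat))
  lab[1:9] <- 1L
  expect_true(annotate_proximity(lab, g, 1L)$excluded)
  lab[10] <- 1L
  expect_false(annotate_proximity(lab, g, 1L)$excluded)
})

test_that("proximal and distant exactly partition non-focal spots", {
  lat <- generate_hex_lattice(14, 14)
  g <- build_hex_graph(lat, n_rings = 3L)
  set.seed(8)
  lab <- sample(1:2, nrow(lat), replace = TRUE, prob = c(0.3, 0.7))
  res <- annotate_proximity(lab, g, 1L, min_focal_spots = 1L)
  nonfocal <- which(lab != 1L)
  expect_true(all(res$status[nonfocal] %in% c("proximal", "distant")))
  expect_true(all(res$status[lab == 1L] %in%
                    c("focal-anchored", "focal-sporadic")))
})

test_that("proximity is invariant under translation and 60-degree rotation", {
  lat <- generate_hex_lattice(10, 10)
  g <- build_hex_graph(lat, n_rings = 3L)
  set.seed(13)
  lab <- sample(1:2, nrow(lat), replace = TRUE)
  base <- annotate_proximity(lab, g, 1L, min_focal_spots = 1L)$status
  # translation by (2 rows, 4 cols) keeps parity
  shifted <- data.frame(array_row = lat$array_row + 2L,
                        array_col = lat$array_col + 4L)
  g2 <- build_hex_graph(shifted, n_rings = 3L)
  expect_equal(annotate_proximity(lab, g2, 1L,
                                  min_focal_spots = 1L)$status, base)
  # 60-degree rotation in axial coordinates: (q, r) -> (-r, q + r)
  q <- (lat$array_col - lat$array_row) %/% 2L
  r <- lat$array_row
  q2 <- -r; r2 <- q + r
  rot <- data.frame(array_row = r2, array_col = 2L * q2 + r2)
  g3 <- build_hex_graph(rot, n_rings = 3L)
  expect_equal(annotate_proximity(lab, g3, 1L,
                                  min_focal_spots = 1L)$status, base)
})

test_that("interfaces vanish across a wide separating band and obey floors", {
  lat <- generate_hex_lattice(16, 16)
  g <- build_hex_graph(lat, n_rings = 3L)
  lab <- ifelse(lat$array_row < 5, 1L,
                ifelse(lat$array_row > 10, 2L, 3L))
  itf <- annotate_interface(lab, g, 1L, 2L)
  expect_false(itf$exists)
  expect_equal(length(itf$f_spots), 0L)
  # straight border: interacting sets are the border bands
  lab2 <- ifelse(lat$array_row < 8, 1L, 2L)
  itf2 <- annotate_interface(lab2, g, 1L, 2L)
  expect_true(itf2$exists)
  oracle <- brute_interface(lat, lab2, 1L, 2L)
  expect_equal(itf2$f_spots, oracle$f_spots)
  expect_true(all(lat$array_row[itf2$f_spots] >= 5))
  # 10 vs 9 interacting spots: the interface is dropped
  expect_true(annotate_interface(lab2, g, 1L, 2L, min_spots =
                                   length(itf2$g_spots))$exists)
  expect_false(annotate_interface(lab2, g, 1L, 2L, min_spots =
                                    length(itf2$g_spots) + 1L)$exists)
})
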