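test_that("region fields are deterministic, complete and spatially coherent", {
  lat <- generate_hex_lattice(14, 14)
  f1 <- generate_region_field(lat, 6, seed = 5)
  f2 <- generate_region_field(lat, 6, seed = 5)
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1)), 1:6)
  expect_equal(generate_region_field(lat, 1, seed = 1),
               rep(1L, nrow(lat)), ignore_attr = TRUE)
  expect_error(generate_region_field(lat, nrow(lat) + 1, seed = 1),
               "exceeds")
  # mean fraction of ring-1 neighbours sharing a spot's label
  g <- build_hex_graph(lat, n_rings = 1L)
  share <- numeric(0)
  for (seed in 1:20) {
    f <- generate_region_field(lat, 6, seed = seed)
    share <- c(share, mean(vapply(seq_len(nrow(lat)), function(i) {
      nb <- g$neighbors[[i]]$index
      if (!length(nb)) return(NA_real_)
      mean(f[nb] == f[i])
    }, numeric(1)), na.rm = TRUE))
  }
  expect_gte(mean(share), 0.6)
})

test_that("abundance concentrates on the dominant state of the true region", {
  cfg <- sim_config(lattice_rows = 14, lattice_cols = 14, seed = 2)
  lat <- generate_hex_lattice(14, 14)
  field <- generate_region_field(lat, cfg$k_true, seed = 3)
  ab <- generate_abundance(field, cfg, seed = 4)
  expect_true(all(rowSums(ab$values) > 0))
  expect_gte(mean(apply(ab$values, 1, which.max) == field), 0.95)
  # noiseless limit: argmax is exact
  cfg0 <- sim_config(abundance_noise_sd = 0)
  ab0 <- generate_abundance(field, cfg0, seed = 4)
  expect_equal(apply(ab0$values, 1, which.max), field,
               ignore_attr = TRUE)
})

test_that("counts are deterministic and planted markers hit their fold change", {
  cfg <- sim_config(lattice_rows = 24, lattice_cols = 24, seed = 6)
  lat <- generate_hex_lattice(24, 24)
  field <- generate_region_field(lat, cfg$k_true, seed = 7)
  gc1 <- generate_counts(field, cfg, seed = 8)
  gc2 <- generate_counts(field, cfg, seed = 8)
  expect_identical(gc1$counts, gc2$counts)
  # library-size-corrected marker means inside vs outside the region
  cpm <- gc1$counts / rowSums(gc1$counts)
  ratios <- vapply(seq_len(cfg$k_true), function(r) {
    mk <- gc1$plan$markers[[r]]
    mean(cpm[field == r, mk]) / mean(cpm[field != r, mk])
  }, numeric(1))
  expect_true(all(abs(ratios / 2^cfg$marker_log2fc - 1) < 0.1))
})

test_that("unplanted marker genes are exchangeable with the background", {
  cfg <- sim_config(lattice_rows = 10, lattice_cols = 10, n_genes = 120,
                    marker_log2fc = 0, signature_shift = 0,
                    lr_interface_effect = 0)
  lat <- generate_hex_lattice(10, 10)
  rejections <- 0L; tests <- 0L
  for (seed in 1:40) {
    field <- generate_region_field(lat, cfg$k_true, seed = seed)
    gc <- generate_counts(field, cfg, seed = 1000 + seed)
    cpm <- gc$counts / rowSums(gc$counts)
    r <- 1L + (seed %% cfg$k_true)
    mk <- gc$plan$markers[[r]]
    p <- rank_sum_test(colMeans(cpm[field == r, mk, drop = FALSE]),
                       colMeans(cpm[field == r,
                                    sample(gc$plan$gene_ids, 10),
                                    drop = FALSE]))
    tests <- tests + 1L
    if (p < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections / tests, 0.15)   # about the nominal 5% level
})

test_that("ligand-receptor planting is local to the interface", {
  cfg <- sim_config(lattice_rows = 16, lattice_cols = 16, seed = 12)
  lat <- generate_hex_lattice(16, 16)
  field <- generate_region_field(lat, cfg$k_true, seed = 13)
  gc <- generate_counts(field, cfg, seed = 14)
  graph <- build_hex_graph(lat, n_rings = 3L)
  lr <- data.frame(ligand = gc$plan$ligand, receptor = gc$plan$receptor,
                   source_region = 3L, target_region = 5L,
                   flagged = TRUE)
  # effect 0 leaves counts untouched
  expect_identical(plant_lr_coexpression(gc$counts, field, lr, 0, graph),
                   gc$counts)
  planted <- plant_lr_coexpression(gc$counts, field, lr, 3, graph)
  src <- which(field == 3L); tgt <- which(field == 5L)
  near <- intersect(tgt, unique(unlist(lapply(src, function(s)
    graph_neighbors <- graph$neighbors[[s]]$index))))
  far <- setdiff(tgt, near)
  if (length(near) >= 3 && length(far) >= 3) {
    expect_gt(mean(planted[near, lr$receptor]),
              mean(planted[far, lr$receptor]))
  }
  # all other genes untouched
  others <- setdiff(colnames(gc$counts), c(lr$ligand, lr$receptor))
  expect_identical(planted[, others], gc$counts[, others])
  expect_error(plant_lr_coexpression(gc$counts, field,
    transform(lr, ligand = "nope"), 1, graph), "unknown gene")
})

test_that("cohorts are reproducible, marker lists disjoint, filters vacuous", {
  sim <- small_sim()
  cfg <- sim$config
  sim2 <- simulate_cohort(cfg)
  s1 <- sim$cohort$samples[[1]]; s2 <- sim2$cohort$samples[[1]]
  expect_equal(as.matrix(s1$counts), as.matrix(s2$counts))
  # planted markers are disjoint across regions
  all_mk <- unlist(sim$truth$markers)
  expect_equal(anyDuplicated(all_mk), 0L)
  # default samples pass QC untouched
  f <- filter_sample(s1)
  expect_equal(dim(f$counts), dim(s1$counts))
  # adding a category leaves earlier samples' substreams unperturbed
  cfg3 <- sim_config(n_samples = c(TRNA = 2L, NEADT = 2L, CRPC = 1L),
                     lattice_rows = cfg$lattice_rows,
                     lattice_cols = cfg$lattice_cols,
                     n_genes = cfg$n_genes, seed = cfg$seed)
  sim3 <- simulate_cohort(cfg3)
  expect_equal(as.matrix(sim3$cohort$samples[["TRNA_01"]]$counts),
               as.matrix(sim$cohort$samples[["TRNA_01"]]$counts))
})
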