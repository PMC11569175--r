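test_that("constant expression and self-control sets score zero", {
  counts <- matrix(5L, 30, 40,
                   dimnames = list(paste0("s", 1:30),
                                   paste0("g", 1:40)))
  s <- toy_sample(counts)
  sc <- score_gene_set(s, paste0("g", 1:7), seed = 1)
  expect_equal(as.numeric(sc), rep(0, 30))
  # set = all genes with bins smaller than ctrl_size: controls exhaust the
  # bins and the score cancels exactly
  sim <- small_sim()
  s2 <- normalize_log(filter_sample(sim$cohort$samples[[1]]))
  sc2 <- score_gene_set(s2, s2$gene_ids, ctrl_size = 50, n_bins = 25,
                        seed = 2)
  expect_equal(as.numeric(sc2), rep(0, nrow(s2$counts)),
               tolerance = 1e-12)
})

test_that("a planted additive shift is recovered by the score", {
  # default gene count so control bins are wide enough (1000 genes,
  # 25 bins) for self-contamination of the control pool to stay small
  cfg <- sim_config(n_samples = c(TRNA = 1L), lattice_rows = 16L,
                    lattice_cols = 16L, seed = 19L)
  sim <- simulate_cohort(cfg)
  s <- normalize_log(filter_sample(sim$cohort$samples[[1]]))
  genes <- paste0("gene", 250:264)   # background genes, no generator shift
  region <- sim$truth$true_region[s$spot_ids]
  delta <- 0.5
  in_r <- region == sim$truth$club_region
  s$norm_expr[in_r, genes] <- s$norm_expr[in_r, genes] + delta
  sc <- score_gene_set(s, genes, seed = 3)
  expect_equal(mean(sc[in_r]) - mean(sc[!in_r]), delta,
               tolerance = 0.1)
})

test_that("scores have mean zero over random sets", {
  sim <- small_sim()
  s <- normalize_log(filter_sample(sim$cohort$samples[[1]]))
  set.seed(4)
  means <- replicate(60, {
    genes <- sample(s$gene_ids, 12)
    mean(score_gene_set(s, genes, seed = sample.int(1e6, 1)))
  })
  expect_lt(abs(mean(means)), 3 * stats::sd(means) / sqrt(length(means)))
})

test_that("scoring is invariant to gene and spot order", {
  sim <- small_sim()
  s <- normalize_log(filter_sample(sim$cohort$samples[[1]]))
  genes <- sim$truth$gene_sets$AR_like
  sc1 <- score_gene_set(s, genes, seed = 5)
  perm_g <- sample(ncol(s$counts)); perm_s <- sample(nrow(s$counts))
  s2 <- st_sample(s$sample_id, s$category, s$counts[perm_s, perm_g],
                  gene_ids = s$gene_ids[perm_g],
                  spot_ids = s$spot_ids[perm_s],
                  array_coords = s$array_coords[perm_s, ])
  s2 <- normalize_log(s2)
  sc2 <- score_gene_set(s2, rev(genes), seed = 5)
  expect_equal(sc2[names(sc1)], sc1, ignore_attr = TRUE)
})

test_that("a missing gene set warns and returns NA scores", {
  counts <- matrix(rpois(100, 5), 10, 10,
                   dimnames = list(NULL, paste0("g", 1:10)))
  s <- toy_sample(counts)
  expect_warning(sc <- score_gene_set(s, c("absent1", "absent2")),
                 "no gene")
  expect_true(all(is.na(sc)))
})

test_that("effect stars follow the quantile tiers and nest", {
  set.seed(6)
  other <- runif(1000)
  res <- quantile_effect_test(rep(5, 100), other)
  expect_equal(res$stars, "***")
  expect_lt(res$p, 1e-10)
  x <- rnorm(200)
  res2 <- quantile_effect_test(x, x)
  expect_equal(res2$stars, "ns")
  # focal mean placed between the 70th and 80th percentile of other
  m <- stats::quantile(other, 0.75)
  res3 <- quantile_effect_test(rnorm(400, m, 0.005), other)
  expect_equal(res3$stars, "*")
  expect_lt(res3$p, 0.05)
  # degenerate equal constants
  res4 <- quantile_effect_test(rep(1, 5), rep(1, 5))
  expect_equal(res4$p, 1)
  expect_equal(res4$stars, "ns")
})

test_that("fraction-score correlation is 1 for co-monotone construction", {
  # 8 samples whose focal fraction and signature expression both increase;
  # baselines overlap the signature range so expression bins are mixed
  set.seed(7)
  n_genes <- 300
  genes <- paste0("g", seq_len(n_genes))
  sig <- paste0("g", 1:5)
  lambda <- stats::runif(n_genes, 5, 200)
  samples <- list()
  asg <- NULL
  for (i in 1:8) {
    n <- 60
    counts <- matrix(stats::rpois(n * n_genes, rep(lambda, each = n)),
                     n, n_genes,
                     dimnames = list(paste0("s", i, "_", 1:n), genes))
    # signature expression grows with the sample index
    counts[, sig] <- matrix(rpois(n * 5, 20 + 15 * i), n, 5)
    lab <- rep(2L, n); lab[seq_len(2 * i)] <- 1L   # focal fraction grows
    s <- toy_sample(counts, sample_id = paste0("smp", i))
    samples[[i]] <- s
    asg <- rbind(asg, data.frame(spot_id = s$spot_ids,
                                 sample_id = s$sample_id, region = lab))
  }
  attr(asg, "k") <- 2L
  res <- fraction_score_correlation(st_cohort(samples), asg, 1L, sig,
                                    min_samples_per_gene = 1L, seed = 8)
  expect_equal(res$rho, 1)
  expect_lt(res$p, 0.01)
})

test_that("degenerate constant scores give rho 0 with a warning", {
  genes <- paste0("g", 1:30)
  samples <- list(); asg <- NULL
  for (i in 1:5) {
    counts <- matrix(7L, 40, 30,
                     dimnames = list(paste0("s", i, "_", 1:40), genes))
    lab <- rep(2L, 40); lab[seq_len(4 * i)] <- 1L
    s <- toy_sample(counts, sample_id = paste0("smp", i))
    samples[[i]] <- s
    asg <- rbind(asg, data.frame(spot_id = s$spot_ids,
                                 sample_id = s$sample_id, region = lab))
  }
  attr(asg, "k") <- 2L
  expect_warning(
    res <- fraction_score_correlation(st_cohort(samples), asg, 1L,
                                      genes[1:4],
                                      min_samples_per_gene = 1L),
    "degenerate")
  expect_equal(res$rho, 0)
  expect_error(
    fraction_score_correlation(st_cohort(samples[1:3]), asg, 1L,
                               genes[1:4]),
    "fewer than 4")
})
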