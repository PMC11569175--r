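# Synthetic Visium-like cohort generator with known ground truth.
#
# Each sample is a staggered hex lattice whose spots belong to one of
# `k_true` spatially coherent latent regions. Region r is dominated by cell
# state r; two designated minor "companion" states co-occur with it at half
# the dominant loading, split between two spot subpopulations. This mirrors
# deconvolution output where a handful of low-abundance states track the
# major tissue compartments, and it gives the NMF model-selection rule a
# well-defined stopping point: components beyond k_true can only split a
# region into its two companion subprofiles, which share the dominant state.

#' Simulation configuration
#'
#' Defaults emulate a small multi-category Visium cohort: 12 sections
#' (3 per category), 30 x 30 staggered lattices (900 spots), 26 cell states
#' of which 8 drive latent regions, negative-binomial counts with planted
#' region markers, category-dependent AR-like signature suppression, and a
#' planted ligand-receptor interaction at one region interface.
#'
#' @param n_samples named integer vector: sections per category.
#' @param lattice_rows,lattice_cols lattice size per sample.
#' @param k_true number of latent regions (<= k_states).
#' @param k_states number of cell states in the abundance matrix.
#' @param n_genes genes per sample.
#' @param markers_per_region planted marker genes per region (disjoint).
#' @param marker_log2fc log2 fold change of planted markers inside their
#'   region.
#' @param nb_dispersion negative binomial dispersion (variance =
#'   mu + mu^2 / dispersion).
#' @param mean_umis_per_spot geometric-mean library size.
#' @param cells_per_spot mean inferred cells per spot in the abundance.
#' @param abundance_noise_sd scale of per-state exponential abundance noise
#'   relative to unit dominant loading.
#' @param spatial_patch_scale number of seed patches grown per region
#'   (1 = each region is a single connected patch).
#' @param signature_shift log2 shift applied to the planted signature gene
#'   set inside its designated region.
#' @param lr_interface_effect log2 inflation of planted ligand/receptor
#'   counts at the planted interface.
#' @param seed cohort-level RNG seed; per-sample substreams are derived at
#'   fixed offsets so adding samples does not perturb earlier ones.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = c(BPH = 3L, TRNA = 3L, NEADT = 3L,
                                     CRPC = 3L),
                       lattice_rows = 30L, lattice_cols = 30L,
                       k_true = 8L, k_states = 26L, n_genes = 1000L,
                       markers_per_region = 10L, marker_log2fc = 2,
                       nb_dispersion = 2, mean_umis_per_spot = 2000,
                       cells_per_spot = 20, abundance_noise_sd = 0.05,
                       spatial_patch_scale = 1, signature_shift = 0.5,
                       lr_interface_effect = 3, seed = 1L) {
  cfg <- list(n_samples = n_samples, lattice_rows = lattice_rows,
              lattice_cols = lattice_cols, k_true = k_true,
              k_states = k_states, n_genes = n_genes,
              markers_per_region = markers_per_region,
              marker_log2fc = marker_log2fc, nb_dispersion = nb_dispersion,
              mean_umis_per_spot = mean_umis_per_spot,
              cells_per_spot = cells_per_spot,
              abundance_noise_sd = abundance_noise_sd,
              spatial_patch_scale = spatial_patch_scale,
              signature_shift = signature_shift,
              lr_interface_effect = lr_interface_effect,
              seed = as.integer(seed))
  stopifnot(cfg$k_true <= cfg$k_states, cfg$k_true >= 1,
            cfg$lattice_rows >= 1, cfg$lattice_cols >= 1,
            cfg$n_genes >= 1, cfg$nb_dispersion > 0,
            all(cfg$n_samples >= 0),
            all(names(cfg$n_samples) %in% st_categories))
  structure(cfg, class = "sim_config")
}

#' Grow a spatially coherent region labeling on a hex lattice
#'
#' `k_true * patch_scale` seed spots are drawn and grown by randomized
#' breadth-first accretion: at every step one unassigned spot adjacent to
#' the assigned set is chosen uniformly and takes the label of a random
#' assigned ring-1 neighbour. Every region ends up as a small number of
#' connected patches. Deterministic given `seed`.
#'
#' @param coords lattice coordinates from [generate_hex_lattice()].
#' @param k_true number of regions.
#' @param patch_scale seed patches per region (rounded, >= 1).
#' @param seed RNG seed.
#' @return integer vector of region labels in 1..k_true.
#' @export
generate_region_field <- function(coords, k_true, patch_scale = 1,
                                  seed = 1L) {
  n <- nrow(coords)
  n_seeds <- max(1L, as.integer(round(patch_scale)))
  if (k_true > n) stop("k_true exceeds the number of spots")
  if (k_true * n_seeds > n) stop("too many seed patches for lattice size")
  graph <- build_hex_graph(coords, n_rings = 1L)
  adj <- lapply(seq_len(n), function(i) graph$neighbors[[i]]$index)
  set.seed(seed)
  labels <- rep(NA_integer_, n)
  seeds <- sample.int(n, k_true * n_seeds)
  labels[seeds] <- rep(seq_len(k_true), each = n_seeds)
  unassigned <- which(is.na(labels))
  while (length(unassigned)) {
    has_nb <- unassigned[vapply(unassigned, function(i)
      any(!is.na(labels[adj[[i]]])), logical(1))]
    if (!length(has_nb)) {             # disconnected leftover: re-seed
      i <- unassigned[sample.int(length(unassigned), 1L)]
      labels[i] <- sample.int(k_true, 1L)
    } else {
      i <- has_nb[sample.int(length(has_nb), 1L)]
      nb_lab <- labels[adj[[i]]]
      nb_lab <- nb_lab[!is.na(nb_lab)]
      labels[i] <- nb_lab[sample.int(length(nb_lab), 1L)]
    }
    unassigned <- unassigned[unassigned != i]
  }
  labels
}

# Companion (minor) cell states for region r: two states drawn from the
# k_true+1 .. k_states range, or none when no minor states exist.
companion_states <- function(r, k_true, k_states) {
  n_minor <- k_states - k_true
  if (n_minor <= 0) return(integer(0))
  m1 <- k_true + ((2L * (r - 1L)) %% n_minor) + 1L
  m2 <- k_true + ((2L * (r - 1L) + 1L) %% n_minor) + 1L
  unique(c(m1, m2))
}

#' Generate a per-spot cell-state abundance matrix for one sample
#'
#' Spot i in region r gets a dominant loading on state r of
#' `0.6 + Gamma(2, 0.35)` inferred cells (heterogeneous within region), a
#' half-strength loading on one of region r's two companion minor states
#' (chosen per spot), and i.i.d. `abundance_noise_sd * Exp(1)` noise on
#' every state; rows are then scaled to `cells_per_spot` expected cells.
#'
#' @param true_region integer region labels per spot.
#' @param cfg a [sim_config()].
#' @param sample_id sample id recorded on the rows.
#' @param seed RNG seed.
#' @return an [abundance_matrix()].
#' @export
generate_abundance <- function(true_region, cfg, sample_id = "sample",
                               seed = 1L) {
  n <- length(true_region)
  set.seed(seed)
  bump <- 0.6 + stats::rgamma(n, shape = 2, scale = 0.35)
  vals <- matrix(cfg$abundance_noise_sd *
                   stats::rexp(n * cfg$k_states), nrow = n)
  sub <- stats::rbinom(n, 1L, 0.5) + 1L   # which companion subprofile
  for (i in seq_len(n)) {
    r <- true_region[i]
    vals[i, r] <- vals[i, r] + bump[i]
    comp <- companion_states(r, cfg$k_true, cfg$k_states)
    if (length(comp)) {
      m <- comp[min(sub[i], length(comp))]
      vals[i, m] <- vals[i, m] + 0.5 * bump[i]
    }
  }
  vals <- vals * cfg$cells_per_spot / mean(rowSums(vals))
  abundance_matrix(vals,
                   state_names = paste0("state", seq_len(cfg$k_states)),
                   spot_ids = paste0(sample_id, "_spot",
                                     seq_len(n)),
                   sample_ids = sample_id)
}

# Gene index layout for the synthetic transcriptome. Leading blocks get
# dedicated roles; everything else is background.
sim_gene_plan <- function(cfg) {
  k <- cfg$k_true
  mpr <- cfg$markers_per_region
  idx <- 0L
  take <- function(n) { out <- idx + seq_len(n); idx <<- idx + n; out }
  markers <- lapply(seq_len(k), function(r) take(mpr))
  ar_like <- take(15L)
  signature <- take(15L)
  lig <- take(1L)
  rec <- take(1L)
  if (idx > cfg$n_genes) stop("n_genes too small for the gene plan")
  genes <- paste0("gene", seq_len(cfg$n_genes))
  list(gene_ids = genes,
       markers = lapply(markers, function(ii) genes[ii]),
       marker_idx = markers,
       ar_like = genes[ar_like], ar_idx = ar_like,
       signature = genes[signature], signature_idx = signature,
       ligand = genes[lig], ligand_idx = lig,
       receptor = genes[rec], receptor_idx = rec)
}

#' Generate negative-binomial counts with planted region markers
#'
#' Baseline gene weights are Gamma-distributed with a floor; planted marker
#' genes have their mean multiplied by `2^marker_log2fc` inside their
#' region, the planted signature set by `2^signature_shift` inside its
#' designated region (the club-like region, region 3 when `k_true >= 3`),
#' and the AR-like set is scaled down four-fold in NEADT/CRPC samples while
#' club-like region markers are left unchanged. Library sizes are
#' log-normal around `mean_umis_per_spot`.
#'
#' @param true_region integer region labels per spot.
#' @param cfg a [sim_config()].
#' @param category sample category (drives the AR-like down-shift).
#' @param seed RNG seed.
#' @return list with `counts` (spots x genes, dense integer matrix),
#'   `gene_ids`, and `plan` (the gene role layout).
#' @export
generate_counts <- function(true_region, cfg, category = "TRNA",
                            seed = 1L) {
  n <- length(true_region)
  plan <- sim_gene_plan(cfg)
  # the gene baseline is a cohort-level property: seeded by cfg$seed so
  # every sample shares one transcriptome and cross-sample DE is meaningful
  set.seed(cfg$seed)
  base_w <- stats::rgamma(cfg$n_genes, shape = 1) + 0.1
  # planted ligand/receptor genes get a fixed moderate baseline so the
  # planted interface effect is a clean known contrast
  base_w[c(plan$ligand_idx, plan$receptor_idx)] <- 1
  set.seed(seed)
  # per-region mean profiles on the relative scale
  prof <- matrix(rep(base_w, cfg$k_true), nrow = cfg$k_true, byrow = TRUE)
  for (r in seq_len(cfg$k_true)) {
    prof[r, plan$marker_idx[[r]]] <-
      prof[r, plan$marker_idx[[r]]] * 2^cfg$marker_log2fc
  }
  sig_region <- club_region(cfg$k_true)
  prof[sig_region, plan$signature_idx] <-
    prof[sig_region, plan$signature_idx] * 2^cfg$signature_shift
  # AR-like genes are highly expressed at baseline and suppressed after
  # androgen deprivation (NEADT/CRPC categories)
  prof[, plan$ar_idx] <- prof[, plan$ar_idx] * 4
  if (category %in% c("NEADT", "CRPC")) {
    prof[, plan$ar_idx] <- prof[, plan$ar_idx] * 0.25
  }
  lib <- stats::rlnorm(n, log(cfg$mean_umis_per_spot) - 0.3^2 / 2, 0.3)
  mu <- prof[true_region, , drop = FALSE]
  mu <- mu / rowSums(mu) * lib
  counts <- matrix(stats::rnbinom(n * cfg$n_genes, mu = as.vector(mu),
                                  size = cfg$nb_dispersion), nrow = n)
  colnames(counts) <- plan$gene_ids
  list(counts = counts, gene_ids = plan$gene_ids, plan = plan)
}

# The club-like focal region of the simulation (region 3 when possible).
club_region <- function(k_true) min(3L, k_true)

# The immune-like partner region for the planted LR interaction.
immune_region <- function(k_true) min(5L, k_true)

#' Plant ligand-receptor co-expression at a region interface
#'
#' For each flagged pair the co-expression is planted in the interface band
#' only: ligand counts are multiplied by `2^effect` in source-region spots
#' within 3 rings of the target region, and receptor counts by `2^effect`
#' in target-region spots within 3 rings of the source region. Spots away
#' from the interface keep their baseline, so the planted signal is
#' specific to this region pair's interface. `effect = 0` leaves the
#' counts untouched.
#'
#' @param counts spots x genes count matrix.
#' @param true_region integer region labels.
#' @param lr_pairs data.frame with columns `ligand`, `receptor`,
#'   `source_region`, `target_region`, `flagged`.
#' @param effect log2 inflation.
#' @param graph [build_hex_graph()] of the sample (rings >= 3).
#' @return modified count matrix.
#' @export
plant_lr_coexpression <- function(counts, true_region, lr_pairs, effect,
                                  graph) {
  for (i in seq_len(nrow(lr_pairs))) {
    if (!isTRUE(lr_pairs$flagged[i])) next
    lg <- lr_pairs$ligand[i]; rg <- lr_pairs$receptor[i]
    if (!all(c(lg, rg) %in% colnames(counts))) {
      stop("unknown gene in lr_pairs: ",
           paste(setdiff(c(lg, rg), colnames(counts)), collapse = ", "))
    }
    src <- which(true_region == lr_pairs$source_region[i])
    tgt <- which(true_region == lr_pairs$target_region[i])
    near3 <- function(spots) unique(unlist(lapply(spots, function(s)
      graph_neighbors(graph, s, ring = 3L, within = TRUE))))
    src_near <- intersect(src, near3(tgt))
    tgt_near <- intersect(tgt, near3(src))
    counts[src_near, lg] <- round(counts[src_near, lg] * 2^effect)
    counts[tgt_near, rg] <- round(counts[tgt_near, rg] * 2^effect)
  }
  counts
}

# Demo ligand-receptor table: the planted pair plus reference-count decoys.
sim_lr_table <- function(plan, cfg) {
  data.frame(
    ligand = c(plan$ligand, plan$gene_ids[50], plan$gene_ids[60],
               plan$gene_ids[70], plan$gene_ids[80]),
    receptor = c(plan$receptor, plan$gene_ids[55], plan$gene_ids[65],
                 plan$gene_ids[75], plan$gene_ids[85]),
    n_references = c(5L, 0L, 2L, 3L, 9L),
    source_region = club_region(cfg$k_true),
    target_region = immune_region(cfg$k_true),
    flagged = c(TRUE, FALSE, FALSE, FALSE, FALSE))
}

#' Simulate one Visium-like sample
#'
#' @param cfg a [sim_config()].
#' @param sample_id sample id.
#' @param category sample category.
#' @param seed sample-level RNG seed.
#' @return list with `sample` ([st_sample()]), `abundance`
#'   ([abundance_matrix()]), `true_region`, `graph`, and `plan`.
#' @export
simulate_sample <- function(cfg, sample_id, category, seed) {
  coords <- generate_hex_lattice(cfg$lattice_rows, cfg$lattice_cols)
  field <- generate_region_field(coords, cfg$k_true,
                                 cfg$spatial_patch_scale, seed = seed)
  ab <- generate_abundance(field, cfg, sample_id = sample_id,
                           seed = seed + 1L)
  gc <- generate_counts(field, cfg, category = category, seed = seed + 2L)
  graph <- build_hex_graph(coords, n_rings = 3L)
  lr <- sim_lr_table(gc$plan, cfg)
  counts <- plant_lr_coexpression(gc$counts, field, lr,
                                  cfg$lr_interface_effect, graph)
  s <- st_sample(sample_id = sample_id, category = category,
                 counts = counts, gene_ids = gc$gene_ids,
                 spot_ids = ab$spot_ids, array_coords = coords)
  list(sample = s, abundance = ab, true_region = field, graph = graph,
       plan = gc$plan)
}

#' Simulate a multi-sample cohort with ground truth
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_cohort` with elements `cohort`
#'   ([st_cohort()]), `abundance` (cohort-level [abundance_matrix()]),
#'   `truth` (per-spot region labels, planted markers, gene sets, LR
#'   table), and `config`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  cats <- rep(names(cfg$n_samples), times = cfg$n_samples)
  samples <- vector("list", length(cats))
  fields <- vector("list", length(cats))
  abunds <- vector("list", length(cats))
  plan <- NULL
  for (i in seq_along(cats)) {
    sid <- sprintf("%s_%02d", cats[i], sum(cats[seq_len(i)] == cats[i]))
    sim <- simulate_sample(cfg, sid, cats[i],
                           seed = cfg$seed + 7919L * i)
    samples[[i]] <- sim$sample
    fields[[i]] <- sim$true_region
    abunds[[i]] <- sim$abundance
    plan <- sim$plan
  }
  ab_all <- abundance_matrix(
    do.call(rbind, lapply(abunds, function(a) a$values)),
    state_names = abunds[[1]]$state_names,
    spot_ids = unlist(lapply(abunds, function(a) a$spot_ids)),
    sample_ids = unlist(lapply(seq_along(abunds), function(i)
      abunds[[i]]$sample_ids)))
  gene_sets <- list(AR_like = plan$ar_like,
                    club_like = plan$markers[[club_region(cfg$k_true)]],
                    planted_signature = plan$signature)
  truth <- list(true_region = stats::setNames(unlist(fields),
                                              ab_all$spot_ids),
                markers = plan$markers,
                club_region = club_region(cfg$k_true),
                immune_region = immune_region(cfg$k_true),
                gene_sets = gene_sets,
                lr_table = sim_lr_table(plan, cfg),
                plan = plan)
  structure(list(cohort = st_cohort(samples), abundance = ab_all,
                 truth = truth, config = cfg),
            class = "sim_cohort")
}

#' Write a simulated cohort in the on-disk layout the readers expect
#'
#' One sub-directory per sample with MTX + barcodes/features + positions
#' CSV, a cohort-level abundance TSV, ground-truth region TSV, gene sets in
#' GMT format, and the ligand-receptor table CSV.
#'
#' @param sim a `sim_cohort` from [simulate_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in sim$cohort$samples) {
    write_spot_matrix(s, file.path(dir, s$sample_id))
  }
  ab <- as.data.frame(sim$abundance$values)
  ab <- cbind(ab, sample_id = sim$abundance$sample_ids)
  utils::write.table(ab, file.path(dir, "abundance.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  truth <- data.frame(spot_id = names(sim$truth$true_region),
                      true_region = sim$truth$true_region)
  utils::write.table(truth, file.path(dir, "true_regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gmt <- vapply(names(sim$truth$gene_sets), function(nm)
    paste(c(nm, "synthetic", sim$truth$gene_sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(gmt, file.path(dir, "gene_sets.gmt"))
  utils::write.csv(sim$truth$lr_table[, c("ligand", "receptor",
                                          "n_references")],
                   file.path(dir, "lr_pairs.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
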