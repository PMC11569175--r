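# Shared fixtures, built in code and cached for the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small 4-sample cohort (two categories) used by several modules.
small_sim <- function() {
  cached("small_sim", {
    cfg <- sim_config(n_samples = c(TRNA = 2L, NEADT = 2L),
                      lattice_rows = 16L, lattice_cols = 16L,
                      n_genes = 300L, seed = 11L)
    simulate_cohort(cfg)
  })
}

# The same cohort, filtered and normalized.
small_sim_norm <- function() {
  cached("small_sim_norm", {
    sim <- small_sim()
    samples <- lapply(sim$cohort$samples, function(s)
      normalize_log(filter_sample(s)))
    st_cohort(samples)
  })
}

# Region assignment data.frame built from simulation ground truth.
truth_assignment <- function(sim, cohort = sim$cohort) {
  spot_ids <- unlist(lapply(cohort$samples, `[[`, "spot_ids"),
                     use.names = FALSE)
  sample_ids <- unlist(lapply(cohort$samples, function(s)
    rep(s$sample_id, length(s$spot_ids))), use.names = FALSE)
  out <- data.frame(spot_id = spot_ids, sample_id = sample_ids,
                    region = unname(sim$truth$true_region[spot_ids]))
  attr(out, "k") <- sim$config$k_true
  out
}

# Minimal normalized st_sample from a dense count matrix.
toy_sample <- function(counts, sample_id = "toy", category = "TRNA",
                       normalize = TRUE) {
  n <- nrow(counts)
  lattice <- generate_hex_lattice(n, 1)
  s <- st_sample(sample_id, category, counts,
                 gene_ids = colnames(counts) %||%
                   paste0("g", seq_len(ncol(counts))),
                 spot_ids = rownames(counts) %||%
                   paste0("s", seq_len(n)),
                 array_coords = lattice[seq_len(n), ])
  if (normalize) normalize_log(s) else s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent BFS shortest-path oracle on the ring-1 hex graph.
bfs_distance <- function(coords, from) {
  g1 <- build_hex_graph(coords, n_rings = 1L)
  d <- rep(NA_integer_, nrow(coords))
  d[from] <- 0L
  frontier <- from
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      nb <- g1$neighbors[[u]]$index
      new <- nb[is.na(d[nb])]
      d[new] <- d[u] + 1L
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  d
}

# Brute-force re-implementation of the proximity/interface rules, written
# directly from their definitions over the full pairwise distance matrix.
brute_proximity <- function(coords, labels, focal, rule = "pair") {
  n <- nrow(coords)
  D <- outer(seq_len(n), seq_len(n),
             function(i, j) hex_distance(coords, i, j))
  anchored <- which(labels == focal &
                      sapply(seq_len(n), function(i)
                        any(labels[D[i, ] == 1] == focal)))
  status <- ifelse(labels == focal, "focal-sporadic", "distant")
  status[anchored] <- "focal-anchored"
  for (q in which(labels != focal)) {
    near <- intersect(which(D[q, ] <= 3 & seq_len(n) != q), anchored)
    ok <- FALSE
    if (rule == "pair") {
      if (length(near) >= 2) {
        for (u in near) for (v in near) {
          if (u < v && D[u, v] == 1) ok <- TRUE
        }
      }
    } else ok <- length(near) >= 2
    if (ok) status[q] <- "proximal"
  }
  status
}

brute_interface <- function(coords, labels, f, g, min_partner = 2) {
  n <- nrow(coords)
  D <- outer(seq_len(n), seq_len(n),
             function(i, j) hex_distance(coords, i, j))
  side <- function(a, b) {
    which(sapply(seq_len(n), function(i) {
      labels[i] == a &&
        any(labels[D[i, ] == 1] == a) &&
        sum(labels[D[i, ] <= 3 & seq_len(n) != i] == b) >= min_partner
    }))
  }
  list(f_spots = side(f, g), g_spots = side(g, f))
}

# Abundance built from k_patterns one-hot state patterns plus tiny noise on
# the active states only (exactly k_patterns states are active).
one_hot_abundance <- function(n_spots = 800, k_patterns = 8,
                              k_states = 26, noise = 1e-3, seed = 21) {
  set.seed(seed)
  pat <- rep(seq_len(k_patterns), length.out = n_spots)
  vals <- matrix(0, n_spots, k_states)
  vals[, seq_len(k_patterns)] <-
    noise * stats::runif(n_spots * k_patterns)
  vals[cbind(seq_len(n_spots), pat)] <- 1
  abundance_matrix(vals, state_names = paste0("state", seq_len(k_states)),
                   spot_ids = paste0("s", seq_len(n_spots)),
                   sample_ids = "one")
}

# The reference study-scale cohort: 12 samples, 30 x 30 lattice, 8 latent
# regions over 26 states, seed 7 — with its fitted region model.
acc_sim <- function() {
  cached("acc_sim", {
    sim <- simulate_cohort(sim_config(seed = 7L))
    model <- select_k_by_uniqueness(sim$abundance, 5, 12, seed = 7L)
    list(sim = sim, model = model, assignment = assign_regions(model))
  })
}

# One normalized simulated sample with a planted LR interaction and the
# truth-derived interface between the club-like and immune-like regions;
# seeds are scanned deterministically for a region field in which the two
# planted regions actually share an interface.
lr_fixture <- function() {
  cached("lr_fixture", {
    for (seed in 23:40) {
      cfg <- sim_config(n_samples = c(TRNA = 1L), lattice_rows = 20L,
                        lattice_cols = 20L, seed = seed)
      sim <- simulate_cohort(cfg)
      s <- normalize_log(filter_sample(sim$cohort$samples[[1]]))
      lab <- unname(sim$truth$true_region[s$spot_ids])
      g <- build_hex_graph(s$array_coords, n_rings = 3L)
      itf <- annotate_interface(lab, g, sim$truth$club_region,
                                sim$truth$immune_region)
      if (itf$exists) break
    }
    stopifnot(itf$exists)
    list(sim = sim, s = s, lab = lab, graph = g, itf = itf)
  })
}
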