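# End-to-end orchestration: simulate (or read) -> QC/normalize -> regions
# -> markers -> graph/interfaces -> signature scores -> ligand-receptor,
# with a JSON run manifest and deterministic table outputs.

#' Pipeline configuration
#'
#' Collects every stage parameter with its standard default (k range 5-12,
#' minimum region size 10, 3 rings, 1000 permutations, control size 50,
#' 25 bins, expression threshold 0.01, minimum 3 literature references,
#' alpha 0.05, log2 fold-change floor 1) plus the simulation configuration
#' and the global seed.
#'
#' @param sim a [sim_config()] used when the run simulates its input.
#' @param input_dir optional directory in [write_cohort()] layout to read
#'   instead of simulating.
#' @param k_min,k_max NMF component range.
#' @param min_region_size region size floor for DE.
#' @param rings neighborhood graph radius.
#' @param n_perms permutations for neighborhood enrichment and LR tests.
#' @param ctrl_size,n_bins gene-set scoring parameters.
#' @param lr_threshold expression-fraction gate for LR tests.
#' @param min_refs literature-reference floor for LR pairs.
#' @param alpha significance threshold used throughout.
#' @param log2fc_min DE fold-change floor (log2).
#' @param min_umis,min_spots_per_gene QC filters.
#' @param seed global seed; stage seeds are derived at fixed offsets.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL,
                            k_min = 5L, k_max = 12L,
                            min_region_size = 10L, rings = 3L,
                            n_perms = 1000L, ctrl_size = 50L,
                            n_bins = 25L, lr_threshold = 0.01,
                            min_refs = 3L, alpha = 0.05, log2fc_min = 1,
                            min_umis = 500, min_spots_per_gene = 5,
                            seed = 1L) {
  structure(list(sim = sim, input_dir = input_dir, k_min = k_min,
                 k_max = k_max, min_region_size = min_region_size,
                 rings = rings, n_perms = n_perms, ctrl_size = ctrl_size,
                 n_bins = n_bins, lr_threshold = lr_threshold,
                 min_refs = min_refs, alpha = alpha,
                 log2fc_min = log2fc_min, min_umis = min_umis,
                 min_spots_per_gene = min_spots_per_gene,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(unclass(config)[setdiff(names(config),
                                             "input_dir")]), f)
  unname(tools::md5sum(f))
}

write_stage_table <- function(tab, path, seed, hash) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d params_md5=%s", seed, hash), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full pipeline
#'
#' Executes the seven stages (simulate, preprocess, call_regions, markers,
#' interfaces, score, lr) on a simulated or on-disk cohort, writes every
#' stage table as TSV (with the seed and a parameter hash in a comment
#' header) plus `manifest.json` under `out_dir`, and returns all results.
#' Reruns with the same configuration and seed produce byte-identical
#' deterministic tables.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with the cohort, model, assignment, marker,
#'   interface, score and LR results plus the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  seed <- config$seed
  wt <- function(tab, name) {
    write_stage_table(tab, file.path(out_dir, name), seed, hash)
  }
  manifest <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest[[length(manifest) + 1L]] <<-
      list(stage = name, seconds = round(proc.time()[["elapsed"]] - t0, 2))
    val
  }

  sim <- stage("simulate", {
    if (is.null(config$input_dir)) simulate_cohort(config$sim)
    else read_cohort_dir(config$input_dir)
  })

  prep <- stage("preprocess", {
    samples <- lapply(sim$cohort$samples, function(s)
      normalize_log(filter_sample(s, config$min_umis,
                                  config$min_spots_per_gene)))
    keep <- unlist(lapply(samples, `[[`, "spot_ids"))
    idx <- match(keep, sim$abundance$spot_ids)
    ab <- abundance_matrix(sim$abundance$values[idx, , drop = FALSE],
                           state_names = sim$abundance$state_names,
                           spot_ids = keep,
                           sample_ids = sim$abundance$sample_ids[idx])
    list(cohort = st_cohort(samples), abundance = ab)
  })

  regions <- stage("call_regions", {
    model <- select_k_by_uniqueness(prep$abundance, config$k_min,
                                    config$k_max, seed = seed + 1L)
    assignment <- assign_regions(model)
    fractions <- region_fractions(assignment)
    cats <- vapply(prep$cohort$samples, `[[`, character(1), "category")
    tests <- tryCatch(compare_fractions(fractions, cats),
                      warning = function(w) suppressWarnings(
                        compare_fractions(fractions, cats)))
    wt(assignment, "regions.tsv")
    wt(data.frame(k = model$k_range_tried,
                  unique_top_states = model$uniqueness_flags,
                  iterations = model$trace$iterations),
       "selection_trace.tsv")
    wt(data.frame(sample_id = rownames(fractions), fractions,
                  row.names = NULL), "fractions.tsv")
    wt(tests, "fraction_tests.tsv")
    list(model = model, assignment = assignment, fractions = fractions,
         tests = tests)
  })
  model <- regions$model
  assignment <- regions$assignment
  # component whose top state is the simulation's club-like dominant state
  focal <- which(model$top_state_per_component ==
                   sim$truth$club_region)[1]
  if (is.na(focal)) focal <- 1L

  markers <- stage("markers", {
    de <- do.call(rbind, lapply(prep$cohort$samples, function(s)
      per_sample_de(s, assignment, config$min_region_size,
                    alpha = config$alpha,
                    log2fc_min = config$log2fc_min)))
    mk <- region_specific_markers(de, alpha = config$alpha)
    gde <- group_de(prep$cohort, assignment, focal,
                    min_spots = config$min_region_size,
                    alpha = config$alpha, log2fc_min = config$log2fc_min)
    ov <- marker_set_overrepresentation(mk, sim$truth$gene_sets)
    wt(de, "de.tsv"); wt(mk, "markers.tsv")
    if (nrow(gde)) wt(gde, "group_de.tsv")
    wt(ov, "marker_set_overrepresentation.tsv")
    list(de = de, markers = mk, group_de = gde, overrep = ov)
  })

  interfaces <- stage("interfaces", {
    graphs <- list(); z_list <- list(); present <- list()
    prox <- list()
    for (i in seq_along(prep$cohort$samples)) {
      s <- prep$cohort$samples[[i]]
      g <- build_hex_graph(s$array_coords, n_rings = config$rings)
      lab <- assignment_for_sample(assignment, s)
      graphs[[s$sample_id]] <- g
      z_list[[s$sample_id]] <-
        neighborhood_enrichment(lab, g, k = model$k,
                                n_perms = config$n_perms,
                                seed = seed + 100L + i)
      present[[s$sample_id]] <- sort(unique(lab[lab >= 1L]))
      prox[[s$sample_id]] <-
        annotate_proximity(lab, g, focal,
                           min_focal_spots = config$min_region_size)
    }
    zmean <- cohort_enrichment(z_list, present)
    wt(data.frame(region = rownames(zmean), zmean, row.names = NULL),
       "enrichment_mean.tsv")
    ptab <- do.call(rbind, lapply(names(prox), function(sid) {
      p <- prox[[sid]]
      if (p$excluded) return(NULL)
      data.frame(sample_id = sid,
                 spot_id = prep$cohort$samples[[sid]]$spot_ids,
                 status = p$status)
    }))
    wt(ptab, "proximity.tsv")
    list(graphs = graphs, z_list = z_list, zmean = zmean, prox = prox)
  })

  scores <- stage("score", {
    set_names <- names(sim$truth$gene_sets)
    rows <- list(); tests <- list()
    for (s in prep$cohort$samples) {
      lab <- assignment_for_sample(assignment, s)
      for (nm in set_names) {
        sc <- score_gene_set(s, sim$truth$gene_sets[[nm]],
                             ctrl_size = config$ctrl_size,
                             n_bins = config$n_bins, seed = seed + 200L)
        rows[[length(rows) + 1L]] <-
          data.frame(sample_id = s$sample_id, set = nm,
                     spot_id = s$spot_ids, score = as.numeric(sc))
        if (sum(lab == focal) >= 2 && sum(lab != focal) >= 2) {
          qt <- quantile_effect_test(sc[lab == focal], sc[lab != focal],
                                     alpha = config$alpha)
          tests[[length(tests) + 1L]] <-
            data.frame(sample_id = s$sample_id, set = nm,
                       mean_focal = qt$mean_focal,
                       mean_other = qt$mean_other, p = qt$p,
                       stars = qt$stars)
        }
      }
    }
    corr <- fraction_score_correlation(
      prep$cohort, assignment, focal,
      sim$truth$gene_sets$planted_signature,
      ctrl_size = config$ctrl_size, n_bins = config$n_bins,
      seed = seed + 201L)
    sc_tab <- do.call(rbind, rows)
    wt(sc_tab, "scores.tsv")
    wt(do.call(rbind, tests), "score_tests.tsv")
    wt(corr$per_sample, "fraction_score_correlation.tsv")
    list(scores = sc_tab, tests = do.call(rbind, tests), corr = corr)
  })

  lr <- stage("lr", {
    pairs <- filter_lr_pairs(sim$truth$lr_table, config$min_refs)
    res <- list()
    for (i in seq_along(prep$cohort$samples)) {
      s <- prep$cohort$samples[[i]]
      g <- interfaces$graphs[[s$sample_id]]
      lab <- assignment_for_sample(assignment, s)
      others <- setdiff(seq_len(model$k), focal)
      for (r in others) {
        itf <- annotate_interface(lab, g, focal, r,
                                  min_spots = config$min_region_size)
        if (!itf$exists) next
        nm <- paste0("focal|region", r)
        res[[length(res) + 1L]] <- lr_test_interface(
          s, itf$f_spots, itf$g_spots, pairs, interface = nm,
          direction = "focal->other", alpha = config$alpha,
          threshold = config$lr_threshold, n_perms = config$n_perms,
          seed = seed + 300L + 37L * i + r)
      }
    }
    res <- if (length(res)) do.call(rbind, res) else
      stop("no interface passed the spot-count floor")
    enr <- interface_enrichment(res)
    wt(res, "lr.tsv")
    wt(enr, "lr_enrichment.tsv")
    list(results = res, enrichment = enr)
  })

  manifest_obj <- list(package = "scmregions",
                       version = as.character(utils::packageVersion(
                         "scmregions")),
                       seed = seed, params_md5 = hash,
                       parameters = unclass(config)[!(names(config) %in%
                                                        c("sim"))],
                       sim = unclass(config$sim),
                       stages = manifest)
  jsonlite::write_json(manifest_obj, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(sim = sim, cohort = prep$cohort,
                 abundance = prep$abundance, model = model,
                 assignment = assignment, regions = regions,
                 markers = markers, interfaces = interfaces,
                 scores = scores, lr = lr, focal = focal,
                 manifest = manifest_obj))
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory with per-sample sub-directories plus
#'   `abundance.tsv`, `true_regions.tsv`, `gene_sets.gmt`, `lr_pairs.csv`.
#' @return list shaped like [simulate_cohort()] output (truth fields
#'   limited to what is on disk).
#' @export
read_cohort_dir <- function(dir) {
  subs <- list.dirs(dir, recursive = FALSE)
  samples <- lapply(subs, function(d) {
    sid <- basename(d)
    cat <- sub("_.*$", "", sid)
    if (!cat %in% st_categories) cat <- "OTHER"
    read_spot_matrix(file.path(d, "matrix.mtx"),
                     file.path(d, "barcodes.tsv"),
                     file.path(d, "features.tsv"),
                     file.path(d, "tissue_positions.csv"),
                     sample_id = sid, category = cat)
  })
  ab <- read_abundance(file.path(dir, "abundance.tsv"))
  truth <- list()
  tr_path <- file.path(dir, "true_regions.tsv")
  if (file.exists(tr_path)) {
    tr <- utils::read.table(tr_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    truth$true_region <- stats::setNames(tr$true_region, tr$spot_id)
  }
  gs_path <- file.path(dir, "gene_sets.gmt")
  if (file.exists(gs_path)) truth$gene_sets <- read_gene_sets(gs_path)
  lr_path <- file.path(dir, "lr_pairs.csv")
  if (file.exists(lr_path)) truth$lr_table <- read_lr_table(lr_path)
  list(cohort = st_cohort(samples), abundance = ab, truth = truth)
}
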