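# Reading, validation, QC filtering and normalization of spot-level data.

st_categories <- c("BPH", "TRNA", "NEADT", "CRPC", "MET", "OTHER")

#' Construct a spatial transcriptomics sample
#'
#' Container for one tissue section: raw UMI counts (spots x genes),
#' staggered hex array coordinates and metadata. Counts are stored sparse.
#'
#' @param sample_id sample identifier.
#' @param category sample category, one of BPH, TRNA, NEADT, CRPC, MET, OTHER.
#' @param counts nonnegative integer matrix or sparse Matrix, spots x genes.
#' @param gene_ids unique gene symbols (length = ncol(counts)).
#' @param spot_ids unique spot barcodes (length = nrow(counts)).
#' @param array_coords data.frame with `array_row`, `array_col` per spot.
#' @param in_tissue logical per spot; defaults to all TRUE.
#' @param norm_expr optional normalized log-scale matrix, same shape as counts.
#' @return object of class `st_sample`.
#' @export
st_sample <- function(sample_id, category, counts, gene_ids, spot_ids,
                      array_coords, in_tissue = NULL, norm_expr = NULL) {
  category <- match.arg(category, st_categories)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "dMatrix")
  if (is.null(in_tissue)) in_tissue <- rep(TRUE, nrow(counts))
  if (anyDuplicated(spot_ids)) stop("spot_ids must be unique")
  if (anyDuplicated(gene_ids)) {
    warning("duplicated gene symbols made unique by suffixing")
    gene_ids <- make.unique(gene_ids, sep = ".")
  }
  stopifnot(length(gene_ids) == ncol(counts),
            length(spot_ids) == nrow(counts),
            nrow(array_coords) == nrow(counts),
            length(in_tissue) == nrow(counts))
  if (any(counts@x < 0)) stop("counts must be nonnegative")
  if (any(counts@x != round(counts@x))) stop("counts must be integral")
  if (anyDuplicated(paste(array_coords$array_row, array_coords$array_col))) {
    stop("array_coords must be unique per spot")
  }
  if (!is.null(norm_expr)) {
    stopifnot(all(dim(norm_expr) == dim(counts)))
  }
  dimnames(counts) <- list(spot_ids, gene_ids)
  structure(list(sample_id = sample_id, category = category, counts = counts,
                 norm_expr = norm_expr, gene_ids = gene_ids,
                 spot_ids = spot_ids,
                 array_coords = as.data.frame(array_coords)[,
                   c("array_row", "array_col"), drop = FALSE],
                 in_tissue = in_tissue),
            class = "st_sample")
}

#' @method print st_sample
#' @export
print.st_sample <- function(x, ...) {
  cat("st_sample", x$sample_id, sprintf("[%s]", x$category), "-",
      nrow(x$counts), "spots x", ncol(x$counts), "genes",
      if (!is.null(x$norm_expr)) "(normalized)" else "(raw)", "\n")
  invisible(x)
}

#' Assemble a cohort from a list of samples
#'
#' @param samples list of [st_sample()] objects with unique sample ids.
#' @return object of class `st_cohort` (list with element `samples`).
#' @export
st_cohort <- function(samples) {
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) stop("sample ids must be unique")
  names(samples) <- ids
  structure(list(samples = samples), class = "st_cohort")
}

#' @method print st_cohort
#' @export
print.st_cohort <- function(x, ...) {
  cat("st_cohort:", length(x$samples), "samples (",
      paste(vapply(x$samples, function(s) s$category, character(1)),
            collapse = ", "), ")\n")
  invisible(x)
}

read_tsv_maybe_gz <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, quote = "", ...)
}

#' Read a 10x Visium style spot matrix from disk
#'
#' Expects the MatrixMarket triplet layout (matrix + barcodes + features)
#' plus a tissue-positions table mapping each barcode to its array
#' coordinates and in-tissue flag. Only in-tissue spots are retained and
#' the matrix is oriented spots x genes regardless of on-disk orientation.
#'
#' @param mtx_path path to the .mtx file.
#' @param barcodes_path path to barcodes.tsv (one barcode per line).
#' @param features_path path to features.tsv (gene symbol in last id column).
#' @param positions_path tissue positions CSV with columns barcode,
#'   in_tissue, array_row, array_col, px_row, px_col (header auto-detected).
#' @param sample_id,category sample metadata, see [st_sample()].
#' @return an [st_sample()] with in-tissue spots only.
#' @export
read_spot_matrix <- function(mtx_path, barcodes_path, features_path,
                             positions_path, sample_id,
                             category = "OTHER") {
  m <- Matrix::readMM(mtx_path)
  barcodes <- read_tsv_maybe_gz(barcodes_path)[[1]]
  feats <- read_tsv_maybe_gz(features_path)
  genes <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  if (nrow(m) == length(genes) && ncol(m) == length(barcodes)) {
    m <- Matrix::t(m)                       # genes x spots on disk (10x)
  } else if (!(nrow(m) == length(barcodes) && ncol(m) == length(genes))) {
    stop("format error: MTX dimensions ", nrow(m), "x", ncol(m),
         " do not match ", length(barcodes), " barcodes and ",
         length(genes), " features")
  }
  pos <- read_positions(positions_path)
  hit <- match(barcodes, pos$barcode)
  if (anyNA(hit)) {
    stop("missing-position error: barcode(s) absent from positions table: ",
         paste(utils::head(barcodes[is.na(hit)], 5L), collapse = ", "))
  }
  pos <- pos[hit, , drop = FALSE]
  keep <- pos$in_tissue != 0
  st_sample(sample_id = sample_id, category = category,
            counts = m[keep, , drop = FALSE], gene_ids = genes,
            spot_ids = barcodes[keep],
            array_coords = data.frame(array_row = pos$array_row[keep],
                                      array_col = pos$array_col[keep]),
            in_tissue = rep(TRUE, sum(keep)))
}

read_positions <- function(path) {
  cols <- c("barcode", "in_tissue", "array_row", "array_col",
            "px_row", "px_col")
  first <- readLines(path, n = 1L)
  has_header <- grepl("barcode", first, fixed = TRUE)
  pos <- utils::read.csv(path, header = has_header,
                         stringsAsFactors = FALSE)
  if (!has_header) names(pos) <- cols[seq_len(ncol(pos))]
  need <- c("barcode", "in_tissue", "array_row", "array_col")
  if (!all(need %in% names(pos))) {
    stop("format error: positions table lacks columns ",
         paste(setdiff(need, names(pos)), collapse = ", "))
  }
  pos
}

#' Apply spot and gene quality-control filters
#'
#' Genes present (nonzero) in fewer than `min_spots_per_gene` spots are
#' dropped, computed on the unfiltered matrix, and then spots with fewer
#' than `min_umis` total UMIs are dropped, in that order.
#'
#' @param s an [st_sample()] with raw counts.
#' @param min_umis minimum UMI total for a spot to be retained (default 500;
#'   spots with strictly fewer are discarded).
#' @param min_spots_per_gene minimum number of spots in which a gene must be
#'   detected (default 5; genes in strictly fewer are discarded).
#' @return filtered [st_sample()]; `norm_expr` is dropped if present.
#' @export
filter_sample <- function(s, min_umis = 500, min_spots_per_gene = 5) {
  stopifnot(inherits(s, "st_sample"))
  keep_gene <- Matrix::colSums(s$counts > 0) >= min_spots_per_gene
  counts <- s$counts[, keep_gene, drop = FALSE]
  keep_spot <- Matrix::rowSums(counts) >= min_umis
  if (!any(keep_spot)) stop("empty-sample error: all spots removed by filter")
  st_sample(sample_id = s$sample_id, category = s$category,
            counts = counts[keep_spot, , drop = FALSE],
            gene_ids = s$gene_ids[keep_gene],
            spot_ids = s$spot_ids[keep_spot],
            array_coords = s$array_coords[keep_spot, , drop = FALSE],
            in_tissue = s$in_tissue[keep_spot])
}

#' Median-library-size normalization with log1p transform
#'
#' Each spot's counts are scaled so its total equals the median spot total
#' of the sample, then log1p-transformed. Deterministic; preserves the zero
#' pattern of the counts.
#'
#' @param s a filtered [st_sample()].
#' @return the sample with `norm_expr` set (dense matrix, spots x genes).
#' @export
normalize_log <- function(s) {
  stopifnot(inherits(s, "st_sample"))
  totals <- Matrix::rowSums(s$counts)
  if (any(totals == 0)) stop("empty-sample error: spot with zero counts")
  target <- stats::median(totals)
  scaled <- as.matrix(s$counts) * (target / totals)
  s$norm_expr <- log1p(scaled)
  dimnames(s$norm_expr) <- dimnames(s$counts)
  s
}

#' Identify mitochondrial and ribosomal genes by symbol
#'
#' @param gene_ids character vector of gene symbols.
#' @param pattern regex for excluded genes; default matches MT-, RPL, RPS
#'   prefixes (case-sensitive).
#' @return logical vector.
#' @export
is_mito_ribo <- function(gene_ids, pattern = "^(MT-|RPL|RPS)") {
  grepl(pattern, gene_ids)
}

#' Construct a spots-by-cell-states abundance matrix
#'
#' @param values nonnegative numeric matrix, spots x cell states.
#' @param state_names unique cell-state names.
#' @param spot_ids spot barcodes (one per row).
#' @param sample_ids sample id per row (scalar recycled).
#' @return object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, state_names = colnames(values),
                             spot_ids = rownames(values),
                             sample_ids = "sample") {
  values <- as.matrix(values)
  if (is.null(state_names)) state_names <- paste0("state", seq_len(ncol(values)))
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(nrow(values)))
  if (length(sample_ids) == 1L) sample_ids <- rep(sample_ids, nrow(values))
  if (any(values < 0)) stop("validation error: negative abundance value")
  if (any(rowSums(values) == 0)) stop("validation error: all-zero spot row")
  stopifnot(length(state_names) == ncol(values),
            length(spot_ids) == nrow(values),
            length(sample_ids) == nrow(values),
            !anyDuplicated(state_names))
  dimnames(values) <- list(spot_ids, state_names)
  structure(list(values = values, state_names = state_names,
                 spot_ids = spot_ids, sample_ids = sample_ids),
            class = "abundance_matrix")
}

#' @method print abundance_matrix
#' @export
print.abundance_matrix <- function(x, ...) {
  cat("abundance_matrix:", nrow(x$values), "spots x", ncol(x$values),
      "cell states,", length(unique(x$sample_ids)), "sample(s)\n")
  invisible(x)
}

#' Read a per-spot cell-state abundance table
#'
#' Tab-separated, header row of state names, first column spot barcodes;
#' an optional `sample_id` column is used to carry per-row sample ids.
#'
#' @param path TSV path.
#' @return an [abundance_matrix()].
#' @export
read_abundance <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  sample_ids <- "sample"
  if ("sample_id" %in% names(tab)) {
    sample_ids <- tab$sample_id
    tab$sample_id <- NULL
  }
  abundance_matrix(as.matrix(tab), state_names = colnames(tab),
                   spot_ids = rownames(tab), sample_ids = sample_ids)
}

#' Read gene sets from a GMT-like file
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path file path.
#' @return named list of character vectors (unique genes per set).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("format error: GMT line with fewer than 3 fields")
    unique(f[-c(1, 2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' Read a ligand-receptor pair table
#'
#' CSV with three columns: ligand gene, receptor gene, number of literature
#' references (header optional, auto-detected).
#'
#' @param path file path.
#' @return data.frame with columns `ligand`, `receptor`, `n_references`.
#' @export
read_lr_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("ligand", tolower(first), fixed = TRUE)
  tab <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) names(tab) <- c("ligand", "receptor", "n_references")
  tab <- tab[, c("ligand", "receptor", "n_references")]
  if (any(tab$n_references < 0)) stop("validation error: negative n_references")
  if (anyDuplicated(tab[, c("ligand", "receptor")])) {
    stop("validation error: duplicate ligand-receptor pair")
  }
  tab
}

#' Write a sample's counts in the 10x Visium on-disk layout
#'
#' Produces matrix.mtx (genes x spots), barcodes.tsv, features.tsv and
#' tissue_positions.csv under `dir`, readable by [read_spot_matrix()].
#'
#' @param s an [st_sample()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_spot_matrix <- function(s, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(s$counts), file.path(dir, "matrix.mtx"))
  writeLines(s$spot_ids, file.path(dir, "barcodes.tsv"))
  writeLines(paste(s$gene_ids, s$gene_ids, "Gene Expression", sep = "\t"),
             file.path(dir, "features.tsv"))
  pos <- data.frame(barcode = s$spot_ids,
                    in_tissue = as.integer(s$in_tissue),
                    array_row = s$array_coords$array_row,
                    array_col = s$array_coords$array_col,
                    px_row = s$array_coords$array_row * 100L,
                    px_col = s$array_coords$array_col * 100L)
  utils::write.csv(pos, file.path(dir, "tissue_positions.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
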