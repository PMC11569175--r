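#' Generate a staggered hexagonal spot lattice
#'
#' Produces integer array coordinates following the 10x Visium convention:
#' spots live at (row, col) with `row + col` even, so that column parity
#' matches row parity and each interior spot has exactly six neighbours at
#' hex distance 1 (about 100 um centre-to-centre on a real slide).
#'
#' @param rows number of array rows (>= 1).
#' @param cols number of spots per row (>= 1).
#' @return data.frame with integer columns `array_row`, `array_col`.
#' @export
generate_hex_lattice <- function(rows, cols) {
  stopifnot(rows >= 1, cols >= 1)
  r <- rep(seq_len(rows) - 1L, each = cols)
  c0 <- rep(seq_len(cols) - 1L, times = rows)
  data.frame(array_row = r, array_col = 2L * c0 + (r %% 2L))
}

#' Hexagonal ring distance between spots
#'
#' Staggered (row, col) coordinates are mapped to axial coordinates
#' `q = (col - row) / 2`, `r = row` (integer because valid Visium spots have
#' `row + col` even); the distance is the standard axial hex metric
#' `(|dq| + |dr| + |dq + dr|) / 2`, which equals the shortest-path length on
#' the 6-neighbour lattice graph.
#'
#' @param coords data.frame with `array_row`, `array_col`.
#' @param i,j integer index vectors into `coords` (recycled pairwise).
#' @return integer vector of ring distances.
#' @export
hex_distance <- function(coords, i, j) {
  ax <- hex_axial(coords)
  dq <- ax$q[i] - ax$q[j]
  dr <- ax$r[i] - ax$r[j]
  as.integer((abs(dq) + abs(dr) + abs(dq + dr)) / 2)
}

hex_axial <- function(coords) {
  bad <- (coords$array_row + coords$array_col) %% 2L != 0L
  if (any(bad)) {
    stop("coordinate parity violation (row + col must be even) at spot(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  list(q = (coords$array_col - coords$array_row) %/% 2L, r = coords$array_row)
}

# Axial offsets for all lattice positions within ring distance n_rings,
# excluding the origin. Ring k holds exactly 6k offsets.
hex_ring_offsets <- function(n_rings) {
  qs <- -n_rings:n_rings
  grid <- expand.grid(q = qs, r = qs)
  d <- (abs(grid$q) + abs(grid$r) + abs(grid$q + grid$r)) / 2
  grid$d <- as.integer(d)
  grid[grid$d >= 1L & grid$d <= n_rings, , drop = FALSE]
}

#' Build a hexagonal neighbourhood graph
#'
#' For every spot, finds all other spots of the same sample within
#' `n_rings` ring distance (default 3, about 300 um). Lookup is by exact
#' lattice position, so missing spots (holes in the tissue) simply have
#' fewer neighbours; the graph metric is the ideal-lattice hex distance.
#'
#' @param coords data.frame with `array_row`, `array_col`; one row per spot.
#' @param n_rings maximum ring distance retained (>= 1).
#' @return object of class `hex_graph`: list with `n`, `n_rings`, `coords`,
#'   and `neighbors`, a list (one element per spot) of data.frames with
#'   columns `index` (neighbour spot index) and `ring` (its ring distance).
#' @export
build_hex_graph <- function(coords, n_rings = 3L) {
  stopifnot(n_rings >= 1L)
  ax <- hex_axial(coords)
  n <- length(ax$q)
  key <- paste(ax$q, ax$r)
  if (anyDuplicated(key)) stop("duplicate array coordinates")
  pos <- seq_len(n)
  names(pos) <- key
  off <- hex_ring_offsets(n_rings)
  neighbors <- vector("list", n)
  for (i in pos) {
    kk <- paste(ax$q[i] + off$q, ax$r[i] + off$r)
    hit <- !is.na(match(kk, names(pos)))
    neighbors[[i]] <- data.frame(index = unname(pos[kk[hit]]),
                                 ring = off$d[hit])
  }
  structure(list(n = n, n_rings = n_rings, coords = coords,
                 neighbors = neighbors),
            class = "hex_graph")
}

#' @method print hex_graph
#' @export
print.hex_graph <- function(x, ...) {
  cat("hex_graph:", x$n, "spots, rings <=", x$n_rings, "\n")
  invisible(x)
}

# Neighbour indices of spot i at ring distance exactly `ring` (or <= ring
# when `within = TRUE`).
graph_neighbors <- function(graph, i, ring, within = FALSE) {
  nb <- graph$neighbors[[i]]
  if (within) nb$index[nb$ring <= ring] else nb$index[nb$ring == ring]
}

# Undirected edge list (u < v) of all spot pairs at ring distance <= max_ring.
graph_edges <- function(graph, max_ring = graph$n_rings) {
  us <- integer(0); vs <- integer(0)
  for (i in seq_len(graph$n)) {
    nb <- graph$neighbors[[i]]
    v <- nb$index[nb$ring <= max_ring & nb$index > i]
    if (length(v)) { us <- c(us, rep.int(i, length(v))); vs <- c(vs, v) }
  }
  cbind(u = us, v = vs)
}
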