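# Small in-code fixtures shared across test files.

# A tiny grid layer with the cell at (row 4, col 4) centred on (0, 0),
# 0.4-degree cells: rook-neighbour centres are ~44.48 km away at the
# equator, diagonal neighbours ~62.9 km.
equator_grid <- function(n = 7, cell_size = 0.4, fill = 0) {
  half <- n / 2
  grid_layer(matrix(fill, n, n),
             origin_lon = -half * cell_size,
             origin_lat = half * cell_size,
             cell_size = cell_size)
}

# Binary range from a 0/1 matrix on the equatorial test grid.
range_from_matrix <- function(m, cell_size = 0.4) {
  n <- nrow(m)
  binary_range(grid_layer(m, origin_lon = -n / 2 * cell_size,
                          origin_lat = n / 2 * cell_size,
                          cell_size = cell_size))
}

# Random 0/1 range guaranteed non-empty.
random_range <- function(n = 8, p = 0.4, cell_size = 0.4) {
  m <- matrix(stats::rbinom(n * n, 1, p), n, n)
  if (sum(m) == 0) m[sample(n * n, 1)] <- 1
  range_from_matrix(m, cell_size)
}

# A small occurrence data frame.
occ_df <- function(taxon, type, lon, lat, id = NULL) {
  n <- max(length(taxon), length(type), length(lon), length(lat))
  data.frame(record_id = id %||% sprintf("r%03d", seq_len(n)),
             taxon = rep_len(taxon, n), type = rep_len(type, n),
             lon = rep_len(lon, n), lat = rep_len(lat, n),
             source = "test", stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force pairwise AUC oracle.
auc_naive <- function(pos, bg) {
  s <- 0
  for (p in pos) for (b in bg) s <- s + (p > b) + 0.5 * (p == b)
  s / (length(pos) * length(bg))
}

# Naive elementwise Schoener's D oracle.
schoener_naive <- function(p, q) {
  acc <- 0
  for (i in seq_along(p)) acc <- acc + abs(p[i] - q[i])
  1 - acc / 2
}

# Random normalised distribution pair on a shared support.
random_pq <- function(len = sample(5:50, 1)) {
  p <- stats::runif(len); q <- stats::runif(len)
  list(p = p / sum(p), q = q / sum(q))
}
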