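#' Normalise a pair of surfaces to probability distributions
#'
#' Niche-overlap statistics compare two occupancy distributions in
#' geographic space.  Both surfaces (continuous suitability or 0/1 ranges)
#' are restricted to their shared valid (non-missing) cells and each is
#' rescaled to sum to one over that common support; a binary range thus
#' becomes uniform over its presence cells.
#'
#' @param surfA,surfB aligned `grid_layer`s (suitability surfaces or
#'   binary ranges).
#' @return list with numeric vectors `p` and `q` (each summing to 1) and
#'   `cells`, the linear indices of the shared support.
#' @export
normalize_pair <- function(surfA, surfB) {
  stopifnot(is_grid_layer(surfA), is_grid_layer(surfB))
  check_aligned(surfA, surfB)
  a <- as.vector(surfA$values)
  b <- as.vector(surfB$values)
  shared <- !is.na(a) & !is.na(b)
  if (any(a[shared] < 0) || any(b[shared] < 0))
    stop_input("surfaces must be non-negative")
  sa <- sum(a[shared]); sb <- sum(b[shared])
  if (sa <= 0 || sb <= 0)
    stop_input("a surface has zero total mass over the shared cells")
  list(p = a[shared] / sa, q = b[shared] / sb, cells = which(shared))
}

check_normalized <- function(p, q) {
  if (length(p) != length(q))
    stop_input("p and q must share one cell index set")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6 ||
      any(p < 0) || any(q < 0))
    stop_input("p and q must be normalised distributions (see normalize_pair)")
  invisible(TRUE)
}

#' Schoener's D
#'
#' `D = 1 - 0.5 * sum(|p - q|)`: one minus the total variation distance
#' between two occupancy distributions.  0 means no niche overlap, 1
#' complete overlap.
#'
#' @param p,q normalised distributions over a common support.
#' @return D in \[0, 1\].
#' @export
schoener_d <- function(p, q) {
  check_normalized(p, q)
  clamp(1 - 0.5 * sum(abs(p - q)), 0, 1)
}

#' Hellinger-based overlap I
#'
#' `I = 1 - 0.5 * sum((sqrt(p) - sqrt(q))^2)`, i.e. one minus half the
#' squared Hellinger distance; algebraically identical to the Bhattacharyya
#' coefficient `sum(sqrt(p * q))`.  Always at least as large as Schoener's
#' D for the same pair.
#'
#' @inheritParams schoener_d
#' @return I in \[0, 1\].
#' @export
hellinger_i <- function(p, q) {
  check_normalized(p, q)
  clamp(1 - 0.5 * sum((sqrt(p) - sqrt(q))^2), 0, 1)
}

#' Range overlap for one taxon pair
#'
#' Shared-cell statistics between two presence/absence ranges: the Sørensen
#' fraction `2|A∩B| / (|A| + |B|)`, the overlap relative to the larger
#' range `|A∩B| / max(|A|, |B|)` and to the smaller range
#' `|A∩B| / min(|A|, |B|)`.  A pair is sympatric when it shares at least
#' `sympatry_cells` cells at the analysis resolution.
#'
#' @param rangeA,rangeB aligned non-empty `binary_range`s.
#' @param sympatry_cells minimum shared cells for a sympatry call (default 1).
#' @return list: `shared_cells`, `sorensen`, `frac_larger`, `frac_smaller`,
#'   `sympatric`.
#' @export
range_overlap <- function(rangeA, rangeB, sympatry_cells = 1) {
  stopifnot(is_binary_range(rangeA), is_binary_range(rangeB))
  check_aligned(rangeA, rangeB)
  nA <- rangeA$cell_count; nB <- rangeB$cell_count
  if (nA == 0 || nB == 0)
    stop_input("range overlap needs two non-empty ranges")
  shared <- sum((!is.na(rangeA$values) & rangeA$values == 1) &
                (!is.na(rangeB$values) & rangeB$values == 1))
  list(shared_cells = shared,
       sorensen = 2 * shared / (nA + nB),
       frac_larger = shared / max(nA, nB),
       frac_smaller = shared / min(nA, nB),
       sympatric = shared >= sympatry_cells)
}

#' All pairwise overlaps
#'
#' Computes range and niche overlap for every unordered taxon pair, in
#' lexicographic order, yielding exactly `n(n-1)/2` rows.  Niche statistics
#' use the supplied occupancy `surfaces` when given (continuous suitability
#' where a model was valid, uniform-over-range otherwise); when `surfaces`
#' is `NULL` the binary ranges themselves are normalised.
#'
#' @param ranges named list of aligned `binary_range`s (unique names).
#' @param surfaces optional named list of `grid_layer`s, same names.
#' @param sympatry_cells passed to [range_overlap()].
#' @return data frame with one row per pair: `taxonA`, `taxonB`, `D`, `I`,
#'   `shared_cells`, `sorensen`, `frac_larger`, `frac_smaller`, `sympatric`.
#' @export
pairwise_overlap <- function(ranges, surfaces = NULL, sympatry_cells = 1) {
  nm <- names(ranges)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop_input("`ranges` must carry unique taxon names")
  if (length(ranges) < 2L)
    stop_input("need at least two taxa for pairwise comparison")
  nm <- sort(nm)
  if (!is.null(surfaces) && !all(nm %in% names(surfaces)))
    stop_input("`surfaces` must cover every taxon in `ranges`")
  occ <- if (is.null(surfaces)) ranges else surfaces
  pairs <- utils::combn(nm, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    ro <- range_overlap(ranges[[a]], ranges[[b]],
                        sympatry_cells = sympatry_cells)
    pq <- normalize_pair(occ[[a]], occ[[b]])
    data.frame(taxonA = a, taxonB = b,
               D = schoener_d(pq$p, pq$q), I = hellinger_i(pq$p, pq$q),
               shared_cells = ro$shared_cells, sorensen = ro$sorensen,
               frac_larger = ro$frac_larger, frac_smaller = ro$frac_smaller,
               sympatric = ro$sympatric, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohort summary of niche overlap
#'
#' Summarises overlap results per cohort in the shape of the niche-occupancy
#' table: percent of pairs with (near-)perfect overlap, percent with D or I
#' above 0.5, and percent with D or I below 0.2 (divergent niche).
#' "Perfect" is `max(D, I) >= 1 - perfect_tol`; printed tables rarely define
#' it, so the rule used is recorded in attribute `perfect_rule`.
#'
#' @param results data frame from [pairwise_overlap()].
#' @param cohorts named list of logical vectors (or row indices) selecting
#'   the pairs of each cohort; default a single `all` cohort.
#' @param perfect_tol tolerance below 1 still counted perfect.
#' @return data frame: `cohort`, `n`, `perfect_pct`, `high_pct`
#'   (D or I > 0.5), `divergent_pct` (D or I < 0.2).  Empty cohorts give
#'   `NA` with a warning.
#' @export
overlap_summary <- function(results, cohorts = list(all = TRUE),
                            perfect_tol = 1e-6) {
  stopifnot(is.data.frame(results))
  out <- lapply(names(cohorts), function(label) {
    r <- results[cohorts[[label]], , drop = FALSE]
    if (nrow(r) == 0L) {
      warning("cohort '", label, "' is empty")
      return(data.frame(cohort = label, n = 0L, perfect_pct = NA_real_,
                        high_pct = NA_real_, divergent_pct = NA_real_))
    }
    hi <- pmax(r$D, r$I)
    lo <- pmin(r$D, r$I)
    data.frame(cohort = label, n = nrow(r),
               perfect_pct = 100 * mean(hi >= 1 - perfect_tol),
               high_pct = 100 * mean(hi > 0.5),
               divergent_pct = 100 * mean(lo < 0.2),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "perfect_rule") <-
    sprintf("max(D, I) >= 1 - %g", perfect_tol)
  res
}

#' Range-overlap asymmetry
#'
#' Mean excess, over sympatric pairs, of the overlap fraction seen by the
#' smaller range relative to the larger one, in percentage points.
#'
#' @param results data frame from [pairwise_overlap()].
#' @return percentage points; `NA` with a warning when no pair is sympatric.
#' @export
asymmetry_stat <- function(results) {
  s <- results[results$sympatric, , drop = FALSE]
  if (nrow(s) == 0L) {
    warning("no sympatric pairs: asymmetry undefined")
    return(NA_real_)
  }
  100 * mean(s$frac_smaller - s$frac_larger)
}

#' Central niche range of a variable
#'
#' The interval covering the middle `coverage` share of occurrence-point
#' values (default the middle 90%, i.e. the 5th to 95th percentile),
#' computed with linear interpolation between order statistics.
#'
#' @param values numeric vector of per-occurrence extractions (>= 2 finite).
#' @param coverage central mass to cover, default 0.9.
#' @return named numeric vector `c(low, high)`.
#' @export
niche_range <- function(values, coverage = 0.9) {
  values <- values[is.finite(values)]
  if (length(values) < 2L)
    stop_input("need at least two finite values")
  tail_p <- (1 - coverage) / 2
  q <- stats::quantile(values, probs = c(tail_p, 1 - tail_p),
                       names = FALSE, type = 7)
  c(low = q[1L], high = q[2L])
}
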