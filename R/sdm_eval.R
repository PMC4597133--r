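#' k-fold split of presence points
#'
#' Deterministic seeded partition into `k` folds whose sizes differ by at
#' most one, for cross-validated evaluation of suitability surfaces.
#'
#' @param n number of points, or a vector whose length is used.
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return list of `k` integer index vectors partitioning `1:n`.
#' @export
kfold_split <- function(n, k = 5, seed = NULL) {
  if (length(n) > 1L) n <- length(n)
  n <- as.integer(n)
  if (n < k) stop_input("need at least k = ", k, " points, got ", n)
  perm <- with_seed(seed, sample.int(n))
  fold_of <- rep(seq_len(k), length.out = n)
  lapply(seq_len(k), function(i) sort(perm[fold_of == i]))
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the probability that a presence
#' score exceeds a background score, counting ties as one half:
#' `P(pos > bg) + 0.5 P(pos = bg)`.  Equivalent to the Mann-Whitney
#' statistic scaled to \[0, 1\].
#'
#' @param pos_scores suitability at presence (test) points.
#' @param bg_scores suitability at background points.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(pos_scores, bg_scores) {
  pos_scores <- pos_scores[!is.na(pos_scores)]
  bg_scores <- bg_scores[!is.na(bg_scores)]
  np <- length(pos_scores); nb <- length(bg_scores)
  if (np == 0L || nb == 0L)
    stop_input("both presence and background scores are required")
  r <- rank(c(pos_scores, bg_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Extract surface values at points
#'
#' Nearest-cell (containing-cell) lookup of one or more aligned layers at a
#' set of points.  Points outside the grid or on missing cells in any layer
#' are dropped; the number dropped is attached as attribute `n_dropped`.
#'
#' @param lon,lat point coordinates, degrees.
#' @param layers a `grid_layer` or named list of aligned `grid_layer`s.
#' @return numeric matrix, points x layers, with attribute `n_dropped`.
#' @export
extract_env <- function(lon, lat, layers) {
  if (is_grid_layer(layers)) layers <- list(value = layers)
  stopifnot(is.list(layers), length(layers) >= 1L)
  do.call(check_aligned, layers)
  rc <- point_cell(layers[[1L]], lon, lat)
  out <- sapply(layers, function(l) {
    v <- rep(NA_real_, nrow(rc))
    inside <- !is.na(rc[, "row"])
    v[inside] <- l$values[rc[inside, , drop = FALSE]]
    v
  })
  out <- matrix(out, nrow = nrow(rc),
                dimnames = list(NULL, names(layers)))
  keep <- stats::complete.cases(out)
  res <- out[keep, , drop = FALSE]
  if (nrow(res) == 0L)
    stop_input("all points fall outside the grid or on missing cells")
  attr(res, "n_dropped") <- sum(!keep)
  res
}

#' Validate a cross-validated suitability model
#'
#' Applies the three-condition accuracy rule for externally produced
#' suitability surfaces: (i) the five-fold average test AUC (ATAUC) must
#' exceed `atauc_min`; (ii) the standard deviation of the fold AUCs (STAUC,
#' sample SD) must be below `stauc_max`; (iii) the ASD15 stability
#' criterion on the across-fold per-cell standard deviation of the
#' predictions.  Two ASD15 readings are available: `"literal"` (default)
#' requires at least `asd_frac` of valid cells to have across-fold SD below
#' `asd_cut`; `"strict"` requires at most `asd_frac` of cells to have SD
#' above `asd_cut`.
#'
#' Either supply `fold_aucs` directly, or supply `fold_surfaces`,
#' `test_points` and `test_folds` (from [kfold_split()]) plus `bg_scores`
#' and the fold AUCs are computed here.
#'
#' @param fold_surfaces list of k aligned `grid_layer` suitability surfaces
#'   (one per fold); also used for the ASD15 statistic.
#' @param test_points two-column matrix/data frame of presence lon/lat.
#' @param test_folds list of index vectors into `test_points`.
#' @param bg_scores background scores: a numeric vector shared by folds or
#'   a list of k vectors.
#' @param fold_aucs optional precomputed fold AUCs (bypasses the above).
#' @param atauc_min,stauc_max,asd_cut,asd_frac rule constants.
#' @param asd_rule `"literal"` or `"strict"` (see Details).
#' @return a `model_metrics` list: `fold_aucs`, `ATAUC`, `STAUC`,
#'   `asd_low_fraction`, `valid`.
#' @export
validate_model <- function(fold_surfaces = NULL, test_points = NULL,
                           test_folds = NULL, bg_scores = NULL,
                           fold_aucs = NULL,
                           atauc_min = 0.7, stauc_max = 0.15,
                           asd_cut = 0.15, asd_frac = 0.10,
                           asd_rule = c("literal", "strict")) {
  asd_rule <- match.arg(asd_rule)
  if (is.null(fold_aucs)) {
    stopifnot(is.list(fold_surfaces), !is.null(test_folds),
              length(fold_surfaces) == length(test_folds))
    do.call(check_aligned, fold_surfaces)
    if (!is.list(bg_scores))
      bg_scores <- rep(list(bg_scores), length(fold_surfaces))
    test_points <- as.matrix(test_points)
    fold_aucs <- vapply(seq_along(fold_surfaces), function(i) {
      idx <- test_folds[[i]]
      pos <- extract_env(test_points[idx, 1L], test_points[idx, 2L],
                         fold_surfaces[[i]])[, 1L]
      auc(pos, bg_scores[[i]])
    }, numeric(1L))
  }
  if (any(fold_aucs < 0 | fold_aucs > 1))
    stop_input("fold AUCs must lie in [0, 1]")
  asd_low_fraction <- NA_real_
  if (!is.null(fold_surfaces) && length(fold_surfaces) > 1L) {
    do.call(check_aligned, fold_surfaces)
    stack <- sapply(fold_surfaces, function(s) as.vector(s$values))
    valid_cells <- stats::complete.cases(stack)
    if (any(valid_cells)) {
      sds <- apply(stack[valid_cells, , drop = FALSE], 1L, stats::sd)
      asd_low_fraction <- mean(sds < asd_cut)
    }
  }
  atauc <- mean(fold_aucs)
  stauc <- stats::sd(fold_aucs)
  asd_ok <- if (is.na(asd_low_fraction)) TRUE else if (asd_rule == "literal")
    asd_low_fraction >= asd_frac else (1 - asd_low_fraction) <= asd_frac
  structure(list(fold_aucs = fold_aucs, ATAUC = atauc, STAUC = stauc,
                 asd_low_fraction = asd_low_fraction,
                 valid = atauc > atauc_min && stauc < stauc_max && asd_ok),
            class = "model_metrics")
}

#' @export
print.model_metrics <- function(x, ...) {
  cat(sprintf("model metrics: ATAUC %.3f, STAUC %.3f, ASD15 low-SD fraction %s -> %s\n",
              x$ATAUC, x$STAUC,
              ifelse(is.na(x$asd_low_fraction), "NA",
                     sprintf("%.2f", x$asd_low_fraction)),
              if (x$valid) "valid" else "not valid"))
  invisible(x)
}

#' Taxon-independent ROC threshold
#'
#' Chooses the binarisation threshold that maximises sensitivity plus
#' specificity over the candidate set formed by the observed presence and
#' background scores.  A cell is deemed present when its value is greater
#' than or equal to the threshold; ties in the objective resolve to the
#' lowest candidate (the most inclusive distribution).
#'
#' @param surface a suitability `grid_layer`.
#' @param presence_points two-column lon/lat matrix or data frame.
#' @param bg_scores numeric background scores.
#' @return the threshold value.
#' @export
roc_threshold <- function(surface, presence_points, bg_scores) {
  presence_points <- as.matrix(presence_points)
  pos <- extract_env(presence_points[, 1L], presence_points[, 2L],
                     surface)[, 1L]
  bg_scores <- bg_scores[!is.na(bg_scores)]
  if (length(pos) == 0L)
    stop_input("no presence point falls on a valid cell")
  cand <- sort(unique(c(pos, bg_scores)))
  obj <- vapply(cand, function(t)
    mean(pos >= t) + mean(bg_scores < t), numeric(1L))
  cand[which.max(obj)]  # which.max returns the first (lowest) maximiser
}

#' Binarise a suitability surface
#'
#' @param surface suitability `grid_layer`.
#' @param threshold presence iff value >= threshold.
#' @return a `binary_range`.
#' @export
binarize_surface <- function(surface, threshold) {
  stopifnot(is_grid_layer(surface))
  out <- surface
  out$values <- (surface$values >= threshold) * 1
  binary_range(out)
}

#' Realised range: thresholded model or buffer fallback
#'
#' Implements the fallback rule for potential distributions: when the
#' suitability model passed validation, the range is the ROC-thresholded
#' surface; otherwise (model invalid, or no surface supplied) it is the
#' circular buffer of `radius_km` around the occurrence points.  The route
#' taken is recorded in attribute `provenance` (`"model"` or `"buffer"`).
#'
#' @param surface suitability `grid_layer`, or `NULL`.
#' @param metrics `model_metrics` for `surface` (ignored when no surface).
#' @param points two-column lon/lat matrix of occurrence points.
#' @param template `grid_layer` lattice for the buffer fallback.
#' @param threshold binarisation threshold (required with a valid model);
#'   typically from [roc_threshold()].
#' @param exclusion_mask optional `binary_range` of excluded land cover.
#' @param radius_km buffer radius, default 50.
#' @return a `binary_range` with attribute `provenance`.
#' @export
realized_range <- function(surface = NULL, metrics = NULL, points = NULL,
                           template = NULL, threshold = NULL,
                           exclusion_mask = NULL, radius_km = 50) {
  use_model <- !is.null(surface) && !is.null(metrics) && isTRUE(metrics$valid)
  if (use_model) {
    if (is.null(threshold))
      stop_input("a valid model needs a `threshold` to binarise")
    rng <- binarize_surface(surface, threshold)
    prov <- "model"
  } else {
    if (is.null(points) || nrow(as.matrix(points)) == 0L)
      stop_input("no surface and no coordinates: cannot build a range")
    if (is.null(template)) template <- surface
    if (is.null(template))
      stop_input("buffer fallback needs a `template` grid")
    points <- as.matrix(points)
    rng <- circular_buffer_range(points[, 1L], points[, 2L], template,
                                 radius_km = radius_km)
    prov <- "buffer"
  }
  if (!is.null(exclusion_mask)) rng <- apply_exclusion_mask(rng, exclusion_mask)
  attr(rng, "provenance") <- prov
  rng
}
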