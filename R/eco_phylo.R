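#' Principal component analysis of environmental extractions
#'
#' Thin wrapper around [stats::prcomp()] with the conventions used
#' throughout the package: variables standardised by default, variance
#' fractions reported (descending, summing to 1), and a deterministic sign
#' convention — the largest-magnitude loading of every component is made
#' positive, so results do not flip between platforms.
#'
#' @param mat numeric matrix, observations x variables (>= 2 of each).
#' @param standardize scale variables to unit variance (default `TRUE`).
#' @return list: `loadings` (variables x PCs), `scores`
#'   (observations x PCs), `variance_fractions`.
#' @export
env_pca <- function(mat, standardize = TRUE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop_input("PCA needs at least 2 observations and 2 variables")
  vars <- apply(mat, 2L, stats::var)
  if (standardize && any(vars == 0)) {
    bad <- colnames(mat)[vars == 0] %||% which(vars == 0)
    stop_input("zero-variance column(s) cannot be standardised: ",
               paste(bad, collapse = ", "))
  }
  fit <- stats::prcomp(mat, center = TRUE, scale. = standardize)
  flip <- apply(fit$rotation, 2L, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  loadings <- sweep(fit$rotation, 2L, flip, `*`)
  scores <- sweep(fit$x, 2L, flip, `*`)
  list(loadings = loadings, scores = scores,
       variance_fractions = fit$sdev^2 / sum(fit$sdev^2))
}

#' Hierarchical clustering on principal components
#'
#' Clusters occurrence points by Ward agglomeration on their first `m`
#' principal-component scores and assigns each taxon to the majority
#' cluster of its points (ties resolve to the lowest cluster id).  The
#' defaults — three components, three clusters — reflect the usual aim of
#' separating broad ecosystem types.
#'
#' @param scores points x PCs matrix (e.g. `env_pca(...)$scores`).
#' @param taxa character vector, one taxon label per point.
#' @param k number of clusters (default 3).
#' @param m number of leading components used (default 3, capped at the
#'   number available).
#' @return list: `assignment` (named integer vector, taxon -> cluster),
#'   `point_clusters`, `cluster_means` (cluster x PC means).
#' @export
hcpc_clusters <- function(scores, taxa, k = 3, m = 3) {
  scores <- as.matrix(scores)
  stopifnot(length(taxa) == nrow(scores))
  if (k > nrow(scores))
    stop_input("k = ", k, " exceeds the number of points")
  m <- min(m, ncol(scores))
  sub <- scores[, seq_len(m), drop = FALSE]
  hc <- stats::hclust(stats::dist(sub), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  assignment <- vapply(split(cl, taxa), function(x) {
    tab <- table(x)
    as.integer(names(tab)[which.max(tab)])  # first max = lowest cluster id
  }, integer(1L))
  means <- do.call(rbind, lapply(sort(unique(cl)), function(ci)
    colMeans(sub[cl == ci, , drop = FALSE])))
  rownames(means) <- sort(unique(cl))
  list(assignment = assignment, point_clusters = cl, cluster_means = means)
}

#' Per-taxon trait table from occurrence extractions
#'
#' Summarises the environmental values extracted at each taxon's
#' coordinate-bearing occurrences into one row per taxon (default summary:
#' median).  Taxa with fewer than `min_points` usable points are excluded
#' with a warning — too few points make both clustering and signal
#' estimates unstable.
#'
#' @param records occurrence data frame (see [occurrence_records()]).
#' @param layers named list of aligned environmental `grid_layer`s.
#' @param fun per-variable summary function (default [stats::median]).
#' @param min_points minimum usable occurrence points per taxon (default 3).
#' @return numeric matrix, taxa x variables, no missing cells.
#' @export
trait_table <- function(records, layers, fun = stats::median,
                        min_points = 3) {
  records <- occurrence_records(records)
  taxa <- sort(unique(records$taxon))
  rows <- list()
  dropped <- character()
  for (tx in taxa) {
    r <- records[records$taxon == tx & !is.na(records$lon), , drop = FALSE]
    m <- if (nrow(r) > 0L)
      tryCatch(extract_env(r$lon, r$lat, layers), error = function(e) NULL)
    else NULL
    if (is.null(m) || nrow(m) < min_points) {
      dropped <- c(dropped, tx)
      next
    }
    rows[[tx]] <- apply(m, 2L, fun)
  }
  if (length(dropped) > 0L)
    warning("taxa excluded (fewer than ", min_points, " usable points): ",
            paste(dropped, collapse = ", "))
  if (length(rows) == 0L)
    stop_input("no taxon has enough coordinate-bearing occurrences")
  do.call(rbind, rows)
}

#' Sister pairs (cherries) of a tree
#'
#' @param tree an `ape::phylo` object.
#' @return two-column character matrix, one row per two-tip clade; each tip
#'   appears in at most one pair.
#' @export
sister_pairs <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  is_tip <- tree$edge[, 2L] <= n_tip
  kids <- split(tree$edge[, 2L][is_tip], tree$edge[, 1L][is_tip])
  cherries <- kids[vapply(kids, length, integer(1L)) == 2L]
  # a node with 2 tip children could still have non-tip children (polytomy)
  all_kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  cherries <- cherries[vapply(names(cherries), function(nd)
    length(all_kids[[nd]]) == 2L, logical(1L))]
  if (length(cherries) == 0L)
    return(matrix(character(), 0L, 2L,
                  dimnames = list(NULL, c("tip1", "tip2"))))
  m <- t(vapply(cherries, function(p) sort(tree$tip.label[p]),
                character(2L)))
  dimnames(m) <- list(NULL, c("tip1", "tip2"))
  m[order(m[, 1L]), , drop = FALSE]
}

#' Blomberg's K phylogenetic signal
#'
#' K compares the observed trait variance to the variance expected under
#' Brownian motion on the given tree:
#' `K = [ (x-a)'(x-a) / (x-a)' C^-1 (x-a) ] / [ (tr C - n / sum(C^-1)) / (n-1) ]`
#' where `C` is the shared-branch-length (phylogenetic covariance) matrix
#' and `a` the generalised-least-squares phylogenetic mean.  K is about 1
#' under Brownian motion, below 1 when relatives resemble each other less
#' than the tree predicts, above 1 when more.  Significance is assessed by
#' randomising tip labels and ranking the observed rate statistic (1/MSE)
#' among the permuted values, with the +1 correction so p is never 0.
#'
#' @param tree rooted `ape::phylo` with branch lengths; >= 4 tips.
#' @param x named numeric trait vector; names must match the tip labels.
#' @param n_perm number of tip-label permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return list of class `k_result`: `K`, `p_value`, `n_perm`, `obs_rate`.
#' @export
blomberg_k <- function(tree, x, n_perm = 1000, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop_input("tree has no branch lengths")
  n <- length(tree$tip.label)
  if (n < 4L) stop_input("need at least 4 tips")
  mism <- c(setdiff(names(x), tree$tip.label),
            setdiff(tree$tip.label, names(x)))
  if (length(mism) > 0L)
    stop_input("trait names and tip labels disagree: ",
               paste(unique(mism), collapse = ", "))
  x <- x[tree$tip.label]
  C <- ape::vcv(tree)
  invC <- solve(C)
  w <- colSums(invC)           # 1' C^-1
  s <- sum(invC)               # 1' C^-1 1
  expected <- (sum(diag(C)) - n / s) / (n - 1)
  quad <- function(v) {
    a <- sum(w * v) / s
    d <- v - a
    c(num = sum(d * d), den = drop(crossprod(d, invC %*% d)))
  }
  obs <- quad(x)
  K <- (obs["num"] / obs["den"]) / expected
  # rate statistic: 1/MSE, large when the tree explains the trait well
  perm_den <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    quad(x[sample.int(n)])["den"], numeric(1L)))
  p <- (1 + sum(perm_den <= obs["den"])) / (n_perm + 1)
  structure(list(K = unname(K), p_value = p, n_perm = n_perm,
                 obs_rate = unname((n - 1) / obs["den"])),
            class = "k_result")
}

#' @export
print.k_result <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.4f (p = %.4g, %d permutations)\n",
              x$K, x$p_value, x$n_perm))
  invisible(x)
}

#' Mantel test
#'
#' Pearson correlation between the off-diagonal entries of two distance
#' matrices, with significance from joint row/column permutation of one
#' matrix: `p = (1 + #{r_perm >= r_obs}) / (n_perm + 1)` (one-sided,
#' positive association).
#'
#' @param distA,distB square symmetric matrices (or `dist` objects) with
#'   zero diagonals, rows/columns in the same taxon order.
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed.
#' @return list of class `mantel_result`: `r`, `p_value`, `n_perm`.
#' @export
mantel_test <- function(distA, distB, n_perm = 1000, seed = NULL) {
  A <- as.matrix(distA); B <- as.matrix(distB)
  if (!isTRUE(all.equal(A, t(A), tolerance = 1e-8,
                        check.attributes = FALSE)) ||
      !isTRUE(all.equal(B, t(B), tolerance = 1e-8,
                        check.attributes = FALSE)))
    stop_input("distance matrices must be symmetric")
  if (!identical(dim(A), dim(B)))
    stop_input("distance matrices must have the same dimension")
  if (any(abs(diag(A)) > 1e-12) || any(abs(diag(B)) > 1e-12))
    stop_input("distance matrices must have zero diagonals")
  n <- nrow(A)
  lt <- lower.tri(A)
  a <- A[lt]
  r_obs <- stats::cor(a, B[lt])
  r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n)
    stats::cor(a, B[idx, idx][lt])
  }, numeric(1L)))
  structure(list(r = r_obs,
                 p_value = (1 + sum(r_perm >= r_obs)) / (n_perm + 1),
                 n_perm = n_perm),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f (p = %.4g, %d permutations)\n",
              x$r, x$p_value, x$n_perm))
  invisible(x)
}

#' Mahalanobis distance matrix between taxa
#'
#' Pairwise Mahalanobis distances between trait-table rows, using the
#' pooled covariance across taxa.  A singular covariance is regularised by
#' adding `ridge * mean(diag(S))` to the diagonal; set `ridge = 0` to make
#' singularity an error instead.
#'
#' @param traits taxa x variables matrix.
#' @param ridge regularisation factor (default 1e-8).
#' @return symmetric distance matrix with taxon dimnames.
#' @export
mahalanobis_dist <- function(traits, ridge = 1e-8) {
  traits <- as.matrix(traits)
  S <- stats::cov(traits)
  invS <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(invS)) {
    if (ridge <= 0)
      stop_input("singular trait covariance; set `ridge` > 0 to regularise")
    invS <- solve(S + diag(ridge * mean(diag(S)), ncol(S)))
  }
  n <- nrow(traits)
  D <- matrix(0, n, n, dimnames = list(rownames(traits), rownames(traits)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- traits[i, ] - traits[j, ]
    D[i, j] <- D[j, i] <- sqrt(drop(d %*% invS %*% d))
  }
  D
}

#' Great-circle distances between taxon centroids
#'
#' Haversine distance matrix between the coordinate centroids (mean
#' longitude/latitude of coordinate-bearing records) of each taxon.
#'
#' @param records occurrence data frame.
#' @param taxa optional taxon subset/order; default all taxa with
#'   coordinates, sorted.
#' @return symmetric distance matrix in kilometres.
#' @export
geo_centroid_dist <- function(records, taxa = NULL) {
  records <- occurrence_records(records)
  r <- records[!is.na(records$lon), , drop = FALSE]
  if (is.null(taxa)) taxa <- sort(unique(r$taxon))
  cen <- t(vapply(taxa, function(tx) {
    ri <- r[r$taxon == tx, , drop = FALSE]
    if (nrow(ri) == 0L)
      stop_input("taxon without coordinates: ", tx)
    c(mean(ri$lon), mean(ri$lat))
  }, numeric(2L)))
  n <- length(taxa)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- haversine_km(cen[i, 1L], cen[i, 2L],
                                       cen[j, 1L], cen[j, 2L])
  D
}

#' Cophenetic (patristic) distance matrix of a tree
#'
#' @param tree `ape::phylo` with branch lengths.
#' @return symmetric matrix of tip-to-tip path lengths.
#' @export
cophenetic_dist <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::cophenetic.phylo(tree)
}

#' Fraction of variables showing phylogenetic niche conservatism
#'
#' @param k_results list of `k_result`s (or data frame with columns `K`,
#'   `p_value`), one per ecogeographic variable.
#' @param alpha significance level (default 0.05).
#' @param rule `"p"` counts variables with `p < alpha`;
#'   `"k_and_p"` additionally requires `K > 1`.
#' @return fraction in \[0, 1\].
#' @export
conservatism_fraction <- function(k_results, alpha = 0.05,
                                  rule = c("p", "k_and_p")) {
  rule <- match.arg(rule)
  if (is.data.frame(k_results)) {
    K <- k_results$K; p <- k_results$p_value
  } else {
    K <- vapply(k_results, `[[`, numeric(1L), "K")
    p <- vapply(k_results, `[[`, numeric(1L), "p_value")
  }
  if (length(K) == 0L) stop_input("no variables supplied")
  sig <- p < alpha
  if (rule == "k_and_p") sig <- sig & K > 1
  mean(sig)
}
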