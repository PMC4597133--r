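test_that("environmental extraction looks up the containing cell", {
  const <- equator_grid(5, fill = 7)
  m <- extract_env(0, 0, const)
  expect_identical(unname(m[1, 1]), 7)
  # step layer: value depends on which side of the boundary a point falls
  step <- equator_grid(5)
  step$values[, 1:2] <- -1; step$values[, 3:5] <- 1
  got <- extract_env(c(-0.9, 0.1, 0.9), c(0, 0, 0), step)
  expect_identical(unname(got[, 1]), c(-1, 1, 1))
  # outside points are dropped and counted
  g2 <- extract_env(c(0, 50), c(0, 0), const)
  expect_identical(nrow(g2), 1L)
  expect_identical(attr(g2, "n_dropped"), 1L)
  expect_error(extract_env(50, 50, const), "outside")
})

test_that("PCA reports variance fractions with a fixed sign convention", {
  # collinear points: one component carries everything
  line <- cbind(1:6, 2 * (1:6))
  p1 <- env_pca(line, standardize = FALSE)
  expect_equal(p1$variance_fractions[1], 1, tolerance = 1e-12)
  # hand-computed covariance eigenvalues: (8/3, 2/3) -> fractions .8/.2
  quad <- rbind(c(2, 0), c(-2, 0), c(0, 1), c(0, -1))
  p2 <- env_pca(quad, standardize = FALSE)
  expect_equal(unname(p2$variance_fractions), c(0.8, 0.2))
  expect_equal(sum(p2$variance_fractions), 1)
  # largest-magnitude loading positive, per component
  set.seed(47)
  p3 <- env_pca(matrix(rnorm(60), 20, 3))
  for (j in 1:3)
    expect_gt(p3$loadings[which.max(abs(p3$loadings[, j])), j], 0)
  # reconstruction restores the standardised input
  x <- matrix(rnorm(80), 20, 4)
  p4 <- env_pca(x, standardize = TRUE)
  expect_equal(p4$scores %*% t(p4$loadings),
               scale(x), tolerance = 1e-8, ignore_attr = TRUE)
  bad <- cbind(a = rnorm(10), flat = rep(1, 10))
  expect_error(env_pca(bad), "flat")
})

test_that("Ward clustering on components recovers separated clouds", {
  set.seed(53)
  pts <- rbind(matrix(rnorm(40, 0), 20, 2),
               matrix(rnorm(40, 8), 20, 2),
               cbind(rnorm(20, 8), rnorm(20, -8)))
  taxa <- rep(c("t1", "t2", "t3"), each = 20)
  cl <- hcpc_clusters(pts, taxa, k = 3, m = 2)
  expect_identical(length(unique(cl$assignment)), 3L)
  expect_identical(length(cl$assignment), 3L)
  # every taxon's points are (almost) wholly in its own cluster
  expect_gte(mean(cl$point_clusters[1:20] == cl$assignment[["t1"]]), 0.95)
  # k = 1 puts everything together
  one <- hcpc_clusters(pts, taxa, k = 1, m = 2)
  expect_true(all(one$assignment == 1L))
  # point order does not change co-membership
  perm <- sample(nrow(pts))
  cl2 <- hcpc_clusters(pts[perm, ], taxa[perm], k = 3, m = 2)
  expect_identical(cl$assignment[["t1"]] == cl$assignment[["t2"]],
                   cl2$assignment[["t1"]] == cl2$assignment[["t2"]])
  expect_identical(cl$assignment[["t2"]] == cl$assignment[["t3"]],
                   cl2$assignment[["t2"]] == cl2$assignment[["t3"]])
  # duplicated point set keeps the partition
  cl3 <- hcpc_clusters(rbind(pts, pts), c(taxa, taxa), k = 3, m = 2)
  expect_identical(length(unique(cl3$assignment)), 3L)
  expect_error(hcpc_clusters(pts[1:2, ], taxa[1:2], k = 5), "exceeds")
})

test_that("sister pairs are exactly the two-tip clades", {
  t1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_identical(sister_pairs(t1),
                   matrix(c("A", "C", "B", "D"), 2, 2,
                          dimnames = list(NULL, c("tip1", "tip2"))))
  t2 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_identical(unname(sister_pairs(t2)[1, ]), c("A", "B"))
  t3 <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
  expect_identical(nrow(sister_pairs(t3)), 1L)
  expect_identical(unname(sister_pairs(t3)[1, ]), c("A", "B"))
})

test_that("Blomberg's K is exactly 1 on a star tree", {
  star <- ape::stree(8, "star")
  star$edge.length <- rep(1, nrow(star$edge))
  set.seed(59)
  for (i in 1:5) {
    x <- setNames(rnorm(8), star$tip.label)
    expect_equal(blomberg_k(star, x, n_perm = 9, seed = 1)$K, 1,
                 tolerance = 1e-12)
  }
})

test_that("Blomberg's K agrees with the independent reference", {
  set.seed(61)
  for (i in 1:8) {
    tt <- make_tree_and_traits(sample(10:30, 1), seed = 100 + i,
                               mode = sample(c("BM", "white_noise"), 1))
    x <- setNames(tt$traits[, 1], rownames(tt$traits))
    mine <- blomberg_k(tt$tree, x, n_perm = 9, seed = 1)$K
    ref <- picante::Kcalc(x[tt$tree$tip.label], tt$tree)
    expect_equal(mine, as.numeric(ref), tolerance = 1e-6)
  }
  tt <- make_tree_and_traits(10, seed = 3)
  x <- setNames(tt$traits[, 1], rownames(tt$traits))
  names(x)[1] <- "stranger"
  expect_error(blomberg_k(tt$tree, x, n_perm = 9), "stranger")
})

test_that("K permutation p-values detect Brownian but not shuffled traits", {
  tt <- make_tree_and_traits(40, seed = 71, mode = "BM")
  x <- setNames(tt$traits[, 1], rownames(tt$traits))
  kb <- blomberg_k(tt$tree, x, n_perm = 199, seed = 2)
  expect_lt(kb$p_value, 0.05)
  expect_gt(kb$p_value, 0)
  set.seed(4)
  xs <- setNames(sample(x), names(x))
  expect_gt(blomberg_k(tt$tree, xs, n_perm = 199, seed = 2)$p_value, 0.05)
  # same seed reproduces the p-value
  expect_identical(kb$p_value,
                   blomberg_k(tt$tree, x, n_perm = 199, seed = 2)$p_value)
})

test_that("Mantel correlation hits its algebraic extremes", {
  set.seed(67)
  pts <- matrix(rnorm(24), 12, 2)
  A <- as.matrix(dist(pts))
  expect_equal(mantel_test(A, A, n_perm = 99, seed = 1)$r, 1)
  B <- max(A) - A; diag(B) <- 0
  expect_equal(mantel_test(A, B, n_perm = 99, seed = 1)$r, -1)
  # r is invariant under joint relabeling of both matrices
  perm <- sample(12)
  expect_equal(mantel_test(A[perm, perm], B[perm, perm],
                           n_perm = 9, seed = 1)$r, -1)
  # p reproducible under a fixed seed
  C <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
  m1 <- mantel_test(A, C, n_perm = 199, seed = 5)
  m2 <- mantel_test(A, C, n_perm = 199, seed = 5)
  expect_identical(m1$p_value, m2$p_value)
  expect_error(mantel_test(A, B[1:11, 1:11]), "dimension")
  asym <- A; asym[1, 2] <- asym[1, 2] + 1
  expect_error(mantel_test(asym, B), "symmetric")
})

test_that("Mantel r agrees with the community-ecology reference", {
  set.seed(73)
  A <- as.matrix(dist(matrix(rnorm(30), 15, 2)))
  B <- as.matrix(dist(matrix(rnorm(30), 15, 2)))
  mine <- mantel_test(A, B, n_perm = 99, seed = 1)$r
  ref <- vegan::mantel(A, B, permutations = 9)$statistic
  expect_equal(mine, as.numeric(ref), tolerance = 1e-10)
})

test_that("distance builders agree with direct computation", {
  set.seed(79)
  tr <- matrix(rnorm(40), 8, 5,
               dimnames = list(paste0("t", 1:8), paste0("v", 1:5)))
  D <- mahalanobis_dist(tr)
  expect_identical(diag(D), setNames(rep(0, 8), rownames(tr)))
  expect_identical(D, t(D))
  S <- cov(tr)
  for (pair in list(c(1, 2), c(3, 7))) {
    ref <- sqrt(stats::mahalanobis(tr[pair[1], ], tr[pair[2], ], S))
    expect_equal(D[pair[1], pair[2]], unname(ref), tolerance = 1e-10)
  }
  # singular covariance: error without ridge, finite with it
  sing <- cbind(tr[, 1], tr[, 1], tr[, 2])
  expect_error(mahalanobis_dist(sing, ridge = 0), "singular")
  expect_true(all(is.finite(mahalanobis_dist(sing))))
  # cophenetic distance of a cherry is the sum of its depths
  cherry <- ape::read.tree(text = "(A:1,B:2);")
  expect_identical(cophenetic_dist(cherry)["A", "B"], 3)
  # geographic centroids: zero self-distance, symmetry
  d <- occ_df(rep(c("a", "b"), each = 2), "H",
              lon = c(0, 2, 10, 12), lat = c(0, 0, 0, 0))
  G <- geo_centroid_dist(d)
  expect_identical(diag(G), setNames(rep(0, 2), c("a", "b")))
  expect_equal(G["a", "b"], haversine_km(1, 0, 11, 0))
})

test_that("conservatism fraction counts significant variables", {
  kr <- data.frame(K = c(1.2, 0.4, 1.5, 0.9), p_value = c(0.01, 0.2, 0.03, 0.04))
  expect_identical(conservatism_fraction(kr), 0.75)
  expect_identical(conservatism_fraction(kr, rule = "k_and_p"), 0.5)
  expect_identical(conservatism_fraction(data.frame(K = 1, p_value = 0.5)), 0)
  expect_identical(conservatism_fraction(data.frame(K = 1, p_value = 0.01)), 1)
})

test_that("trait table summarises per taxon and excludes sparse taxa", {
  lay <- list(e1 = equator_grid(5, fill = 2), e2 = equator_grid(5, fill = 5))
  d <- rbind(occ_df("rich", "H", lon = runif(5, -0.9, 0.9),
                    lat = runif(5, -0.9, 0.9)),
             occ_df("sparse", "H", lon = 0, lat = 0, id = "s1"))
  expect_warning(tt <- trait_table(d, lay), "sparse")
  expect_identical(rownames(tt), "rich")
  expect_identical(unname(tt["rich", ]), c(2, 5))
})
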