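test_that("environmental fields are seeded, standardised and autocorrelated", {
  l1 <- make_env_layers(2, nrow = 30, ncol = 30, correlation_length = 5,
                        seed = 5)
  l2 <- make_env_layers(2, nrow = 30, ncol = 30, correlation_length = 5,
                        seed = 5)
  expect_identical(l1, l2)
  v <- l1[[1]]$values
  expect_equal(mean(v), 0, tolerance = 1e-12)
  expect_equal(sd(v), 1, tolerance = 1e-12)
  # lag-1 spatial autocorrelation: near zero for white noise, high for
  # smoothed fields (averaged over seeds)
  lag1 <- function(m) cor(as.vector(m[-nrow(m), ]), as.vector(m[-1, ]))
  ac_white <- sapply(1:20, function(s)
    lag1(make_env_layers(1, 40, 40, correlation_length = 1,
                         seed = s)[[1]]$values))
  ac_smooth <- sapply(1:20, function(s)
    lag1(make_env_layers(1, 40, 40, correlation_length = 9,
                         seed = s)[[1]]$values))
  expect_lt(abs(mean(ac_white)), 0.1)
  expect_gt(mean(ac_smooth), 0.5)
  expect_error(make_env_layers(1, correlation_length = 0.5), "at least 1")
})

test_that("latent structure induces between-layer correlation", {
  ind <- make_env_layers(6, 40, 40, seed = 3, n_latent = 0)
  cor_ind <- cor(sapply(ind, function(l) as.vector(l$values)))
  dep <- make_env_layers(6, 40, 40, seed = 3, n_latent = 2,
                         latent_noise = 0.3)
  cor_dep <- cor(sapply(dep, function(l) as.vector(l$values)))
  off <- upper.tri(cor_ind)
  expect_gt(mean(abs(cor_dep[off])), mean(abs(cor_ind[off])))
  expect_gt(max(abs(cor_dep[off])), 0.5)
})

test_that("ecoregion patches cover all classes deterministically", {
  tmpl <- equator_grid(20, cell_size = 0.1)
  eco <- make_ecoregions(tmpl, 4, seed = 11)
  expect_setequal(unique(as.vector(eco$values)), 1:4)
  expect_identical(eco$values, make_ecoregions(tmpl, 4, seed = 11)$values)
  one <- make_ecoregions(tmpl, 1, seed = 11)
  expect_identical(unique(as.vector(one$values)), 1)
  expect_error(make_ecoregions(equator_grid(2), 100), "more classes")
})

test_that("taxon occurrences concentrate near the niche centre", {
  env <- make_env_layers(2, 40, 40, correlation_length = 7, seed = 13)
  tx <- make_taxon(env, "narrow",
                   centers = c(env01 = 0.5, env02 = -0.5),
                   breadths = c(env01 = 0.3, env02 = 0.3),
                   n_records = 200, coord_fraction = 1,
                   germplasm_fraction = 0.5, seed = 17)
  expect_identical(nrow(tx$records), 200L)
  expect_equal(max(tx$suitability$values), 1)
  vals <- extract_env(tx$records$lon, tx$records$lat, env)
  expect_lt(abs(mean(vals[, "env01"]) - 0.5), 0.5)
  expect_lt(abs(mean(vals[, "env02"]) + 0.5), 0.5)
  # very broad niche: suitability near-uniform
  broad <- make_taxon(env, "broad",
                      centers = c(env01 = 0), breadths = c(env01 = 1e6),
                      n_records = 10, seed = 1)
  expect_lt(diff(range(broad$suitability$values)), 1e-6)
  # germplasm_fraction 0 means SRS 0 downstream
  nog <- make_taxon(env, "nog", centers = c(env01 = 0),
                    breadths = c(env01 = 1), n_records = 50, seed = 2,
                    germplasm_fraction = 0)
  cnt <- partition_counts(nog$records, "nog")
  expect_identical(cnt$n_G, 0L)
  expect_identical(srs(cnt$n_G, cnt$n_H), 0)
})

test_that("Brownian tip variance scales with tree depth", {
  tt <- make_tree_and_traits(12, seed = 23, mode = "BM")
  depth <- max(ape::node.depth.edgelength(tt$tree))
  sigma2 <- 2.5
  set.seed(29)
  tips <- replicate(500, gapkit:::sim_bm(tt$tree, sigma2 = sigma2))
  # each tip's variance across replicates ~ sigma2 * its root-to-tip depth
  expect_equal(mean(apply(tips, 1, var)) / (sigma2 * depth), 1,
               tolerance = 0.1)
  # ultrametric: all tips at the same depth
  expect_lt(diff(range(ape::node.depth.edgelength(tt$tree)[1:12])), 1e-8)
})

test_that("trees and traits are reproducible and round-trip as Newick", {
  a <- make_tree_and_traits(10, seed = 31)
  b <- make_tree_and_traits(10, seed = 31)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$traits, b$traits)
  f <- tempfile(fileext = ".nwk")
  ape::write.tree(a$tree, f)
  back <- ape::read.tree(f)
  expect_identical(sort(back$tip.label), sort(a$tree$tip.label))
  expect_equal(cophenetic_dist(back)[a$tree$tip.label, a$tree$tip.label],
               cophenetic_dist(a$tree), tolerance = 1e-8)
})

test_that("worlds are bit-identical by seed and keep records on the grid", {
  cfg <- world_config(n_taxa = 6, nrow = 25, ncol = 25, seed = 37,
                      records_range = c(20, 60))
  w1 <- make_world(cfg)
  w2 <- make_world(cfg)
  expect_identical(w1$records, w2$records)
  expect_identical(w1$env_layers, w2$env_layers)
  expect_identical(ape::write.tree(w1$tree), ape::write.tree(w2$tree))
  xy <- w1$records[!is.na(w1$records$lon), ]
  tmpl <- w1$env_layers[[1]]
  rc <- gapkit:::point_cell(tmpl, xy$lon, xy$lat)
  expect_false(anyNA(rc))
  # each taxon's germplasm share matches its truth
  for (tx in names(w1$taxa)) {
    cnt <- partition_counts(w1$records, tx)
    expect_equal(cnt$n_G / (cnt$n_G + cnt$n_H),
                 w1$taxa[[tx]]$germplasm_fraction, tolerance = 0.05)
  }
})

test_that("taxa with disjoint niches land in distinct clusters", {
  hits <- 0L
  n_rep <- 50L
  for (s in seq_len(n_rep)) {
    env <- make_env_layers(2, 30, 30, correlation_length = 7, seed = 200 + s)
    taxa <- list(
      make_taxon(env, "lowlow", c(env01 = -1.2, env02 = -1.2),
                 c(env01 = 0.35, env02 = 0.35), n_records = 40,
                 coord_fraction = 1, seed = 300 + s),
      make_taxon(env, "highhigh", c(env01 = 1.2, env02 = 1.2),
                 c(env01 = 0.35, env02 = 0.35), n_records = 40,
                 coord_fraction = 1, seed = 400 + s))
    rec <- rbind(taxa[[1]]$records, taxa[[2]]$records)
    vals <- extract_env(rec$lon, rec$lat, env)
    pca <- env_pca(vals)
    cl <- hcpc_clusters(pca$scores, rec$taxon, k = 2, m = 2)
    if (cl$assignment[["lowlow"]] != cl$assignment[["highhigh"]])
      hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("a taxon with no germplasm is always flagged high priority", {
  env <- make_env_layers(2, 25, 25, correlation_length = 5, seed = 41)
  eco <- make_ecoregions(env[[1]], 5, seed = 42)
  tx <- make_taxon(env, "orphan", c(env01 = 0), c(env01 = 0.8),
                   n_records = 60, coord_fraction = 0.5,
                   germplasm_fraction = 0, seed = 43)
  cnt <- partition_counts(tx$records, "orphan")
  xy <- tx$records[!is.na(tx$records$lon), ]
  rng <- circular_buffer_range(xy$lon, xy$lat, env[[1]])
  sc <- fps_classify(srs(cnt$n_G, cnt$n_H), grs(NULL, rng),
                     ers(eco, rng, NULL), "orphan")
  expect_lte(sc$FPS, 3)
  expect_identical(as.character(sc$category), "HPS")
})

test_that("written worlds reload with everything intact", {
  w <- make_world(world_config(n_taxa = 4, nrow = 20, ncol = 20, seed = 47,
                               records_range = c(20, 40)))
  d <- tempfile("world")
  write_world(w, d)
  expect_true(all(file.exists(file.path(d, c("occ.csv", "eco.asc",
                                             "exclusion.asc", "tree.nwk",
                                             "truth.json")))))
  back <- read_world(d)
  expect_identical(nrow(back$records), nrow(w$records))
  expect_equal(back$env_layers[[1]]$values, w$env_layers[[1]]$values,
               tolerance = 1e-15)
  expect_setequal(back$tree$tip.label, w$tree$tip.label)
  expect_identical(names(back$suitability), names(w$taxa))
  expect_identical(unname(back$life_history[names(w$life_history)]),
                   unname(w$life_history))
})
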