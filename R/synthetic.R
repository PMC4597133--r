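# Synthetic study worlds: seeded, self-contained stand-ins for the real
# inputs of a crop-wild-relative gap analysis (climate/soil rasters,
# ecoregion map, genebank + herbarium occurrences, phylogeny), with the
# generating truth retained so downstream estimates can be checked.

# Box moving-average smoother with edge replication; w is the window width
# in cells (forced odd).
smooth_box <- function(m, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L) return(m)
  h <- (w - 1L) %/% 2L
  pad_rows <- function(x) rbind(x[rep(1L, h), , drop = FALSE], x,
                                x[rep(nrow(x), h), , drop = FALSE])
  run_cols <- function(x) {  # moving average down each column
    cs <- apply(x, 2L, cumsum)
    cs <- rbind(0, cs)
    (cs[(w + 1L):nrow(cs), , drop = FALSE] -
       cs[1L:(nrow(cs) - w), , drop = FALSE]) / w
  }
  m <- run_cols(pad_rows(m))
  t(run_cols(pad_rows(t(m))))
}

#' Synthetic environmental layers
#'
#' Spatially autocorrelated continuous fields: white noise smoothed by a
#' square moving average of width `correlation_length` cells, then
#' standardised to mean 0, SD 1.  These emulate standardised bioclimatic /
#' edaphic predictor surfaces.
#'
#' Real predictor sets (e.g. the 19 bioclimatic variables) are strongly
#' inter-correlated; `n_latent > 0` reproduces that by building each layer
#' as a random mixture of `n_latent` shared latent fields plus a
#' layer-specific component weighted `latent_noise`.
#'
#' @param n_layers number of layers (>= 1).
#' @param nrow,ncol grid shape.
#' @param correlation_length smoothing window, cells (>= 1; 1 = white
#'   noise).
#' @param seed RNG seed; the same seed reproduces the layers bit for bit.
#' @param origin_lon,origin_lat,cell_size grid georeferencing.
#' @param n_latent shared latent fields driving between-layer correlation
#'   (0 = independent layers).
#' @param latent_noise weight of each layer's private field when
#'   `n_latent > 0`, in (0, 1\].
#' @return named list of `grid_layer`s (`env01`, `env02`, ...).
#' @export
make_env_layers <- function(n_layers, nrow = 60, ncol = 60,
                            correlation_length = 7, seed = NULL,
                            origin_lon = -105, origin_lat = 45,
                            cell_size = 0.25, n_latent = 0,
                            latent_noise = 0.3) {
  stopifnot(n_layers >= 1L, n_latent >= 0L,
            latent_noise > 0, latent_noise <= 1)
  if (correlation_length < 1)
    stop_input("`correlation_length` must be at least 1 cell")
  field <- function() {
    m <- smooth_box(matrix(stats::rnorm(nrow * ncol), nrow, ncol),
                    correlation_length)
    (m - mean(m)) / stats::sd(m)
  }
  with_seed(seed, {
    latents <- if (n_latent > 0L) replicate(n_latent, field(),
                                            simplify = FALSE)
    layers <- lapply(seq_len(n_layers), function(i) {
      if (n_latent > 0L) {
        w <- stats::rnorm(n_latent)
        w <- w / sqrt(sum(w^2))
        m <- Reduce(`+`, Map(`*`, latents, w)) * (1 - latent_noise) +
          latent_noise * field()
        m <- (m - mean(m)) / stats::sd(m)
      } else m <- field()
      grid_layer(m, origin_lon, origin_lat, cell_size)
    })
    names(layers) <- sprintf("env%02d", seq_len(n_layers))
    layers
  })
}

#' Synthetic ecoregion map
#'
#' Voronoi-style categorical patches: `n_classes` seed cells are drawn and
#' every cell takes the class of its nearest seed (Euclidean in cell
#' indices; ties to the lowest class id).  All classes are non-empty.
#'
#' @param template `grid_layer` lattice.
#' @param n_classes number of ecosystem classes.
#' @param seed RNG seed.
#' @return categorical `grid_layer` with integer classes `1..n_classes`.
#' @export
make_ecoregions <- function(template, n_classes, seed = NULL) {
  stopifnot(is_grid_layer(template), n_classes >= 1L)
  nr <- nrow(template$values); nc <- ncol(template$values)
  if (n_classes > nr * nc)
    stop_input("more classes than grid cells")
  with_seed(seed, {
    cells <- sample.int(nr * nc, n_classes)
    seed_r <- (cells - 1L) %% nr + 1L
    seed_c <- (cells - 1L) %/% nr + 1L
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    best_d <- matrix(Inf, nr, nc)
    cls <- matrix(1L, nr, nc)
    for (k in seq_len(n_classes)) {
      d <- (rows - seed_r[k])^2 + (cols - seed_c[k])^2
      upd <- d < best_d
      best_d[upd] <- d[upd]
      cls[upd] <- k
    }
    out <- template
    out$values <- cls * 1
    out
  })
}

#' Synthetic land-cover exclusion mask
#'
#' A single compact blob of excluded cells (urban / water / bare / ice
#' stand-in) covering approximately `fraction` of the grid, grown outward
#' from a random centre.
#'
#' @param template `grid_layer` lattice.
#' @param fraction target excluded share of cells, in \[0, 1).
#' @param seed RNG seed.
#' @return a `binary_range` (1 = excluded).
#' @export
make_exclusion_mask <- function(template, fraction = 0.05, seed = NULL) {
  stopifnot(is_grid_layer(template), fraction >= 0, fraction < 1)
  nr <- nrow(template$values); nc <- ncol(template$values)
  with_seed(seed, {
    n_take <- ceiling(fraction * nr * nc)
    v <- matrix(0, nr, nc)
    if (n_take > 0L) {
      cr <- sample.int(nr, 1L); cc <- sample.int(nc, 1L)
      rows <- matrix(seq_len(nr), nr, nc)
      cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      d <- (rows - cr)^2 + (cols - cc)^2
      cut <- sort(d)[n_take]
      sel <- which(d <= cut)[seq_len(n_take)]  # deterministic tie-break
      v[sel] <- 1
    }
    out <- template
    out$values <- v
    binary_range(out)
  })
}

#' Synthetic taxon: Gaussian niche, truth and occurrence records
#'
#' Builds a taxon with a Gaussian niche response over selected environmental
#' variables: `suitability = exp(-0.5 * sum(((env - center) / breadth)^2))`,
#' rescaled to maximum 1.  Coordinate-bearing occurrences are sampled
#' without replacement across cells with probability proportional to
#' suitability (jittered uniformly within the cell); the remaining records
#' carry no coordinates, mimicking un-georeferenced genebank and herbarium
#' entries.  A fraction of all records is flagged `G` (germplasm), the rest
#' `H` (reference).
#'
#' @param env_layers named list of aligned environmental `grid_layer`s.
#' @param name taxon name.
#' @param centers named numeric vector of niche optima (names must be
#'   layer names).
#' @param breadths named positive vector of niche breadths, same names.
#' @param n_records total records (with and without coordinates).
#' @param coord_fraction share of records that carry coordinates.
#' @param germplasm_fraction share of records flagged `G`.
#' @param seed RNG seed.
#' @return list of class `taxon_truth`: `taxon`, `centers`, `breadths`,
#'   `suitability` (`grid_layer`), `records` (data frame), `n_records`,
#'   `germplasm_fraction`.
#' @export
make_taxon <- function(env_layers, name, centers, breadths,
                       n_records = 120, coord_fraction = 0.37,
                       germplasm_fraction = 0.25, seed = NULL) {
  stopifnot(all(names(centers) %in% names(env_layers)),
            identical(names(centers), names(breadths)),
            all(breadths > 0),
            germplasm_fraction >= 0, germplasm_fraction <= 1)
  do.call(check_aligned, env_layers)
  tmpl <- env_layers[[1L]]
  z2 <- 0
  for (v in names(centers))
    z2 <- z2 + ((env_layers[[v]]$values - centers[[v]]) / breadths[[v]])^2
  suit <- exp(-0.5 * z2)
  mx <- suppressWarnings(max(suit, na.rm = TRUE))
  if (!is.finite(mx) || mx <= 0)
    stop_input("suitability is zero everywhere for taxon ", name)
  suit <- suit / mx
  surface <- tmpl
  surface$values <- suit
  with_seed(seed, {
    n_coord <- round(coord_fraction * n_records)
    ok <- which(!is.na(suit) & suit > 0)
    if (n_coord > length(ok))
      stop_input("not enough suitable cells to place ", n_coord,
                 " occurrences for taxon ", name)
    cells <- sample(ok, n_coord, prob = suit[ok])
    nr <- nrow(suit)
    r <- (cells - 1L) %% nr + 1L
    cc <- (cells - 1L) %/% nr + 1L
    cs <- tmpl$cell_size
    lon <- tmpl$origin_lon + (cc - 1L) * cs + stats::runif(n_coord) * cs
    lat <- tmpl$origin_lat - (r - 1L) * cs - stats::runif(n_coord) * cs
    type <- rep("H", n_records)
    type[sample.int(n_records, round(germplasm_fraction * n_records))] <- "G"
    records <- data.frame(
      record_id = sprintf("%s_%04d", name, seq_len(n_records)),
      taxon = name, type = type,
      lon = c(lon, rep(NA_real_, n_records - n_coord)),
      lat = c(lat, rep(NA_real_, n_records - n_coord)),
      source = "synthetic", stringsAsFactors = FALSE)
    structure(list(taxon = name, centers = centers, breadths = breadths,
                   suitability = surface, records = records,
                   n_records = n_records,
                   germplasm_fraction = germplasm_fraction),
              class = "taxon_truth")
  })
}

#' Noisy cross-validation fold surfaces for a known suitability truth
#'
#' Emulates the fold-to-fold variation of a fitted distribution model by
#' adding independent Gaussian noise to the true surface, clamped to
#' \[0, 1\] — the surrogate consumed by the model-validation stage.
#'
#' @param surface the true suitability `grid_layer`.
#' @param k number of folds (default 5).
#' @param noise_sd per-cell noise SD (default 0.08).
#' @param seed RNG seed.
#' @return list of `k` `grid_layer`s.
#' @export
make_fold_surfaces <- function(surface, k = 5, noise_sd = 0.08,
                               seed = NULL) {
  stopifnot(is_grid_layer(surface), k >= 2L, noise_sd >= 0)
  with_seed(seed, lapply(seq_len(k), function(i) {
    out <- surface
    out$values <- clamp(surface$values +
                          stats::rnorm(length(surface$values),
                                       sd = noise_sd), 0, 1)
    out
  }))
}

#' Random ultrametric tree with simulated traits
#'
#' A coalescent-style random ultrametric tree plus tip traits evolved
#' either by Brownian motion along the branches (rate `sigma2`) or as
#' exchangeable white noise (no phylogenetic structure) — the two
#' calibration regimes for the phylogenetic-signal statistics.
#'
#' @param n_tips number of tips (>= 4).
#' @param seed RNG seed.
#' @param mode `"BM"` or `"white_noise"`.
#' @param sigma2 Brownian rate (variance per unit branch length).
#' @param n_traits number of independent trait columns.
#' @param tip_labels optional tip names (default `t01`, `t02`, ...).
#' @return list: `tree` (`ape::phylo`), `traits` (tips x traits matrix).
#' @export
make_tree_and_traits <- function(n_tips, seed = NULL,
                                 mode = c("BM", "white_noise"),
                                 sigma2 = 1, n_traits = 1,
                                 tip_labels = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_tips >= 4L)
  if (is.null(tip_labels))
    tip_labels <- sprintf("t%02d", seq_len(n_tips))
  stopifnot(length(tip_labels) == n_tips)
  with_seed(seed, {
    tree <- ape::rcoal(n_tips, tip.label = tip_labels)
    traits <- sapply(seq_len(n_traits), function(j)
      if (mode == "BM") sim_bm(tree, sigma2) else
        stats::setNames(stats::rnorm(n_tips), tree$tip.label))
    traits <- matrix(traits, nrow = n_tips,
                     dimnames = list(tree$tip.label,
                                     sprintf("trait%02d", seq_len(n_traits))))
    list(tree = tree, traits = traits)
  })
}

# Brownian motion along the branches; root state 0.  Uses the caller's RNG
# stream.
sim_bm <- function(tree, sigma2 = 1) {
  n_tip <- length(tree$tip.label)
  vals <- numeric(n_tip + tree$Nnode)
  edges <- ape::reorder.phylo(tree, "cladewise")
  steps <- stats::rnorm(nrow(edges$edge),
                        sd = sqrt(sigma2 * edges$edge.length))
  for (e in seq_len(nrow(edges$edge)))
    vals[edges$edge[e, 2L]] <- vals[edges$edge[e, 1L]] + steps[e]
  stats::setNames(vals[seq_len(n_tip)], tree$tip.label)
}

#' Configuration of a synthetic world
#'
#' Collects every generator parameter with validation.  The defaults define
#' the package's reference study conditions: a 60 x 60 grid of 0.25-degree
#' cells, 8 standardised environmental layers, 10 ecoregion classes, 5%
#' excluded land cover, and 36 taxa whose niche optima evolve by Brownian
#' motion on a shared random ultrametric phylogeny (so niches carry
#' phylogenetic signal), each taxon with 40-200 records of which 37% carry
#' coordinates and a germplasm share drawn between 5% and 60%.
#'
#' @param n_taxa number of taxa.
#' @param n_env_layers environmental layers.
#' @param nrow,ncol,cell_size,origin_lon,origin_lat grid geometry.
#' @param correlation_length smoothing window of the fields, cells.
#' @param n_ecoregions ecosystem classes.
#' @param exclusion_fraction excluded land-cover share.
#' @param n_niche_vars leading environmental variables defining niches.
#' @param n_latent,latent_noise between-layer correlation structure (see
#'   [make_env_layers()]).
#' @param records_range integer range of per-taxon record totals.
#' @param coord_fraction share of records with coordinates.
#' @param germplasm_range range of per-taxon germplasm shares.
#' @param breadth_meanlog,breadth_sdlog log-normal niche-breadth parameters
#'   (environmental SD units).
#' @param bm_sigma2 Brownian rate of niche-optimum evolution.
#' @param seed master RNG seed.
#' @return validated `world_config` list.
#' @export
world_config <- function(n_taxa = 36, n_env_layers = 8,
                         nrow = 60, ncol = 60, cell_size = 0.25,
                         origin_lon = -105, origin_lat = 45,
                         correlation_length = 7, n_ecoregions = 10,
                         exclusion_fraction = 0.05, n_niche_vars = 3,
                         n_latent = 3, latent_noise = 0.3,
                         records_range = c(40, 200),
                         coord_fraction = 0.37,
                         germplasm_range = c(0.05, 0.6),
                         breadth_meanlog = log(0.8), breadth_sdlog = 0.3,
                         bm_sigma2 = 1, seed = 1) {
  cfg <- list(n_taxa = n_taxa, n_env_layers = n_env_layers, nrow = nrow,
              ncol = ncol, cell_size = cell_size, origin_lon = origin_lon,
              origin_lat = origin_lat,
              correlation_length = correlation_length,
              n_ecoregions = n_ecoregions,
              exclusion_fraction = exclusion_fraction,
              n_niche_vars = n_niche_vars, n_latent = n_latent,
              latent_noise = latent_noise, records_range = records_range,
              coord_fraction = coord_fraction,
              germplasm_range = germplasm_range,
              breadth_meanlog = breadth_meanlog,
              breadth_sdlog = breadth_sdlog, bm_sigma2 = bm_sigma2,
              seed = seed)
  if (cfg$n_taxa < 2) stop_input("`n_taxa` must be at least 2")
  if (cfg$n_niche_vars < 1 || cfg$n_niche_vars > cfg$n_env_layers)
    stop_input("`n_niche_vars` must lie in [1, n_env_layers]")
  if (cfg$coord_fraction <= 0 || cfg$coord_fraction > 1)
    stop_input("`coord_fraction` must lie in (0, 1]")
  if (any(cfg$germplasm_range < 0) || any(cfg$germplasm_range > 1))
    stop_input("`germplasm_range` must lie in [0, 1]")
  if (diff(cfg$records_range) < 0 || cfg$records_range[1] < 1)
    stop_input("`records_range` must be an increasing positive range")
  structure(cfg, class = "world_config")
}

#' Generate a complete synthetic study world
#'
#' Composes the layer, ecoregion, exclusion, taxon and phylogeny generators
#' into one seeded world.  Regeneration with the same configuration is
#' bit-identical.
#'
#' @param config a [world_config()].
#' @return list of class `synthetic_world`: `env_layers`, `ecoregions`,
#'   `exclusion_mask`, `taxa` (list of `taxon_truth`), `records` (all taxa
#'   combined), `tree`, `life_history` (named vector, annual/perennial),
#'   `config`.
#' @export
make_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  cfg <- config
  seed <- as.integer(cfg$seed)
  env <- make_env_layers(cfg$n_env_layers, cfg$nrow, cfg$ncol,
                         cfg$correlation_length, seed = seed,
                         origin_lon = cfg$origin_lon,
                         origin_lat = cfg$origin_lat,
                         cell_size = cfg$cell_size,
                         n_latent = cfg$n_latent,
                         latent_noise = cfg$latent_noise)
  eco <- make_ecoregions(env[[1L]], cfg$n_ecoregions, seed = seed + 1L)
  excl <- make_exclusion_mask(env[[1L]], cfg$exclusion_fraction,
                              seed = seed + 2L)
  taxa_names <- sprintf("taxon%02d", seq_len(cfg$n_taxa))
  niche_vars <- names(env)[seq_len(cfg$n_niche_vars)]
  tt <- make_tree_and_traits(cfg$n_taxa, seed = seed + 3L, mode = "BM",
                             sigma2 = cfg$bm_sigma2,
                             n_traits = cfg$n_niche_vars,
                             tip_labels = taxa_names)
  # centre and scale the evolved optima per variable (a linear map, so the
  # phylogenetic structure is preserved) to match the standardised layers
  centers <- apply(tt$traits, 2L, function(x) (x - mean(x)) / stats::sd(x))
  rownames(centers) <- rownames(tt$traits)  # tree tip order, not 1..n
  centers <- centers[taxa_names, , drop = FALSE]
  colnames(centers) <- niche_vars
  per_taxon <- with_seed(seed + 4L, {
    data.frame(
      taxon = taxa_names,
      n_records = sample(cfg$records_range[1L]:cfg$records_range[2L],
                         cfg$n_taxa, replace = TRUE),
      germplasm_fraction = stats::runif(cfg$n_taxa,
                                        cfg$germplasm_range[1L],
                                        cfg$germplasm_range[2L]),
      life_history = sample(c("annual", "perennial"), cfg$n_taxa,
                            replace = TRUE),
      stringsAsFactors = FALSE)
  })
  breadths <- with_seed(seed + 5L,
    matrix(stats::rlnorm(cfg$n_taxa * cfg$n_niche_vars,
                         cfg$breadth_meanlog, cfg$breadth_sdlog),
           cfg$n_taxa, cfg$n_niche_vars,
           dimnames = list(taxa_names, niche_vars)))
  taxa <- lapply(seq_len(cfg$n_taxa), function(i)
    make_taxon(env, taxa_names[i],
               centers = stats::setNames(centers[i, ], niche_vars),
               breadths = stats::setNames(breadths[i, ], niche_vars),
               n_records = per_taxon$n_records[i],
               coord_fraction = cfg$coord_fraction,
               germplasm_fraction = per_taxon$germplasm_fraction[i],
               seed = seed + 10L + i))
  names(taxa) <- taxa_names
  records <- do.call(rbind, lapply(taxa, `[[`, "records"))
  rownames(records) <- NULL
  structure(list(env_layers = env, ecoregions = eco, exclusion_mask = excl,
                 taxa = taxa, records = records, tree = tt$tree,
                 life_history = stats::setNames(per_taxon$life_history,
                                                taxa_names),
                 config = cfg),
            class = "synthetic_world")
}

#' Write a synthetic world to a directory
#'
#' Exports everything a shell pipeline can consume: `occ.csv`, ASCII-grid
#' rasters under `layers/` and `suitability/`, `eco.asc`, `exclusion.asc`,
#' `tree.nwk`, and `truth.json` recording every generator parameter.
#'
#' @param world a `synthetic_world`.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(file.path(dir, "layers"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "suitability"), showWarnings = FALSE)
  utils::write.csv(world$records, file.path(dir, "occ.csv"),
                   row.names = FALSE)
  for (nm in names(world$env_layers))
    write_ascii_grid(world$env_layers[[nm]],
                     file.path(dir, "layers", paste0(nm, ".asc")))
  write_ascii_grid(world$ecoregions, file.path(dir, "eco.asc"))
  write_ascii_grid(world$exclusion_mask, file.path(dir, "exclusion.asc"))
  for (nm in names(world$taxa))
    write_ascii_grid(world$taxa[[nm]]$suitability,
                     file.path(dir, "suitability", paste0(nm, ".asc")))
  ape::write.tree(world$tree, file.path(dir, "tree.nwk"))
  truth <- list(
    config = unclass(world$config),
    life_history = as.list(world$life_history),
    taxa = lapply(world$taxa, function(t)
      list(centers = as.list(t$centers), breadths = as.list(t$breadths),
           n_records = t$n_records,
           germplasm_fraction = t$germplasm_fraction)))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a synthetic world directory
#'
#' @param dir directory produced by [write_world()].
#' @return a `synthetic_world`-shaped list (without the full `taxon_truth`
#'   record split, which lives in `occ.csv`).
#' @export
read_world <- function(dir) {
  layer_files <- sort(list.files(file.path(dir, "layers"),
                                 pattern = "\\.asc$", full.names = TRUE))
  env <- lapply(layer_files, read_ascii_grid)
  names(env) <- sub("\\.asc$", "", basename(layer_files))
  suit_files <- sort(list.files(file.path(dir, "suitability"),
                                pattern = "\\.asc$", full.names = TRUE))
  suit <- lapply(suit_files, read_ascii_grid)
  names(suit) <- sub("\\.asc$", "", basename(suit_files))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  structure(list(
    env_layers = env,
    ecoregions = read_ascii_grid(file.path(dir, "eco.asc")),
    exclusion_mask = binary_range(
      read_ascii_grid(file.path(dir, "exclusion.asc"))),
    suitability = suit,
    records = load_occurrences(file.path(dir, "occ.csv")),
    tree = ape::read.tree(file.path(dir, "tree.nwk")),
    life_history = unlist(truth$life_history),
    config = truth$config), class = "synthetic_world_dir")
}
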