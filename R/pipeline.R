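#' Analysis configuration
#'
#' All tunable constants of the gap-analysis pipeline in one validated
#' object.  Defaults follow the standard methodology: 50-km collecting
#' buffers, five-fold validation against 10,000 background points, the
#' ATAUC > 0.7 / STAUC < 0.15 / ASD15 validity rule, three principal
#' components and three clusters for the environmental typology, and 1000
#' permutations for the phylogenetic statistics.  Unknown keys are
#' rejected.
#'
#' @param buffer_radius_km collecting-buffer radius (km).
#' @param k_folds cross-validation folds.
#' @param background_n background points for AUC and thresholding.
#' @param atauc_min,stauc_max,asd_cut,asd_frac,asd_rule model-validity
#'   constants (see [validate_model()]).
#' @param pcs leading principal components used for clustering.
#' @param clusters number of environmental clusters.
#' @param n_perm permutations for Blomberg's K and the Mantel test.
#' @param sympatry_cells minimum shared cells for a sympatry call.
#' @param perfect_tol tolerance of the "perfect overlap" summary rule.
#' @param fold_noise_sd noise SD of the surrogate fold surfaces built for
#'   suitability truths (synthetic worlds only).
#' @param min_points minimum occurrence points for a taxon to enter
#'   clustering and signal estimation.
#' @param seed master RNG seed of a run.
#' @param ... unknown keys; supplying any is an error.
#' @return a `run_config` list.
#' @export
run_config <- function(buffer_radius_km = 50, k_folds = 5,
                       background_n = 10000, atauc_min = 0.7,
                       stauc_max = 0.15, asd_cut = 0.15, asd_frac = 0.10,
                       asd_rule = "literal", pcs = 3, clusters = 3,
                       n_perm = 1000, sympatry_cells = 1,
                       perfect_tol = 1e-6, fold_noise_sd = 0.08,
                       min_points = 3, seed = 1, ...) {
  extra <- list(...)
  if (length(extra) > 0L)
    stop_input("unknown configuration key(s): ",
               paste(names(extra), collapse = ", "))
  cfg <- list(buffer_radius_km = buffer_radius_km, k_folds = k_folds,
              background_n = background_n, atauc_min = atauc_min,
              stauc_max = stauc_max, asd_cut = asd_cut,
              asd_frac = asd_frac, asd_rule = asd_rule, pcs = pcs,
              clusters = clusters, n_perm = n_perm,
              sympatry_cells = sympatry_cells, perfect_tol = perfect_tol,
              fold_noise_sd = fold_noise_sd, min_points = min_points,
              seed = seed)
  stopifnot(cfg$buffer_radius_km > 0, cfg$k_folds >= 2,
            cfg$background_n >= 1, cfg$atauc_min >= 0, cfg$atauc_min <= 1,
            cfg$stauc_max > 0, cfg$asd_cut > 0,
            cfg$asd_frac >= 0, cfg$asd_frac <= 1,
            cfg$asd_rule %in% c("literal", "strict"),
              cfg$pcs >= 1, cfg$clusters >= 1, cfg$n_perm >= 1,
            cfg$sympatry_cells >= 1, cfg$fold_noise_sd >= 0,
            cfg$min_points >= 1)
  structure(cfg, class = "run_config")
}

# Pull the per-taxon suitability surfaces out of either world flavour.
world_suitability <- function(world) {
  if (!is.null(world$taxa))
    lapply(world$taxa, `[[`, "suitability")
  else world$suitability
}

#' Run the full gap-analysis pipeline
#'
#' End-to-end orchestration over a (synthetic or loaded) world: record
#' cleaning, per-taxon model validation with buffer fallback, SRS/GRS/ERS/
#' FPS scoring and priority bands, collecting-gap and hotspot maps,
#' pairwise range and niche overlap with cohort summaries, environmental
#' ordination and clustering, per-variable Blomberg's K and a Mantel test
#' of environmental versus phylogenetic distance.  The run is a pure
#' function of (world, config): rerunning with the same inputs reproduces
#' every output byte for byte.
#'
#' @param world a `synthetic_world` from [make_world()] or a directory
#'   world from [read_world()].
#' @param out_dir optional directory; when given, writes `scores.csv`,
#'   `overlap.csv`, `summary.csv`, `clusters.csv`, `ksignal.csv`,
#'   `run.json`, `run.log` and `rasters/`.
#' @param config a [run_config()].
#' @return invisible list with elements `scores`, `priority`, `overlap`,
#'   `summary`, `asymmetry_pp`, `clusters`, `pca`, `ksignal`,
#'   `conservatism`, `mantel`, `metrics`, `ranges`, `hotspot`, `richness`.
#' @export
run_pipeline <- function(world, out_dir = NULL, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- as.integer(config$seed)
  env <- world$env_layers
  template <- env[[1L]]
  eco <- world$ecoregions
  excl <- world$exclusion_mask
  suit <- world_suitability(world)
  records <- deduplicate(occurrence_records(world$records))
  taxa <- sort(unique(records$taxon))
  log_lines <- c(sprintf("gapkit run, seed %d", seed),
                 sprintf("taxa: %d, records: %d (after de-duplication)",
                         length(taxa), nrow(records)),
                 sprintf("config: %s",
                         paste(names(config), unlist(config), sep = "=",
                               collapse = ", ")))

  # --- per-taxon validation, realised range, gap scores ------------------
  valid_cells <- which(!is.na(template$values))
  scores <- NULL
  metrics_list <- list()
  ranges <- list()
  surfaces <- list()
  gap_maps <- list()
  for (i in seq_along(taxa)) {
    tx <- taxa[i]
    tseed <- seed + 1000L + i
    cnt <- partition_counts(records, tx)
    r <- records[records$taxon == tx & !is.na(records$lon), , drop = FALSE]
    pts <- cbind(r$lon, r$lat)
    surface <- suit[[tx]]
    metrics <- NULL
    threshold <- NULL
    if (!is.null(surface) && nrow(pts) >= config$k_folds) {
      folds <- kfold_split(nrow(pts), config$k_folds, seed = tseed)
      fold_surfs <- make_fold_surfaces(surface, config$k_folds,
                                       noise_sd = config$fold_noise_sd,
                                       seed = tseed + 1L)
      bg_cells <- with_seed(tseed + 2L,
                            sample(valid_cells, config$background_n,
                                   replace = TRUE))
      bg_scores <- lapply(fold_surfs, function(s) s$values[bg_cells])
      metrics <- validate_model(fold_surfs, pts, folds, bg_scores,
                                atauc_min = config$atauc_min,
                                stauc_max = config$stauc_max,
                                asd_cut = config$asd_cut,
                                asd_frac = config$asd_frac,
                                asd_rule = config$asd_rule)
      if (metrics$valid)
        threshold <- roc_threshold(surface, pts,
                                   surface$values[bg_cells])
    }
    rng <- realized_range(surface, metrics, pts, template, threshold,
                          exclusion_mask = excl,
                          radius_km = config$buffer_radius_km)
    g <- records[records$taxon == tx & records$type == "G" &
                   !is.na(records$lon), , drop = FALSE]
    gbuf <- if (nrow(g) > 0L)
      circular_buffer_range(g$lon, g$lat, template,
                            radius_km = config$buffer_radius_km)
    else NULL
    row <- fps_classify(srs(cnt$n_G, cnt$n_H),
                        grs(gbuf, rng),
                        ers(eco, rng, gbuf), taxon = tx)
    row$provenance <- attr(rng, "provenance")
    row$ATAUC <- if (is.null(metrics)) NA_real_ else metrics$ATAUC
    row$STAUC <- if (is.null(metrics)) NA_real_ else metrics$STAUC
    row$model_valid <- !is.null(metrics) && metrics$valid
    scores <- rbind(scores, row)
    metrics_list[[tx]] <- metrics
    ranges[[tx]] <- rng
    surfaces[[tx]] <- if (row$provenance == "model")
      apply_exclusion_mask(surface, excl) else rng
    gap_maps[[tx]] <- collecting_gap_map(rng, gbuf)
  }
  priority <- priority_table(scores)
  hps <- as.character(scores$taxon[scores$category == "HPS"])
  hotspot <- if (length(hps) > 0L) hotspot_map(gap_maps[hps]) else NULL
  richness <- richness_map(ranges)
  log_lines <- c(log_lines,
                 sprintf("valid models: %d of %d taxa",
                         sum(scores$model_valid), nrow(scores)),
                 sprintf("priority split: %s",
                         paste(priority$categories$category,
                               round(priority$categories$percent, 1),
                               sep = "=", collapse = "%, ")))

  # --- pairwise overlap ---------------------------------------------------
  overlap <- pairwise_overlap(ranges, surfaces,
                              sympatry_cells = config$sympatry_cells)
  life <- world$life_history
  sisters <- sister_pairs(world$tree)
  sister_key <- paste(sisters[, 1L], sisters[, 2L])
  cohorts <- list(
    all = rep(TRUE, nrow(overlap)),
    annual = life[overlap$taxonA] == "annual" &
      life[overlap$taxonB] == "annual",
    perennial = life[overlap$taxonA] == "perennial" &
      life[overlap$taxonB] == "perennial",
    allopatric = !overlap$sympatric,
    sympatric = overlap$sympatric,
    sister = paste(overlap$taxonA, overlap$taxonB) %in% sister_key)
  if (is.null(life)) cohorts$annual <- cohorts$perennial <- NULL
  summary_tab <- overlap_summary(overlap, cohorts,
                                 perfect_tol = config$perfect_tol)
  asym <- asymmetry_stat(overlap)

  # --- environmental ordination and clustering ---------------------------
  pt_rec <- records[!is.na(records$lon), , drop = FALSE]
  pt_env <- extract_env(pt_rec$lon, pt_rec$lat, env)
  pt_keep <- attr(pt_env, "n_dropped") == 0L
  pt_taxa <- if (pt_keep) pt_rec$taxon else {
    # re-derive which rows survived extraction
    full <- sapply(env, function(l) {
      rc <- point_cell(l, pt_rec$lon, pt_rec$lat)
      v <- rep(NA_real_, nrow(rc))
      ins <- !is.na(rc[, "row"])
      v[ins] <- l$values[rc[ins, , drop = FALSE]]
      v
    })
    pt_rec$taxon[stats::complete.cases(full)]
  }
  enough <- names(which(table(pt_taxa) >= config$min_points))
  keep_pt <- pt_taxa %in% enough
  pca <- env_pca(pt_env[keep_pt, , drop = FALSE], standardize = TRUE)
  clus <- hcpc_clusters(pca$scores, pt_taxa[keep_pt],
                        k = config$clusters, m = config$pcs)

  # --- phylogenetic signal and distance correlation ----------------------
  traits <- suppressWarnings(
    trait_table(records, env, min_points = config$min_points))
  tree <- ape::keep.tip(world$tree,
                        intersect(world$tree$tip.label, rownames(traits)))
  traits <- traits[tree$tip.label, , drop = FALSE]
  ksignal <- do.call(rbind, lapply(seq_len(ncol(traits)), function(j) {
    kr <- blomberg_k(tree, stats::setNames(traits[, j], rownames(traits)),
                     n_perm = config$n_perm, seed = seed + 5000L + j)
    data.frame(variable = colnames(traits)[j], K = kr$K,
               p_value = kr$p_value, stringsAsFactors = FALSE)
  }))
  ksignal$p_adj_BH <- stats::p.adjust(ksignal$p_value, method = "BH")
  conserv <- conservatism_fraction(ksignal)
  mant <- mantel_test(mahalanobis_dist(traits), cophenetic_dist(tree),
                      n_perm = config$n_perm, seed = seed + 6000L)
  log_lines <- c(log_lines,
                 sprintf("pairwise comparisons: %d; sympatric: %.1f%%",
                         nrow(overlap), 100 * mean(overlap$sympatric)),
                 sprintf("conservatism: %.1f%% of variables (p < 0.05)",
                         100 * conserv),
                 sprintf("Mantel r = %.4f (p = %.4g)", mant$r,
                         mant$p_value))

  result <- list(scores = scores, priority = priority, overlap = overlap,
                 summary = summary_tab, asymmetry_pp = asym,
                 clusters = clus, pca = pca, ksignal = ksignal,
                 conservatism = conserv, mantel = mant,
                 metrics = metrics_list, ranges = ranges,
                 hotspot = hotspot, richness = richness)
  if (!is.null(out_dir)) write_run(result, out_dir, config, log_lines)
  invisible(result)
}

# Serialise a pipeline result: CSV tables, ASCII rasters, human log and a
# machine-readable JSON sidecar.
write_run <- function(result, out_dir, config, log_lines) {
  dir.create(file.path(out_dir, "rasters"), recursive = TRUE,
             showWarnings = FALSE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(result$priority$taxa, "scores.csv")
  wcsv(result$overlap, "overlap.csv")
  wcsv(result$summary, "summary.csv")
  wcsv(data.frame(taxon = names(result$clusters$assignment),
                  cluster = result$clusters$assignment), "clusters.csv")
  wcsv(result$ksignal, "ksignal.csv")
  if (!is.null(result$hotspot))
    write_ascii_grid(result$hotspot,
                     file.path(out_dir, "rasters", "hotspot.asc"))
  write_ascii_grid(result$richness,
                   file.path(out_dir, "rasters", "richness.asc"))
  jsonlite::write_json(
    list(config = unclass(config),
         mantel = list(r = result$mantel$r,
                       p_value = result$mantel$p_value),
         conservatism_fraction = result$conservatism,
         asymmetry_pp = result$asymmetry_pp,
         pc_variance_fractions = result$pca$variance_fractions,
         categories = result$priority$categories),
    file.path(out_dir, "run.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
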