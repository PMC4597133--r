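#' Sampling representativeness score (SRS)
#'
#' Ten times the proportion of a taxon's records that are germplasm
#' accessions: `10 * n_G / (n_G + n_H)`.  All records count, with or
#' without coordinates.  The x10 scaling puts the score on the 0-10 scale
#' shared by the other representativeness scores and the priority bands.
#'
#' @param n_G germplasm record count.
#' @param n_H reference (herbarium) record count.
#' @return score in \[0, 10\].
#' @export
srs <- function(n_G, n_H) {
  stopifnot(n_G >= 0, n_H >= 0)
  if (n_G + n_H == 0)
    stop_input("no records at all: SRS undefined")
  10 * n_G / (n_G + n_H)
}

#' Geographic representativeness score (GRS)
#'
#' Ten times the fraction of the taxon's potential distribution area covered
#' by 50-km buffers around its germplasm collection sites, using
#' cosine-latitude-weighted cell areas.
#'
#' @param germplasm_buffers `binary_range` of buffered germplasm points, or
#'   `NULL` when the taxon has no mappable germplasm (score 0).
#' @param range `binary_range` potential distribution (non-empty).
#' @return score in \[0, 10\].
#' @export
grs <- function(germplasm_buffers, range) {
  stopifnot(is_binary_range(range))
  if (range$cell_count == 0)
    stop_input("empty potential distribution: GRS undefined")
  if (is.null(germplasm_buffers)) return(0)
  stopifnot(is_binary_range(germplasm_buffers))
  check_aligned(germplasm_buffers, range)
  inter <- range_intersection(range, germplasm_buffers)
  10 * inter$area_km2 / range$area_km2
}

# Cellwise AND of two aligned binary ranges.
range_intersection <- function(a, b) {
  out <- a
  class(out) <- "grid_layer"
  out$cell_count <- NULL; out$area_km2 <- NULL
  out$values <- ((!is.na(a$values) & a$values == 1) &
                 (!is.na(b$values) & b$values == 1)) * 1
  binary_range(out)
}

#' Ecological representativeness score (ERS)
#'
#' Compares the ecosystem classes where germplasm has been collected with
#' the full set of classes spanned by the taxon's distribution:
#' `10 * |classes in buffers AND range| / |classes in range|`.  Class
#' presence is categorical (a class either occurs or not); areas are not
#' weighted.
#'
#' @param ecoregions categorical `grid_layer` of ecosystem classes.
#' @param range `binary_range` potential distribution.
#' @param germplasm_buffers `binary_range` of buffered germplasm points, or
#'   `NULL` (score 0).
#' @return score in \[0, 10\].
#' @export
ers <- function(ecoregions, range, germplasm_buffers) {
  stopifnot(is_grid_layer(ecoregions), is_binary_range(range))
  check_aligned(ecoregions, range)
  in_range <- !is.na(range$values) & range$values == 1
  range_classes <- unique(ecoregions$values[in_range])
  range_classes <- range_classes[!is.na(range_classes)]
  if (length(range_classes) == 0L)
    stop_input("range covers only cells with no ecoregion class: ERS undefined")
  if (is.null(germplasm_buffers)) return(0)
  stopifnot(is_binary_range(germplasm_buffers))
  check_aligned(ecoregions, germplasm_buffers)
  in_both <- in_range & !is.na(germplasm_buffers$values) &
    germplasm_buffers$values == 1
  got <- unique(ecoregions$values[in_both])
  got <- got[!is.na(got)]
  10 * length(intersect(got, range_classes)) / length(range_classes)
}

#' Final prioritization score and priority band
#'
#' FPS is the equal-weight mean of SRS, GRS and ERS.  Priority bands follow
#' the printed ranges, implemented half-open so every score falls in exactly
#' one band: high priority (HPS) for FPS in \[0, 3\], medium (MPS) in
#' (3, 5\], low (LPS) in (5, 7.5\], and no further collecting required
#' (NFCR) in (7.5, 10\].
#'
#' @param SRS,GRS,ERS component scores, each in \[0, 10\].
#' @param taxon optional taxon label carried through.
#' @return one-row data frame: `taxon`, `SRS`, `GRS`, `ERS`, `FPS`,
#'   `category` (factor HPS < MPS < LPS < NFCR).
#' @export
fps_classify <- function(SRS, GRS, ERS, taxon = NA_character_) {
  s <- c(SRS, GRS, ERS)
  if (any(!is.finite(s)) || any(s < 0 | s > 10))
    stop_input("scores must lie in [0, 10]")
  fps <- mean(s)
  category <- if (fps <= 3) "HPS" else if (fps <= 5) "MPS" else
    if (fps <= 7.5) "LPS" else "NFCR"
  data.frame(taxon = taxon, SRS = SRS, GRS = GRS, ERS = ERS, FPS = fps,
             category = factor(category, levels = priority_levels()),
             stringsAsFactors = FALSE)
}

priority_levels <- function() c("HPS", "MPS", "LPS", "NFCR")

#' Collecting-gap map
#'
#' Cells of the potential distribution not yet covered by germplasm
#' collection buffers — the candidate zones for further collecting.
#'
#' @param range `binary_range` potential distribution.
#' @param germplasm_buffers `binary_range` or `NULL`.
#' @return a `binary_range` (`range AND NOT buffers`).
#' @export
collecting_gap_map <- function(range, germplasm_buffers) {
  stopifnot(is_binary_range(range))
  pres <- !is.na(range$values) & range$values == 1
  if (!is.null(germplasm_buffers)) {
    stopifnot(is_binary_range(germplasm_buffers))
    check_aligned(range, germplasm_buffers)
    pres <- pres & !(!is.na(germplasm_buffers$values) &
                     germplasm_buffers$values == 1)
  }
  out <- range
  class(out) <- "grid_layer"
  out$cell_count <- NULL; out$area_km2 <- NULL
  out$values <- pres * 1
  binary_range(out)
}

#' Hotspot map for high-priority collecting
#'
#' Cellwise count of overlapping collecting-gap maps of high-priority taxa;
#' high values mark areas where one expedition could sample many taxa.
#'
#' @param gap_maps list of aligned `binary_range` gap maps (HPS taxa).
#' @return a `grid_layer` of counts; an empty input yields a zero map with
#'   a warning.
#' @export
hotspot_map <- function(gap_maps) {
  if (length(gap_maps) == 0L) {
    warning("no high-priority taxa: hotspot map is empty")
    return(NULL)
  }
  richness_map(gap_maps)
}

#' Priority table across taxa
#'
#' Orders taxa for reporting: by priority band (HPS first), then ascending
#' FPS, then taxon name for stability.  Expert priority scores, when
#' supplied, are joined untouched.
#'
#' @param scores data frame of per-taxon rows as from [fps_classify()].
#' @param expert optional data frame with columns `taxon` and expert score
#'   columns to pass through.
#' @return list with `taxa` (the ordered table) and `categories`
#'   (per-band counts and percentages).
#' @export
priority_table <- function(scores, expert = NULL) {
  stopifnot(is.data.frame(scores), nrow(scores) >= 1L)
  if (!is.null(expert))
    scores <- merge(scores, expert, by = "taxon", all.x = TRUE, sort = FALSE)
  scores$category <- factor(as.character(scores$category),
                            levels = priority_levels())
  ord <- order(scores$category, scores$FPS, scores$taxon)
  taxa <- scores[ord, , drop = FALSE]
  rownames(taxa) <- NULL
  n <- table(taxa$category)
  categories <- data.frame(category = names(n), n = as.integer(n),
                           percent = 100 * as.integer(n) / nrow(taxa),
                           stringsAsFactors = FALSE)
  list(taxa = taxa, categories = categories)
}
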