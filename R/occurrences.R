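#' Load occurrence records
#'
#' Reads a delimited occurrence table with columns `taxon`, `type`, `lon`,
#' `lat` and optionally `record_id` and `source`.  Darwin-Core-style aliases
#' (`decimalLongitude`, `decimalLatitude`, `scientificName`) are accepted.
#' `type` is `G` for germplasm accessions (genebank samples) or `H` for
#' reference records (herbarium vouchers, literature).  Rows whose
#' coordinates do not parse, are incomplete, or fall outside valid ranges
#' are retained with both coordinates absent, so record counts — and hence
#' the sampling representativeness score — are preserved.
#'
#' @param path CSV file (UTF-8, header required).
#' @return a data frame of occurrence records with columns `record_id`,
#'   `taxon`, `type`, `lon`, `lat`, `source`.
#' @export
load_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  alias <- c(decimalLongitude = "lon", decimallongitude = "lon",
             decimalLatitude = "lat", decimallatitude = "lat",
             scientificName = "taxon")
  hit <- names(df) %in% names(alias)
  names(df)[hit] <- alias[names(df)[hit]]
  need <- c("taxon", "type", "lon", "lat")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop_input("occurrence file lacks mandatory column(s): ",
               paste(missing_cols, collapse = ", "))
  if (!"record_id" %in% names(df))
    df$record_id <- sprintf("r%06d", seq_len(nrow(df)))
  if (!"source" %in% names(df)) df$source <- ""
  occurrence_records(data.frame(
    record_id = df$record_id, taxon = df$taxon, type = df$type,
    lon = suppressWarnings(as.numeric(df$lon)),
    lat = suppressWarnings(as.numeric(df$lat)),
    source = df$source, stringsAsFactors = FALSE))
}

#' Validate a data frame of occurrence records
#'
#' Enforces the record contract: `type` in \{G, H\}; coordinates either both
#' present and in range (longitude in \[-180, 180\], latitude in
#' \[-90, 90\]) or both absent.  Out-of-range or half-missing coordinates
#' are blanked rather than dropped.
#'
#' @param df data frame with at least `record_id`, `taxon`, `type`, `lon`,
#'   `lat`.
#' @return the validated data frame.
#' @export
occurrence_records <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("record_id", "taxon", "type", "lon", "lat")
  if (!all(need %in% names(df)))
    stop_input("records need columns: ", paste(need, collapse = ", "))
  bad_type <- !(df$type %in% c("G", "H"))
  if (any(bad_type))
    stop_input("record type must be 'G' or 'H'; offending record(s): ",
               paste(utils::head(df$record_id[bad_type], 5L), collapse = ", "))
  invalid <- is.na(df$lon) | is.na(df$lat) |
    abs(df$lat) > 90 | abs(df$lon) > 180
  df$lon[invalid] <- NA_real_
  df$lat[invalid] <- NA_real_
  if (!"source" %in% names(df)) df$source <- ""
  df
}

#' Remove duplicate records
#'
#' Records sharing taxon, record type and coordinates rounded to 4 decimal
#' places (about 11 m) are collapsed to the one with the smallest
#' `record_id`.  Record type is part of the key on purpose: a genebank
#' accession never erases a herbarium voucher collected at the same site,
#' which is the conservative choice for the sampling score.
#' Coordinate-free records are never merged.
#'
#' @param records occurrence data frame.
#' @param digits rounding applied to coordinates before comparison.
#' @return the de-duplicated data frame, original row order preserved.
#' @export
deduplicate <- function(records, digits = 4) {
  records <- occurrence_records(records)
  has_xy <- !is.na(records$lon)
  key <- ifelse(has_xy,
                paste(records$taxon, records$type,
                      sprintf("%.*f", digits, records$lon),
                      sprintf("%.*f", digits, records$lat), sep = "|"),
                paste0("nocoord|", seq_len(nrow(records))))
  ord <- order(records$record_id)
  keep_sorted <- ord[!duplicated(key[ord])]
  records[sort(keep_sorted), , drop = FALSE]
}

#' Germplasm / reference partition counts
#'
#' @param records occurrence data frame.
#' @param taxon taxon name; an unknown taxon yields zero counts.
#' @return list with `n_G`, `n_H` (all records) and `n_G_coord`,
#'   `n_H_coord` (coordinate-bearing subsets used by the spatial scores).
#' @export
partition_counts <- function(records, taxon) {
  records <- occurrence_records(records)
  r <- records[records$taxon == taxon, , drop = FALSE]
  xy <- !is.na(r$lon)
  list(n_G = sum(r$type == "G"),
       n_H = sum(r$type == "H"),
       n_G_coord = sum(r$type == "G" & xy),
       n_H_coord = sum(r$type == "H" & xy))
}

#' Restrict records to a native-area mask
#'
#' Drops coordinate-bearing records whose containing cell is absent from the
#' native mask, preventing distributions inflated beyond known native
#' boundaries.  Coordinate-free records are kept (they still count toward
#' sampling representativeness).
#'
#' @param records occurrence data frame.
#' @param native_mask `binary_range` on the analysis grid; 1 = native.
#' @return the filtered data frame.
#' @export
filter_native <- function(records, native_mask) {
  records <- occurrence_records(records)
  stopifnot(is_binary_range(native_mask))
  has_xy <- !is.na(records$lon)
  keep <- !has_xy
  if (any(has_xy)) {
    rc <- point_cell(native_mask, records$lon[has_xy], records$lat[has_xy])
    inside <- !is.na(rc[, "row"])
    val <- rep(NA_real_, nrow(rc))
    val[inside] <- native_mask$values[cbind(rc[inside, "row"],
                                            rc[inside, "col"])]
    keep[has_xy] <- !is.na(val) & val == 1
  }
  records[keep, , drop = FALSE]
}
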