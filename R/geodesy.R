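#' Great-circle distance
#'
#' Haversine distance on a sphere of radius 6371 km.  A spherical earth is
#' deliberate: at the 50-km scale of collecting buffers the ellipsoidal
#' correction is well under 1% and the sphere keeps results hand-checkable.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees; vectors are
#'   recycled.
#' @return distance(s) in kilometres.
#' @examples
#' haversine_km(0, 0, 0, 90)  # quarter circumference, ~10007.54 km
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE))
    stop_input("latitudes must lie in [-90, 90]")
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

#' Circular-buffer range around occurrence points
#'
#' Builds the CA50-style presence range used both as the fallback
#' distribution for taxa without a valid suitability model and as the
#' footprint of germplasm collections: a cell is present iff the great-circle
#' distance from its centre to the nearest point is at most `radius_km`.
#' Membership is decided at cell centres, not by polygon rasterisation.
#'
#' @param lon,lat point coordinates in degrees (records without coordinates
#'   should be dropped beforehand; `NA`s are ignored here).
#' @param template a `grid_layer` supplying the lattice.
#' @param radius_km buffer radius; default 50.
#' @return a `binary_range` aligned with `template`.
#' @export
circular_buffer_range <- function(lon, lat, template, radius_km = 50) {
  stopifnot(is_grid_layer(template))
  keep <- !is.na(lon) & !is.na(lat)
  lon <- lon[keep]; lat <- lat[keep]
  if (length(lon) == 0L)
    stop_input("no coordinate-bearing points: cannot build a buffer range")
  if (!is.finite(radius_km) || radius_km <= 0)
    stop_input("`radius_km` must be positive")
  lon_m <- cell_lon_matrix(template)
  lat_m <- cell_lat_matrix(template)
  nearest <- matrix(Inf, nrow(lon_m), ncol(lon_m))
  for (i in seq_along(lon))
    nearest <- pmin(nearest, haversine_km(lon_m, lat_m, lon[i], lat[i]))
  out <- template
  out$values <- (nearest <= radius_km) * 1
  binary_range(out)
}
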