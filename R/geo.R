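#' Great-circle distance between GPS fixes
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the IUGG mean
#' Earth radius). At city scale the error against an ellipsoid model is well
#' under 0.5%, which is negligible relative to GPS positional noise.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorized).
#' @return Distance(s) in kilometers.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371.0088)
}

#' Project coordinates to a local planar frame
#'
#' Equirectangular projection about the centroid latitude, in meters. Valid
#' at the city scales where stay-point clustering operates; used so that
#' ordinary Euclidean K-means can run on GPS fixes.
#'
#' @param lat,lon decimal degrees.
#' @param lat0 reference latitude; defaults to the mean of `lat`.
#' @return A two-column matrix (x, y) in meters.
#' @keywords internal
project_local_m <- function(lat, lon, lat0 = mean(lat)) {
  r <- 6371008.8
  x <- (lon * pi / 180) * cos(lat0 * pi / 180) * r
  y <- (lat * pi / 180) * r
  cbind(x = x, y = y)
}
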