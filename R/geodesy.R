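#' Great-circle (haversine) distance in kilometres
#'
#' Spherical haversine distance between points given in decimal degrees.
#' The Earth radius defaults to the mean radius, 6371 km.
#'
#' @param lat1,lon1 Latitude/longitude of the first point(s), degrees.
#' @param lat2,lon2 Latitude/longitude of the second point(s), degrees.
#' @param radius_km Sphere radius in km.
#' @return Numeric vector of distances in km.
#' @examples
#' haversine_km(0, 0, 0, 180) # half the Earth's circumference
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = radius_km)
}

check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(lat < -90) || any(lat > 90))
    stop("latitude out of [-90, 90]")
  if (any(!is.finite(lon)) || any(lon <= -180) || any(lon > 180))
    stop("longitude out of (-180, 180]")
  invisible(NULL)
}

#' Migration distance from an origin to non-breeding centroids
#'
#' Distance in thousands of kilometres between a fixed origin (for the
#' source dataset, the centroid of the Jutland part of Denmark) and each
#' species' non-breeding-range centroid. Sedentary species get distance 0
#' by definition; migratory species must have centroid coordinates.
#'
#' @param records Data frame with columns `species`, `status` (`"sedentary"`
#'   or `"migratory"`), `lat`, `lon` (centroid, degrees; may be `NA` for
#'   sedentary species).
#' @param origin_lat,origin_lon Origin coordinates in degrees.
#' @param radius_km Sphere radius in km.
#' @return Data frame with columns `species` and `distance` (thousands of km).
#' @export
migration_distance <- function(records, origin_lat, origin_lon,
                               radius_km = 6371) {
  stopifnot(is.data.frame(records),
            all(c("species", "status", "lat", "lon") %in% names(records)))
  if (!all(records$status %in% c("sedentary", "migratory")))
    stop("status must be 'sedentary' or 'migratory'")
  mig <- records$status == "migratory"
  if (any(mig & (is.na(records$lat) | is.na(records$lon))))
    stop("migratory species without centroid coordinates: ",
         paste(records$species[mig & (is.na(records$lat) | is.na(records$lon))],
               collapse = ", "))
  d <- numeric(nrow(records))
  if (any(mig))
    d[mig] <- haversine_km(records$lat[mig], records$lon[mig],
                           origin_lat, origin_lon,
                           radius_km = radius_km) / 1000
  data.frame(species = records$species, distance = d,
             row.names = NULL, stringsAsFactors = FALSE)
}
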