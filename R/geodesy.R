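# Mean Earth radius (km) used for all great-circle computations.
EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance between two points
#'
#' Haversine distance in kilometres on a sphere of radius 6371.0088 km.
#' Coordinates are unprojected decimal degrees; great-circle distance is
#' the appropriate metric for a study region spanning thousands of km.
#'
#' @param p1,p2 Numeric vectors `c(lat, lon)` in decimal degrees, or
#'   two-column matrices `(lat, lon)` for vectorised use.
#' @return Distance(s) in km.
#' @export
#' @examples
#' haversine_km(c(48.2, 16.37), c(52.23, 21.01)) # Vienna - Warsaw
haversine_km <- function(p1, p2) {
  to_lonlat <- function(p) {
    if (is.null(dim(p))) p <- matrix(p, ncol = 2, byrow = TRUE)
    cbind(p[, 2], p[, 1]) # geosphere expects (lon, lat)
  }
  geosphere::distHaversine(to_lonlat(p1), to_lonlat(p2), r = EARTH_RADIUS_KM)
}

#' Pairwise great-circle distance matrix
#'
#' @param sites A data frame with `lat` and `lon` columns (decimal
#'   degrees), one row per site.
#' @return A symmetric n x n matrix of distances in km with zero
#'   diagonal.
#' @export
distance_matrix <- function(sites) {
  stopifnot(nrow(sites) >= 1)
  ll <- cbind(sites$lon, sites$lat)
  d <- geosphere::distm(ll, ll, fun = function(x, y) {
    geosphere::distHaversine(x, y, r = EARTH_RADIUS_KM)
  })
  dimnames(d) <- NULL
  d
}

# cross-distance matrix (km) between two site tables; rows = a, cols = b
cross_distance_matrix <- function(a, b) {
  d <- geosphere::distm(
    cbind(a$lon, a$lat), cbind(b$lon, b$lat),
    fun = function(x, y) geosphere::distHaversine(x, y, r = EARTH_RADIUS_KM)
  )
  dimnames(d) <- NULL
  d
}

#' Build a regular latitude-longitude prediction grid
#'
#' Full Cartesian lattice over a bounding box. Both boundary rows and
#' columns are included whenever the span is an integer multiple of the
#' resolution. The default box covers the European native range of the
#' host fly, including western Russia.
#'
#' @param bbox Named or positional numeric vector
#'   `(lat_min, lat_max, lon_min, lon_max)` in decimal degrees.
#' @param resolution Grid spacing in decimal degrees (> 0).
#' @return A tibble of grid points with columns `lat`, `lon`, carrying
#'   the bbox and resolution as attributes.
#' @export
#' @examples
#' make_grid(c(35, 70, -10, 60), resolution = 0.5) # 71 x 141 points
make_grid <- function(bbox = c(34, 71, -11, 61), resolution = 0.5) {
  bbox <- as.numeric(bbox)
  if (length(bbox) != 4) abort("bbox must have 4 elements", class = "wolb_domain_error")
  names(bbox) <- c("lat_min", "lat_max", "lon_min", "lon_max")
  if (bbox["lat_min"] >= bbox["lat_max"] || bbox["lon_min"] >= bbox["lon_max"]) {
    abort("bbox must satisfy lat_min < lat_max and lon_min < lon_max",
      class = "wolb_domain_error"
    )
  }
  if (resolution <= 0) abort("resolution must be > 0", class = "wolb_domain_error")
  axis_points <- function(lo, hi) {
    # include hi when the span is an integer multiple of the resolution
    # (up to fp tolerance); otherwise stop short of it
    n_steps <- floor((hi - lo) / resolution + 1e-9)
    lo + resolution * seq(0, n_steps)
  }
  lats <- axis_points(bbox["lat_min"], bbox["lat_max"])
  lons <- axis_points(bbox["lon_min"], bbox["lon_max"])
  grid <- tidyr::expand_grid(lat = lats, lon = lons)
  attr(grid, "bbox") <- bbox
  attr(grid, "resolution") <- resolution
  grid
}

#' Export grid or surface points as GeoJSON
#'
#' Writes a GeoJSON `FeatureCollection` of points; any columns beyond
#' `lat`/`lon` become feature properties.
#'
#' @param points A data frame with `lat` and `lon` columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_geojson_points <- function(points, path) {
  extra <- setdiff(names(points), c("lat", "lon"))
  features <- purrr::pmap(points, function(lat, lon, ...) {
    props <- list(...)
    list(
      type = "Feature",
      geometry = list(type = "Point", coordinates = c(lon, lat)),
      properties = if (length(props)) props else setNames(list(), character(0))
    )
  })
  obj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
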