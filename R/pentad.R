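#' Decode a pentad code into grid-cell coordinates
#'
#' Pentads are 5-arc-minute by 5-arc-minute atlas grid cells named after
#' their north-west corner, in the `ddmm_dddmm` style used by southern
#' African atlas projects: the part before the underscore gives degrees and
#' minutes of latitude *south*, the part after gives degrees and minutes of
#' longitude *east*. `"3355_1825"` is the cell whose north-west corner lies
#' at 33 deg 55 min S, 18 deg 25 min E. The longitude field may carry a
#' three-digit degree part (`"0000_00000"` is the origin cell).
#'
#' Coordinates are returned in decimal degrees with south negative. The
#' cell is half-open toward the south-east: it contains latitudes in
#' `(lat_min - 5', lat_min]` and longitudes in `[lon_min, lon_min + 5')`,
#' so every point on the grid belongs to exactly one pentad. The midpoint
#' lies 2.5 arc-minutes south and east of the named corner.
#'
#' @param code character vector of pentad codes.
#' @return A data.frame of class `pentad_code` with columns `code`,
#'   `lat_min`, `lon_min` (NW corner, decimal degrees) and `midpoint_lat`,
#'   `midpoint_lon`.
#' @seealso [encode_pentad()]
#' @examples
#' decode_pentad("3355_1825")
#' @export
decode_pentad <- function(code) {
  if (!is.character(code) || length(code) == 0) {
    stop("`code` must be a non-empty character vector", call. = FALSE)
  }
  ok <- grepl("^[0-9]{4}_[0-9]{4,5}$", code)
  if (any(!ok)) {
    bad <- code[!ok][1L]
    stop(sprintf("malformed pentad code '%s': expected ddmm_dddmm digits", bad),
         call. = FALSE)
  }
  lat_part <- sub("_.*$", "", code)
  lon_part <- sub("^.*_", "", code)
  lat_deg <- as.integer(substr(lat_part, 1L, 2L))
  lat_min_part <- as.integer(substr(lat_part, 3L, 4L))
  nlon <- nchar(lon_part)
  lon_deg <- as.integer(substr(lon_part, 1L, nlon - 2L))
  lon_min_part <- as.integer(substr(lon_part, nlon - 1L, nlon))
  bad_min <- lat_min_part %% 5L != 0L | lon_min_part %% 5L != 0L |
    lat_min_part >= 60L | lon_min_part >= 60L
  if (any(bad_min)) {
    stop(sprintf(
      "malformed pentad code '%s': minutes field must be a multiple of 5 below 60",
      code[bad_min][1L]), call. = FALSE)
  }
  lat_corner <- -(lat_deg + lat_min_part / 60)
  lon_corner <- lon_deg + lon_min_part / 60
  out <- data.frame(
    code = code,
    lat_min = lat_corner,
    lon_min = lon_corner,
    midpoint_lat = lat_corner - 2.5 / 60,
    midpoint_lon = lon_corner + 2.5 / 60,
    stringsAsFactors = FALSE
  )
  class(out) <- c("pentad_code", "data.frame")
  out
}

#' Encode coordinates as a pentad code
#'
#' Maps decimal-degree coordinates (south negative, east positive) to the
#' code of the pentad containing them, under the half-open cell convention
#' of [decode_pentad()]. Any point in a cell — corner, midpoint or interior
#' — encodes to the same code.
#'
#' @param lat,lon numeric vectors of coordinates in decimal degrees.
#' @return character vector of pentad codes.
#' @examples
#' encode_pentad(-33.9583, 18.4583) # "3355_1825"
#' @export
encode_pentad <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (any(lat > 0)) {
    stop("only southern-hemisphere latitudes (lat <= 0) are on this grid",
         call. = FALSE)
  }
  if (any(lon < 0)) {
    stop("only eastern longitudes (lon >= 0) are on this grid", call. = FALSE)
  }
  # cell index counted in 5' steps; a corner coordinate belongs to the
  # cell extending south-east of it (half-open convention)
  s <- -lat
  lat_idx <- floor(round(s * 12, 9))
  lon_idx <- floor(round(lon * 12, 9))
  lat_deg <- lat_idx %/% 12L
  lat_mm <- (lat_idx %% 12L) * 5L
  lon_deg <- lon_idx %/% 12L
  lon_mm <- (lon_idx %% 12L) * 5L
  sprintf("%02d%02d_%02d%02d", lat_deg, lat_mm, lon_deg, lon_mm)
}

#' @export
print.pentad_code <- function(x, ...) {
  cat(sprintf("<pentad_code> %d cell(s)\n", nrow(x)))
  print.data.frame(utils::head(x, 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0 km, the convention used
#' throughout the package for hub and road distances. Distances enter the
#' effort model only through a log transform, so the sub-0.3 percent error
#' of the spherical approximation is immaterial.
#'
#' @param a,b numeric length-2 vectors `c(lat, lon)` in decimal degrees, or
#'   two-column matrices (recycled against each other).
#' @return numeric vector of distances in km.
#' @examples
#' haversine_km(c(0, 0), c(1, 0)) # one degree of latitude, ~111.195 km
#' @export
haversine_km <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 2)
  b <- matrix(as.numeric(b), ncol = 2)
  # geosphere expects lon-lat order and returns metres
  geosphere::distHaversine(a[, 2:1, drop = FALSE], b[, 2:1, drop = FALSE],
                           r = 6371.0) # r in km -> result in km
}

#' Minimum distance from a pentad midpoint to a landmark set
#'
#' Roads are consumed as densified polyline vertex lists (vertex spacing of
#' about 1 km or less is expected of the caller), so the point-to-vertex
#' minimum approximates the point-to-line distance to within half the
#' vertex spacing. Hub landmark sets are simply hub pentad midpoints.
#'
#' @param pentad a single-row [decode_pentad()] result, a pentad code
#'   string, or a length-2 `c(lat, lon)` vector.
#' @param landmarks a two-column matrix or data.frame of `lat, lon`
#'   landmark coordinates in decimal degrees.
#' @return minimum haversine distance in km.
#' @export
min_distance_km <- function(pentad, landmarks) {
  if (is.character(pentad)) pentad <- decode_pentad(pentad)
  if (inherits(pentad, "pentad_code") || is.data.frame(pentad)) {
    stopifnot(nrow(pentad) == 1L)
    p <- c(pentad$midpoint_lat, pentad$midpoint_lon)
  } else {
    p <- as.numeric(pentad)
  }
  landmarks <- as.matrix(landmarks)
  if (nrow(landmarks) == 0L) {
    stop("landmark set is empty", call. = FALSE)
  }
  min(haversine_km(matrix(p, nrow = nrow(landmarks), ncol = 2, byrow = TRUE),
                   landmarks))
}
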