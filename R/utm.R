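# WGS84 <-> UTM, Snyder transverse-Mercator series. Distances between trees
# within a city are what matter downstream, so one zone (the centroid's) is
# used for a whole city even if it straddles a zone boundary.

WGS84_A <- 6378137.0
WGS84_F <- 1 / 298.257223563
UTM_K0 <- 0.9996
UTM_FE <- 500000.0
UTM_FN_SOUTH <- 10000000.0

#' UTM zone of a longitude
#' @param lon longitude, decimal degrees.
#' @return integer zone 1-60.
#' @export
utm_zone <- function(lon) {
  z <- floor((lon + 180) / 6) + 1
  as.integer(pmin(pmax(z, 1), 60))
}

#' Project WGS84 coordinates to UTM
#'
#' Forward transverse-Mercator projection so that tree-to-tree distances are
#' in meters. All points are projected in a single zone (by default the zone
#' of the centroid), keeping intra-city geometry consistent.
#'
#' @param lat,lon decimal degrees (vectors); `|lat|` must be <= 84.
#' @param zone optional zone override; default: zone of `mean(lon)`.
#' @return data frame `easting`, `northing` (meters), `zone`, `hemisphere`.
#' @export
to_planar <- function(lat, lon, zone = NULL) {
  stopifnot(length(lat) == length(lon))
  if (any(abs(lat) > 84, na.rm = TRUE))
    stop("polar latitudes (|lat| > 84) are not supported by UTM")
  if (is.null(zone)) zone <- utm_zone(mean(lon, na.rm = TRUE))
  south <- mean(lat, na.rm = TRUE) < 0
  lon0 <- (zone - 1) * 6 - 180 + 3

  a <- WGS84_A; f <- WGS84_F
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2)
  phi <- lat * pi / 180
  dlam <- (lon - lon0) * pi / 180

  N <- a / sqrt(1 - e2 * sin(phi)^2)
  T <- tan(phi)^2
  C <- ep2 * cos(phi)^2
  A <- cos(phi) * dlam
  M <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
            (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
            (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
            (35 * e2^3 / 3072) * sin(6 * phi))
  easting <- UTM_K0 * N * (A + (1 - T + C) * A^3 / 6 +
             (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120) + UTM_FE
  northing <- UTM_K0 * (M + N * tan(phi) *
              (A^2 / 2 + (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
               (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720))
  if (south) northing <- northing + UTM_FN_SOUTH
  data.frame(easting = easting, northing = northing, zone = zone,
             hemisphere = if (south) "S" else "N",
             stringsAsFactors = FALSE)
}

#' Inverse UTM projection
#'
#' @param easting,northing meters.
#' @param zone UTM zone.
#' @param hemisphere `"N"` or `"S"`.
#' @return data frame `latitude`, `longitude` in decimal degrees.
#' @export
from_planar <- function(easting, northing, zone, hemisphere = "N") {
  a <- WGS84_A; f <- WGS84_F
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2)
  e1 <- (1 - sqrt(1 - e2)) / (1 + sqrt(1 - e2))
  lon0 <- (zone - 1) * 6 - 180 + 3

  y <- ifelse(hemisphere == "S", northing - UTM_FN_SOUTH, northing)
  x <- easting - UTM_FE
  M <- y / UTM_K0
  mu <- M / (a * (1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256))
  phi1 <- mu + (3 * e1 / 2 - 27 * e1^3 / 32) * sin(2 * mu) +
    (21 * e1^2 / 16 - 55 * e1^4 / 32) * sin(4 * mu) +
    (151 * e1^3 / 96) * sin(6 * mu) + (1097 * e1^4 / 512) * sin(8 * mu)

  N1 <- a / sqrt(1 - e2 * sin(phi1)^2)
  R1 <- a * (1 - e2) / (1 - e2 * sin(phi1)^2)^1.5
  T1 <- tan(phi1)^2
  C1 <- ep2 * cos(phi1)^2
  D <- x / (N1 * UTM_K0)

  phi <- phi1 - (N1 * tan(phi1) / R1) *
    (D^2 / 2 - (5 + 3 * T1 + 10 * C1 - 4 * C1^2 - 9 * ep2) * D^4 / 24 +
     (61 + 90 * T1 + 298 * C1 + 45 * T1^2 - 252 * ep2 - 3 * C1^2) * D^6 / 720)
  lam <- (D - (1 + 2 * T1 + C1) * D^3 / 6 +
          (5 - 2 * C1 + 28 * T1 - 3 * C1^2 + 8 * ep2 + 24 * T1^2) * D^5 / 120) /
    cos(phi1)
  data.frame(latitude = phi * 180 / pi, longitude = lon0 + lam * 180 / pi)
}

# planar coordinates of an inventory's spatially valid trees
inventory_planar <- function(inv) {
  stopifnot(inherits(inv, "inventory"))
  ok <- inv$coord_valid
  if (!any(ok)) stop("no trees with valid coordinates")
  pts <- to_planar(inv$latitude[ok], inv$longitude[ok])
  pts$row <- which(ok)
  pts
}
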