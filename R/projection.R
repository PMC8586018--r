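# Local planar coordinates for a high-latitude study area.

#' Mean Earth radius (m) used for all spherical geometry
#' @keywords internal
.R_EARTH <- 6371008.8

#' Project longitude/latitude to local planar coordinates
#'
#' Azimuthal equidistant projection on a sphere of radius 6371.0088 km,
#' centred on the study-area centroid. Distances from the centre are exact;
#' distortion elsewhere is negligible over the ~100 km extent of a fjord
#' system (inverse round-trips to well under 1 m within 300 km).
#'
#' @param lonlat two-column matrix (or length-2 vector) of WGS84 degrees.
#' @param centre length-2 vector `c(lon, lat)`: the projection centre.
#' @return matrix with columns `x`, `y` in metres (east, north of centre).
#' @seealso [from_local_xy()] for the inverse.
#' @export
to_local_xy <- function(lonlat, centre) {
  lonlat <- .as_lonlat_matrix(lonlat)
  lam <- lonlat[, 1] * pi / 180
  phi <- lonlat[, 2] * pi / 180
  lam0 <- centre[1] * pi / 180
  phi0 <- centre[2] * pi / 180
  dl <- lam - lam0
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dl)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ang <- acos(cosc)
  # k = c / sin(c) with the c -> 0 limit handled explicitly
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  x <- .R_EARTH * k * cos(phi) * sin(dl)
  y <- .R_EARTH * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dl))
  cbind(x = x, y = y)
}

#' Inverse of [to_local_xy()]
#'
#' @param xy two-column matrix (or length-2 vector) of metres.
#' @param centre length-2 vector `c(lon, lat)` used for the forward projection.
#' @return matrix with columns `lon`, `lat` in WGS84 degrees.
#' @export
from_local_xy <- function(xy, centre) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  x <- xy[, 1]
  y <- xy[, 2]
  lam0 <- centre[1] * pi / 180
  phi0 <- centre[2] * pi / 180
  rho <- sqrt(x^2 + y^2)
  c_ang <- rho / .R_EARTH
  phi <- ifelse(rho < 1e-9, phi0,
                asin(cos(c_ang) * sin(phi0) + y * sin(c_ang) * cos(phi0) / rho))
  lam <- ifelse(rho < 1e-9, lam0,
                lam0 + atan2(x * sin(c_ang),
                             rho * cos(c_ang) * cos(phi0) - y * sin(c_ang) * sin(phi0)))
  cbind(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

.as_lonlat_matrix <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  p <- as.matrix(p)
  if (ncol(p) != 2) stop("coordinates must have two columns (lon, lat)")
  storage.mode(p) <- "double"
  p
}
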