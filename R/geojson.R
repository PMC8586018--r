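# Minimal GeoJSON reader/writer for the three geometry types the seascape
# interface uses: colony Points (with a `size` property), glacier-front
# LineStrings (with `front_id`) and one land Polygon. WGS84, lon-lat order.

#' Write a seascape to GeoJSON
#'
#' @param seascape list with `colonies` (data frame: `id`, `lon`, `lat`,
#'   `size`), `fronts` (list of lists with `id` and a two-column lon/lat
#'   `coords` matrix) and `land` (closed lon/lat ring matrix, or `NULL`).
#' @param path output path.
#' @export
write_seascape_geojson <- function(seascape, path) {
  feats <- list()
  for (i in seq_len(nrow(seascape$colonies))) {
    cl <- seascape$colonies[i, ]
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      properties = list(id = cl$id, size = cl$size),
      geometry = list(type = "Point", coordinates = c(cl$lon, cl$lat)))
  }
  for (fr in seascape$fronts) {
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      properties = list(front_id = fr$id),
      geometry = list(type = "LineString",
                      coordinates = unname(fr$coords)))
  }
  if (!is.null(seascape$land)) {
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      properties = list(id = "land"),
      geometry = list(type = "Polygon",
                      coordinates = list(unname(seascape$land))))
  }
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a seascape from GeoJSON
#'
#' Inverse of [write_seascape_geojson()]. Point features become colonies,
#' LineStrings glacier fronts, and the Polygon the land ring.
#'
#' @param path GeoJSON file path.
#' @return seascape list (`colonies`, `fronts`, `land`).
#' @export
read_seascape_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) stop("not a FeatureCollection")
  colonies <- list()
  fronts <- list()
  land <- NULL
  for (ft in gj$features) {
    geom <- ft$geometry
    if (geom$type == "Point") {
      cc <- unlist(geom$coordinates)
      colonies[[length(colonies) + 1L]] <- data.frame(
        id = ft$properties$id, lon = cc[1], lat = cc[2],
        size = ft$properties$size, stringsAsFactors = FALSE)
    } else if (geom$type == "LineString") {
      coords <- do.call(rbind, lapply(geom$coordinates, unlist))
      colnames(coords) <- c("lon", "lat")
      fronts[[length(fronts) + 1L]] <- list(id = ft$properties$front_id,
                                            coords = coords)
    } else if (geom$type == "Polygon") {
      ring <- do.call(rbind, lapply(geom$coordinates[[1]], unlist))
      colnames(ring) <- c("lon", "lat")
      land <- ring
    }
  }
  list(colonies = do.call(rbind, colonies), fronts = fronts, land = land)
}
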