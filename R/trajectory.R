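# Ingest, filtering and trip segmentation for central-place-forager GPS fixes.
#
# The preprocessing order is fixed: interval subsampling -> speed filter ->
# trip segmentation -> over-land filter. `preprocess_fixes()` enforces it.

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km.
#'
#' @param p1,p2 two-column matrices (or length-2 vectors) of lon/lat degrees;
#'   recycled against each other row-wise.
#' @return numeric vector of distances (km); symmetric and non-negative.
#' @export
great_circle_km <- function(p1, p2) {
  p1 <- .as_lonlat_matrix(p1)
  p2 <- .as_lonlat_matrix(p2)
  .check_lonlat(p1)
  .check_lonlat(p2)
  geosphere::distHaversine(p1, p2, r = .R_EARTH) / 1000
}

.check_lonlat <- function(p) {
  bad <- which(!is.finite(p[, 1]) | !is.finite(p[, 2]) |
                 abs(p[, 1]) > 180 | abs(p[, 2]) > 90)
  if (length(bad)) {
    stop("invalid coordinates at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(p)
}

#' Read a GPS fix table
#'
#' Reads a tab-delimited fix table with columns `individual_id`, `colony_id`,
#' `timestamp_iso8601_utc`, `lon_wgs84`, `lat_wgs84`. Fixes are returned
#' time-sorted within individual; duplicate timestamps within an individual
#' are collapsed to the first occurrence with a warning.
#'
#' @param path file path.
#' @return data frame with columns `individual_id`, `colony_id`, `time`
#'   (POSIXct, UTC), `lon`, `lat`, sorted by individual then time.
#' @export
read_fixes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  need <- c("individual_id", "colony_id", "timestamp_iso8601_utc",
            "lon_wgs84", "lat_wgs84")
  if (!all(need %in% names(raw))) {
    stop("fix table header must contain: ", paste(need, collapse = ", "))
  }
  tm <- as.POSIXct(raw$timestamp_iso8601_utc, tz = "UTC",
                   format = "%Y-%m-%dT%H:%M:%S", optional = TRUE)
  bad_t <- which(is.na(tm))
  if (length(bad_t)) {
    stop("unparseable timestamp at line(s) ",
         paste(utils::head(bad_t + 1L, 5), collapse = ", "))
  }
  lon <- suppressWarnings(as.numeric(raw$lon_wgs84))
  lat <- suppressWarnings(as.numeric(raw$lat_wgs84))
  bad_c <- which(is.na(lon) | is.na(lat) | abs(lon) > 180 | abs(lat) > 90)
  if (length(bad_c)) {
    stop("invalid coordinate at line(s) ",
         paste(utils::head(bad_c + 1L, 5), collapse = ", "))
  }
  fx <- data.frame(individual_id = as.character(raw$individual_id),
                   colony_id = as.character(raw$colony_id),
                   time = tm, lon = lon, lat = lat,
                   stringsAsFactors = FALSE)
  fx <- fx[order(fx$individual_id, fx$time), , drop = FALSE]
  dup <- duplicated(fx[, c("individual_id", "time")])
  if (any(dup)) {
    warning(sum(dup), " duplicate timestamp(s) collapsed to first occurrence")
    fx <- fx[!dup, , drop = FALSE]
  }
  rownames(fx) <- NULL
  fx
}

#' Write a GPS fix table
#'
#' Inverse of [read_fixes()]: tab-delimited text with ISO-8601 UTC timestamps.
#'
#' @param fixes data frame as returned by [read_fixes()] or [simulate_tracks()].
#' @param path output path.
#' @export
write_fixes <- function(fixes, path) {
  out <- data.frame(
    individual_id = fixes$individual_id,
    colony_id = fixes$colony_id,
    timestamp_iso8601_utc = format(fixes$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    lon_wgs84 = sprintf("%.8f", fixes$lon),
    lat_wgs84 = sprintf("%.8f", fixes$lat))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove aberrant fixes by a maximum-speed rule
#'
#' Iteratively removes the later fix of any consecutive pair whose implied
#' ground speed exceeds `vmax_kmh`, re-evaluating against the last retained
#' fix after each removal, until no violation remains. Operates within
#' individual.
#'
#' @param fixes time-sorted fix data frame (one or more individuals).
#' @param vmax_kmh maximum plausible speed; default 80 km/h.
#' @return filtered fix data frame.
#' @export
filter_speed <- function(fixes, vmax_kmh = 80) {
  do.call(rbind, lapply(split(fixes, fixes$individual_id), function(fx) {
    n <- nrow(fx)
    if (n < 2) return(fx)
    keep <- logical(n)
    keep[1] <- TRUE
    last <- 1L
    for (i in 2:n) {
      dt_h <- as.numeric(difftime(fx$time[i], fx$time[last], units = "hours"))
      d_km <- great_circle_km(c(fx$lon[last], fx$lat[last]),
                              c(fx$lon[i], fx$lat[i]))
      v <- if (dt_h > 0) d_km / dt_h else Inf
      if (v <= vmax_kmh) {
        keep[i] <- TRUE
        last <- i
      }
    }
    fx[keep, , drop = FALSE]
  })) -> out
  rownames(out) <- NULL
  out
}

#' Subsample fixes to a standard interval
#'
#' Greedy selection: the first fix is kept; thereafter the fix closest to
#' (last kept + `interval_min`) within `tolerance_min` is kept. Where no fix
#' falls inside the tolerance window (a gap), the first fix after the window
#' is kept and the gap is retained as-is.
#'
#' @param fixes time-sorted fix data frame.
#' @param interval_min target interval (minutes), default 10.
#' @param tolerance_min half-width of the acceptance window (minutes), default 1.
#' @return subsampled fix data frame.
#' @export
subsample_interval <- function(fixes, interval_min = 10, tolerance_min = 1) {
  stopifnot(interval_min > 0, tolerance_min >= 0)
  do.call(rbind, lapply(split(fixes, fixes$individual_id), function(fx) {
    n <- nrow(fx)
    if (n < 2) return(fx)
    t_min <- as.numeric(difftime(fx$time, fx$time[1], units = "mins"))
    keep <- integer(0)
    i <- 1L
    keep <- 1L
    repeat {
      target <- t_min[keep[length(keep)]] + interval_min
      cand <- which(t_min >= target - tolerance_min &
                      t_min <= target + tolerance_min)
      cand <- cand[cand > keep[length(keep)]]
      if (length(cand)) {
        nxt <- cand[which.min(abs(t_min[cand] - target))]
      } else {
        nxt <- which(t_min > target + tolerance_min)
        if (!length(nxt)) break
        nxt <- nxt[1]
      }
      keep <- c(keep, nxt)
      if (nxt == n) break
    }
    fx[keep, , drop = FALSE]
  })) -> out
  rownames(out) <- NULL
  out
}

#' Segment fixes of one individual into foraging trips
#'
#' A trip is a maximal run of consecutive fixes whose great-circle distance to
#' the colony centroid exceeds `radius_m`; runs spanning less than
#' `min_duration_min` (first to last fix of the run) are discarded. A trip is
#' complete when the run is followed by an at-colony fix in the record.
#'
#' @param fixes time-sorted fixes of a single individual.
#' @param colony list or one-row data frame with `id`, `lon`, `lat` (and
#'   optionally `size`).
#' @param radius_m colony-area radius (m), default 200.
#' @param min_duration_min minimum trip duration (minutes), default 50.
#' @return list of trip objects (class `"trip"`), each carrying the trip
#'   fixes, start/end instants, `complete` flag, `max_range_km` and a stable
#'   id `<individual>_T<nn>`.
#' @export
segment_trips <- function(fixes, colony, radius_m = 200, min_duration_min = 50) {
  if (nrow(fixes) == 0) return(list())
  if (length(unique(fixes$individual_id)) > 1) {
    stop("segment_trips() expects fixes of a single individual")
  }
  d_km <- great_circle_km(cbind(fixes$lon, fixes$lat),
                          matrix(c(colony$lon, colony$lat), nrow = 1))
  away <- d_km > radius_m / 1000
  r <- rle(away)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  trips <- list()
  k <- 0L
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    i0 <- starts[j]
    i1 <- ends[j]
    dur <- as.numeric(difftime(fixes$time[i1], fixes$time[i0], units = "mins"))
    if (dur < min_duration_min) next
    k <- k + 1L
    tf <- fixes[i0:i1, , drop = FALSE]
    rownames(tf) <- NULL
    trips[[k]] <- structure(list(
      trip_id = sprintf("%s_T%02d", fixes$individual_id[1], k),
      individual_id = fixes$individual_id[1],
      colony_id = colony$id,
      fixes = tf,
      start = fixes$time[i0],
      end = fixes$time[i1],
      complete = i1 < nrow(fixes),
      max_range_km = max(d_km[i0:i1]),
      land_fraction = NA_real_
    ), class = "trip")
  }
  trips
}

#' @export
print.trip <- function(x, ...) {
  cat(sprintf("<trip %s: %d fixes, %.0f min, max range %.1f km, %s>\n",
              x$trip_id, nrow(x$fixes),
              as.numeric(difftime(x$end, x$start, units = "mins")),
              x$max_range_km,
              if (x$complete) "complete" else "incomplete"))
  invisible(x)
}

#' Proportion of a trip's fixes over land
#'
#' @param trip a trip object from [segment_trips()].
#' @param land closed polygon ring: two-column lon/lat matrix.
#' @return proportion in \[0, 1\].
#' @export
land_fraction <- function(trip, land) {
  land <- .as_lonlat_matrix(land)
  if (nrow(unique(land)) < 3) stop("degenerate land polygon")
  p <- cbind(trip$fixes$lon, trip$fixes$lat)
  mean(mgcv::in.out(land, p))
}

#' Drop trips with too many fixes over land
#'
#' Trips whose proportion of fixes over land is greater than or equal to
#' `threshold` are removed (kittiwakes bathe and collect nest material on
#' land; such excursions are not foraging trips). The computed fraction is
#' attached to the retained trips.
#'
#' @param trips list of trip objects.
#' @param land closed polygon ring (lon/lat matrix).
#' @param threshold removal threshold, default 0.5.
#' @return filtered list of trips, each with `land_fraction` filled in.
#' @export
filter_overland <- function(trips, land, threshold = 0.5) {
  kept <- list()
  for (tr in trips) {
    tr$land_fraction <- land_fraction(tr, land)
    if (tr$land_fraction < threshold) kept[[length(kept) + 1L]] <- tr
  }
  kept
}

#' Morphometric sexing from head-bill length
#'
#' Classifies individuals by the standard head-bill cut-off: female if
#' length <= cutoff, male otherwise.
#'
#' @param length_mm head-bill length(s), mm; must be positive.
#' @param cutoff_mm cut-off, default 90.5 mm.
#' @return character vector, `"female"` or `"male"`.
#' @export
sex_from_headbill <- function(length_mm, cutoff_mm = 90.5) {
  if (any(!is.finite(length_mm)) || any(length_mm <= 0)) {
    stop("head-bill length must be positive")
  }
  ifelse(length_mm <= cutoff_mm, "female", "male")
}

#' Mann-Whitney U test (normal approximation)
#'
#' U computed from rank sums with midrank ties; the p-value uses the normal
#' approximation with tie-corrected variance and continuity correction.
#' Used to check that restricting analyses to complete trips does not bias
#' the sample towards shorter trips.
#'
#' @param x,y numeric samples (both non-empty).
#' @return list with `U` (for `x`) and `p`.
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  if (length(unique(c(x, y))) == 1) {
    return(list(U = length(x) * length(y) / 2, p = 1))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Preprocess raw fixes into analysis-ready trips
#'
#' Applies the fixed pipeline order: subsample to the standard interval,
#' speed-filter, segment into trips per colony radius and minimum duration,
#' then drop trips that are mostly over land. Returns both the retained
#' complete trips and everything needed for the completeness check.
#'
#' @param fixes fix data frame (all individuals).
#' @param colonies data frame with `id`, `lon`, `lat`; row per colony.
#' @param land land polygon ring (lon/lat matrix), or `NULL` to skip the
#'   over-land filter.
#' @param interval_min,tolerance_min see [subsample_interval()].
#' @param vmax_kmh see [filter_speed()].
#' @param radius_m,min_duration_min see [segment_trips()].
#' @param land_threshold see [filter_overland()].
#' @return list with `trips` (complete trips only), `incomplete` (trips
#'   flagged incomplete), `counts` (records retained at each stage) and
#'   `completeness_test` (Mann-Whitney U on max range, complete vs
#'   incomplete; `NULL` when either group is empty).
#' @export
preprocess_fixes <- function(fixes, colonies, land = NULL,
                             interval_min = 10, tolerance_min = 1,
                             vmax_kmh = 80, radius_m = 200,
                             min_duration_min = 50, land_threshold = 0.5) {
  counts <- c(raw = nrow(fixes))
  fixes <- subsample_interval(fixes, interval_min, tolerance_min)
  counts["subsampled"] <- nrow(fixes)
  fixes <- filter_speed(fixes, vmax_kmh)
  counts["speed_filtered"] <- nrow(fixes)
  trips <- list()
  for (fx in split(fixes, fixes$individual_id)) {
    cid <- fx$colony_id[1]
    col <- colonies[match(cid, colonies$id), ]
    if (is.na(col$id)) stop("unknown colony id: ", cid)
    trips <- c(trips, segment_trips(fx, col, radius_m, min_duration_min))
  }
  counts["trips"] <- length(trips)
  if (!is.null(land)) trips <- filter_overland(trips, land, land_threshold)
  counts["trips_after_land_filter"] <- length(trips)
  complete <- Filter(function(tr) tr$complete, trips)
  incomplete <- Filter(function(tr) !tr$complete, trips)
  counts["complete_trips"] <- length(complete)
  completeness_test <- NULL
  if (length(complete) && length(incomplete)) {
    completeness_test <- mann_whitney_u(
      vapply(complete, `[[`, 0, "max_range_km"),
      vapply(incomplete, `[[`, 0, "max_range_km"))
  }
  list(trips = complete, incomplete = incomplete, counts = counts,
       completeness_test = completeness_test)
}
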