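# Glacier-front use: 400-m front buffers, the two-consecutive-fix use rule,
# per-individual use profiles, and Bolnick proportional-similarity
# dissimilarity in front use.

#' Centroid of a glacier front line
#'
#' The midpoint along the polyline's arc length, computed in the local
#' projection and returned in lon/lat.
#'
#' @param coords two-column lon/lat vertex matrix (>= 2 vertices).
#' @param centre projection centre `c(lon, lat)`.
#' @return length-2 vector `c(lon, lat)`.
#' @export
front_centroid <- function(coords, centre) {
  coords <- .as_lonlat_matrix(coords)
  if (nrow(coords) < 2) stop("a front polyline needs at least 2 vertices")
  xy <- to_local_xy(coords, centre)
  seg <- sqrt(rowSums(diff(xy)^2))
  L <- sum(seg)
  if (L == 0) return(c(lon = coords[1, 1], lat = coords[1, 2]))
  target <- L / 2
  cum <- c(0, cumsum(seg))
  j <- max(which(cum <= target))
  f <- (target - cum[j]) / seg[j]
  mid <- xy[j, ] + f * (xy[j + 1, ] - xy[j, ])
  ll <- from_local_xy(mid, centre)
  c(lon = ll[1, 1], lat = ll[1, 2])
}

# minimum Euclidean distance from each point (n x 2) to a polyline (m x 2)
.dist_to_polyline <- function(pts, verts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  n <- nrow(pts)
  dmin <- rep(Inf, n)
  for (j in seq_len(nrow(verts) - 1)) {
    a <- verts[j, ]
    b <- verts[j + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d <- sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2)
    } else {
      t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
      t <- pmin(1, pmax(0, t))
      px <- a[1] + t * ab[1]
      py <- a[2] + t * ab[2]
      d <- sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)
    }
    dmin <- pmin(dmin, d)
  }
  dmin
}

# closest point on a closed ring (n x 2) to a single point
.closest_point_on_ring <- function(ring, p) {
  best <- NULL
  bestd <- Inf
  for (j in seq_len(nrow(ring) - 1)) {
    a <- ring[j, ]
    b <- ring[j + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) 0 else sum((p - a) * ab) / len2
    t <- min(1, max(0, t))
    cp <- a + t * ab
    d <- sum((p - cp)^2)
    if (d < bestd) {
      bestd <- d
      best <- cp
    }
  }
  best
}

#' Euclidean buffer around a glacier front line
#'
#' Round-capped buffer of the polyline in the local projection. Containment
#' is exact (distance to the polyline); the returned outline polygon is a
#' discretised approximation used for serialization and area computation.
#' A point exactly on the boundary counts as inside.
#'
#' @param polyline_xy two-column matrix of projected vertices (m).
#' @param radius_m buffer radius, default 400 m.
#' @param n_arc arc discretisation (points per half circle), default 64.
#' @return object of class `"front_buffer"`: vertices, radius, outline
#'   polygon (closed ring, projected m) and its shoelace `area_m2`.
#' @export
buffer_front <- function(polyline_xy, radius_m = 400, n_arc = 64) {
  v <- as.matrix(polyline_xy)
  v <- v[!duplicated(v) | seq_len(nrow(v)) == 1, , drop = FALSE]
  if (nrow(v) < 2) stop("degenerate polyline: need >= 2 distinct vertices")
  stopifnot(radius_m > 0)
  segs <- nrow(v) - 1
  dirs <- diff(v)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  norms <- cbind(-dirs[, 2], dirs[, 1])
  arc <- function(ctr, a0, a1, n) {
    th <- seq(a0, a1, length.out = n)
    cbind(ctr[1] + radius_m * cos(th), ctr[2] + radius_m * sin(th))
  }
  ang <- atan2(dirs[, 2], dirs[, 1])
  left <- list()
  for (j in seq_len(segs)) {
    left[[length(left) + 1L]] <- rbind(v[j, ] + radius_m * norms[j, ],
                                       v[j + 1, ] + radius_m * norms[j, ])
    if (j < segs) {
      a0 <- ang[j] + pi / 2
      a1 <- ang[j + 1] + pi / 2
      if (a1 - a0 > pi) a1 <- a1 - 2 * pi
      if (a0 - a1 > pi) a1 <- a1 + 2 * pi
      left[[length(left) + 1L]] <- arc(v[j + 1, ], a0, a1, 16)
    }
  }
  right <- list()
  for (j in rev(seq_len(segs))) {
    right[[length(right) + 1L]] <- rbind(v[j + 1, ] - radius_m * norms[j, ],
                                         v[j, ] - radius_m * norms[j, ])
    if (j > 1) {
      a0 <- ang[j] - pi / 2
      a1 <- ang[j - 1] - pi / 2
      if (a1 - a0 > pi) a1 <- a1 - 2 * pi
      if (a0 - a1 > pi) a1 <- a1 + 2 * pi
      right[[length(right) + 1L]] <- arc(v[j, ], a0, a1, 16)
    }
  }
  # caps sweep a half circle: at the far end through the forward direction,
  # at the near end through the reversed direction
  cap_end <- arc(v[nrow(v), ], ang[segs] + pi / 2, ang[segs] - pi / 2, n_arc)
  cap_start <- arc(v[1, ], ang[1] - pi / 2, ang[1] - 3 * pi / 2, n_arc)
  ring <- do.call(rbind, c(left, list(cap_end), right, list(cap_start)))
  ring <- rbind(ring, ring[1, ])
  area <- abs(sum(ring[-nrow(ring), 1] * ring[-1, 2] -
                    ring[-1, 1] * ring[-nrow(ring), 2])) / 2
  structure(list(vertices = v, radius_m = radius_m, outline = ring,
                 area_m2 = area), class = "front_buffer")
}

#' Test points for containment in a front buffer
#'
#' @param points two-column matrix of projected coordinates (m).
#' @param buffer a [buffer_front()] object.
#' @return logical vector; boundary points count as inside.
#' @export
in_buffer <- function(points, buffer) {
  .dist_to_polyline(points, buffer$vertices) <= buffer$radius_m
}

#' Score glacier-front use of one trip
#'
#' A front is used when the trip contains at least two consecutive fixes
#' (at the standard 10-min interval) inside the front's 400-m buffer.
#'
#' @param trip a trip object ([segment_trips()]).
#' @param fronts list of fronts (`id`, lon/lat `coords`).
#' @param centre projection centre `c(lon, lat)`.
#' @param radius_m buffer radius, default 400 m.
#' @return named binary integer vector over fronts.
#' @export
trip_front_use <- function(trip, fronts, centre, radius_m = 400) {
  xy <- to_local_xy(cbind(trip$fixes$lon, trip$fixes$lat), centre)
  out <- integer(length(fronts))
  names(out) <- vapply(fronts, `[[`, "", "id")
  for (k in seq_along(fronts)) {
    fv <- to_local_xy(fronts[[k]]$coords, centre)
    inside <- .dist_to_polyline(xy, fv) <= radius_m
    if (length(inside) >= 2 && any(inside[-1] & inside[-length(inside)])) {
      out[k] <- 1L
    }
  }
  out
}

#' Per-individual glacier-front use profile
#'
#' Trip-level binary use is summed by front over the individual's trips;
#' proportions `p_ik` are the counts divided by their total. Individuals
#' whose trips used no front at all are flagged `excluded` (they carry no
#' front-use information and are removed from the dissimilarity analysis).
#'
#' @param trips list of trips of one individual.
#' @param fronts list of fronts.
#' @param centre projection centre.
#' @param radius_m buffer radius, default 400 m.
#' @return object of class `"front_use_profile"`: `individual_id`, `counts`,
#'   `p` (proportions; `NA` when excluded), `excluded`.
#' @export
use_profile <- function(trips, fronts, centre, radius_m = 400) {
  stopifnot(length(trips) >= 1)
  id <- trips[[1]]$individual_id
  counts <- Reduce(`+`, lapply(trips, trip_front_use, fronts = fronts,
                               centre = centre, radius_m = radius_m))
  tot <- sum(counts)
  structure(list(individual_id = id, counts = counts,
                 p = if (tot > 0) counts / tot else rep(NA_real_,
                                                        length(counts)),
                 excluded = tot == 0), class = "front_use_profile")
}

#' Bolnick proportional-similarity dissimilarity in front use
#'
#' `H = sum_k min(p_ik, p_jk)` over fronts; the dissimilarity is
#' `DH = 1 - H`, from 0 (identical front use) to 1 (no shared front use).
#'
#' @param profile_i,profile_j [use_profile()] objects on the same front set,
#'   neither excluded.
#' @return `DH` in \[0, 1\].
#' @export
bolnick_dissimilarity <- function(profile_i, profile_j) {
  for (pr in list(profile_i, profile_j)) {
    if (pr$excluded) {
      stop("individual ", pr$individual_id,
           " used no glacier front and is excluded from the dissimilarity")
    }
  }
  if (length(profile_i$p) != length(profile_j$p)) {
    stop("profiles are not aligned on the same front set")
  }
  1 - sum(pmin(profile_i$p, profile_j$p))
}

#' Pairwise front-use dissimilarity matrix
#'
#' @param profiles list of non-excluded [use_profile()] objects.
#' @return symmetric `DH` matrix with zero diagonal, individual ids as
#'   dimnames.
#' @export
dh_matrix <- function(profiles) {
  keep <- !vapply(profiles, `[[`, TRUE, "excluded")
  profiles <- profiles[keep]
  n <- length(profiles)
  if (n < 2) stop("need >= 2 non-excluded individuals")
  ids <- vapply(profiles, `[[`, "", "individual_id")
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- bolnick_dissimilarity(profiles[[i]],
                                                  profiles[[j]])
    }
  }
  m
}

#' Colony-to-front great-circle distances
#'
#' Distances (km) from each colony centroid to each glacier front's line
#' centroid.
#'
#' @param colonies data frame with `id`, `lon`, `lat`.
#' @param fronts list of fronts (`id`, `coords`).
#' @param centre projection centre (for the arc-length centroid).
#' @return colony x front matrix of km, with dimnames.
#' @export
colony_front_distances <- function(colonies, fronts, centre) {
  ctr <- t(vapply(fronts, function(fr) front_centroid(fr$coords, centre),
                  numeric(2)))
  m <- matrix(NA_real_, nrow(colonies), length(fronts),
              dimnames = list(colonies$id,
                              vapply(fronts, `[[`, "", "id")))
  for (i in seq_len(nrow(colonies))) {
    m[i, ] <- great_circle_km(matrix(c(colonies$lon[i], colonies$lat[i]),
                                     nrow = 1), ctr)
  }
  m
}
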