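# Synthetic seascapes and central-place-forager GPS tracks with known
# ground truth, emulating kittiwake tracking in a glacial-fjord system:
# five colonies, up to 25 tidewater glacier fronts within a 50-km study
# radius, 10-min fixes, and a colony-dependent, distance-decaying glacier
# front preference on the logit scale.

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic seascape and track
#' generator. Defaults mirror the study conditions the pipeline is built
#' for: five colonies, 25 glacier fronts inside a 50-km radius, 10-min
#' fixes, 1-10 trips per individual with mean 4.3, and a multinomial-logit
#' front choice with distance slope -0.22 per km.
#'
#' @param seed integer seed; identical configuration and seed give
#'   bit-identical output.
#' @param n_colonies number of colonies. With the default 5 and no explicit
#'   `colony_positions`, the Kongsfjorden colony layout and sizes are used.
#' @param colony_positions optional two-column lon/lat matrix.
#' @param colony_sizes optional breeding-pair counts (same length).
#' @param n_fronts number of glacier fronts (default 25; 0 gives a
#'   pelagic-only seascape).
#' @param front_polylines optional list of lon/lat vertex matrices; when
#'   supplied, `n_fronts` is ignored.
#' @param land_polygon optional closed lon/lat ring; `NULL` generates a
#'   default coastal block.
#' @param study_radius_km radius of the study area around its centre
#'   (default 50 km); all fronts fall inside it.
#' @param centre optional `c(lon, lat)` seascape centre; defaults to the
#'   centroid of the four inner-fjord Kongsfjorden colonies.
#' @param fix_interval GPS fix interval, minutes (default 10).
#' @param trips_range integer range of trips per individual (default 1-10).
#' @param trips_mean target mean trips per individual (default 4.3; trip
#'   counts are drawn as `min + Binomial(max - min, p)` with `p` matched to
#'   the mean).
#' @param individuals_per_colony tracked birds per colony (default 10).
#' @param beta_distance logit slope of front choice per km of colony-front
#'   distance (default -0.22).
#' @param alpha logit intercept of front choice. It cancels in the
#'   multinomial choice rule (same constant for every front) and is kept for
#'   interface completeness.
#' @param p_pelagic probability a trip targets open water instead of any
#'   front (default 0.3).
#' @param p_overland probability a trip deliberately targets land (default
#'   0); used to exercise the over-land trip filter.
#' @param p_truncate probability an individual's record ends mid-trip
#'   (default 0.1), producing an incomplete final trip.
#' @param dwell_time minutes spent at the chosen destination (default 120).
#' @param commute_speed_kmh straight-line commuting ground speed (default 35).
#' @param ou_sigma spatial SD of the dwell Ornstein-Uhlenbeck process, m
#'   (default 300).
#' @param ou_tau_pos position autocorrelation timescale of the dwell, min
#'   (default 30).
#' @param ou_tau_vel velocity autocorrelation timescale, min; 0 (default)
#'   gives a pure OU dwell, > 0 an OU-Foraging dwell.
#' @param gps_noise_sd isotropic GPS measurement noise SD, m (default 20).
#' @return validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_colonies = 5L,
                       colony_positions = NULL,
                       colony_sizes = NULL,
                       n_fronts = 25L,
                       front_polylines = NULL,
                       land_polygon = NULL,
                       study_radius_km = 50,
                       centre = NULL,
                       fix_interval = 10,
                       trips_range = c(1L, 10L),
                       trips_mean = 4.3,
                       individuals_per_colony = 10L,
                       beta_distance = -0.22,
                       alpha = 0,
                       p_pelagic = 0.3,
                       p_overland = 0,
                       p_truncate = 0.1,
                       dwell_time = 120,
                       commute_speed_kmh = 35,
                       ou_sigma = 300,
                       ou_tau_pos = 30,
                       ou_tau_vel = 0,
                       gps_noise_sd = 20) {
  stopifnot(fix_interval > 0,
            p_pelagic >= 0, p_pelagic <= 1,
            p_overland >= 0, p_overland <= 1, p_pelagic + p_overland <= 1,
            p_truncate >= 0, p_truncate <= 1,
            ou_sigma > 0, ou_tau_pos > 0, ou_tau_vel >= 0,
            length(trips_range) == 2, trips_range[1] >= 1,
            trips_range[2] >= trips_range[1],
            trips_mean >= trips_range[1], trips_mean <= trips_range[2],
            individuals_per_colony >= 1, n_colonies >= 1, n_fronts >= 0,
            study_radius_km > 0, dwell_time > 0, commute_speed_kmh > 0,
            gps_noise_sd >= 0)
  if (!is.null(colony_positions)) {
    colony_positions <- .as_lonlat_matrix(colony_positions)
    n_colonies <- nrow(colony_positions)
    if (is.null(colony_sizes)) stop("colony_sizes required with colony_positions")
    stopifnot(length(colony_sizes) == n_colonies, all(colony_sizes > 0))
  }
  if (is.null(centre)) {
    kc <- kongsfjorden_colonies()
    inner <- kc[kc$id != "FGL", ]
    centre <- c(mean(inner$lon), mean(inner$lat))
  }
  structure(list(
    seed = as.integer(seed), n_colonies = as.integer(n_colonies),
    colony_positions = colony_positions, colony_sizes = colony_sizes,
    n_fronts = as.integer(n_fronts), front_polylines = front_polylines,
    land_polygon = land_polygon, study_radius_km = study_radius_km,
    centre = centre, fix_interval = fix_interval,
    trips_range = as.integer(trips_range), trips_mean = trips_mean,
    individuals_per_colony = as.integer(individuals_per_colony),
    beta_distance = beta_distance, alpha = alpha,
    p_pelagic = p_pelagic, p_overland = p_overland, p_truncate = p_truncate,
    dwell_time = dwell_time, commute_speed_kmh = commute_speed_kmh,
    ou_sigma = ou_sigma, ou_tau_pos = ou_tau_pos, ou_tau_vel = ou_tau_vel,
    gps_noise_sd = gps_noise_sd), class = "sim_config")
}

#' Multinomial-logit glacier-front choice probabilities
#'
#' Probability that a front-directed trip from a colony targets each front:
#' proportional to `exp(alpha + beta_distance * d_k)` with `d_k` the
#' colony-to-front great-circle distance in km. The intercept cancels.
#'
#' @param d_km numeric vector of colony-front distances (km).
#' @param alpha logit intercept.
#' @param beta_distance logit slope per km.
#' @return probability vector summing to 1.
#' @export
front_choice_probs <- function(d_km, alpha = 0, beta_distance = -0.22) {
  eta <- alpha + beta_distance * d_km
  eta <- eta - max(eta)
  w <- exp(eta)
  w / sum(w)
}

#' Generate a synthetic seascape
#'
#' Lays out colonies, glacier-front polylines and a land polygon. With the
#' default configuration the colony layout and sizes are the Kongsfjorden
#' ones; fronts are placed with a fjord/regional split (a handful within
#' ~16 km of the centre, the rest out to just inside the study radius), each
#' a short 3-vertex polyline. Placement retries keep fronts off colonies,
#' off each other and off land; exhausting the retry budget is an error.
#'
#' @param config a [sim_config()].
#' @return list of class `"seascape"`: `colonies` (data frame `id`, `lon`,
#'   `lat`, `size`), `fronts` (list of `id` + lon/lat `coords`), `land`
#'   (closed lon/lat ring), `centre`, `study_radius_km`.
#' @export
simulate_seascape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .simulate_seascape_impl(config))
}

.simulate_seascape_impl <- function(config) {
  centre <- config$centre
  R_km <- config$study_radius_km

  land <- config$land_polygon
  if (is.null(land)) {
    # coastal block to the northeast of the fjord centre, in projected km
    ring_km <- rbind(c(20, 18), c(48, 18), c(48, 46), c(20, 46), c(20, 18))
    land <- from_local_xy(ring_km * 1000, centre)
    colnames(land) <- c("lon", "lat")
  } else {
    land <- .as_lonlat_matrix(land)
  }

  if (!is.null(config$colony_positions)) {
    colonies <- data.frame(id = sprintf("C%02d", seq_len(config$n_colonies)),
                           lon = config$colony_positions[, 1],
                           lat = config$colony_positions[, 2],
                           size = config$colony_sizes,
                           stringsAsFactors = FALSE)
  } else if (config$n_colonies == 5L) {
    kc <- kongsfjorden_colonies()
    colonies <- kc[, c("id", "lon", "lat", "size")]
  } else {
    colonies <- .place_colonies(config, centre, land)
  }

  fronts <- list()
  if (!is.null(config$front_polylines)) {
    fronts <- lapply(seq_along(config$front_polylines), function(i) {
      list(id = sprintf("F%02d", i),
           coords = .as_lonlat_matrix(config$front_polylines[[i]]))
    })
  } else if (config$n_fronts > 0) {
    fronts <- .place_fronts(config, centre, colonies, land)
  }

  structure(list(colonies = colonies, fronts = fronts, land = land,
                 centre = centre, study_radius_km = R_km),
            class = "seascape")
}

.place_colonies <- function(config, centre, land) {
  n <- config$n_colonies
  R_km <- config$study_radius_km
  xy <- matrix(NA_real_, n, 2)
  tries <- 0L
  i <- 1L
  while (i <= n) {
    tries <- tries + 1L
    if (tries > 500L * n) stop("colony placement failed: retry budget exhausted")
    r <- stats::runif(1, 2, 0.6 * R_km) * 1000
    th <- stats::runif(1, 0, 2 * pi)
    cand <- c(r * cos(th), r * sin(th))
    ll <- from_local_xy(cand, centre)
    if (mgcv::in.out(land, ll)) next
    if (i > 1 && min(sqrt(rowSums(sweep(xy[seq_len(i - 1), , drop = FALSE],
                                        2, cand)^2))) < 3000) next
    xy[i, ] <- cand
    i <- i + 1L
  }
  ll <- from_local_xy(xy, centre)
  data.frame(id = sprintf("C%02d", seq_len(n)),
             lon = ll[, 1], lat = ll[, 2],
             size = round(stats::runif(n, 100, 4500)),
             stringsAsFactors = FALSE)
}

.place_fronts <- function(config, centre, colonies, land) {
  n <- config$n_fronts
  n_inner <- min(6L, n)
  col_xy <- to_local_xy(cbind(colonies$lon, colonies$lat), centre)
  fronts <- vector("list", n)
  placed <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(500L)) {
      if (i <= n_inner) {
        r <- stats::runif(1, 3, 16) * 1000
      } else {
        r <- stats::runif(1, 18, config$study_radius_km - 2) * 1000
      }
      th <- stats::runif(1, 0, 2 * pi)
      ctr <- c(r * cos(th), r * sin(th))
      if (mgcv::in.out(land, from_local_xy(ctr, centre))) next
      if (min(sqrt(rowSums(sweep(col_xy, 2, ctr)^2))) < 1500) next
      if (i > 1) {
        prev <- placed[seq_len(i - 1), , drop = FALSE]
        if (min(sqrt(rowSums(sweep(prev, 2, ctr)^2))) < 2500) next
      }
      ori <- stats::runif(1, 0, pi)
      half <- stats::runif(1, 750, 1500)
      u <- c(cos(ori), sin(ori))
      perp <- c(-u[2], u[1]) * stats::runif(1, -150, 150)
      verts <- rbind(ctr - half * u, ctr + perp, ctr + half * u)
      ll <- from_local_xy(verts, centre)
      colnames(ll) <- c("lon", "lat")
      fronts[[i]] <- list(id = sprintf("F%02d", i), coords = ll)
      placed[i, ] <- ctr
      ok <- TRUE
      break
    }
    if (!ok) stop("front placement failed: retry budget exhausted")
  }
  fronts
}

# exact OU update over steps `dt` (minutes), one dimension
.sim_ou_path <- function(x0, mu, dt, tau, sigma2) {
  n <- length(dt)
  x <- numeric(n)
  cur <- x0
  phi <- exp(-dt / tau)
  sd_step <- sqrt(sigma2 * (1 - phi^2))
  z <- stats::rnorm(n)
  for (k in seq_len(n)) {
    cur <- mu + phi[k] * (cur - mu) + sd_step[k] * z[k]
    x[k] <- cur
  }
  x
}

# state transition of the OU-Foraging (position + velocity) process
.ouf_transition <- function(dt, tau_pos, tau_vel, sigma2) {
  l1 <- -1 / tau_pos
  l2 <- -1 / tau_vel
  A <- matrix(c(0, -1 / (tau_pos * tau_vel), 1, -(1 / tau_pos + 1 / tau_vel)), 2, 2)
  I2 <- diag(2)
  Phi <- (exp(l1 * dt) * (A - l2 * I2) - exp(l2 * dt) * (A - l1 * I2)) / (l1 - l2)
  Sst <- diag(c(sigma2, sigma2 / (tau_pos * tau_vel)))
  Q <- Sst - Phi %*% Sst %*% t(Phi)
  list(Phi = Phi, Q = (Q + t(Q)) / 2)
}

.sim_ouf_path <- function(x0, v0, mu, dt, tau_pos, tau_vel, sigma2) {
  n <- length(dt)
  x <- numeric(n)
  z <- c(x0 - mu, v0)
  for (k in seq_len(n)) {
    tr <- .ouf_transition(dt[k], tau_pos, tau_vel, sigma2)
    ev <- eigen(tr$Q, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2)
    z <- as.numeric(tr$Phi %*% z) + as.numeric(L %*% stats::rnorm(2))
    x[k] <- mu + z[1]
  }
  x
}

#' Simulate GPS tracks over a seascape
#'
#' For each individual, a number of foraging trips is drawn (range and mean
#' per the configuration). Each trip targets, with probability
#' `1 - p_pelagic - p_overland`, a glacier front chosen by the
#' multinomial-logit distance rule ([front_choice_probs()]); otherwise a
#' random pelagic (or, if configured, over-land) destination. A trip is an
#' outbound straight-line commute at constant ground speed, an
#' Ornstein-Uhlenbeck dwell around the destination, and a straight return;
#' fixes are sampled every `fix_interval` minutes on a common time grid with
#' isotropic Gaussian GPS noise, with a few at-colony fixes between trips.
#' With probability `p_truncate` an individual's record ends mid final trip.
#'
#' @param config a [sim_config()].
#' @param seascape result of [simulate_seascape()] (same configuration).
#' @return list with `fixes` (data frame `individual_id`, `colony_id`,
#'   `time`, `lon`, `lat`) and `truth` (class `"truth_record"`): individual
#'   table (with sex), per-trip table (type, chosen front, destination,
#'   first/last away fix index, completeness), per-individual true
#'   front-choice proportions `p_ik`, and the generating parameters.
#' @export
simulate_tracks <- function(config, seascape) {
  stopifnot(inherits(config, "sim_config"), inherits(seascape, "seascape"))
  withr::with_seed(config$seed + 1L, .simulate_tracks_impl(config, seascape))
}

.simulate_tracks_impl <- function(config, seascape) {
  centre <- seascape$centre
  colonies <- seascape$colonies
  col_xy <- to_local_xy(cbind(colonies$lon, colonies$lat), centre)
  n_fronts <- length(seascape$fronts)
  front_ids <- vapply(seascape$fronts, `[[`, "", "id")
  front_ctr_ll <- if (n_fronts) t(vapply(seascape$fronts, function(fr)
    front_centroid(fr$coords, centre), numeric(2))) else NULL
  front_ctr_xy <- if (n_fronts) to_local_xy(front_ctr_ll, centre) else NULL
  # colony x front great-circle distances drive the choice rule
  d_cf <- if (n_fronts) colony_front_distances(colonies, seascape$fronts,
                                               centre) else NULL

  v <- config$commute_speed_kmh * 1000 / 60      # m per minute
  dt <- config$fix_interval
  origin <- as.POSIXct("2017-07-15 00:00:00", tz = "UTC")
  land <- seascape$land
  land_xy <- to_local_xy(land, centre)
  land_ctr_xy <- colMeans(land_xy[-nrow(land_xy), , drop = FALSE])

  # with no fronts in the seascape, front-share trips become pelagic
  p_front <- if (n_fronts > 0) 1 - config$p_pelagic - config$p_overland else 0
  trips_p <- if (diff(config$trips_range) > 0) {
    (config$trips_mean - config$trips_range[1]) / diff(config$trips_range)
  } else 0

  all_fix <- list()
  trip_rows <- list()
  ind_rows <- list()
  for (ci in seq_len(nrow(colonies))) {
    for (bi in seq_len(config$individuals_per_colony)) {
      id <- sprintf("%s_B%02d", colonies$id[ci], bi)
      sex <- sample(c("female", "male"), 1)
      n_trips <- config$trips_range[1] +
        stats::rbinom(1, diff(config$trips_range), trips_p)
      truncate_last <- stats::runif(1) < config$p_truncate

      cxy <- col_xy[ci, ]
      pos <- matrix(cxy, nrow = sample(2:4, 1), ncol = 2, byrow = TRUE)
      away <- rep(FALSE, nrow(pos))
      for (tj in seq_len(n_trips)) {
        u <- stats::runif(1)
        if (n_fronts > 0 && u < p_front) {
          type <- "front"
          pk <- front_choice_probs(d_cf[ci, ], config$alpha,
                                   config$beta_distance)
          k <- sample.int(n_fronts, 1, prob = pk)
          dest <- front_ctr_xy[k, ]
          front_id <- front_ids[k]
        } else if (u < p_front + config$p_overland) {
          # planted over-land excursion: nearest land, long stationary visit
          type <- "overland"
          cp <- .closest_point_on_ring(land_xy, cxy)
          dir_in <- land_ctr_xy - cp
          dest <- cp + 2500 * dir_in / sqrt(sum(dir_in^2))
          front_id <- NA_character_
        } else {
          type <- "pelagic"
          for (try in seq_len(100L)) {
            r <- stats::runif(1, 8, config$study_radius_km - 5) * 1000
            th <- stats::runif(1, 0, 2 * pi)
            dest <- cxy + c(r * cos(th), r * sin(th))
            if (!mgcv::in.out(land, from_local_xy(dest, centre))) break
          }
          front_id <- NA_character_
        }
        D <- sqrt(sum((dest - cxy)^2))
        t_out <- D / v
        # over-land excursions are long stationary visits, so the land
        # filter sees an unambiguous majority of fixes over land
        dwell_min <- if (type == "overland") {
          max(config$dwell_time, 2.4 * 2 * t_out)
        } else config$dwell_time
        # dwell fix offsets relative to departure; grid generously covers the
        # return leg (whose length depends on where the dwell ends)
        max_T <- 2 * t_out + dwell_min +
          (10 * config$ou_sigma) / v + 2 * dt
        r_grid <- seq(dt, max_T, by = dt)
        dwell_idx <- which(r_grid > t_out &
                             r_grid <= t_out + dwell_min)
        dw_t <- r_grid[dwell_idx] - t_out
        dw_dt <- diff(c(0, dw_t, dwell_min))
        if (config$ou_tau_vel > 0) {
          dx <- .sim_ouf_path(dest[1], 0, dest[1], dw_dt, config$ou_tau_pos,
                              config$ou_tau_vel, config$ou_sigma^2)
          dy <- .sim_ouf_path(dest[2], 0, dest[2], dw_dt, config$ou_tau_pos,
                              config$ou_tau_vel, config$ou_sigma^2)
        } else {
          dx <- .sim_ou_path(dest[1], dest[1], dw_dt, config$ou_tau_pos,
                             config$ou_sigma^2)
          dy <- .sim_ou_path(dest[2], dest[2], dw_dt, config$ou_tau_pos,
                             config$ou_sigma^2)
        }
        m <- length(dw_t)
        dwell_end <- c(dx[m + 1], dy[m + 1])
        D_back <- sqrt(sum((dwell_end - cxy)^2))
        t_back <- D_back / v
        T_trip <- t_out + dwell_min + t_back
        rel <- r_grid[r_grid < T_trip]
        tp <- matrix(NA_real_, length(rel), 2)
        is_out <- rel <= t_out
        is_dwell <- rel > t_out & rel <= t_out + dwell_min
        is_back <- !is_out & !is_dwell
        if (any(is_out)) {
          tp[is_out, ] <- rep(cxy, each = sum(is_out)) +
            outer(v * rel[is_out] / D, dest - cxy)
        }
        if (any(is_dwell)) {
          # dwell fixes are exactly the grid points simulated above
          tp[is_dwell, ] <- cbind(dx[seq_len(m)], dy[seq_len(m)])
        }
        if (any(is_back)) {
          s <- (rel[is_back] - t_out - dwell_min) / t_back
          tp[is_back, ] <- rep(dwell_end, each = sum(is_back)) +
            outer(s, cxy - dwell_end)
        }
        # truth boundaries follow the trip definition: fixes > 200 m from
        # the colony (the final return-leg fix can fall inside that radius)
        d_tp <- sqrt((tp[, 1] - cxy[1])^2 + (tp[, 2] - cxy[2])^2)
        away_tp <- d_tp > 200
        first_away_local <- nrow(pos) + which(away_tp)[1]
        last_away_local <- nrow(pos) + max(which(away_tp))
        pos <- rbind(pos, tp)
        away <- c(away, away_tp)
        last_trip <- tj == n_trips
        cut <- FALSE
        if (last_trip && truncate_last && nrow(tp) > 2) {
          ncut <- sample.int(nrow(tp) - 1L, 1)  # keep at least one away fix
          pos <- pos[seq_len(nrow(pos) - nrow(tp) + ncut), , drop = FALSE]
          away <- away[seq_len(nrow(pos))]
          last_away_local <- max(which(away))
          cut <- TRUE
        }
        trip_rows[[length(trip_rows) + 1L]] <- data.frame(
          individual_id = id, colony_id = colonies$id[ci], trip_index = tj,
          type = type, front_id = front_id,
          dest_x = dest[1], dest_y = dest[2],
          first_fix = first_away_local,
          last_fix = last_away_local,
          complete = !cut, stringsAsFactors = FALSE)
        if (cut) break
        # post-trip colony fixes
        n_col <- if (last_trip) 2L else sample(2:4, 1)
        pos <- rbind(pos, matrix(cxy, nrow = n_col, ncol = 2, byrow = TRUE))
        away <- c(away, rep(FALSE, n_col))
      }
      noise <- matrix(stats::rnorm(length(pos), 0, config$gps_noise_sd),
                      ncol = 2)
      ll <- from_local_xy(pos + noise, centre)
      tm <- origin + (seq_len(nrow(pos)) - 1L) * dt * 60
      all_fix[[length(all_fix) + 1L]] <- data.frame(
        individual_id = id, colony_id = colonies$id[ci], time = tm,
        lon = ll[, 1], lat = ll[, 2], stringsAsFactors = FALSE)
      ind_rows[[length(ind_rows) + 1L]] <- data.frame(
        individual_id = id, colony_id = colonies$id[ci], sex = sex,
        n_trips = n_trips, stringsAsFactors = FALSE)
    }
  }
  fixes <- do.call(rbind, all_fix)
  rownames(fixes) <- NULL
  trips <- do.call(rbind, trip_rows)
  individuals <- do.call(rbind, ind_rows)

  # true per-individual front-choice proportions over complete front trips
  p_ik <- NULL
  if (n_fronts) {
    p_ik <- matrix(0, nrow(individuals), n_fronts,
                   dimnames = list(individuals$individual_id, front_ids))
    ft <- trips[trips$type == "front" & trips$complete, , drop = FALSE]
    if (nrow(ft)) {
      tab <- table(factor(ft$individual_id,
                          levels = individuals$individual_id),
                   factor(ft$front_id, levels = front_ids))
      cnt <- matrix(as.numeric(tab), nrow(individuals), n_fronts,
                    dimnames = dimnames(p_ik))
      tot <- rowSums(cnt)
      p_ik[tot > 0, ] <- cnt[tot > 0, , drop = FALSE] / tot[tot > 0]
    }
  }
  truth <- structure(list(
    individuals = individuals, trips = trips, p_ik = p_ik,
    beta_distance = config$beta_distance, alpha = config$alpha,
    p_pelagic = config$p_pelagic, centre = centre,
    colony_front_km = d_cf), class = "truth_record")
  list(fixes = fixes, truth = truth)
}

#' Serialize a truth record as structured text (JSON)
#' @param truth a `"truth_record"` from [simulate_tracks()].
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  class(out) <- NULL
  out$p_ik <- if (!is.null(out$p_ik)) {
    list(individuals = rownames(out$p_ik), fronts = colnames(out$p_ik),
         values = unname(out$p_ik))
  }
  out$colony_front_km <- if (!is.null(out$colony_front_km)) {
    unname(as.matrix(out$colony_front_km))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
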