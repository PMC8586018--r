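# Shared fixtures, all built in code.

# UD filled from an analytic isotropic Gaussian density (not a KDE): used
# for closed-form Bhattacharyya / isopleth checks.
make_gaussian_ud <- function(mu, sigma, cell = 100, half_extent = 6 * sigma) {
  i0 <- floor((mu[1] - half_extent) / cell)
  i1 <- floor((mu[1] + half_extent) / cell)
  j0 <- floor((mu[2] - half_extent) / cell)
  j1 <- floor((mu[2] + half_extent) / cell)
  cx <- (seq(i0, i1) + 0.5) * cell
  cy <- (seq(j0, j1) + 0.5) * cell
  mass <- outer(dnorm(cx, mu[1], sigma), dnorm(cy, mu[2], sigma))
  ud_new(mass / sum(mass), i0, j0, cell)
}

# forward OU simulator used as the data generator in fit-recovery tests
# (kept separate from the package internals)
sim_ou_series <- function(n, dt, tau, sigma2, mu = 0) {
  x <- numeric(n)
  x[1] <- rnorm(1, mu, sqrt(sigma2))
  phi <- exp(-dt / tau)
  s <- sqrt(sigma2 * (1 - phi^2))
  for (k in 2:n) x[k] <- mu + phi * (x[k - 1] - mu) + rnorm(1, 0, s)
  x
}

# hand-built trip object (bypasses segmentation) for patch-use unit tests
make_trip <- function(lonlat, id = "bird1", colony = "C1",
                      t0 = as.POSIXct("2017-07-15 12:00:00", tz = "UTC")) {
  fixes <- data.frame(individual_id = id, colony_id = colony,
                      time = t0 + seq_len(nrow(lonlat)) * 600,
                      lon = lonlat[, 1], lat = lonlat[, 2],
                      stringsAsFactors = FALSE)
  structure(list(trip_id = paste0(id, "_T01"), individual_id = id,
                 colony_id = colony, fixes = fixes,
                 start = fixes$time[1], end = fixes$time[nrow(fixes)],
                 complete = TRUE, max_range_km = NA_real_,
                 land_fraction = NA_real_), class = "trip")
}

# small fix table on a regular 10-min grid from planar offsets (m) around a
# colony at `centre`
fixes_from_xy <- function(xy, centre, id = "bird1", colony = "C1",
                          interval_min = 10,
                          t0 = as.POSIXct("2017-07-15 00:00:00", tz = "UTC")) {
  ll <- from_local_xy(xy, centre)
  data.frame(individual_id = id, colony_id = colony,
             time = t0 + (seq_len(nrow(xy)) - 1) * interval_min * 60,
             lon = ll[, 1], lat = ll[, 2], stringsAsFactors = FALSE)
}

KONGS_CENTRE <- c(12.2525, 78.9325)

# exhaustive enumeration of the ANOSIM null distribution for two groups
# (independent oracle for the sampled permutation p)
exact_anosim_p <- function(d, groups) {
  n <- nrow(d)
  lower <- lower.tri(d)
  rk <- matrix(0, n, n)
  rk[lower] <- rank(d[lower])
  stat <- function(g) {
    same <- outer(g, g, "==")
    (mean(rk[lower][!same[lower]]) - mean(rk[lower][same[lower]])) /
      (n * (n - 1) / 4)
  }
  obs <- stat(groups)
  idx_a <- combn(n, sum(groups == groups[1]))
  stats <- apply(idx_a, 2, function(ia) {
    g <- rep("B", n)
    g[ia] <- "A"
    stat(g)
  })
  list(R = obs, p = mean(stats >= obs - 1e-12))
}
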