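colony <- list(id = "C1", lon = KONGS_CENTRE[1], lat = KONGS_CENTRE[2])

test_that("great-circle distance: identity, quarter equator, colony pair", {
  expect_equal(great_circle_km(c(12, 79), c(12, 79)), 0)
  # quarter of the equator: pi * R / 2
  expect_equal(great_circle_km(c(0, 0), c(90, 0)), pi * 6371.0088 / 2,
               tolerance = 1e-6)
  expect_equal(great_circle_km(c(0, 0), c(90, 0)), 10007.5, tolerance = 1e-4)
  # Krykkjefjellet - Ossian Sarsfjellet from 0.01-degree coordinates
  kry_oss <- great_circle_km(c(12.18, 78.89), c(12.44, 78.92))
  expect_equal(kry_oss, 6.50, tolerance = 0.02)
  # symmetry
  expect_equal(great_circle_km(c(12.18, 78.89), c(12.44, 78.92)),
               great_circle_km(c(12.44, 78.92), c(12.18, 78.89)))
})

test_that("read_fixes parses, sorts, validates and deduplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- "individual_id\tcolony_id\ttimestamp_iso8601_utc\tlon_wgs84\tlat_wgs84"
  writeLines(c(hdr,
               "b1\tC1\t2017-07-15T00:20:00Z\t12.30\t78.93",
               "b1\tC1\t2017-07-15T00:00:00Z\t12.10\t78.91",
               "b1\tC1\t2017-07-15T00:10:00Z\t12.20\t78.92"), path)
  fx <- read_fixes(path)
  expect_equal(nrow(fx), 3)
  expect_equal(length(unique(fx$individual_id)), 1)
  expect_true(!is.unsorted(fx$time))
  expect_equal(fx$lon, c(12.10, 12.20, 12.30))

  writeLines(c(hdr, "b1\tC1\t2017-07-15T00:00:00Z\t12.10\t97.0"), path)
  expect_error(read_fixes(path), "line")

  writeLines(c(hdr, "b1\tC1\t2017-07-15T00:00:00Z\t12.10\t78.91"),
             paste0(path, "2"))
  writeLines(c(hdr,
               "b1\tC1\t2017-07-15T00:00:00Z\t12.10\t78.91",
               "b1\tC1\t2017-07-15T00:00:00Z\t12.11\t78.92"), path)
  expect_warning(fx <- read_fixes(path), "duplicate")
  expect_equal(nrow(fx), 1)
  expect_equal(fx$lon, 12.10)
})

test_that("fix tables round-trip through write_fixes/read_fixes byte-stably", {
  cfg <- sim_config(seed = 3, individuals_per_colony = 1)
  sea <- simulate_seascape(cfg)
  sim <- simulate_tracks(cfg, sea)
  p1 <- withr::local_tempfile()
  p2 <- withr::local_tempfile()
  write_fixes(sim$fixes, p1)
  back <- read_fixes(p1)
  write_fixes(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(back$lon, sim$fixes$lon, tolerance = 1e-7)
})

test_that("speed filter removes aberrant fixes iteratively", {
  t0 <- as.POSIXct("2017-07-15 00:00:00", tz = "UTC")
  ctr <- KONGS_CENTRE
  # two fixes 10 min apart, 20 km apart: 120 km/h, second removed
  xy <- rbind(c(0, 0), c(20000, 0))
  fx <- fixes_from_xy(xy, ctr)
  out <- filter_speed(fx, 80)
  expect_equal(nrow(out), 1)

  # all speeds < 80: identity
  xy <- rbind(c(0, 0), c(5000, 0), c(10000, 0), c(15000, 0))
  fx <- fixes_from_xy(xy, ctr)
  expect_equal(nrow(filter_speed(fx, 80)), 4)

  # A-B-C where only B is aberrant: B removed, A and C retained because the
  # A -> C speed is legal
  xy <- rbind(c(0, 0), c(25000, 0), c(5000, 0))
  fx <- fixes_from_xy(xy, ctr)
  out <- filter_speed(fx, 80)
  expect_equal(nrow(out), 2)
  expect_equal(great_circle_km(cbind(out$lon, out$lat)[2, ],
                               cbind(fx$lon, fx$lat)[3, ]), 0)
})

test_that("interval subsampling keeps every 5th 2-min fix and is the identity at 10 min", {
  ctr <- KONGS_CENTRE
  t0 <- as.POSIXct("2017-07-15 00:00:00", tz = "UTC")
  n <- 31
  fx2 <- data.frame(individual_id = "b1", colony_id = "C1",
                    time = t0 + (seq_len(n) - 1) * 120,
                    lon = 12 + seq_len(n) / 1000, lat = 78.9)
  out <- subsample_interval(fx2, 10, 1)
  expect_equal(out$time, fx2$time[seq(1, n, by = 5)])

  fx10 <- fx2[seq(1, n, by = 5), ]
  expect_equal(subsample_interval(fx10, 10, 1), fx10, ignore_attr = TRUE)
})

test_that("subsampling a jittered 2/3-min series leaves gaps in [9, 11] min", {
  withr::with_seed(11, {
    t0 <- as.POSIXct("2017-07-15 00:00:00", tz = "UTC")
    steps <- sample(c(2, 3), 400, replace = TRUE)
    tm <- t0 + cumsum(c(0, steps)) * 60
    fx <- data.frame(individual_id = "b1", colony_id = "C1", time = tm,
                     lon = 12 + seq_along(tm) / 1000, lat = 78.9)
    out <- subsample_interval(fx, 10, 1)
    gaps <- diff(as.numeric(out$time)) / 60
    expect_true(all(gaps >= 9 & gaps <= 11))
  })
})

test_that("trip segmentation applies the colony radius and minimum duration", {
  ctr <- KONGS_CENTRE
  at_col <- matrix(0, 5, 2)
  away <- cbind(rep(1000, 7), 0)  # 1 km out, 7 fixes = 60 min span
  xy <- rbind(at_col, away, at_col)
  fx <- fixes_from_xy(xy, ctr)
  trips <- segment_trips(fx, colony)
  expect_length(trips, 1)
  expect_equal(nrow(trips[[1]]$fixes), 7)
  expect_true(trips[[1]]$complete)
  expect_equal(trips[[1]]$trip_id, "bird1_T01")
  expect_equal(trips[[1]]$max_range_km, 1, tolerance = 1e-3)

  # 4 fixes outside (30-min span): below the 50-min rule
  xy <- rbind(at_col, cbind(rep(1000, 4), 0), at_col)
  expect_length(segment_trips(fixes_from_xy(xy, ctr), colony), 0)

  # record ends while the bird is away: incomplete
  xy <- rbind(at_col, away)
  trips <- segment_trips(fixes_from_xy(xy, ctr), colony)
  expect_length(trips, 1)
  expect_false(trips[[1]]$complete)

  expect_length(segment_trips(fx[0, ], colony), 0)
})

test_that("segmentation is invariant to pre/appending at-colony fixes", {
  ctr <- KONGS_CENTRE
  away <- cbind(rep(1500, 8), 0)
  core <- rbind(matrix(0, 3, 2), away, matrix(0, 3, 2))
  padded <- rbind(matrix(0, 6, 2), away, matrix(0, 6, 2))
  tr1 <- segment_trips(fixes_from_xy(core, ctr), colony)
  tr2 <- segment_trips(fixes_from_xy(padded, ctr), colony)
  expect_length(tr1, 1)
  expect_length(tr2, 1)
  expect_equal(nrow(tr1[[1]]$fixes), nrow(tr2[[1]]$fixes))
  expect_equal(tr1[[1]]$max_range_km, tr2[[1]]$max_range_km)
})

test_that("land fraction and the >= 50% over-land filter", {
  ctr <- KONGS_CENTRE
  # square land polygon, 10 x 10 km east of the colony
  land <- from_local_xy(rbind(c(5000, -5000), c(15000, -5000),
                              c(15000, 5000), c(5000, 5000),
                              c(5000, -5000)), ctr)
  sea_xy <- cbind(seq(-2000, -4000, length.out = 10), 0)
  land_xy <- cbind(seq(6000, 14000, length.out = 10), 0)

  tr_sea <- make_trip(from_local_xy(sea_xy, ctr))
  expect_equal(land_fraction(tr_sea, land), 0)
  expect_length(filter_overland(list(tr_sea), land), 1)

  mixed <- rbind(land_xy[1:6, ], sea_xy[1:4, ])
  tr_mixed <- make_trip(from_local_xy(mixed, ctr))
  expect_equal(land_fraction(tr_mixed, land), 0.6)
  expect_length(filter_overland(list(tr_mixed), land), 0)

  # exactly 50% is removed ("equal to or greater")
  half <- rbind(land_xy[1:5, ], sea_xy[1:5, ])
  tr_half <- make_trip(from_local_xy(half, ctr))
  expect_equal(land_fraction(tr_half, land), 0.5)
  expect_length(filter_overland(list(tr_half), land), 0)

  expect_error(land_fraction(tr_sea, land[c(1, 1, 1), ]), "degenerate")
})

test_that("morphometric sexing uses the inclusive 90.5-mm cut-off", {
  expect_equal(sex_from_headbill(88.0), "female")
  expect_equal(sex_from_headbill(90.5), "female")
  expect_equal(sex_from_headbill(92.1), "male")
  expect_equal(sex_from_headbill(c(90.5, 90.6)), c("female", "male"))
  expect_error(sex_from_headbill(-1), "positive")
})

test_that("Mann-Whitney U matches a brute-force pairwise enumeration", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$U, 0)
  r <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$U, 4.5)  # n1 * n2 / 2 by symmetry
  r <- mann_whitney_u(rep(2, 4), rep(2, 5))
  expect_equal(r$U, 10)
  expect_equal(r$p, 1)

  withr::with_seed(21, {
    for (rep in 1:5) {
      x <- sample(1:15, 20, replace = TRUE)  # ties on purpose
      y <- sample(3:18, 20, replace = TRUE)
      u_brute <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
      expect_equal(mann_whitney_u(x, y)$U, u_brute)
    }
  })
})
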