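test_that("the regional M>2 catalog fixture parses completely", {
  cat1 <- read_catalog(catalog_fixture("neuwied_m2_2009_2012"))
  expect_equal(nrow(cat1), 10)
  expect_equal(format(cat1$origin_time[1], "%Y-%m-%d %H:%M:%OS2"),
               "2009-09-10 12:36:21.70")
  expect_true(all(cat1$magnitude > 2.0))
  expect_true(cat1$depth_manual[cat1$label == "Bad Ems"])

  sep <- read_catalog(catalog_fixture("neuwied_sep2009"))
  be <- sep[sep$label == "Bad Ems", ]
  expect_equal(be$magnitude, 3.2)
  expect_equal(be$depth_km, 5.0)
  expect_true(be$depth_manual)

  jun <- read_catalog(catalog_fixture("neuwied_jun2010"))
  expect_equal(nrow(jun), 11)
  expect_true(all(jun$magnitude < 2))
})

test_that("empty and malformed catalogs are handled row-wise", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("label,date,time_utc,depth_km,magnitude,lon,lat", f)
  expect_equal(nrow(read_catalog(f)), 0)

  writeLines(c("label,date,time_utc,depth_km,magnitude,lon,lat",
               "Good,2010-01-01,01:02:03.0,5,1.5,7.3,50.3",
               "Bad,notadate,01:02:03.0,5,1.5,7.3,50.3",
               "AlsoBad,2010-01-03,01:02:03.0,5,1.5,999,50.3"), f)
  cat2 <- read_catalog(f)
  expect_equal(nrow(cat2), 1)
  expect_equal(attr(cat2, "rejected"), c(2L, 3L))
})

test_that("great-circle distances match an independent formula", {
  expect_equal(haversine_km(c(7.33, 50.31), c(7.33, 50.31)), 0)
  expect_equal(haversine_km(c(0, 0), c(180, 0)), pi * 6371.0,
               tolerance = 1e-6)
  a <- c(7.33, 50.31); b <- c(7.72, 50.40)
  expect_equal(haversine_km(a, b), slc_km(a, b), tolerance = 0.1)

  # triangle inequality on random coordinate triples
  set.seed(3)
  for (i in 1:20) {
    p <- cbind(runif(3, -180, 180), runif(3, -90, 90))
    d12 <- haversine_km(p[1, ], p[2, ])
    d23 <- haversine_km(p[2, ], p[3, ])
    d13 <- haversine_km(p[1, ], p[3, ])
    expect_lte(d13, d12 + d23 + 1e-6)
  }
})

test_that("event filtering is strict in magnitude and monotone in radius", {
  station <- c(7.40, 50.35)
  cat1 <- read_catalog(catalog_fixture("neuwied_m2_2009_2012"))
  kept <- filter_events(cat1, station, 100, 2.0)
  expect_equal(nrow(kept), 10)
  expect_true(all(diff(as.numeric(kept$origin_time)) >= 0))

  expect_equal(nrow(filter_events(cat1, c(8.5, 51.5), 0, 2.0)), 0)

  sep <- read_catalog(catalog_fixture("neuwied_sep2009"))
  sel <- filter_events(sep, station, 100, 2.0)
  expect_equal(sel$label, "Bad Ems")   # only the M 3.2 event exceeds 2.0

  # idempotence and monotonicity
  again <- filter_events(kept, station, 100, 2.0)
  expect_equal(nrow(again), nrow(kept))
  n_r <- sapply(c(5, 15, 30, 100), function(r)
    nrow(filter_events(cat1, station, r, 2.0)))
  expect_true(all(diff(n_r) >= 0))
  n_m <- sapply(c(2.0, 2.4, 2.8, 3.2), function(m)
    nrow(filter_events(cat1, station, 100, m)))
  expect_true(all(diff(n_m) <= 0))
})

test_that("event windows are re-timed to the origin with coverage", {
  t0 <- as.POSIXct("2010-06-10 00:00:00", tz = "UTC")
  s <- data.frame(timestamp = t0 + seq(0, 48 * 3600, by = 600),
                  index = 1)
  ev <- list(origin_time = t0 + 24 * 3600)
  w <- extract_event_window(s, ev, 24, 24)
  expect_equal(range(w$t_rel_hours), c(-24, 24))
  expect_equal(attr(w, "coverage"), 1.0)

  ev_late <- list(origin_time = t0 + 47 * 3600)
  w2 <- extract_event_window(s, ev_late, 24, 24)
  expect_lt(attr(w2, "coverage"), 1)
  expect_error(extract_event_window(s, list(origin_time = t0 + 900000),
                                    24, 24),
               "event outside series")

  # extraction commutes with a common time shift
  off <- 7200
  s_shift <- s; s_shift$timestamp <- s$timestamp + off
  w3 <- extract_event_window(s_shift,
                             list(origin_time = ev$origin_time + off),
                             24, 24)
  expect_equal(w3$t_rel_hours, w$t_rel_hours)

  # an injected dip is found at its injected offset
  dip <- s
  dip$index[dip$timestamp >= ev$origin_time - 3 * 3600 &
              dip$timestamp <= ev$origin_time - 2 * 3600] <- 0
  w4 <- extract_event_window(dip, ev, 24, 24)
  expect_true(all(w4$t_rel_hours[w4$index == min(w4$index)] >= -3 &
                    w4$t_rel_hours[w4$index == min(w4$index)] <= -2))
})

test_that("nocturnal suppression scoring flags displaced nights", {
  t0 <- as.POSIXct("2010-06-01 00:00:00", tz = "UTC")
  mk_night <- function(level) {
    data.frame(timestamp = t0 + seq(0, 6 * 3600, by = 600),
               index = level)
  }
  ref <- lapply(c(0.4, 0.5, 0.6, 0.45, 0.55), mk_night)
  base <- night_baseline(ref)
  expect_equal(base$n_nights, 5)

  same <- flag_rest_suppression(mk_night(base$mean), base)
  expect_equal(same$score, 0)
  expect_false(same$flag)

  raised <- flag_rest_suppression(mk_night(base$mean + 5 * base$sd), base)
  expect_equal(raised$score, 5, tolerance = 1e-9)
  expect_true(raised$flag)

  expect_error(night_baseline(ref[1:3]), "no baseline")
  degenerate <- night_baseline(lapply(rep(0, 5), mk_night))
  expect_error(flag_rest_suppression(mk_night(0), degenerate),
               "degenerate baseline")
})

test_that("synthetic catalogs respect their own generating envelope", {
  station <- c(7.40, 50.35)
  cat_s <- generate_catalog(25, "2010-01-01", "2010-12-31",
                            magnitude_range = c(0.5, 3.5),
                            station = station, radius_km = 40, seed = 9)
  expect_equal(nrow(filter_events(cat_s, station, 40 + 1e-6, 0.4)), 25)
  cat_s2 <- generate_catalog(25, "2010-01-01", "2010-12-31",
                             magnitude_range = c(0.5, 3.5),
                             station = station, radius_km = 40, seed = 9)
  expect_identical(cat_s$lon, cat_s2$lon)

  at_station <- generate_catalog(5, "2010-01-01", "2010-02-01",
                                 station = station, radius_km = 0, seed = 2)
  expect_equal(max(haversine_km(cbind(at_station$lon, at_station$lat),
                                station)), 0, tolerance = 1e-6)
})
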