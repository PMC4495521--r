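test_that("consensus is the half-up rounded mean of three scores", {
  expect_equal(aggregate_operator_scores(c(4, 4, 4)), 4L)
  expect_equal(aggregate_operator_scores(c(3, 4, 5)), 4L)
  expect_equal(aggregate_operator_scores(c(2, 3, 3)), 3L)  # 2.667 -> 3
  expect_equal(aggregate_operator_scores(c(0, 0, 1)), 0L)  # 0.333 -> 0
  expect_equal(aggregate_operator_scores(c(7, 7, 6)), 7L)
  expect_error(aggregate_operator_scores(c(1, 2, 8)), "invalid category")
  expect_error(aggregate_operator_scores(c(1, 2, -1)), "invalid category")
  expect_error(aggregate_operator_scores(c(1, 2)), "three operator scores")
})

test_that("the manual scoring schedule yields the daily window count", {
  w <- schedule_manual_windows(as.Date("2009-09-10"))
  expect_equal(nrow(w), 144)
  expect_equal(format(w$start[1], "%H:%M:%S"), "00:00:00")
  expect_equal(format(w$start[2], "%H:%M:%S"), "00:10:00")
  expect_equal(as.numeric(w$end[1] - w$start[1], units = "secs"), 60)
  expect_equal(nrow(schedule_manual_windows(as.Date("2009-09-10"),
                                            span_hours = 12)), 72)
  expect_equal(nrow(schedule_manual_windows(as.Date("2009-09-10"),
                                            cadence_minutes = 60)), 24)
  expect_error(schedule_manual_windows(as.Date("2009-09-10"),
                                       cadence_minutes = 0),
               "invalid cadence")
})

make_series <- function(timestamps, raw, mode = "day",
                        registered_ok = TRUE) {
  out <- data.frame(timestamp = timestamps, raw = raw,
                    sensor_mode = rep_len(mode, length(raw)),
                    sigma = 0,
                    registered_ok = rep_len(registered_ok, length(raw)),
                    flagged = FALSE)
  class(out) <- c("activity_series", "data.frame")
  out
}

test_that("pairing takes the within-window median and drops flagged samples", {
  t0 <- as.POSIXct("2010-06-01 00:00:00", tz = "UTC")
  s <- make_series(t0 + c(5, 15, 25), c(10, 12, 900),
                   registered_ok = c(TRUE, TRUE, FALSE))
  ann <- data.frame(timestamp = t0, consensus = 2L)
  p <- pair_samples(s, ann)
  expect_equal(nrow(p$S_d), 1)
  expect_equal(p$S_d$A, 11)        # median of {10, 12}; 900 excluded
  expect_equal(p$S_d$C, 2L)

  # a window with no samples emits no pair
  ann2 <- rbind(ann, data.frame(timestamp = t0 + 600, consensus = 3L))
  p2 <- pair_samples(s, ann2)
  expect_equal(nrow(p2$S_d) + nrow(p2$S_n), 1)
  expect_error(pair_samples(s, data.frame(timestamp = t0 + 9000,
                                          consensus = 1L)),
               "no pairs")
})

test_that("a full-coverage synthetic day pairs every annotation window", {
  # 24 h of 10-s samples, day mode 06-20 h, night otherwise
  t0 <- as.POSIXct("2010-06-01 00:00:00", tz = "UTC")
  ts <- t0 + seq(10, 86400 - 10, by = 10)
  h <- as.numeric(format(ts, "%H", tz = "UTC"))
  s <- make_series(ts, runif(length(ts), 0, 100),
                   mode = ifelse(h >= 6 & h < 20, "day", "night"))
  ann <- data.frame(timestamp = schedule_manual_windows(as.Date("2010-06-01"))$start,
                    consensus = 3L)
  p <- pair_samples(s, ann)
  expect_equal(nrow(p$S_d) + nrow(p$S_n), 144)
  expect_equal(nrow(p$S_d), 14 * 6)   # 14 daytime hours
})

test_that("exact polynomial relationships are recovered with zero residual", {
  A <- seq(0, 900, by = 100)
  S_d <- data.frame(A = A, C = 0.01 * A + 1)
  S_n <- data.frame(A = A, C = 1e-6 * A^2)
  m <- fit_calibration(S_d, S_n)
  expect_equal(m$day_coeffs, c(1, 0.01), tolerance = 1e-10)
  expect_equal(m$rms_day, 0, tolerance = 1e-10)
  expect_equal(m$night_coeffs, c(0, 0, 1e-6), tolerance = 1e-10)
  expect_equal(m$rms_night, 0, tolerance = 1e-10)
  expect_error(fit_calibration(data.frame(A = c(1, 1, 1), C = c(1, 2, 3)),
                               S_n),
               "rank deficient")
})

test_that("noisy fits agree with an independent normal-equations oracle", {
  set.seed(0)
  A <- runif(100, 0, 500)
  C_d <- 1 + 0.01 * A + rnorm(100, 0, 0.3)
  C_n <- 0.5 + 0.003 * A + 2e-6 * A^2 + rnorm(100, 0, 0.3)
  m <- fit_calibration(data.frame(A = A, C = C_d),
                       data.frame(A = A, C = C_n))
  od <- normal_eq_fit(A, C_d, 1)
  on <- normal_eq_fit(A, C_n, 2)
  expect_equal(m$day_coeffs, od$coeffs, tolerance = 1e-8)
  expect_equal(m$rms_day, od$rms, tolerance = 1e-8)
  expect_equal(m$night_coeffs, on$coeffs, tolerance = 1e-8)
  expect_equal(m$rms_night, on$rms, tolerance = 1e-8)

  # the fitted polynomial can never do worse than the best constant
  expect_lte(m$rms_day, sqrt(mean((C_d - mean(C_d))^2)) + 1e-12)
  expect_lte(m$rms_night, sqrt(mean((C_n - mean(C_n))^2)) + 1e-12)
})

test_that("coefficient recovery sharpens as the pair count grows", {
  rel_err <- sapply(c(30, 300), function(n) {
    set.seed(42)
    A <- runif(n, 0, 500)
    C <- 2 + 0.008 * A + rnorm(n, 0, 0.3)
    m <- fit_calibration(
      data.frame(A = A, C = C),
      data.frame(A = A, C = 0.5 + 1e-5 * A^2 + rnorm(n, 0, 0.3)))
    max(abs(m$day_coeffs - c(2, 0.008)) / c(2, 0.008))
  })
  expect_lt(rel_err[2], rel_err[1])
})

test_that("calibrated indices evaluate the polynomial and clamp to [0, 7]", {
  m <- structure(list(day_coeffs = c(1, 0.01),
                      night_coeffs = c(0, 0, 1e-6)),
                 class = "calibration_model")
  expect_equal(apply_calibration(m, 100, "day"), 2)
  expect_equal(apply_calibration(m, -200, "day"), 0)   # -1 clamps up
  expect_equal(apply_calibration(m, 5000, "day"), 7)   # 51 clamps down
  expect_equal(apply_calibration(m, 1000, "night"), 1)
  expect_error(apply_calibration(m, 10, "dusk"), "no model for mode")
})

test_that("the temporal median filter removes isolated spikes", {
  t0 <- as.POSIXct("2010-06-01 00:00:00", tz = "UTC")
  n <- 121
  s <- data.frame(timestamp = t0 + (0:(n - 1)) * 10, index = 0)

  expect_identical(median_filter_series(s)$index, rep(0, n))

  spike <- s; spike$index[60] <- 7
  expect_identical(median_filter_series(spike)$index, rep(0, n))

  # idempotent on a step signal
  step <- s; step$index <- rep(c(0, 5), each = ceiling(n / 2))[1:n]
  once <- median_filter_series(step)
  twice <- median_filter_series(once)
  expect_identical(twice$index, once$index)

  empty <- s[0, ]
  expect_equal(nrow(median_filter_series(empty)), 0)
})
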