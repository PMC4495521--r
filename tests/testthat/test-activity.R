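test_that("pixel noise is zero for repeated frames and matches injected noise", {
  H <- 32; W <- 32
  base <- matrix(128, H, W)
  mask <- mound_mask(rect_mask(H, W, 0.4))
  t0 <- as.POSIXct("2010-06-01 10:00:00", tz = "UTC")

  reps <- frame_sequence(frames_at(rep(list(base), 12)), cadence = 10)
  expect_equal(estimate_pixel_noise(reps, mask, "day", register = FALSE), 0)

  # i.i.d. Gaussian noise sd = 2 per frame: the difference of two frames
  # has scale 2 * sqrt(2)
  set.seed(0)
  noisy <- lapply(1:51, function(i)
    pmin(pmax(base + matrix(rnorm(H * W, 0, 2), H, W), 0), 255))
  sn <- frame_sequence(frames_at(noisy), cadence = 10)
  sigma <- estimate_pixel_noise(sn, mask, "day", n_pairs = 50,
                                register = FALSE)
  expect_equal(sigma, 2 * sqrt(2), tolerance = 0.1)

  short <- frame_sequence(frames_at(rep(list(base), 5)), cadence = 10)
  expect_error(estimate_pixel_noise(short, mask, "day"),
               "insufficient data")
})

test_that("noise is estimated separately per sensor mode", {
  H <- 32; W <- 32
  base <- matrix(128, H, W)
  mask <- mound_mask(rect_mask(H, W, 0.4))
  set.seed(1)
  day <- rep(list(base), 15)
  night <- lapply(1:15, function(i)
    pmin(pmax(base + matrix(rnorm(H * W, 0, 3), H, W), 0), 255))
  seqm <- frame_sequence(
    frames_at(c(day, night), mode = rep(c("day", "night"), each = 15)),
    cadence = 10)
  s_day <- estimate_pixel_noise(seqm, mask, "day", register = FALSE)
  s_night <- estimate_pixel_noise(seqm, mask, "night", register = FALSE)
  expect_equal(s_day, 0)
  expect_gt(s_night, 2)
})

test_that("a moving dot contributes its vacated and occupied pixels", {
  H <- 32; W <- 32
  bg <- matrix(100, H, W)
  mask <- mound_mask(rect_mask(H, W, 0.6))
  put_dot <- function(g, y, x) { g[y:(y + 1), x:(x + 1)] <- 180; g }
  prev_g <- put_dot(bg, 12, 12)
  cur_g <- put_dot(bg, 18, 18)
  fr <- frames_at(list(prev_g, cur_g))
  s <- compute_raw_activity(fr[[1]], fr[[2]], mask, sigma = 1)
  expect_equal(s$raw, 8 * 80)    # 4 pixels vacated + 4 occupied, |delta| 80

  # identical frames: the difference image is black
  s0 <- compute_raw_activity(fr[[1]], fr[[1]], mask, sigma = 1)
  expect_equal(s0$raw, 0)

  # the same motion entirely outside the mask contributes nothing
  border_dots <- frames_at(list(put_dot(bg, 2, 2), put_dot(bg, 2, 8)))
  expect_equal(compute_raw_activity(border_dots[[1]], border_dots[[2]],
                                    mound_mask(rect_mask(H, W, 0.5)),
                                    1)$raw, 0)

  # content outside M never changes the sum
  prev2 <- prev_g; prev2[1, ] <- 0
  cur2 <- cur_g; cur2[1, ] <- 255
  fr2 <- frames_at(list(prev2, cur2))
  expect_equal(compute_raw_activity(fr2[[1]], fr2[[2]], mask, 1)$raw,
               s$raw)

  # day/night boundary pairs are flagged, not computed
  mixed <- frames_at(list(prev_g, cur_g), mode = c("day", "night"))
  sm <- compute_raw_activity(mixed[[1]], mixed[[2]], mask, 1)
  expect_true(sm$flagged)
  expect_true(is.na(sm$raw))
})

test_that("production difference sum matches a brute-force loop bit-exactly", {
  for (seed in 1:25) {
    set.seed(seed)
    H <- 32; W <- 32
    prev_g <- round(matrix(runif(H * W, 0, 255), H, W))
    cur_g <- round(matrix(runif(H * W, 0, 255), H, W))
    mask_m <- matrix(runif(H * W) < 0.4, H, W)
    if (!any(mask_m)) mask_m[1, 1] <- TRUE
    sigma <- runif(1, 0, 20)
    fr <- frames_at(list(prev_g, cur_g))
    got <- compute_raw_activity(fr[[1]], fr[[2]], mound_mask(mask_m), sigma)
    expect_identical(got$raw,
                     brute_force_activity(prev_g, cur_g, mask_m, sigma))
  }
})

test_that("a static scene yields zero activity throughout", {
  sc <- scene_config(n_frames = 100, n_ants = 0, noise_sd = c(day = 0,
                                                              night = 0),
                     jitter_px = 0, seed = 5,
                     start = as.POSIXct("2010-06-01 10:00:00", tz = "UTC"))
  sv <- generate_video(sc)
  as <- compute_activity_series(sv$sequence, sv$mask)
  expect_equal(nrow(as), 99)
  expect_true(all(as$raw == 0))
})

test_that("mean activity increases with the number of moving ants", {
  mean_raw <- sapply(c(1, 5, 20), function(n) {
    sc <- scene_config(n_frames = 60, n_ants = n, seed = 1,
                       start = as.POSIXct("2010-06-01 10:00:00",
                                          tz = "UTC"))
    sv <- generate_video(sc)
    mean(compute_activity_series(sv$sequence, sv$mask)$raw)
  })
  expect_true(all(diff(mean_raw) > 0))
})

test_that("registration compensates camera jitter in the activity series", {
  mk <- function(jit) {
    sc <- scene_config(n_frames = 150, n_ants = 8, jitter_px = jit,
                       seed = 5,
                       start = as.POSIXct("2010-06-01 10:00:00",
                                          tz = "UTC"))
    sv <- generate_video(sc)
    mean(compute_activity_series(sv$sequence, sv$mask)$raw)
  }
  a_still <- mk(0)
  a_jit <- mk(2)
  expect_lt(abs(a_jit - a_still) / a_still, 0.05)
})

test_that("dropouts and sensor switches yield no sample", {
  g <- textured_grid(12, 32, 32)
  t0 <- as.POSIXct("2010-06-01 10:00:00", tz = "UTC")
  frames <- list(
    frame_record(g, t0, "day"),
    frame_record(g, t0 + 10, "day"),
    frame_record(g, t0 + 50, "day"),     # 40-s gap: dropout
    frame_record(g, t0 + 60, "night"),   # sensor switch
    frame_record(g, t0 + 70, "night"))
  s <- frame_sequence(frames, cadence = 10)
  as <- compute_activity_series(s, mound_mask(rect_mask(32, 32, 0.4)),
                                sigma = c(day = 0, night = 0),
                                register = FALSE)
  expect_equal(nrow(as), 2)   # pairs (1,2) and (4,5) only
})
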