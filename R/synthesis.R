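#' Synthetic scene configuration
#'
#' Describes a synthetic mound scene: a static textured background, a
#' central elliptical mound region in which small high-contrast ants
#' perform a random walk, per-mode Gaussian sensor noise, integer camera
#' jitter, and a day/night sensor schedule. Daytime frames are rendered as
#' 3-channel color images with bright ants on the darker mound; night
#' frames are single-channel near-infrared with dark ants on bright,
#' strongly NIR-reflective grass. Frame differencing is agnostic to the
#' contrast sign, and the generator deliberately exercises both.
#'
#' @param width,height Frame geometry in pixels.
#' @param n_frames Number of frames.
#' @param cadence Inter-frame interval, seconds (the 10-s analysis
#'   cadence).
#' @param start UTC start instant.
#' @param day_start,day_end Hours (UTC) between which the color sensor is
#'   active; outside them the near-infrared sensor runs.
#' @param n_ants Ant-count schedule: a single number, a vector of length
#'   `n_frames`, or a profile data frame from [generate_daily_profile()]
#'   (matched to frame times by hour of day).
#' @param ant_size Ant footprint side length, pixels.
#' @param contrast Absolute intensity offset of an ant against its local
#'   background.
#' @param speed Random-walk step scale, pixels/frame.
#' @param noise_sd Named `c(day =, night =)` Gaussian sensor noise sd.
#' @param jitter_px Maximum absolute camera jitter per frame, pixels
#'   (uniform integer in \[-jitter_px, jitter_px\] per axis).
#' @param seed Integer seed fixing every random draw.
#' @return List of class `scene_config`.
#' @export
scene_config <- function(width = 64, height = 48, n_frames = 360,
                         cadence = 10,
                         start = as.POSIXct("2010-06-01 00:00:00",
                                            tz = "UTC"),
                         day_start = 6, day_end = 20,
                         n_ants = 5, ant_size = 2, contrast = 80,
                         speed = 1.5,
                         noise_sd = c(day = 2, night = 2),
                         jitter_px = 1, seed = 1) {
  stopifnot(width > 8, height > 8, n_frames >= 1, cadence > 0,
            ant_size >= 1, contrast >= 0, all(noise_sd >= 0),
            jitter_px >= 0)
  structure(list(width = width, height = height, n_frames = n_frames,
                 cadence = cadence, start = as.POSIXct(start, tz = "UTC"),
                 day_start = day_start, day_end = day_end,
                 n_ants = n_ants, ant_size = ant_size, contrast = contrast,
                 speed = speed, noise_sd = noise_sd, jitter_px = jitter_px,
                 seed = seed),
            class = "scene_config")
}

scene_mask_matrix <- function(H, W) {
  # central ellipse: the visible mound top
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((yy - (H + 1) / 2) / (0.32 * H))^2 +
    ((xx - (W + 1) / 2) / (0.35 * W))^2 <= 1
}

smooth3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- function(i, n) pmin(pmax(i, 1), n)
  out <- matrix(0, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    out <- out + m[pad(seq_len(H) + dy, H), pad(seq_len(W) + dx, W)]
  }
  out / 9
}

scene_backgrounds <- function(H, W, mask) {
  tex <- smooth3(matrix(stats::runif(H * W), H, W))
  tex <- (tex - min(tex)) / max(1e-12, diff(range(tex)))
  day <- round(60 + 70 * tex)          # dark-ish mound scene
  night <- round(150 + 80 * tex)       # bright NIR grass
  night[mask] <- round(100 + 60 * tex[mask])  # mound material darker in NIR
  list(day = day, night = night)
}

frame_mode_at <- function(times, day_start, day_end) {
  h <- as.numeric(format(times, "%H", tz = "UTC")) +
    as.numeric(format(times, "%M", tz = "UTC")) / 60 +
    as.numeric(format(times, "%S", tz = "UTC")) / 3600
  ifelse(h >= day_start & h < day_end, "day", "night")
}

ant_schedule_counts <- function(config, times) {
  n <- config$n_ants
  if (is.data.frame(n)) {
    h <- (as.numeric(times) - as.numeric(trunc(times[1], "days"))) %% 86400
    idx <- pmin(nrow(n), findInterval(h, n$time_s) + 0L)
    idx[idx < 1L] <- 1L
    return(n$n_ants[idx])
  }
  rep_len(n, length(times))
}

stamp_ants <- function(base, pos, size, value) {
  if (nrow(pos) == 0L) return(base)
  H <- nrow(base); W <- ncol(base)
  for (k in seq_len(nrow(pos))) {
    y <- pos[k, 1]; x <- pos[k, 2]
    ys <- y:min(H, y + size - 1); xs <- x:min(W, x + size - 1)
    base[ys, xs] <- value
  }
  base
}

replicate_shift <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  m[pmin(pmax(seq_len(H) - dy, 1), H), pmin(pmax(seq_len(W) - dx, 1), W)]
}

#' Render a synthetic frame sequence with ground truth
#'
#' Deterministic given the config seed. Ants walk randomly inside the
#' mound ellipse; each frame the whole scene is translated by the sampled
#' camera jitter (replicate-padded), per-mode Gaussian sensor noise is
#' added, and the frame is quantized to the 8-bit grid. Daytime frames are
#' rendered as 3-channel images and pass through [to_intensity()], exactly
#' as real frames would.
#'
#' @param config A [scene_config()].
#' @return List with `sequence` (a [frame_sequence()]), `mask` (the
#'   [mound_mask()] the ants are confined to), and `truth`: a list with
#'   per-frame data frame `frames` (`timestamp`, `sensor_mode`, `n_ants`,
#'   `jitter_dy`, `jitter_dx`) and `positions` (list of k x 2 matrices of
#'   ant upper-left corners).
#' @export
generate_video <- function(config) {
  H <- config$height; W <- config$width
  mask <- scene_mask_matrix(H, W)
  if (config$ant_size^2 > sum(mask)) stop("infeasible scene")
  set.seed(config$seed)
  bg <- scene_backgrounds(H, W, mask)
  times <- config$start + (seq_len(config$n_frames) - 1) * config$cadence
  modes <- frame_mode_at(times, config$day_start, config$day_end)
  counts <- ant_schedule_counts(config, times)
  n_max <- max(counts, 1L)

  # persistent walker positions (upper-left corners), confined to the mask
  # bounding box and re-drawn if they leave the ellipse
  inside <- which(mask, arr.ind = TRUE)
  draw_pos <- function(k) inside[sample(nrow(inside), k, replace = TRUE), ,
                                 drop = FALSE]
  pos <- draw_pos(n_max)

  frames <- vector("list", config$n_frames)
  positions <- vector("list", config$n_frames)
  jit <- matrix(0L, config$n_frames, 2)
  amp <- config$jitter_px
  for (i in seq_len(config$n_frames)) {
    if (i > 1L) {
      step <- matrix(round(stats::rnorm(2 * n_max, 0, config$speed)),
                     n_max, 2)
      cand <- pos + step
      okp <- cand[, 1] >= 1 & cand[, 1] <= H &
        cand[, 2] >= 1 & cand[, 2] <= W
      okp[okp] <- mask[cand[okp, , drop = FALSE]]
      pos[okp, ] <- cand[okp, , drop = FALSE]
      still <- which(!okp)
      if (length(still)) pos[still, ] <- draw_pos(length(still))
    }
    mode <- modes[i]
    k <- counts[i]
    act <- pos[seq_len(k), , drop = FALSE]
    ant_val <- if (mode == "day") {
      min(255, 60 + 70 + config$contrast)
    } else {
      max(0, 100 - config$contrast)
    }
    fr <- stamp_ants(bg[[mode]], act, config$ant_size, ant_val)
    if (amp > 0) {
      jit[i, ] <- sample(seq(-amp, amp), 2, replace = TRUE)
      fr <- replicate_shift(fr, jit[i, 1], jit[i, 2])
    }
    sdn <- config$noise_sd[[mode]]
    if (sdn > 0) fr <- fr + matrix(stats::rnorm(H * W, 0, sdn), H, W)
    fr <- pmin(pmax(round(fr), 0), 255)
    raw <- if (mode == "day") array(fr, c(H, W, 3)) else fr
    frames[[i]] <- frame_record(to_intensity(raw, mode), times[i], mode,
                                source_id = "SynthCam")
    positions[[i]] <- act
  }
  truth_frames <- data.frame(timestamp = times, sensor_mode = modes,
                             n_ants = counts,
                             jitter_dy = jit[, 1], jitter_dx = jit[, 2])
  list(sequence = frame_sequence(frames, cadence = config$cadence),
       mask = mound_mask(mask),
       truth = list(frames = truth_frames, positions = positions))
}

#' Daily ant-count profile
#'
#' The standard daily routine of red wood ants is an M-shaped curve:
#' activity rises from dawn, peaks at midday and again in the late
#' afternoon, and falls off in the evening, with a near-zero nocturnal
#' rest phase. `"M_shaped"` renders that shape from two Gaussian bumps
#' (centers 12:00 and 17:00); `"flat"` is a constant schedule;
#' `"suppressed_night"` takes the M-shaped baseline and displaces the
#' level inside a configured window around an origin time — emulating the
#' anomalous nights on which the rest phase is replaced by activity.
#'
#' @param shape `"M_shaped"`, `"flat"` or `"suppressed_night"`.
#' @param cadence Schedule resolution, seconds.
#' @param n_max Ant count at the main (midday) peak.
#' @param night_level Mean nocturnal ant count.
#' @param flat_level Count used by `"flat"`.
#' @param origin_hour,pre_hours,post_hours,delta `"suppressed_night"`
#'   window: the level is shifted by `delta` ants for hours in
#'   `[origin_hour - pre_hours, origin_hour + post_hours]`.
#' @return Data frame covering 24 h: `time_s` (seconds from 00:00 UTC),
#'   `hour`, `level` (continuous), `n_ants` (= `round(level)`).
#' @export
generate_daily_profile <- function(shape = c("M_shaped", "flat",
                                             "suppressed_night"),
                                   cadence = 10, n_max = 30,
                                   night_level = 0.5, flat_level = 5,
                                   origin_hour = 2, pre_hours = 8,
                                   post_hours = 4, delta = 10) {
  shape <- match.arg(shape)
  time_s <- seq(0, 86400 - cadence, by = cadence)
  h <- time_s / 3600
  level <- switch(
    shape,
    flat = rep(flat_level, length(h)),
    {
      bump <- function(c0, s) exp(-((h - c0) / s)^2 / 2)
      day <- h >= 6 & h < 20
      lv <- rep(night_level, length(h))
      lv[day] <- night_level +
        (n_max - night_level) * (bump(12, 1.8)[day] +
                                   0.85 * bump(17, 1.5)[day])
      lv
    }
  )
  if (shape == "suppressed_night") {
    win <- (h - origin_hour) %% 24
    in_win <- win <= post_hours | win >= 24 - pre_hours
    level[in_win] <- pmax(0, level[in_win] + delta)
  }
  data.frame(time_s = time_s, hour = h, level = level,
             n_ants = as.integer(round(level)))
}

#' Ground-truth categories for a profile on an annotation schedule
#'
#' Maps the mean profile level within each scoring window linearly onto
#' categories 0..6 (category 7, sunbathing, is a special state the
#' generator does not emulate).
#'
#' @param profile A [generate_daily_profile()] data frame.
#' @param windows A [schedule_manual_windows()] data frame.
#' @return Data frame `timestamp`, `category`.
#' @export
truth_categories <- function(profile, windows) {
  day0 <- trunc(windows$start[1], "days")
  w_s <- as.numeric(windows$start) - as.numeric(day0)
  w_e <- as.numeric(windows$end) - as.numeric(day0)
  lv <- vapply(seq_along(w_s), function(i) {
    sel <- profile$time_s >= w_s[i] & profile$time_s < w_e[i]
    if (!any(sel)) profile$level[which.min(abs(profile$time_s - w_s[i]))]
    else mean(profile$level[sel])
  }, numeric(1))
  data.frame(timestamp = windows$start,
             category = pmin(6L, pmax(0L, as.integer(
               round(6 * lv / max(profile$level))))))
}

#' Simulate three operator score streams
#'
#' Each operator reports the true category, independently perturbed by
#' plus or minus one level at the given disagreement rate (clipped to the
#' 0..7 range); the consensus is the rounded mean, exactly as for real
#' annotations.
#'
#' @param truth Data frame `timestamp`, `category` (0..7).
#' @param disagreement Per-operator probability of a one-level error.
#' @param seed Integer seed.
#' @return Data frame `timestamp`, `op1`, `op2`, `op3`, `consensus`.
#' @export
generate_operator_scores <- function(truth, disagreement = 0.2, seed = 1) {
  stopifnot(all(truth$category %in% 0:7))
  set.seed(seed)
  n <- nrow(truth)
  ops <- sapply(1:3, function(j) {
    err <- stats::runif(n) < disagreement
    dir <- sample(c(-1L, 1L), n, replace = TRUE)
    pmin(7L, pmax(0L, truth$category + ifelse(err, dir, 0L)))
  })
  consensus <- vapply(seq_len(n), function(i)
    aggregate_operator_scores(ops[i, ]), integer(1))
  data.frame(timestamp = truth$timestamp, op1 = ops[, 1], op2 = ops[, 2],
             op3 = ops[, 3], consensus = consensus)
}

#' Generate a synthetic earthquake catalog
#'
#' Events are uniform in time over the window, uniform over the spherical
#' disc of the given radius around the station (distance drawn by inverse
#' transform of the spherical-cap area, bearing uniform), with magnitudes
#' uniform in the given range.
#'
#' @param n Number of events.
#' @param start,end UTC window.
#' @param magnitude_range Length-2 numeric.
#' @param station `c(lon, lat)` degrees.
#' @param radius_km Disc radius.
#' @param seed Integer seed.
#' @return A `quake_catalog` data frame (depths uniform 2–15 km,
#'   `depth_manual = FALSE`).
#' @export
generate_catalog <- function(n, start, end, magnitude_range = c(0.1, 3.5),
                             station, radius_km = 40, seed = 1) {
  set.seed(seed)
  t0 <- as.numeric(as.POSIXct(start, tz = "UTC"))
  t1 <- as.numeric(as.POSIXct(end, tz = "UTC"))
  times <- sort(as.POSIXct(stats::runif(n, t0, t1), tz = "UTC",
                           origin = "1970-01-01"))
  R <- EARTH_RADIUS_KM
  u <- stats::runif(n)
  d_km <- R * acos(1 - u * (1 - cos(radius_km / R)))
  brg <- stats::runif(n, 0, 360)
  pts <- geosphere::destPoint(c(station[[1]], station[[2]]), brg,
                              d_km * 1000, r = R * 1000)
  out <- data.frame(label = sprintf("synthetic-%02d", seq_len(n)),
                    origin_time = times,
                    depth_km = round(stats::runif(n, 2, 15), 1),
                    depth_manual = FALSE,
                    magnitude = round(stats::runif(n, magnitude_range[1],
                                                   magnitude_range[2]), 1),
                    lon = pts[, 1], lat = pts[, 2])
  class(out) <- c("quake_catalog", "data.frame")
  out
}
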