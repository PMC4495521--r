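# shared fixture builders -- everything is generated in code

# a reproducible textured intensity grid with strong gradients everywhere
textured_grid <- function(seed, H = 48, W = 64) {
  set.seed(seed)
  round(matrix(stats::runif(H * W, 0, 255), H, W))
}

# translate a grid and fill the uncovered border from the original, so the
# shifted image has no constant padding band (wrap-free construction)
translate_filled <- function(grid, shift) {
  out <- apply_shift(grid, shift)
  out[is.na(out)] <- grid[is.na(out)]
  out
}

# central rectangular mask
rect_mask <- function(H, W, frac = 0.5) {
  m <- matrix(FALSE, H, W)
  ry <- round(H * (1 - frac) / 2); rx <- round(W * (1 - frac) / 2)
  m[(ry + 1):(H - ry), (rx + 1):(W - rx)] <- TRUE
  m
}

# independent straight-loop implementation of the masked, thresholded
# difference sum (the production path is vectorized)
brute_force_activity <- function(prev, cur, mask, sigma) {
  total <- 0
  for (u in seq_len(nrow(prev))) {
    for (v in seq_len(ncol(prev))) {
      if (!mask[u, v]) next
      if (is.na(cur[u, v]) || is.na(prev[u, v])) next
      d <- abs(cur[u, v] - prev[u, v])
      if (d > 3 * sigma) total <- total + d
    }
  }
  total
}

# spherical law of cosines, an independent distance formula
slc_km <- function(a, b, R = 6371.0) {
  to_rad <- pi / 180
  la1 <- a[2] * to_rad; la2 <- b[2] * to_rad
  dlo <- (b[1] - a[1]) * to_rad
  d <- acos(pmin(1, pmax(-1, sin(la1) * sin(la2) +
                           cos(la1) * cos(la2) * cos(dlo))))
  R * d
}

# normal-equations polynomial least squares (independent of lm.fit)
normal_eq_fit <- function(A, C, degree) {
  X <- sapply(0:degree, function(k) A^k)
  beta <- solve(crossprod(X), crossprod(X, C))
  list(coeffs = as.numeric(beta),
       rms = sqrt(mean((C - X %*% beta)^2)))
}

# frame records on a fixed 10-s grid
frames_at <- function(grids, mode = "day", cadence = 10,
                      start = as.POSIXct("2010-06-01 10:00:00", tz = "UTC")) {
  mode <- rep_len(mode, length(grids))
  lapply(seq_along(grids), function(i)
    frame_record(grids[[i]], start + (i - 1) * cadence, mode[i]))
}

# rotate planar points clockwise by phi degrees (azimuth increases by phi)
rotate_azimuth <- function(pts, phi) {
  a <- phi * pi / 180
  cbind(x = pts[, 1] * cos(a) + pts[, 2] * sin(a),
        y = -pts[, 1] * sin(a) + pts[, 2] * cos(a))
}
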