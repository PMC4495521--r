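#' Project geographic coordinates to a local planar frame
#'
#' Azimuthal equidistant projection about a center point: each point is
#' mapped to (x, y) = (d sin(beta), d cos(beta)) where d is the
#' great-circle distance (km) and beta the initial bearing from the
#' center. At the tens-of-km scale of a mound survey, planar treatment of
#' the projected points is standard, but the projection step is explicit.
#'
#' @param lonlat Two-column matrix or data frame of lon/lat in degrees.
#' @param center Length-2 `c(lon, lat)`; defaults to the centroid.
#' @return Matrix with columns `x`, `y` in km (x east, y north).
#' @export
project_local <- function(lonlat, center = NULL) {
  ll <- as.matrix(lonlat)
  if (is.null(center)) center <- colMeans(ll)
  d <- haversine_km(center, ll)
  b <- geosphere::bearing(center, ll) * pi / 180
  cbind(x = d * sin(b), y = d * cos(b))
}

#' Axial orientation histogram of a point set via the Hough transform
#'
#' Accumulates every point into a standard (rho, theta) Hough accumulator
#' and reports, per orientation bin, the total support of accumulator
#' cells holding at least `min_support` points. Orientations are axial
#' azimuths in degrees from North over \[0, 180): a set of points aligned
#' along azimuth alpha concentrates its mass in a single rho cell at the
#' alpha bin, whereas unaligned points spread across cells. Local maxima of
#' the histogram are the preferential alignment directions; their widths
#' reflect the directional variation.
#'
#' @param points Two-column matrix or data frame of planar (x, y)
#'   coordinates (x east, y north; use [project_local()] for lon/lat).
#' @param angle_bins Number of orientation bins over \[0, 180).
#' @param rho_bin Width of the signed-distance bins; default 1/50 of the
#'   point-set diameter.
#' @param min_support Minimum points per accumulator cell for the cell to
#'   count as line support. The default (4) is deliberately above the
#'   minimum of 2 points that define a line: cells holding only 2–3 points
#'   arise by chance at almost every angle of a structured point set, and
#'   admitting them floods the histogram with off-axis support.
#' @return Object of class `orientation_histogram`: list with `theta_deg`
#'   (bin centers), `counts`, `bin_width`, and the parameters used.
#' @export
hough_orientation <- function(points, angle_bins = 180, rho_bin = NULL,
                              min_support = 4) {
  pts <- as.matrix(points)
  if (nrow(pts) < 2L) stop("at least two points required")
  x <- pts[, 1]; y <- pts[, 2]
  diam <- sqrt(diff(range(x))^2 + diff(range(y))^2)
  if (diam == 0) stop("degenerate point set")
  if (is.null(rho_bin)) rho_bin <- diam / 50
  bw <- 180 / angle_bins
  theta <- (seq_len(angle_bins) - 1) * bw       # bin centers, degrees from N
  counts <- numeric(angle_bins)
  for (k in seq_len(angle_bins)) {
    a <- theta[k] * pi / 180
    # signed distance to lines of azimuth theta: normal (cos a, -sin a)
    rho <- x * cos(a) - y * sin(a)
    # anchor the binning at the smallest rho so the histogram is exactly
    # invariant under translation (and under scaling when rho_bin is
    # rescaled); the offset keeps exactly-collinear points from straddling
    # a cell boundary through floating-point jitter
    cell <- floor((rho - min(rho)) / rho_bin + 1e-9)
    tab <- tabulate(match(cell, unique(cell)))
    counts[k] <- sum(tab[tab >= min_support])
  }
  structure(list(theta_deg = theta, counts = counts, bin_width = bw,
                 rho_bin = rho_bin, min_support = min_support),
            class = "orientation_histogram")
}

axial_mean_sd <- function(theta_deg, weights) {
  # vector summation on doubled angles (axial data, period 180 degrees)
  a2 <- 2 * theta_deg * pi / 180
  w <- weights / sum(weights)
  C <- sum(w * cos(a2)); S <- sum(w * sin(a2))
  R <- sqrt(C^2 + S^2)
  mean2 <- atan2(S, C)
  mean_deg <- (mean2 / 2 * 180 / pi) %% 180
  sd_deg <- if (R >= 1) 0 else sqrt(-2 * log(R)) / 2 * 180 / pi
  c(mean = mean_deg, sd = sd_deg)
}

circular_smooth <- function(counts, width_bins) {
  if (width_bins <= 1) return(counts)
  k <- floor(width_bins / 2)
  n <- length(counts)
  out <- counts
  for (off in seq_len(k)) {
    out <- out + counts[(seq_len(n) - 1 + off) %% n + 1] +
      counts[(seq_len(n) - 1 - off) %% n + 1]
  }
  out / (2 * k + 1)
}

#' Find orientation modes in an axial histogram
#'
#' Smooths the histogram with a circular moving average, finds strict
#' local maxima (axial wraparound: the 179 degree bin neighbors the 0
#' degree bin), partitions the axis at the minima between consecutive
#' maxima, and reports for each mode the count-weighted axial circular
#' mean and standard deviation (vector summation on doubled angles) plus
#' its total support. A flat histogram has no modes.
#'
#' @param hist An [hough_orientation()] result.
#' @param smooth_deg Width of the circular smoothing window, degrees.
#' @param prominence Minimum smoothed peak height, as a fraction of the
#'   maximum smoothed count, for a maximum to count as a mode.
#' @return Data frame with `mean_deg`, `sd_deg`, `support`, ordered by
#'   decreasing support.
#' @export
find_modes <- function(hist, smooth_deg = 9, prominence = 0.1) {
  counts <- hist$counts
  n <- length(counts)
  if (n == 0L || all(counts == 0)) return(empty_modes())
  if (diff(range(counts)) == 0) return(empty_modes())   # flat: no modes
  sm <- circular_smooth(counts, max(1, round(smooth_deg / hist$bin_width)))
  peaks <- circular_plateau_maxima(sm)
  peaks <- peaks[sm[peaks] >= prominence * max(sm)]
  if (!length(peaks)) return(empty_modes())
  if (length(peaks) == 1L) {
    st <- axial_mean_sd(hist$theta_deg, counts)
    return(data.frame(mean_deg = st[["mean"]], sd_deg = st[["sd"]],
                      support = sum(counts)))
  }
  # boundaries: minimum of the smoothed curve between consecutive peaks
  bounds <- integer(length(peaks))
  for (i in seq_along(peaks)) {
    a <- peaks[i]; b <- peaks[if (i == length(peaks)) 1L else i + 1L]
    span <- if (b > a) (a:b) else c(a:n, 1:b)
    bounds[i] <- span[which.min(sm[span])]
  }
  modes <- lapply(seq_along(peaks), function(i) {
    lo <- bounds[if (i == 1L) length(peaks) else i - 1L]
    hi <- bounds[i]
    span <- if (hi > lo) ((lo + 1):hi) else
      if (hi == lo) seq_len(n) else c(if (lo < n) (lo + 1):n else NULL, 1:hi)
    w <- counts[span]
    if (sum(w) == 0) return(NULL)
    st <- axial_mean_sd(hist$theta_deg[span], w)
    data.frame(mean_deg = st[["mean"]], sd_deg = st[["sd"]],
               support = sum(w))
  })
  modes <- do.call(rbind, modes[!vapply(modes, is.null, logical(1))])
  modes[order(-modes$support), , drop = FALSE]
}

# strict local maxima with plateau handling on a circular vector:
# a run of equal values is a maximum when both run neighbors are lower;
# its central bin is reported
circular_plateau_maxima <- function(v) {
  n <- length(v)
  r <- rle(v)
  k <- length(r$values)
  if (k == 1L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  prev_val <- r$values[c(k, seq_len(k - 1))]
  next_val <- r$values[c(seq_len(k - 1) + 1L, 1L)]
  peaks <- integer(0)
  for (i in seq_len(k)) {
    if (r$values[i] > prev_val[i] && r$values[i] > next_val[i]) {
      peaks <- c(peaks, starts[i] + (r$lengths[i] - 1L) %/% 2L)
    }
  }
  # a maximal run wrapping across the ends appears as two rle runs
  if (k >= 2L && r$values[1] == r$values[k]) {
    lower_before <- r$values[k - 1] < r$values[k]
    lower_after <- r$values[2] < r$values[1]
    if (lower_before && lower_after) {
      len <- r$lengths[1] + r$lengths[k]
      mid <- (starts[k] + (len - 1L) %/% 2L - 1L) %% n + 1L
      peaks <- c(peaks, mid)
    }
  }
  sort(unique(peaks))
}

empty_modes <- function() {
  data.frame(mean_deg = numeric(), sd_deg = numeric(), support = numeric())
}
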