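#' Registration parameters
#'
#' @param max_shift Largest translation searched, in pixels.
#' @param min_score Smallest acceptable peak mean normalized
#'   cross-correlation; below it the frame is flagged and the shift falls
#'   back to (0, 0).
#' @param min_points Fewest interest points that must contribute at the
#'   winning shift.
#' @param patch_radius Half-width of the square correlation patch around
#'   each interest point (radius 3 gives 7 x 7 patches).
#' @param n_points Number of interest points requested from the detector.
#' @param min_sep Minimum Chebyshev separation between interest points, px.
#' @param subpixel If `TRUE`, refine the integer peak by fitting a parabola
#'   to the score surface along each axis. The default integer shift keeps
#'   downstream differencing exact on the 8-bit grid.
#' @return A list of class `registration_params`.
#' @export
registration_params <- function(max_shift = 10, min_score = 0.5,
                                min_points = 5, patch_radius = 3,
                                n_points = 30, min_sep = 3,
                                subpixel = FALSE) {
  structure(list(max_shift = max_shift, min_score = min_score,
                 min_points = min_points, patch_radius = patch_radius,
                 n_points = n_points, min_sep = min_sep,
                 subpixel = subpixel),
            class = "registration_params")
}

#' Detect well-distinguishable image points
#'
#' Interest points are local maxima of the gradient magnitude (central
#' differences), restricted to pixels outside the mound mask — so that ant
#' motion inside the mask cannot bias the camera-motion estimate — and away
#' from the image border. Points are picked greedily in order of decreasing
#' gradient strength subject to a minimum mutual separation.
#'
#' @param grid Intensity matrix.
#' @param mask Optional logical matrix; `TRUE` pixels (the mound) are
#'   excluded.
#' @param n_points Maximum number of points returned.
#' @param min_sep Minimum Chebyshev distance between selected points.
#' @param border Margin in pixels excluded along every edge (must leave
#'   room for the correlation patch plus the shift search).
#' @return Integer matrix with columns `y`, `x` (1-based).
#' @export
detect_interest_points <- function(grid, mask = NULL, n_points = 30,
                                   min_sep = 3, border = 8) {
  H <- nrow(grid); W <- ncol(grid)
  gy <- rbind(grid[2, , drop = FALSE], grid[-1, , drop = FALSE]) -
    rbind(grid[1, , drop = FALSE], grid[-H, , drop = FALSE])
  gx <- cbind(grid[, 2, drop = FALSE], grid[, -1, drop = FALSE]) -
    cbind(grid[, 1, drop = FALSE], grid[, -W, drop = FALSE])
  g <- gy^2 + gx^2
  if (!is.null(mask)) g[mask] <- 0
  g[c(seq_len(min(border, H)), seq(max(1, H - border + 1), H)), ] <- 0
  g[, c(seq_len(min(border, W)), seq(max(1, W - border + 1), W))] <- 0

  ord <- order(g, decreasing = TRUE)
  ord <- ord[g[ord] > 0]
  sel_y <- integer(0); sel_x <- integer(0)
  for (idx in ord) {
    y <- ((idx - 1) %% H) + 1
    x <- ((idx - 1) %/% H) + 1
    if (length(sel_y) &&
        any(pmax(abs(sel_y - y), abs(sel_x - x)) < min_sep)) next
    sel_y <- c(sel_y, y); sel_x <- c(sel_x, x)
    if (length(sel_y) >= n_points) break
  }
  cbind(y = sel_y, x = sel_x)
}

#' Estimate the camera translation between two frames
#'
#' Finds the integer translation of the current frame relative to the
#' reference that maximizes the mean normalized cross-correlation over
#' patches centered on interest points detected in the reference (outside
#' the mound mask). Camera motion at the mound is well modeled as a pure
#' translation (wind-induced sway), so no rotation or scale is estimated.
#'
#' @param reference,current Intensity matrices of identical dimensions.
#' @param mask Optional logical mound mask passed to the point detector.
#' @param params A [registration_params()] list.
#' @return A list of class `registration_result` with elements `shift`
#'   (`c(dy, dx)`), `score`, `n_points` and `ok`. When `ok` is `FALSE`
#'   (score or point count below threshold) the shift is `c(0, 0)` and the
#'   frame should be flagged downstream, preserving the time base.
#' @export
register_frame <- function(reference, current, mask = NULL,
                           params = registration_params()) {
  if (!all(dim(reference) == dim(current))) stop("inconsistent geometry")
  p <- params
  pts <- detect_interest_points(reference, mask,
                                n_points = p$n_points, min_sep = p$min_sep,
                                border = p$patch_radius + 1)
  if (nrow(pts) < p$min_points) {
    return(structure(list(shift = c(dy = 0, dx = 0), score = NA_real_,
                          n_points = nrow(pts), ok = FALSE),
                     class = "registration_result"))
  }
  res <- .ncc_shift_search(reference, current, pts,
                           p$patch_radius, p$max_shift)
  ok <- is.finite(res$score) && res$score >= p$min_score &&
    res$n_points >= p$min_points
  shift <- c(dy = res$dy, dx = res$dx)
  if (ok && p$subpixel) {
    shift <- c(
      dy = res$dy + parabolic_offset(res$surface, res$dy, res$dx,
                                     p$max_shift, axis = "y"),
      dx = res$dx + parabolic_offset(res$surface, res$dy, res$dx,
                                     p$max_shift, axis = "x")
    )
  }
  if (!ok) shift <- c(dy = 0, dx = 0)
  structure(list(shift = shift,
                 score = if (is.finite(res$score)) res$score else NA_real_,
                 n_points = res$n_points, ok = ok),
            class = "registration_result")
}

parabolic_offset <- function(surface, dy, dx, max_shift, axis) {
  i <- dy + max_shift + 1; j <- dx + max_shift + 1
  n <- nrow(surface)
  if (axis == "y") {
    if (i <= 1 || i >= n) return(0)
    sm <- surface[i - 1, j]; s0 <- surface[i, j]; sp <- surface[i + 1, j]
  } else {
    if (j <= 1 || j >= n) return(0)
    sm <- surface[i, j - 1]; s0 <- surface[i, j]; sp <- surface[i, j + 1]
  }
  den <- sm - 2 * s0 + sp
  if (!is.finite(den) || den >= 0) return(0)
  off <- 0.5 * (sm - sp) / den
  max(-0.5, min(0.5, off))
}

#' Translate an intensity grid, marking uncovered pixels invalid
#'
#' Applies an integer translation `(dy, dx)`: the output pixel `(y, x)`
#' takes the input value at `(y - dy, x - dx)`. Border pixels with no
#' source are set to `NA` and must be excluded from differencing.
#'
#' @param grid Intensity matrix.
#' @param shift Length-2 numeric `c(dy, dx)`; rounded to integers.
#' @return Matrix of the same shape with `NA` in uncovered positions.
#' @export
apply_shift <- function(grid, shift) {
  dy <- round(shift[[1]]); dx <- round(shift[[2]])
  H <- nrow(grid); W <- ncol(grid)
  out <- matrix(NA_real_, H, W)
  ys <- seq_len(H) - dy; xs <- seq_len(W) - dx
  vy <- ys >= 1 & ys <= H; vx <- xs >= 1 & xs <= W
  out[vy, vx] <- grid[ys[vy], xs[vx]]
  out
}
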