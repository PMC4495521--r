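#' Consensus category from three operator scores
#'
#' Three independent operators score each one-minute window on the eight
#' activity categories 0 (no ants on top of the mound) to 6 (crowded top)
#' plus 7 (sunbathing). The consensus C(t) is the rounded mean of the three
#' scores; rounding is half-up, so the consensus stays on the category
#' grid.
#'
#' @param scores Integer vector of length 3, each in 0..7.
#' @return Integer consensus category in 0..7.
#' @export
aggregate_operator_scores <- function(scores) {
  if (length(scores) != 3L) stop("exactly three operator scores required")
  if (any(scores != round(scores)) || any(scores < 0 | scores > 7)) {
    stop("invalid category")
  }
  as.integer(floor(mean(scores) + 0.5))
}

#' Scoring-window schedule for manual annotation
#'
#' Manual scoring evaluates a one-minute sequence every 10 minutes of each
#' day, giving 144 discrete activity indices per 24 h.
#'
#' @param day A `Date` (or string) giving the UTC calendar day, or a
#'   `POSIXct` start instant.
#' @param span_hours Span covered, in hours (default a full day).
#' @param cadence_minutes Interval between window starts.
#' @param window_seconds Length of each scored window.
#' @return Data frame with `start` and `end` (`POSIXct`, UTC).
#' @export
schedule_manual_windows <- function(day, span_hours = 24,
                                    cadence_minutes = 10,
                                    window_seconds = 60) {
  if (cadence_minutes <= 0) stop("invalid cadence")
  t0 <- if (inherits(day, "POSIXct")) as.POSIXct(day, tz = "UTC") else
    as.POSIXct(paste(as.Date(day), "00:00:00"), tz = "UTC")
  n <- floor(span_hours * 60 / cadence_minutes)
  starts <- t0 + seq_len(n) * 60 * cadence_minutes - 60 * cadence_minutes
  data.frame(start = starts, end = starts + window_seconds)
}

#' Read an annotation CSV
#'
#' Accepts columns `timestamp_utc`, `op1`, `op2`, `op3` (consensus is
#' computed) or `timestamp_utc`, `consensus`.
#'
#' @param path CSV path.
#' @return Data frame with `timestamp` (`POSIXct` UTC), operator columns if
#'   present, and `consensus`.
#' @export
read_annotations <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$timestamp <- as.POSIXct(x$timestamp_utc, tz = "UTC")
  if (!"consensus" %in% names(x)) {
    if (!all(c("op1", "op2", "op3") %in% names(x))) {
      stop("need op1..op3 or consensus column")
    }
    x$consensus <- vapply(seq_len(nrow(x)), function(i)
      aggregate_operator_scores(c(x$op1[i], x$op2[i], x$op3[i])),
      integer(1))
  }
  x
}

#' Pair raw activity samples with manual consensus categories
#'
#' For every annotation window, the consensus category C(t) is paired with
#' the median raw activity of unflagged, registration-valid samples inside
#' the window. Each window yields at most one pair; the pair is assigned to
#' the daytime set S_d or the night-time set S_n by the majority sensor
#' mode of its samples (ties toward day). Windows with no usable samples
#' emit no pair.
#'
#' @param series An `activity_series` data frame.
#' @param annotations Data frame with `timestamp` (window start) and
#'   `consensus`.
#' @param window_seconds Annotation window length.
#' @return List with data frames `S_d` and `S_n`, each with columns `A`
#'   (median raw activity) and `C` (consensus category).
#' @export
pair_samples <- function(series, annotations, window_seconds = 60) {
  ok <- !series$flagged & series$registered_ok & !is.na(series$raw)
  s <- series[ok, , drop = FALSE]
  ts <- as.numeric(s$timestamp)
  rows <- lapply(seq_len(nrow(annotations)), function(i) {
    t0 <- as.numeric(annotations$timestamp[i])
    in_win <- ts >= t0 & ts < t0 + window_seconds
    if (!any(in_win)) return(NULL)
    modes <- s$sensor_mode[in_win]
    mode <- if (sum(modes == "night") > sum(modes == "day")) "night" else "day"
    use <- in_win & s$sensor_mode == mode
    data.frame(A = stats::median(s$raw[use]),
               C = annotations$consensus[i], mode = mode)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no pairs")
  all <- do.call(rbind, rows)
  list(S_d = all[all$mode == "day", c("A", "C")],
       S_n = all[all$mode == "night", c("A", "C")])
}

poly_design <- function(A, degree) {
  stats::model.matrix(~ stats::poly(A, degree, raw = TRUE))
}

fit_mode_poly <- function(pairs, degree) {
  if (nrow(pairs) < degree + 2) stop("insufficient pairs")
  if (length(unique(pairs$A)) <= degree) stop("rank deficient")
  X <- poly_design(pairs$A, degree)
  fit <- stats::lm.fit(X, pairs$C)
  if (fit$rank < ncol(X)) stop("rank deficient")
  list(coeffs = unname(fit$coefficients),   # intercept first
       rms = sqrt(mean(fit$residuals^2)), n = nrow(pairs))
}

#' Fit the day/night calibration polynomials
#'
#' Fits a first-order polynomial p_d to the daytime pairs S_d and a
#' second-order polynomial p_n to the night-time pairs S_n by least
#' squares, i.e. minimizing the root-mean-squared difference between the
#' consensus categories C(t) and p(A(t)). The two sensor streams are
#' calibrated separately because the color and near-infrared sensors
#' produce systematically different images.
#'
#' @param S_d,S_n Data frames with columns `A` (raw activity) and `C`
#'   (consensus category); at least 3 day and 4 night pairs.
#' @param fit_window Optional `POSIXct` length-2 span the pairs were drawn
#'   from (typically 2–3 weeks); recorded in the model.
#' @return Object of class `calibration_model` with `day_coeffs`
#'   (intercept, slope), `night_coeffs` (intercept, linear, quadratic),
#'   `rms_day`, `rms_night`, `n_day`, `n_night`, `fit_window`.
#' @export
fit_calibration <- function(S_d, S_n, fit_window = NULL) {
  d <- fit_mode_poly(S_d, 1L)
  n <- fit_mode_poly(S_n, 2L)
  structure(list(day_coeffs = d$coeffs, night_coeffs = n$coeffs,
                 rms_day = d$rms, rms_night = n$rms,
                 n_day = d$n, n_night = n$n, fit_window = fit_window),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> p_d: %.6g + %.6g*A (rms %.3f, n=%d)\n",
              x$day_coeffs[1], x$day_coeffs[2], x$rms_day, x$n_day))
  cat(sprintf("                    p_n: %.6g + %.6g*A + %.6g*A^2 (rms %.3f, n=%d)\n",
              x$night_coeffs[1], x$night_coeffs[2], x$night_coeffs[3],
              x$rms_night, x$n_night))
  invisible(x)
}

#' Map raw activity onto the manual category scale
#'
#' Evaluates the fitted per-mode polynomial at the raw activity value and
#' clamps the result to the category range \[0, 7\]. The calibrated index
#' is left continuous (not snapped to integers) so it can be compared to
#' the integer manual curve.
#'
#' @param model A [fit_calibration()] model.
#' @param raw Numeric vector of raw activity values.
#' @param mode `"day"` or `"night"` (scalar or vector matching `raw`).
#' @return Numeric vector of calibrated indices in \[0, 7\].
#' @export
apply_calibration <- function(model, raw, mode) {
  mode <- rep_len(mode, length(raw))
  if (!all(mode %in% c("day", "night"))) stop("no model for mode")
  out <- numeric(length(raw))
  d <- mode == "day"
  cd <- model$day_coeffs; cn <- model$night_coeffs
  out[d] <- cd[1] + cd[2] * raw[d]
  out[!d] <- cn[1] + cn[2] * raw[!d] + cn[3] * raw[!d]^2
  pmin(7, pmax(0, out))
}

#' Calibrate a whole activity series
#'
#' @param model A `calibration_model`.
#' @param series An `activity_series`.
#' @return Data frame `timestamp`, `index`, `sensor_mode` (flagged or
#'   unregistered samples dropped).
#' @export
calibrate_series <- function(model, series) {
  ok <- !series$flagged & !is.na(series$raw)
  s <- series[ok, , drop = FALSE]
  data.frame(timestamp = s$timestamp,
             index = apply_calibration(model, s$raw, s$sensor_mode),
             sensor_mode = s$sensor_mode)
}

#' Temporal median filter
#'
#' Replaces each value by the median over samples whose timestamps fall in
#' a centered window (default total width 10 minutes, i.e. +/- 5 minutes),
#' truncated at the series edges. Suppresses residual image-noise spikes
#' in the calibrated index.
#'
#' @param series Data frame with `timestamp` and a value column.
#' @param window_minutes Total window width in minutes.
#' @param value Name of the value column (default `"index"`).
#' @return The input with the value column median-filtered.
#' @export
median_filter_series <- function(series, window_minutes = 10,
                                 value = "index") {
  if (nrow(series) == 0L) return(series)
  tt <- as.numeric(series$timestamp)
  if (is.unsorted(tt)) stop("series must be time-ordered")
  half <- window_minutes * 60 / 2
  v <- series[[value]]
  lo <- findInterval(tt - half, tt, left.open = TRUE) + 1L
  hi <- findInterval(tt + half, tt)
  out <- vapply(seq_along(v), function(i)
    stats::median(v[lo[i]:hi[i]]), numeric(1))
  series[[value]] <- out
  series
}
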