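#' Construct a single timestamped frame record
#'
#' A frame record holds one normalized single-channel intensity image
#' \eqn{I_{uv}(t)} together with its acquisition time and the sensor that
#' produced it. Intensities are stored as integers in \[0, 255\] (the native
#' 8-bit range of both camera sensors) and promoted to floating point only
#' inside computations.
#'
#' @param intensity Numeric matrix (rows = image height) with values in
#'   \[0, 255\].
#' @param timestamp `POSIXct` acquisition instant (UTC, seconds resolution).
#' @param sensor_mode `"day"` (color sensor) or `"night"` (near-infrared
#'   sensor with active illumination).
#' @param source_id Camera label, e.g. `"AntCam1"`.
#' @return An object of class `frame_record`.
#' @export
frame_record <- function(intensity, timestamp, sensor_mode,
                         source_id = "AntCam1") {
  stopifnot(is.matrix(intensity))
  if (any(intensity < 0 | intensity > 255, na.rm = TRUE)) {
    stop("intensity values must lie in [0, 255]")
  }
  sensor_mode <- match.arg(sensor_mode, c("day", "night"))
  timestamp <- as.POSIXct(timestamp, tz = "UTC")
  structure(
    list(intensity = intensity, timestamp = timestamp,
         sensor_mode = sensor_mode, source_id = source_id),
    class = "frame_record"
  )
}

#' Construct an ordered frame sequence
#'
#' @param frames List of [frame_record()] objects, ordered in time.
#' @param cadence Nominal inter-frame interval in seconds (the analysis
#'   cadence; one frame every 10 s by default).
#' @param dropouts Optional data frame of detected acquisition gaps
#'   (`after`, `gap_seconds`); gaps longer than 3 times the cadence count
#'   as dropouts.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, cadence = 10, dropouts = NULL) {
  if (length(frames) == 0L) stop("no frames")
  dims <- vapply(frames, function(f) dim(f$intensity), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("inconsistent geometry")
  }
  tt <- vapply(frames, function(f) as.numeric(f$timestamp), numeric(1))
  if (is.unsorted(tt, strictly = TRUE)) {
    stop("timestamps must be strictly increasing")
  }
  if (is.null(dropouts)) dropouts <- find_dropouts(tt, cadence)
  structure(
    list(frames = frames, cadence = cadence, dropouts = dropouts),
    class = "frame_sequence"
  )
}

find_dropouts <- function(times_sec, cadence) {
  gaps <- diff(times_sec)
  idx <- which(gaps > 3 * cadence)
  data.frame(after = idx, gap_seconds = gaps[idx])
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]]$intensity)
  modes <- table(vapply(x$frames, `[[`, "", "sensor_mode"))
  cat(sprintf("<frame_sequence> %d frames (%dx%d px), cadence %gs\n",
              length(x$frames), d[1], d[2], x$cadence))
  cat("  modes:", paste(names(modes), modes, sep = "=", collapse = " "),
      "| dropouts:", nrow(x$dropouts), "\n")
  invisible(x)
}

#' Reduce a raw camera image to a single intensity channel
#'
#' Night-time near-infrared frames are single-channel and pass through
#' unchanged. Daytime RGB frames are reduced with the fixed luma weights
#' (0.299, 0.587, 0.114) and rounded back to the 8-bit integer grid, so the
#' reduction is bit-reproducible and idempotent.
#'
#' @param raw Numeric matrix (1 channel) or H x W x 3 array (RGB), values in
#'   \[0, 255\].
#' @param sensor_mode Sensor that produced `raw`; only used for validation.
#' @return Numeric H x W matrix of integers in \[0, 255\].
#' @export
to_intensity <- function(raw, sensor_mode = c("day", "night")) {
  sensor_mode <- match.arg(sensor_mode)
  if (is.matrix(raw)) return(raw)
  if (is.array(raw) && length(dim(raw)) == 3L && dim(raw)[3] == 3L) {
    out <- round(0.299 * raw[, , 1] + 0.587 * raw[, , 2] + 0.114 * raw[, , 3])
    return(matrix(out, dim(raw)[1], dim(raw)[2]))
  }
  stop("unsupported image")
}

#' Label the sensor mode of a frame
#'
#' An explicit metadata tag always wins; otherwise the channel-count
#' heuristic is applied: 3-channel images come from the color (day) sensor,
#' 1-channel images from the near-infrared (night) sensor.
#'
#' @param raw The raw image (matrix or 3-channel array).
#' @param tag Optional metadata tag; `"IR"`, `"night"` map to night,
#'   `"day"`, `"color"`, `"RGB"` to day.
#' @return `"day"` or `"night"`.
#' @export
classify_sensor_mode <- function(raw, tag = NULL) {
  if (!is.null(tag) && !is.na(tag) && nzchar(tag)) {
    tl <- tolower(tag)
    if (tl %in% c("ir", "night", "nir", "infrared")) return("night")
    if (tl %in% c("day", "color", "colour", "rgb")) return("day")
  }
  if (is.matrix(raw)) "night" else "day"
}

parse_frame_timestamp <- function(x) {
  # filename stem convention: YYYYMMDDTHHMMSSZ
  t <- as.POSIXct(x, format = "%Y%m%dT%H%M%SZ", tz = "UTC")
  ok <- !is.na(t)
  iso <- as.POSIXct(x[!ok], format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  t[!ok] <- iso
  t
}

format_frame_timestamp <- function(t) {
  format(as.POSIXct(t, tz = "UTC"), "%Y%m%dT%H%M%SZ", tz = "UTC")
}

read_png_255 <- function(path) {
  img <- png::readPNG(path)
  img <- round(img * 255)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 2L) img <- img[, , 1]           # gray + alpha
    else if (dim(img)[3] == 4L) img <- img[, , 1:3]    # drop alpha
    else if (dim(img)[3] == 1L) img <- img[, , 1]
  }
  img
}

#' Read a timestamped frame sequence from disk
#'
#' Frames are PNG files either named `YYYYMMDDTHHMMSSZ.png` in a directory,
#' or listed in a CSV manifest with columns `path`, `timestamp_utc` and
#' optionally `sensor_mode`. Every frame is reduced to a single intensity
#' channel ([to_intensity()]) and labeled with its sensor mode (manifest tag
#' first, channel-count heuristic otherwise). Frames whose timestamps cannot
#' be parsed are rejected and reported in the `rejected` attribute;
#' inter-frame gaps longer than 3 times the cadence are recorded as
#' dropouts.
#'
#' @param path Directory of PNG frames, or path to a manifest CSV.
#' @param cadence Nominal inter-frame interval in seconds.
#' @return A [frame_sequence()] with attributes `rejected` (character vector
#'   of skipped files) and the dropout table in `$dropouts`.
#' @export
read_frame_sequence <- function(path, cadence = 10) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.png$", full.names = TRUE)
    if (length(files) == 0L) stop("no frames")
    stems <- sub("\\.png$", "", basename(files))
    ts <- parse_frame_timestamp(stems)
    manifest <- data.frame(path = files, timestamp_utc = ts,
                           sensor_mode = NA_character_)
  } else {
    manifest <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("path", "timestamp_utc") %in% names(manifest))) {
      stop("manifest must have columns path, timestamp_utc")
    }
    if (is.null(manifest$sensor_mode)) manifest$sensor_mode <- NA_character_
    manifest$timestamp_utc <- parse_frame_timestamp(manifest$timestamp_utc)
    manifest$path <- ifelse(
      file.exists(manifest$path), manifest$path,
      file.path(dirname(path), manifest$path)
    )
  }
  rejected <- manifest$path[is.na(manifest$timestamp_utc)]
  manifest <- manifest[!is.na(manifest$timestamp_utc), , drop = FALSE]
  if (nrow(manifest) == 0L) stop("no frames")
  manifest <- manifest[order(manifest$timestamp_utc), , drop = FALSE]

  frames <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    raw <- read_png_255(manifest$path[i])
    mode <- classify_sensor_mode(raw, manifest$sensor_mode[i])
    frames[[i]] <- frame_record(to_intensity(raw, mode),
                                manifest$timestamp_utc[i], mode)
  }
  seq <- frame_sequence(frames, cadence = cadence)
  attr(seq, "rejected") <- rejected
  seq
}

#' Write a frame sequence to a directory of PNG frames plus manifest
#'
#' Intensity grids are written as 8-bit grayscale PNG named by timestamp;
#' the sensor mode travels in `manifest.csv` so that a write-then-read
#' round trip is lossless in pixels, timestamps and mode labels.
#'
#' @param seq A [frame_sequence()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_frame_sequence <- function(seq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stems <- vapply(seq$frames, function(f) format_frame_timestamp(f$timestamp),
                  character(1))
  paths <- file.path(dir, paste0(stems, ".png"))
  for (i in seq_along(seq$frames)) {
    png::writePNG(seq$frames[[i]]$intensity / 255, paths[i])
  }
  manifest <- data.frame(
    path = basename(paths),
    timestamp_utc = format(vapply(seq$frames, function(f)
      as.character(format(f$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")),
      character(1))),
    sensor_mode = vapply(seq$frames, `[[`, "", "sensor_mode")
  )
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
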