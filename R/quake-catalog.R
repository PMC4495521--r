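EARTH_RADIUS_KM <- 6371.0

#' Read an earthquake catalog CSV
#'
#' Expected columns: `label` (epicenter name), `date` (ISO `YYYY-MM-DD`),
#' `time_utc` (`HH:MM:SS` with optional fractional seconds), `depth_km`,
#' `magnitude`, `lon`, `lat`, and optionally `depth_manual` (logical;
#' catalog entries whose focal depth was determined manually, marked with
#' an asterisk in printed tables). Malformed rows are rejected and reported
#' with their row numbers in the `rejected` attribute.
#'
#' @param path CSV path.
#' @return Data frame of class `quake_catalog`, time-sorted, with
#'   `origin_time` (`POSIXct` UTC, fractional seconds kept), `label`,
#'   `depth_km`, `depth_manual`, `magnitude`, `lon`, `lat`.
#' @export
read_catalog <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(depth_km = "character"))
  if (nrow(x) == 0L) {
    out <- data.frame(label = character(), origin_time =
                        as.POSIXct(character(), tz = "UTC"),
                      depth_km = numeric(), depth_manual = logical(),
                      magnitude = numeric(), lon = numeric(),
                      lat = numeric())
    class(out) <- c("quake_catalog", "data.frame")
    return(out)
  }
  need <- c("label", "date", "time_utc", "depth_km", "magnitude",
            "lon", "lat")
  if (!all(need %in% names(x))) {
    stop("catalog must have columns ", paste(need, collapse = ", "))
  }
  # an asterisk in depth_km also marks a manual determination
  star <- grepl("\\*", x$depth_km)
  depth <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", x$depth_km)))
  manual <- if ("depth_manual" %in% names(x)) as.logical(x$depth_manual) | star
            else star
  origin <- as.POSIXct(paste(x$date, x$time_utc), tz = "UTC",
                       format = "%Y-%m-%d %H:%M:%OS")
  ok <- !is.na(origin) & !is.na(depth) & !is.na(x$magnitude) &
    !is.na(x$lon) & !is.na(x$lat) &
    x$lon >= -180 & x$lon <= 180 & x$lat >= -90 & x$lat <= 90 &
    depth >= 0
  rejected <- which(!ok)
  out <- data.frame(label = x$label[ok], origin_time = origin[ok],
                    depth_km = depth[ok], depth_manual = manual[ok],
                    magnitude = x$magnitude[ok], lon = x$lon[ok],
                    lat = x$lat[ok])
  out <- out[order(out$origin_time), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  class(out) <- c("quake_catalog", "data.frame")
  out
}

#' Path to a bundled earthquake-catalog fixture
#'
#' Three printed regional catalogs for the Neuwied Basin ship with the
#' package: `"neuwied_m2_2009_2012"` (the ten magnitude > 2.0 events within
#' 40 km of the two cameras, 2009–2012), `"neuwied_sep2009"` (all events of
#' September 2009 within 40 km of AntCam 1) and `"neuwied_jun2010"` (all
#' events of June 2010 within 40 km of AntCam 1).
#'
#' @param name Catalog name (see above).
#' @return Path to the CSV file.
#' @export
catalog_fixture <- function(name = c("neuwied_m2_2009_2012",
                                     "neuwied_sep2009",
                                     "neuwied_jun2010")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, ".csv"), package = "antwatch",
              mustWork = TRUE)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0 km.
#'
#' @param a,b Numeric length-2 `c(lon, lat)` in degrees, or two-column
#'   matrices.
#' @return Distance(s) in km.
#' @export
haversine_km <- function(a, b) {
  geosphere::distHaversine(a, b, r = EARTH_RADIUS_KM * 1000) / 1000
}

#' Filter a catalog by distance and magnitude around a station
#'
#' Keeps events with great-circle epicentral distance at most `radius_km`
#' from the station and magnitude strictly greater than `min_magnitude`
#' (the printed selections use "magnitude > 2.0"), time-sorted.
#'
#' @param catalog A `quake_catalog` data frame.
#' @param station Length-2 `c(lon, lat)` in degrees (camera location).
#' @param radius_km Maximum epicentral distance.
#' @param min_magnitude Strict lower magnitude bound.
#' @return Filtered catalog with an added `distance_km` column.
#' @export
filter_events <- function(catalog, station, radius_km, min_magnitude) {
  if (nrow(catalog) == 0L) {
    catalog$distance_km <- numeric(0)
    return(catalog)
  }
  d <- haversine_km(cbind(catalog$lon, catalog$lat),
                    c(station[[1]], station[[2]]))
  keep <- d <= radius_km & catalog$magnitude > min_magnitude
  out <- catalog[keep, , drop = FALSE]
  out$distance_km <- d[keep]
  out <- out[order(out$origin_time), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract an event-locked activity window
#'
#' Re-times a calibrated index series relative to an earthquake origin
#' (t = 0 at the origin time) and returns the samples within
#' \[-pre_hours, +post_hours\], together with the fraction of the window
#' actually covered by the series.
#'
#' @param series Data frame with `timestamp` and `index`.
#' @param event One row of a `quake_catalog` (or a list with
#'   `origin_time`).
#' @param pre_hours,post_hours Window extent either side of the origin.
#' @return Data frame `t_rel_hours`, `index` with attribute `coverage` in
#'   \[0, 1\].
#' @export
extract_event_window <- function(series, event, pre_hours = 24,
                                 post_hours = 24) {
  t0 <- as.numeric(as.POSIXct(event$origin_time, tz = "UTC"))
  tt <- as.numeric(series$timestamp)
  rel <- (tt - t0) / 3600
  keep <- rel >= -pre_hours & rel <= post_hours
  if (!any(keep)) stop("event outside series")
  lo <- max(-pre_hours, (min(tt) - t0) / 3600)
  hi <- min(post_hours, (max(tt) - t0) / 3600)
  cov <- max(0, hi - lo) / (pre_hours + post_hours)
  out <- data.frame(t_rel_hours = rel[keep], index = series$index[keep])
  attr(out, "coverage") <- cov
  out
}

#' Build a nocturnal baseline from reference nights
#'
#' Summarizes at least five earthquake-free reference nights: the mean and
#' standard deviation of the nightly mean calibrated index, plus a
#' per-hour mean profile. Nights are identified upstream by sensor mode.
#'
#' @param nights List of data frames (`timestamp`, `index`), one per
#'   reference night.
#' @return List of class `night_baseline` with `mean`, `sd`, `n_nights`,
#'   `hourly` (data frame `hour`, `mean`).
#' @export
night_baseline <- function(nights) {
  if (length(nights) < 5L) stop("no baseline")
  means <- vapply(nights, function(x) mean(x$index), numeric(1))
  all <- do.call(rbind, nights)
  hour <- as.integer(format(all$timestamp, "%H", tz = "UTC"))
  hourly <- stats::aggregate(list(mean = all$index),
                             by = list(hour = hour), FUN = mean)
  structure(list(mean = mean(means), sd = stats::sd(means),
                 n_nights = length(nights), hourly = hourly),
            class = "night_baseline")
}

#' Flag suppression (or elevation) of the nocturnal rest phase
#'
#' The nocturnal rest phase is normally near-zero activity; its departure
#' in the hours before an earthquake is the anomaly of interest. The score
#' is the displacement of the night's mean calibrated index from the
#' baseline nightly mean, in baseline standard-deviation units; the night
#' is flagged when the absolute score exceeds the threshold. This statistic
#' is a deliberately simple operational definition introduced by this
#' package, not a published quantity.
#'
#' @param night Data frame (`timestamp`, `index`) for one night.
#' @param baseline A [night_baseline()].
#' @param threshold Flag when `|score| > threshold` (default 3).
#' @return List with `score` and `flag`.
#' @export
flag_rest_suppression <- function(night, baseline, threshold = 3) {
  if (!inherits(baseline, "night_baseline")) stop("no baseline")
  if (!is.finite(baseline$sd) || baseline$sd == 0) {
    stop("degenerate baseline")
  }
  score <- (mean(night$index) - baseline$mean) / baseline$sd
  list(score = score, flag = abs(score) > threshold)
}
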