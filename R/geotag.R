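#' Parse raw NMEA sentences into GPS fixes
#'
#' Reads GGA sentences (position, UTC time-of-day, fix quality), using RMC
#' sentences, when present, to resolve the date. Checksums are validated
#' (XOR of all characters between `$` and `*`); malformed or
#' checksum-failing lines are skipped with a warning. Latitude/longitude
#' are converted from the NMEA `ddmm.mmmm` convention to signed decimal
#' degrees. Fixes with quality code 0 (no fix) are dropped by default.
#'
#' @param lines Character vector of raw NMEA sentences, or a file path.
#' @param drop_quality Integer vector of fix-quality codes to drop,
#'   default `0`.
#' @return A data.frame of class `geo_fixes` with columns `timestamp`
#'   (seconds UTC; seconds since midnight if no RMC date was seen), `lat`,
#'   `lon` (decimal degrees) and `quality`, ordered by time.
#' @export
parse_nmea <- function(lines, drop_quality = 0L) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  date_offset <- 0
  out <- list()
  skipped <- 0L
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    body <- nmea_body(ln)
    if (is.null(body)) { skipped <- skipped + 1L; next }
    f <- strsplit(body, ",", fixed = TRUE)[[1]]
    type <- sub("^..", "", f[1])                 # drop talker id
    if (type == "RMC" && length(f) >= 10 && nzchar(f[10])) {
      d <- f[10]                                 # ddmmyy
      day <- as.numeric(substr(d, 1, 2))
      date_offset <- (day - 1) * 86400           # relative day offset
    } else if (type == "GGA" && length(f) >= 7) {
      lat <- nmea_coord(f[3], f[4], lat = TRUE)
      lon <- nmea_coord(f[5], f[6], lat = FALSE)
      tod <- nmea_time(f[2])
      q <- suppressWarnings(as.integer(f[7]))
      if (anyNA(c(lat, lon, tod, q))) { skipped <- skipped + 1L; next }
      out[[length(out) + 1L]] <-
        data.frame(timestamp = tod + date_offset, lat = lat, lon = lon,
                   quality = q)
    }
  }
  if (skipped > 0L)
    warning(sprintf("skipped %d malformed or invalid NMEA line(s)", skipped))
  fixes <- do.call(rbind, out)
  if (!is.null(fixes)) fixes <- fixes[!(fixes$quality %in% drop_quality), ]
  if (is.null(fixes) || nrow(fixes) == 0L)
    stop("no valid GPS fixes found in NMEA input")
  fixes <- fixes[order(fixes$timestamp), ]
  rownames(fixes) <- NULL
  class(fixes) <- c("geo_fixes", "data.frame")
  fixes
}

# returns sentence body if framing and checksum are valid, else NULL
nmea_body <- function(ln) {
  if (!startsWith(ln, "$")) return(NULL)
  star <- regexpr("*", ln, fixed = TRUE)
  if (star < 0 || star + 2L > nchar(ln)) return(NULL)
  body <- substr(ln, 2L, star - 1L)
  want <- toupper(substr(ln, star + 1L, star + 2L))
  got <- nmea_checksum(body)
  if (!identical(got, want)) return(NULL)
  body
}

nmea_checksum <- function(body) {
  cs <- Reduce(bitwXor, utf8ToInt(body), accumulate = FALSE)
  toupper(format(as.hexmode(cs), width = 2))
}

nmea_coord <- function(v, hemi, lat) {
  if (!nzchar(v) || !nzchar(hemi)) return(NA_real_)
  x <- suppressWarnings(as.numeric(v))
  if (is.na(x)) return(NA_real_)
  deg <- floor(x / 100)
  dec <- deg + (x - deg * 100) / 60
  sign <- if (hemi %in% c("S", "W")) -1 else 1
  val <- sign * dec
  lim <- if (lat) 90 else 180
  if (abs(val) > lim) return(NA_real_)
  val
}

nmea_time <- function(v) {
  if (!nzchar(v)) return(NA_real_)
  x <- suppressWarnings(as.numeric(v))
  if (is.na(x)) return(NA_real_)
  hh <- floor(x / 10000); mm <- floor((x - hh * 10000) / 100)
  hh * 3600 + mm * 60 + (x - hh * 10000 - mm * 100)
}

#' Associate frames with GPS positions
#'
#' Linearly interpolates latitude and longitude between the two fixes
#' bracketing each frame timestamp; frames before the first or after the
#' last fix are clamped to the nearest fix. Frames and fixes are assumed to
#' share a clock; `clock_offset` (seconds, added to frame timestamps) can
#' absorb a constant disagreement.
#'
#' @param frame_times Numeric vector of frame timestamps, seconds.
#' @param fixes A [parse_nmea()] result (or data.frame with `timestamp`,
#'   `lat`, `lon`).
#' @param clock_offset Constant offset added to frame timestamps, seconds.
#' @return data.frame with columns `timestamp`, `lat`, `lon`.
#' @export
tag_frames <- function(frame_times, fixes, clock_offset = 0) {
  if (is.null(fixes) || nrow(fixes) == 0L) stop("no GPS fixes to tag with")
  t <- frame_times + clock_offset
  interp <- function(y) {
    if (nrow(fixes) == 1L) return(rep(y[1L], length(t)))
    stats::approx(fixes$timestamp, y, xout = t, rule = 2)$y
  }
  data.frame(timestamp = frame_times,
             lat = interp(fixes$lat), lon = interp(fixes$lon))
}

#' Build the along-row yield transect
#'
#' Combines per-frame detections with per-frame positions into transect
#' records: tree count, diameters, and cumulative along-row distance
#' (haversine distance summed over successive frame positions).
#'
#' @param detections data.frame of per-tree detections with at least
#'   `frame_id` and `diameter_mm` (as written by [run_pipeline()]); frames
#'   with zero trees are taken from `frame_ids`.
#' @param positions data.frame with one row per frame: `frame_id`, `lat`,
#'   `lon`.
#' @return data.frame of class `transect` with columns `frame_id`, `lat`,
#'   `lon`, `tree_count`, `mean_diameter_mm`, `distance_m`, plus a
#'   `diameters_mm` list-column.
#' @export
build_transect <- function(detections, positions) {
  stopifnot(all(c("frame_id", "lat", "lon") %in% names(positions)))
  n <- nrow(positions)
  dist <- numeric(n)
  if (n > 1L) {
    p <- cbind(positions$lon, positions$lat)
    steps <- geosphere::distHaversine(p[-n, , drop = FALSE],
                                      p[-1, , drop = FALSE])
    dist <- cumsum(c(0, steps))
  }
  diam <- lapply(positions$frame_id, function(fid)
    detections$diameter_mm[detections$frame_id == fid])
  out <- data.frame(frame_id = positions$frame_id,
                    lat = positions$lat, lon = positions$lon,
                    tree_count = vapply(diam, length, integer(1)),
                    mean_diameter_mm = vapply(diam, function(d)
                      if (length(d)) mean(d) else NA_real_, numeric(1)),
                    distance_m = dist)
  out$diameters_mm <- diam
  class(out) <- c("transect", "data.frame")
  out
}

#' Write a transect to CSV
#'
#' @param transect A [build_transect()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transect_csv <- function(transect, path) {
  df <- transect
  df$diameters_mm <- vapply(df$diameters_mm, function(d)
    paste(sprintf("%.2f", d), collapse = ";"), character(1))
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  invisible(path)
}

#' Write a transect as a GeoJSON FeatureCollection of points
#'
#' @param transect A [build_transect()] result.
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_transect_geojson <- function(transect, path) {
  features <- lapply(seq_len(nrow(transect)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(transect$lon[i], transect$lat[i])),
         properties = list(
           frame_id = transect$frame_id[i],
           tree_count = transect$tree_count[i],
           mean_diameter_mm = transect$mean_diameter_mm[i],
           distance_m = transect$distance_m[i],
           diameters_mm = transect$diameters_mm[[i]]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write GPS fixes as NMEA GGA sentences
#'
#' Fixture writer used by the synthetic suite generator and the parser
#' round-trip tests: emits one GGA sentence per fix with a valid checksum.
#'
#' @param fixes data.frame with `timestamp` (seconds UTC), `lat`, `lon`,
#'   and optionally `quality` (default 1).
#' @param path Optional output file; when `NULL` the sentences are
#'   returned.
#' @return Character vector of sentences (invisibly when written to file).
#' @export
write_nmea_log <- function(fixes, path = NULL) {
  q <- if ("quality" %in% names(fixes)) fixes$quality else
    rep(1L, nrow(fixes))
  lines <- vapply(seq_len(nrow(fixes)), function(i) {
    tod <- fixes$timestamp[i] %% 86400
    hh <- floor(tod / 3600); mm <- floor((tod - hh * 3600) / 60)
    ss <- tod - hh * 3600 - mm * 60
    lat <- fixes$lat[i]; lon <- fixes$lon[i]
    latd <- floor(abs(lat)); latm <- (abs(lat) - latd) * 60
    lond <- floor(abs(lon)); lonm <- (abs(lon) - lond) * 60
    body <- sprintf(
      "GPGGA,%02d%02d%06.3f,%02d%010.7f,%s,%03d%010.7f,%s,%d,08,0.9,10.0,M,0.0,M,,",
      hh, mm, ss, latd, latm, if (lat < 0) "S" else "N",
      lond, lonm, if (lon < 0) "W" else "E", q[i])
    paste0("$", body, "*", nmea_checksum(body))
  }, character(1))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
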