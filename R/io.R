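#' Read and write accelerometer CSV files
#'
#' The on-disk dialect is a comma-separated file with a metadata comment line
#' `# start=<ISO8601> rate=<Hz> unit=<g|ms2>` followed by a header `x,y,z`.
#' The canonical in-memory unit is g; files recorded in m/s^2 are divided by
#' the standard gravity 9.80665 on read.
#'
#' @param path File path.
#' @param rate_hz,unit Optional overrides used when the metadata line is
#'   absent; `unit` is `"g"` or `"ms2"`.
#' @return [read_accel()] returns an [accel_trace()] in g.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' tr <- accel_trace(rnorm(50, sd = 0.01), rnorm(50, sd = 0.01),
#'                   rnorm(50, 1, 0.01), rate_hz = 100)
#' write_accel(tr, f)
#' identical(nrow(read_accel(f)), 50L)
#' @export
read_accel <- function(path, rate_hz = NULL, unit = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  start_time <- .epoch()
  if (startsWith(first, "#")) {
    meta <- .parse_accel_meta(first)
    if (is.null(rate_hz)) rate_hz <- meta$rate
    if (is.null(unit)) unit <- meta$unit
    if (!is.null(meta$start)) start_time <- meta$start
  }
  if (is.null(rate_hz)) {
    stop("sampling rate not in file header; pass `rate_hz`", call. = FALSE)
  }
  unit <- match.arg(unit %||% "g", c("g", "ms2"))
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  missing_cols <- setdiff(c("x", "y", "z"), names(df))
  if (length(missing_cols) > 0L) {
    stop("accelerometer file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  scale <- if (unit == "ms2") 1 / 9.80665 else 1
  bad <- which(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))
  if (length(bad) > 0L) {
    stop("non-finite acceleration sample at row ", bad[1L], " of ", path,
         call. = FALSE)
  }
  accel_trace(df$x * scale, df$y * scale, df$z * scale,
              rate_hz = rate_hz, start_time = start_time)
}

.parse_accel_meta <- function(line) {
  grab <- function(key) {
    m <- regmatches(line, regexec(paste0(key, "=([^ ]+)"), line))[[1L]]
    if (length(m) == 2L) m[2L] else NULL
  }
  start <- grab("start")
  list(
    start = if (!is.null(start))
      as.POSIXct(start, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OS"),
    rate = if (!is.null(grab("rate"))) as.numeric(grab("rate")),
    unit = grab("unit")
  )
}

#' @param trace An [accel_trace()] to write.
#' @rdname read_accel
#' @export
write_accel <- function(trace, path) {
  header <- sprintf("# start=%s rate=%s unit=g",
                    format(trace_start(trace), "%Y-%m-%dT%H:%M:%OS3",
                           tz = "UTC"),
                    format(trace_rate(trace), digits = 15))
  writeLines(header, path)
  readr::write_csv(tibble::as_tibble(trace), path, append = TRUE,
                   col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Construct a GPS track
#'
#' @param time `POSIXct` timestamps (UTC), strictly increasing.
#' @param lat,lon Coordinates in decimal degrees (WGS84).
#' @return A tibble of class `gps_track` with columns `time`, `lat`, `lon`.
#' @export
gps_track <- function(time, lat, lon) {
  if (is.character(time)) time <- as.POSIXct(time, tz = "UTC")
  n <- length(time)
  if (length(lat) != n || length(lon) != n) {
    stop("`time`, `lat`, `lon` must have equal length", call. = FALSE)
  }
  if (n > 1L) {
    dt <- diff(as.numeric(time))
    if (any(dt <= 0)) {
      i <- which(dt <= 0)[1L] + 1L
      stop("GPS timestamps not strictly increasing at point ", i,
           " (", format(time[i], "%Y-%m-%d %H:%M:%S"), ")", call. = FALSE)
    }
  }
  if (any(abs(lat) > 90) || any(abs(lon) > 180)) {
    stop("coordinates out of range (|lat| <= 90, |lon| <= 180)",
         call. = FALSE)
  }
  out <- tibble::tibble(time = time, lat = as.numeric(lat),
                        lon = as.numeric(lon))
  class(out) <- c("gps_track", class(out))
  out
}

#' Read a GPS track from GPX 1.1 or delimited text
#'
#' `read_gpx()` flattens all track segments of all tracks into one ordered
#' point sequence; times are normalised to UTC. `read_gps_csv()` reads the
#' delimited alternative with columns `time,lat,lon`.
#'
#' @param path File path.
#' @return A [gps_track()].
#' @export
read_gpx <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pts <- xml2::xml_find_all(doc, ".//trk/trkseg/trkpt")
  if (length(pts) == 0L) stop("no track points in ", path, call. = FALSE)
  gps_track(
    time = as.POSIXct(xml2::xml_text(xml2::xml_find_all(pts, "time")),
                      tz = "UTC", format = "%Y-%m-%dT%H:%M:%OS"),
    lat = as.numeric(xml2::xml_attr(pts, "lat")),
    lon = as.numeric(xml2::xml_attr(pts, "lon"))
  )
}

#' @rdname read_gpx
#' @export
read_gps_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  gps_track(df$time, df$lat, df$lon)
}

#' @param track A [gps_track()] to write (single track, single segment).
#' @rdname read_gpx
#' @export
write_gpx <- function(track, path) {
  pt <- sprintf(
    '      <trkpt lat="%.7f" lon="%.7f"><time>%s</time></trkpt>',
    track$lat, track$lon,
    format(track$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gpx version="1.1" creator="caninestep" xmlns="http://www.topografix.com/GPX/1/1">',
    "  <trk>", "    <trkseg>", pt, "    </trkseg>", "  </trk>", "</gpx>"),
    path)
  invisible(path)
}

#' Step annotation intervals
#'
#' Annotations are swing-phase intervals (final contact to next initial
#' contact of a thoracic limb) exported from video annotation, in seconds
#' relative to the accelerometer trace start once synchronised. The
#' accumulated synchronisation offset already applied is kept in the
#' `source_offset_s` attribute.
#'
#' @param start_s,end_s Interval bounds in seconds, `start_s < end_s`.
#' @return A tibble of class `annotation_set` with columns `start_s`, `end_s`.
#' @export
annotation_set <- function(start_s, end_s) {
  if (length(start_s) != length(end_s)) {
    stop("`start_s` and `end_s` must have equal length", call. = FALSE)
  }
  if (any(end_s <= start_s)) {
    stop("every annotation must satisfy start_s < end_s", call. = FALSE)
  }
  if (is.unsorted(start_s)) {
    stop("annotations must be sorted by start_s", call. = FALSE)
  }
  out <- tibble::tibble(start_s = as.numeric(start_s),
                        end_s = as.numeric(end_s))
  structure(out, source_offset_s = 0,
            class = c("annotation_set", class(out)))
}

#' @param path CSV file with columns `start_s,end_s`.
#' @rdname annotation_set
#' @export
read_annotations <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  annotation_set(df$start_s, df$end_s)
}

#' Shift annotations by a clap-synchronisation offset
#'
#' Video and accelerometer clocks are synchronised by a clap visible in both
#' streams; the measured offset is applied here. Offsets accumulate in the
#' `source_offset_s` attribute so repeated application is auditable.
#'
#' @param annotations An [annotation_set()].
#' @param offset_s Finite offset in seconds added to every interval.
#' @return The shifted [annotation_set()].
#' @export
apply_sync_offset <- function(annotations, offset_s) {
  if (!is.numeric(offset_s) || length(offset_s) != 1L ||
      !is.finite(offset_s)) {
    stop("`offset_s` must be a single finite number", call. = FALSE)
  }
  prev <- attr(annotations, "source_offset_s") %||% 0
  out <- tibble::tibble(start_s = annotations$start_s + offset_s,
                        end_s = annotations$end_s + offset_s)
  structure(out, source_offset_s = prev + offset_s,
            class = c("annotation_set", class(tibble::tibble())))
}
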