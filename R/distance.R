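#' Inverted-pendulum step length
#'
#' Step length from the per-step "bounce" of the dorso-ventral
#' acceleration: `length = (A_max - A_min)^(1/4)` metres. The relation
#' comes from modelling each leg pair as an inverted pendulum pivoting at
#' the scapulohumeral (thoracic) or coxofemoral (pelvic) joint, with the
#' collar sensing the vertical undulation of the centre of mass. By default
#' the bounce is taken in g, which yields plausible canine step lengths
#' (0.1-1 g gives 0.56-1.0 m); `unit = "ms2"` converts the bounce to m/s^2
#' (times 9.80665) before the fourth root, for users who prefer SI inputs
#' to the formula.
#'
#' @param a_max_g,a_min_g Bounce extrema in g; vectorised,
#'   `a_max_g >= a_min_g`.
#' @param unit `"g"` (default) or `"ms2"`.
#' @return Step length in metres (0 for a degenerate zero bounce).
#' @examples
#' step_length_m(0.8, -0.2)   # bounce of 1 g -> 1 m
#' @export
step_length_m <- function(a_max_g, a_min_g, unit = c("g", "ms2")) {
  unit <- match.arg(unit)
  bounce <- a_max_g - a_min_g
  if (any(!is.finite(bounce)) || any(bounce < 0)) {
    stop("`a_max_g` must be >= `a_min_g` and finite", call. = FALSE)
  }
  if (unit == "ms2") bounce <- bounce * 9.80665
  bounce^0.25
}

#' Attach step lengths to detected steps
#'
#' @param steps Step tibble from [count_steps()] (columns `time_s`,
#'   `a_max_g`, `a_min_g`).
#' @param unit Passed to [step_length_m()].
#' @return The tibble with a `length_m` column appended.
#' @export
add_step_lengths <- function(steps, unit = "g") {
  steps$length_m <- if (nrow(steps) == 0L) numeric() else
    step_length_m(steps$a_max_g, steps$a_min_g, unit)
  steps
}

#' Total walk distance from detected steps
#'
#' Each step is considered independently; a stride covers two consecutive
#' steps, so summing per-step lengths equals summing per-stride lengths.
#'
#' @inheritParams add_step_lengths
#' @return Distance in metres.
#' @export
walk_distance_m <- function(steps, unit = "g") {
  if (nrow(steps) == 0L) return(0)
  sum(step_length_m(steps$a_max_g, steps$a_min_g, unit))
}

#' Great-circle path length of a GPS track
#'
#' Haversine distance summed over consecutive points, Earth radius
#' 6,371,000 m.
#'
#' @param track A [gps_track()].
#' @return Path length in metres (0 for a single point).
#' @export
haversine_path_m <- function(track) {
  n <- nrow(track)
  if (n < 2L) return(0)
  p <- cbind(track$lon, track$lat)
  sum(geosphere::distHaversine(p[-n, , drop = FALSE],
                               p[-1L, , drop = FALSE], r = 6371000))
}

#' Walk-segmentation parameters
#'
#' Rule base for extracting walks from a day-long GPS track: points moving
#' at a plausible walking speed form runs, runs separated by short gaps
#' (signal dropouts, kerb waits) are merged, and segments shorter than
#' `min_walk_m` are rejected.
#'
#' @param v_min_kmh,v_max_kmh Valid travelling speed range (km/h).
#' @param min_walk_m Minimum path distance for a segment to count (m).
#' @param max_gap_s Maximum gap bridged when merging runs (s).
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(v_min_kmh = 1, v_max_kmh = 12,
                                min_walk_m = 100, max_gap_s = 120) {
  stopifnot(v_min_kmh > 0, v_max_kmh > v_min_kmh, min_walk_m > 0,
            max_gap_s >= 0)
  structure(list(v_min_kmh = v_min_kmh, v_max_kmh = v_max_kmh,
                 min_walk_m = min_walk_m, max_gap_s = max_gap_s),
            class = "segmentation_config")
}

#' Segment a GPS track into walks
#'
#' @param track A time-sorted [gps_track()].
#' @param cfg A [segmentation_config()].
#' @return A tibble of class `walk_segments`, one row per accepted walk:
#'   `start_time`, `end_time`, `gps_distance_m`, `n_points`.
#' @export
segment_walks <- function(track, cfg = segmentation_config()) {
  empty <- tibble::tibble(start_time = track$time[0], end_time = track$time[0],
                          gps_distance_m = numeric(), n_points = integer())
  n <- nrow(track)
  if (n < 2L) return(empty)
  p <- cbind(track$lon, track$lat)
  d <- geosphere::distHaversine(p[-n, , drop = FALSE], p[-1L, , drop = FALSE],
                                r = 6371000)
  dt <- diff(as.numeric(track$time))
  v_kmh <- d / dt * 3.6
  moving <- v_kmh >= cfg$v_min_kmh & v_kmh <= cfg$v_max_kmh
  runs <- .mask_runs(moving)               # runs over the n-1 intervals
  if (nrow(runs) == 0L) return(empty)
  # merge runs separated by a short gap
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (r in 2:nrow(runs)) {
      gap_s <- as.numeric(track$time[runs$start[r]]) -
        as.numeric(track$time[merged$end[nrow(merged)] + 1L])
      if (gap_s <= cfg$max_gap_s) {
        merged$end[nrow(merged)] <- runs$end[r]
      } else {
        merged <- rbind(merged, runs[r, , drop = FALSE])
      }
    }
  }
  segs <- purrr::map_dfr(seq_len(nrow(merged)), function(r) {
    i0 <- merged$start[r]            # first interval index
    i1 <- merged$end[r] + 1L         # last point index
    tibble::tibble(start_time = track$time[i0], end_time = track$time[i1],
                   gps_distance_m = sum(d[i0:(i1 - 1L)]),
                   n_points = i1 - i0 + 1L)
  })
  segs <- segs[segs$gps_distance_m >= cfg$min_walk_m, , drop = FALSE]
  class(segs) <- c("walk_segments", class(tibble::tibble()))
  segs
}

#' Estimate accelerometer distance over a GPS-defined walk
#'
#' Extracts the time-aligned accelerometer slice for one walk segment
#' (absolute timestamps; no cross-correlation refinement), counts steps and
#' sums inverted-pendulum step lengths.
#'
#' @param trace An [accel_trace()] spanning the walk.
#' @param walk One row of [segment_walks()] output (or any object with
#'   `start_time`/`end_time`).
#' @param cfg A [step_config()].
#' @param orient,orientation_cfg Passed to [count_steps()].
#' @param unit Bounce unit for [step_length_m()].
#' @return A one-row tibble: `algo_distance_m`, `n_steps`.
#' @export
estimate_walk <- function(trace, walk, cfg = step_config(), orient = TRUE,
                          orientation_cfg = orientation_config(),
                          unit = "g") {
  t0 <- as.numeric(walk$start_time) - as.numeric(trace_start(trace))
  t1 <- as.numeric(walk$end_time) - as.numeric(trace_start(trace))
  if (t1 <= t0) return(tibble::tibble(algo_distance_m = 0, n_steps = 0L))
  if (t0 < 0 || t1 > trace_duration(trace) + 1 / trace_rate(trace)) {
    stop("walk interval lies outside the accelerometer trace span",
         call. = FALSE)
  }
  sl <- slice_trace(trace, t0, t1)
  steps <- count_steps(sl, cfg, orient = orient,
                       orientation_cfg = orientation_cfg)
  tibble::tibble(algo_distance_m = walk_distance_m(steps, unit),
                 n_steps = nrow(steps))
}

#' Compare accelerometer and GPS distance over all walks of a track
#'
#' @param trace An [accel_trace()].
#' @param track A [gps_track()] covering the same period.
#' @param seg_cfg A [segmentation_config()].
#' @param cfg A [step_config()].
#' @param ... Passed to [estimate_walk()].
#' @return A tibble with one row per walk: `start_time`, `end_time`,
#'   `gps_distance_m`, `algo_distance_m`, `n_steps`, `similarity_pct`
#'   (see [mean_similarity()] for the per-walk similarity definition).
#' @export
compare_walks <- function(trace, track, seg_cfg = segmentation_config(),
                          cfg = step_config(), ...) {
  walks <- segment_walks(track, seg_cfg)
  if (nrow(walks) == 0L) {
    return(tibble::tibble(start_time = track$time[0],
                          end_time = track$time[0],
                          gps_distance_m = numeric(),
                          algo_distance_m = numeric(), n_steps = integer(),
                          similarity_pct = numeric()))
  }
  est <- purrr::map_dfr(seq_len(nrow(walks)), function(r) {
    estimate_walk(trace, walks[r, ], cfg, ...)
  })
  dplyr::bind_cols(walks[, c("start_time", "end_time", "gps_distance_m")],
                   est) |>
    dplyr::mutate(similarity_pct =
                    (1 - abs(.data$gps_distance_m - .data$algo_distance_m) /
                       .data$gps_distance_m) * 100)
}
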