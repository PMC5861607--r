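#' Construct a tri-axial accelerometer trace
#'
#' An `accel_trace` is a tibble with columns `x`, `y`, `z` holding uniformly
#' sampled acceleration in g, plus a sampling rate and an absolute start time
#' carried as attributes. After orientation correction the `z` column is the
#' dorso-ventral (back-to-belly) axis, so gravity reads close to +1 g there.
#' There are no per-sample timestamps: sample `i` is at
#' `start_time + (i - 1) / rate_hz`.
#'
#' @param x,y,z Numeric vectors of equal length, acceleration in g.
#' @param rate_hz Sampling frequency in Hz (> 0).
#' @param start_time Absolute start time (`POSIXct`, UTC) or a string parsed
#'   as UTC. Defaults to the Unix epoch for traces with no absolute anchor.
#' @return A tibble of class `accel_trace` with columns `x`, `y`, `z`.
#' @examples
#' tr <- accel_trace(x = numeric(100), y = numeric(100), z = rep(1, 100),
#'                   rate_hz = 100)
#' trace_rate(tr)
#' @export
accel_trace <- function(x, y, z, rate_hz, start_time = .epoch()) {
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) ||
      rate_hz <= 0) {
    stop("`rate_hz` must be a single positive number", call. = FALSE)
  }
  if (is.character(start_time)) {
    start_time <- as.POSIXct(start_time, tz = "UTC")
  }
  n <- length(x)
  if (n < 1L || length(y) != n || length(z) != n) {
    stop("`x`, `y`, `z` must be non-empty vectors of equal length",
         call. = FALSE)
  }
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad) > 0L) {
    stop("non-finite acceleration sample at row ", bad[1L], call. = FALSE)
  }
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y),
                        z = as.numeric(z))
  new_accel_trace(out, rate_hz = as.numeric(rate_hz), start_time = start_time)
}

new_accel_trace <- function(df, rate_hz, start_time) {
  structure(df,
            rate_hz = rate_hz,
            start_time = start_time,
            class = c("accel_trace", class(tibble::tibble())))
}

.epoch <- function() as.POSIXct(0, origin = "1970-01-01", tz = "UTC")

#' Trace metadata accessors
#'
#' @param trace An [accel_trace()].
#' @return `trace_rate()` the sampling rate in Hz; `trace_start()` the
#'   absolute start time; `trace_times()` relative sample times in seconds
#'   from the trace start; `trace_duration()` the spanned time in seconds.
#' @export
trace_rate <- function(trace) attr(trace, "rate_hz")

#' @rdname trace_rate
#' @export
trace_start <- function(trace) attr(trace, "start_time")

#' @rdname trace_rate
#' @export
trace_times <- function(trace) (seq_len(nrow(trace)) - 1) / trace_rate(trace)

#' @rdname trace_rate
#' @export
trace_duration <- function(trace) (nrow(trace) - 1) / trace_rate(trace)

#' Extract a time slice of a trace
#'
#' @param trace An [accel_trace()].
#' @param start_s,end_s Slice bounds in seconds relative to the trace start;
#'   samples with `start_s <= t < end_s` are kept (the start time attribute
#'   is advanced accordingly).
#' @return An [accel_trace()] covering the requested window.
#' @export
slice_trace <- function(trace, start_s, end_s) {
  t <- trace_times(trace)
  keep <- which(t >= start_s & t < end_s)
  if (length(keep) == 0L) {
    stop("requested slice [", start_s, ", ", end_s,
         ") contains no samples", call. = FALSE)
  }
  new_accel_trace(tibble::as_tibble(trace)[keep, , drop = FALSE],
                  rate_hz = trace_rate(trace),
                  start_time = trace_start(trace) + t[keep[1L]])
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> %d samples @ %g Hz (%.1f s), start %s\n",
              nrow(x), trace_rate(x), trace_duration(x),
              format(trace_start(x), "%Y-%m-%d %H:%M:%OS3 UTC")))
  NextMethod()
}

#' Plot the three axes of an accelerometer trace
#'
#' @param object An [accel_trace()].
#' @param ... Ignored.
#' @return A ggplot with one facet per axis.
#' @export
autoplot.accel_trace <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$time_s <- trace_times(object)
  long <- tidyr::pivot_longer(df, c("x", "y", "z"),
                              names_to = "axis", values_to = "accel_g")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$accel_g)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$axis)) +
    ggplot2::labs(x = "time (s)", y = "acceleration (g)")
}
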