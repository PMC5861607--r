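#' Allometric stride frequency
#'
#' Body-mass scaling law for quadruped stride frequency,
#' `269 * W^(-0.14)` strides per minute, converted to Hz. Evaluated at the
#' heaviest and lightest dog of a cohort it brackets the valid step
#' frequency band (e.g. 64 kg -> 2.50 Hz, 11.3 kg -> 3.19 Hz).
#'
#' @param weight_kg Body mass in kg (> 0); vectorised.
#' @return Stride frequency in Hz.
#' @examples
#' round(stride_frequency_hz(c(64, 11.3)), 2)
#' @export
stride_frequency_hz <- function(weight_kg) {
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0)) {
    stop("`weight_kg` must be positive and finite", call. = FALSE)
  }
  269 * weight_kg^(-0.14) / 60
}

#' Valid step-frequency band
#'
#' @param f_lo_hz,f_hi_hz Band edges in Hz, `0 < f_lo_hz < f_hi_hz`. The
#'   defaults are the study band: the allometric endpoints 2.50-3.19 Hz of
#'   an 11.3-64 kg cohort widened by a safety margin. The band implies the
#'   valid inter-step period range `t_min = 1/f_hi_hz`, `t_max = 1/f_lo_hz`.
#' @return A list of class `step_band` with the edges and implied periods.
#' @export
step_band <- function(f_lo_hz = 2.25, f_hi_hz = 3.75) {
  stopifnot(f_lo_hz > 0, f_hi_hz > f_lo_hz)
  structure(list(f_lo_hz = f_lo_hz, f_hi_hz = f_hi_hz,
                 t_min_s = 1 / f_hi_hz, t_max_s = 1 / f_lo_hz),
            class = "step_band")
}

#' Step-detection parameters
#'
#' @param dv_baseline_cutoff_hz Cutoff of the slow dorso-ventral baseline
#'   that is subtracted before crossing detection (Hz).
#' @param zero_window_s Window length for the adaptive zero-line (s).
#' @param zero_hop_s Hop between zero-line windows; defaults to half the
#'   window.
#' @param band A [step_band()] of valid step frequencies.
#' @param smooth_cutoff_hz Cutoff of the light smoothing low-pass applied
#'   before crossing detection. Zero-crossing detectors are jittery on
#'   wideband sensor noise (several spurious crossings per true one), so
#'   the signal is smoothed to just above the step band; the default 8 Hz
#'   attenuates the 3.75 Hz band edge by under 0.3%.
#' @param candidate_window Number of candidates per rejection window.
#' @param max_marked Maximum marked candidates tolerated per window; a
#'   window with more is rejected wholesale.
#' @param filter_order Butterworth order for the baseline filter.
#' @param baseline_subtract If `TRUE` (default) the low-pass component is
#'   treated as a baseline and subtracted, leaving the step-band
#'   oscillation; if `FALSE` the low-pass output itself is returned (the
#'   literal filter reading, which suppresses the steps and is kept only
#'   for comparison).
#' @return A list of class `step_config`.
#' @export
step_config <- function(dv_baseline_cutoff_hz = 0.2, zero_window_s = 20,
                        zero_hop_s = zero_window_s / 2, band = step_band(),
                        smooth_cutoff_hz = 8, candidate_window = 10,
                        max_marked = 3, filter_order = 4,
                        baseline_subtract = TRUE) {
  stopifnot(dv_baseline_cutoff_hz > 0, zero_window_s > 0, zero_hop_s > 0,
            inherits(band, "step_band"),
            smooth_cutoff_hz > band$f_hi_hz, candidate_window >= 1,
            max_marked >= 0, max_marked < candidate_window,
            filter_order >= 1)
  structure(list(dv_baseline_cutoff_hz = dv_baseline_cutoff_hz,
                 zero_window_s = zero_window_s, zero_hop_s = zero_hop_s,
                 band = band, smooth_cutoff_hz = smooth_cutoff_hz,
                 candidate_window = candidate_window,
                 max_marked = max_marked, filter_order = filter_order,
                 baseline_subtract = baseline_subtract),
            class = "step_config")
}

#' Extract the oscillatory dorso-ventral signal
#'
#' Takes the dorso-ventral (`z`) axis of a re-oriented trace and subtracts
#' its slow baseline (the low-pass component below
#' `dv_baseline_cutoff_hz`, which carries gravity and posture drift),
#' leaving the step-band oscillation that the crossing detector operates
#' on.
#'
#' @param trace A re-oriented [accel_trace()].
#' @param cfg A [step_config()].
#' @return A tibble with columns `time_s` and `dv_g`, one row per sample;
#'   the sampling rate is carried in attribute `rate_hz`.
#' @export
preprocess_dv <- function(trace, cfg = step_config()) {
  if (trace_duration(trace) < cfg$zero_window_s) {
    stop("trace shorter than the zero-line window (",
         cfg$zero_window_s, " s)", call. = FALSE)
  }
  rate <- trace_rate(trace)
  z <- trace$z
  if (cfg$smooth_cutoff_hz < rate / 2) {
    z <- lowpass_zero_phase(z, rate, cfg$smooth_cutoff_hz, cfg$filter_order)
  }
  base <- lowpass_zero_phase(z, rate, cfg$dv_baseline_cutoff_hz,
                             cfg$filter_order)
  dv <- if (cfg$baseline_subtract) z - base else base
  out <- tibble::tibble(time_s = trace_times(trace), dv_g = dv)
  attr(out, "rate_hz") <- rate
  out
}

#' Adaptive zero-line of the dorso-ventral signal
#'
#' For each window position the zero-line value is halfway between the
#' maximal peak and minimal nadir of the signal within the window,
#' `(max + min) / 2`, extended as a step function to every sample. Windows
#' advance by `zero_hop_s`; the final window is anchored at the trace end
#' so all samples are covered.
#'
#' @param dv Output of [preprocess_dv()] (columns `time_s`, `dv_g`).
#' @param cfg A [step_config()].
#' @return The input tibble with a `zero_g` column appended.
#' @export
adaptive_zero_line <- function(dv, cfg = step_config()) {
  t <- dv$time_s
  v <- dv$dv_g
  n <- length(v)
  dur <- t[n] - t[1L]
  win <- min(cfg$zero_window_s, dur)
  if (dur <= cfg$zero_window_s) {
    dv$zero_g <- (max(v) + min(v)) / 2
    return(dv)
  }
  starts <- seq(t[1L], t[n] - win, by = cfg$zero_hop_s)
  if (utils::tail(starts, 1L) < t[n] - win) {
    starts <- c(starts, t[n] - win)
  }
  mids <- vapply(starts, function(s) {
    w <- v[t >= s & t <= s + win]
    (max(w) + min(w)) / 2
  }, numeric(1))
  # step-function extension: each sample takes the value of the window
  # whose centre is nearest
  centres <- starts + win / 2
  idx <- findInterval(t, c(-Inf, centres[-1L] - diff(centres) / 2))
  dv$zero_g <- mids[idx]
  dv
}

#' Falling-flank zero-crossings as step candidates
#'
#' A candidate is emitted at every sample pair where the signal passes from
#' above the zero-line to at or below it (the falling flank); the crossing
#' time is linearly interpolated between the samples. Each candidate's
#' `a_max_g`/`a_min_g` are the extrema of the signal between the rising
#' crossings flanking it, i.e. the peak and nadir of that step's "bounce".
#'
#' @param dv Output of [adaptive_zero_line()] (columns `time_s`, `dv_g`,
#'   `zero_g`).
#' @return A tibble of candidates: `time_s`, `a_max_g`, `a_min_g`.
#' @export
falling_crossings <- function(dv) {
  t <- dv$time_s
  d <- dv$dv_g - dv$zero_g
  n <- length(d)
  empty <- tibble::tibble(time_s = numeric(), a_max_g = numeric(),
                          a_min_g = numeric())
  if (n < 2L) return(empty)
  i <- seq_len(n - 1L)
  fall <- which(d[i] > 0 & d[i + 1L] <= 0)
  if (length(fall) == 0L) return(empty)
  rise <- which(d[i] <= 0 & d[i + 1L] > 0)
  frac <- d[fall] / (d[fall] - d[fall + 1L])
  time_s <- t[fall] + frac * (t[fall + 1L] - t[fall])
  # bounce window: previous rising crossing to next rising crossing
  if (length(rise) == 0L) {
    prev_rise <- rep(1L, length(fall))
    next_rise <- rep(n, length(fall))
  } else {
    pos <- findInterval(fall, rise)  # last rising crossing before each fall
    prev_rise <- ifelse(pos >= 1L, rise[pmax(pos, 1L)], 1L)
    next_rise <- ifelse(pos + 1L <= length(rise),
                        rise[pmin(pos + 1L, length(rise))], n)
  }
  ext <- purrr::map2(prev_rise, next_rise, function(a, b) {
    w <- dv$dv_g[a:min(b + 1L, n)]
    c(max(w), min(w))
  })
  tibble::tibble(time_s = time_s,
                 a_max_g = purrr::map_dbl(ext, 1L),
                 a_min_g = purrr::map_dbl(ext, 2L))
}

#' Mark candidates outside the valid step cadence
#'
#' A candidate is unmarked (plausible step) iff its interval to the
#' previous candidate lies within the valid period range
#' `[1/f_hi, 1/f_lo]` implied by the band; the first candidate is judged by
#' its following interval instead. Marked candidates are shuffles, pauses
#' or other head movements outside walking cadence. A lone candidate has no
#' interval evidence and is marked.
#'
#' @param candidates Time-sorted output of [falling_crossings()].
#' @param band A [step_band()].
#' @return The candidates with a logical `marked` column appended.
#' @export
mark_candidates <- function(candidates, band = step_band()) {
  n <- nrow(candidates)
  if (n == 0L) {
    candidates$marked <- logical()
    return(candidates)
  }
  if (is.unsorted(candidates$time_s)) {
    stop("candidates must be time-sorted", call. = FALSE)
  }
  if (n == 1L) {
    candidates$marked <- TRUE
    return(candidates)
  }
  gaps <- diff(candidates$time_s)
  in_band <- gaps >= band$t_min_s & gaps <= band$t_max_s
  candidates$marked <- c(!in_band[1L], !in_band)
  candidates
}

#' Windowed rejection of shuffling bouts
#'
#' A window of `candidate_window` consecutive candidates slides with stride
#' one; a window is rejected when it contains more than `max_marked` marked
#' candidates. A candidate becomes an accepted step iff it is unmarked and
#' belongs to at least one non-rejected window. Bouts shorter than one
#' window are judged by a single truncated window so short walks still
#' count.
#'
#' @param candidates Output of [mark_candidates()].
#' @param cfg A [step_config()].
#' @return A tibble of accepted steps: `time_s`, `a_max_g`, `a_min_g`.
#' @export
windowed_rejection <- function(candidates, cfg = step_config()) {
  n <- nrow(candidates)
  cols <- c("time_s", "a_max_g", "a_min_g")
  if (n == 0L) return(candidates[, cols])
  w <- cfg$candidate_window
  marked <- candidates$marked
  if (n <= w) {
    accepted_all <- sum(marked) <= cfg$max_marked
    keep <- !marked & accepted_all
    return(candidates[keep, cols])
  }
  cm <- cumsum(c(0L, as.integer(marked)))
  starts <- seq_len(n - w + 1L)
  win_ok <- (cm[starts + w] - cm[starts]) <= cfg$max_marked
  in_ok <- logical(n)
  for (s in starts[win_ok]) in_ok[s:(s + w - 1L)] <- TRUE
  candidates[!marked & in_ok, cols]
}

#' Count steps in a trace
#'
#' Full step-counting pipeline: orientation correction, dorso-ventral
#' baseline subtraction, adaptive zero-line, falling-flank crossing
#' detection, cadence marking and windowed shuffle rejection. Deterministic
#' for a fixed input and configuration.
#'
#' @param trace A raw [accel_trace()].
#' @param cfg A [step_config()].
#' @param orient Run the orientation stage first (default `TRUE`; set
#'   `FALSE` for traces already dorso-ventrally aligned).
#' @param orientation_cfg An [orientation_config()] for the first stage.
#' @return A tibble of accepted steps with columns `time_s`, `a_max_g`,
#'   `a_min_g`.
#' @examples
#' spec <- sim_spec(list(seg_rest(15), seg_walk(30, 3), seg_rest(15)),
#'                  seed = 7)
#' sim <- simulate_trace(spec)
#' nrow(count_steps(sim$trace))   # close to 90 true steps
#' @export
count_steps <- function(trace, cfg = step_config(), orient = TRUE,
                        orientation_cfg = orientation_config()) {
  if (orient) trace <- orient_trace(trace, orientation_cfg)
  trace |>
    preprocess_dv(cfg) |>
    adaptive_zero_line(cfg) |>
    falling_crossings() |>
    mark_candidates(cfg$band) |>
    windowed_rejection(cfg)
}

#' Plot the processed dorso-ventral signal with detected steps
#'
#' @param dv Output of [adaptive_zero_line()].
#' @param steps Optional step tibble from [count_steps()] to overlay.
#' @return A ggplot.
#' @export
plot_dv_steps <- function(dv, steps = NULL) {
  p <- ggplot2::ggplot(dv, ggplot2::aes(.data$time_s, .data$dv_g)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$zero_g), colour = "steelblue",
                       linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = "dorso-ventral acceleration (g)")
  if (!is.null(steps) && nrow(steps) > 0L) {
    p <- p + ggplot2::geom_vline(data = steps,
                                 ggplot2::aes(xintercept = .data$time_s),
                                 colour = "firebrick", alpha = 0.4)
  }
  p
}
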