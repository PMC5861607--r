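#' Orientation-correction parameters
#'
#' Controls the collar re-orientation stage: a slow low-pass isolates the
#' gravity baseline, samples whose baseline norm lies near the 1 g sphere
#' are candidate gravity references, and only orientations held stably for
#' at least `stability_window_s` count (shorter runs are treated as posture
#' transitions and excluded).
#'
#' @param gravity_cutoff_hz Low-pass cutoff for the gravity baseline (Hz).
#' @param sphere_tol_g Tolerance around the unit sphere: candidates satisfy
#'   `| ||a|| - 1 | <= sphere_tol_g` (g).
#' @param stability_window_s Minimum duration an orientation must be held to
#'   count as stable (s).
#' @param stability_tol_deg Maximum angular excursion of the baseline vector
#'   within a stable run (degrees).
#' @param filter_order Butterworth order for the baseline filter.
#' @return A list of class `orientation_config`.
#' @export
orientation_config <- function(gravity_cutoff_hz = 0.1, sphere_tol_g = 0.2,
                               stability_window_s = 10,
                               stability_tol_deg = 10, filter_order = 4) {
  stopifnot(gravity_cutoff_hz > 0, sphere_tol_g > 0, sphere_tol_g < 1,
            stability_window_s > 0, stability_tol_deg > 0, filter_order >= 1)
  structure(list(gravity_cutoff_hz = gravity_cutoff_hz,
                 sphere_tol_g = sphere_tol_g,
                 stability_window_s = stability_window_s,
                 stability_tol_deg = stability_tol_deg,
                 filter_order = filter_order),
            class = "orientation_config")
}

#' Per-axis gravity baseline of a trace
#'
#' Removes all movement above the gravity cutoff with a zero-phase
#' Butterworth low-pass (see [lowpass_zero_phase()]), leaving the slowly
#' varying gravity/posture component on each axis. Zero phase means the
#' baseline has no lag: filtering a time-reversed trace and reversing the
#' result equals filtering the original.
#'
#' @param trace An [accel_trace()] at least 30 s long.
#' @param cfg An [orientation_config()].
#' @return An [accel_trace()] of identical shape holding the baseline.
#' @export
gravity_baseline <- function(trace, cfg = orientation_config()) {
  if (trace_duration(trace) < 30) {
    stop("trace too short for gravity baseline estimation (need >= 30 s, ",
         "got ", round(trace_duration(trace), 1), " s)", call. = FALSE)
  }
  rate <- trace_rate(trace)
  f <- function(v) lowpass_zero_phase(v, rate, cfg$gravity_cutoff_hz,
                                      cfg$filter_order)
  new_accel_trace(tibble::tibble(x = f(trace$x), y = f(trace$y),
                                 z = f(trace$z)),
                  rate_hz = rate, start_time = trace_start(trace))
}

#' Stable gravity segments of a baseline trace
#'
#' Projects the baseline onto polar coordinates (norm, direction) and keeps
#' maximal runs where (a) the norm lies within `sphere_tol_g` of the 1 g
#' sphere and (b) the baseline direction stays within `stability_tol_deg` of
#' the run's reference direction, for at least `stability_window_s`. Runs
#' shorter than the window are posture transitions and are excluded.
#'
#' @param baseline Output of [gravity_baseline()].
#' @param cfg An [orientation_config()].
#' @return A tibble with columns `start_s`, `end_s` (possibly zero rows).
#' @export
stable_gravity_segments <- function(baseline, cfg = orientation_config()) {
  rate <- trace_rate(baseline)
  m <- cbind(baseline$x, baseline$y, baseline$z)
  nrm <- sqrt(rowSums(m^2))
  ok <- abs(nrm - 1) <= cfg$sphere_tol_g & nrm > 0
  t <- trace_times(baseline)
  cos_tol <- cos(cfg$stability_tol_deg * pi / 180)
  u <- m / pmax(nrm, .Machine$double.eps)

  runs <- .mask_runs(ok)
  out <- list()
  for (r in seq_len(nrow(runs))) {
    i0 <- runs$start[r]
    i1 <- runs$end[r]
    # greedy split at orientation transitions: reference direction is the
    # first sample of each sub-run, reset whenever the excursion exceeds tol
    s <- i0
    while (s <= i1) {
      cosang <- u[s:i1, , drop = FALSE] %*% u[s, ]
      brk <- which(cosang < cos_tol)
      e <- if (length(brk) == 0L) i1 else s + brk[1L] - 2L
      if (t[e] - t[s] >= cfg$stability_window_s) {
        out[[length(out) + 1L]] <- c(t[s], t[e])
      }
      s <- e + 1L
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric()))
  }
  m2 <- do.call(rbind, out)
  tibble::tibble(start_s = m2[, 1L], end_s = m2[, 2L])
}

.mask_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Solve the sagittal-plane rotation placing gravity dorso-ventrally
#'
#' Restricted Wahba problem: find the rotation minimising the least-squares
#' cost `J(theta) = 1/2 * sum_k || T(theta) w_k - v_k ||^2` over sagittal
#' rotations `T(theta)` (see [apply_rotation()]), where `w_k` are the unit
#' gravity-baseline directions inside the stable segments and the target
#' `v_k = (0, 0, 1)` is gravity on the dorso-ventral axis. Restricted to
#' this one-parameter family the minimiser is closed-form:
#' `theta* = atan2(-sum(w_x), sum(w_z))`.
#'
#' @param trace An [accel_trace()] (raw; the baseline is recomputed
#'   internally).
#' @param segments Stable segments from [stable_gravity_segments()].
#' @param cfg An [orientation_config()].
#' @return An object of class `rotation_fit` with elements `theta_rad`,
#'   `cost` (J at the optimum), `n_candidate_samples` and `segments`.
#' @export
solve_sagittal_rotation <- function(trace, segments,
                                    cfg = orientation_config()) {
  if (nrow(segments) == 0L) {
    stop("no stable gravity reference found", call. = FALSE)
  }
  baseline <- gravity_baseline(trace, cfg)
  t <- trace_times(baseline)
  keep <- rep(FALSE, length(t))
  for (r in seq_len(nrow(segments))) {
    keep <- keep | (t >= segments$start_s[r] & t <= segments$end_s[r])
  }
  m <- cbind(baseline$x, baseline$y, baseline$z)[keep, , drop = FALSE]
  nrm <- sqrt(rowSums(m^2))
  u <- m / pmax(nrm, .Machine$double.eps)
  theta <- atan2(-sum(u[, 1L]), sum(u[, 3L]))
  structure(list(theta_rad = theta,
                 cost = .wahba_cost(theta, u),
                 n_candidate_samples = nrow(u),
                 segments = segments),
            class = "rotation_fit")
}

.wahba_cost <- function(theta, u) {
  rot <- u %*% t(.sagittal_matrix(theta))  # rows are T(theta) w_k
  0.5 * sum(rot[, 1L]^2 + rot[, 2L]^2 + (rot[, 3L] - 1)^2)
}

.sagittal_matrix <- function(theta) {
  matrix(c(cos(theta), 0, sin(theta),
           0, 1, 0,
           -sin(theta), 0, cos(theta)),
         nrow = 3, byrow = TRUE)
}

#' Rotate a trace about the sagittal plane
#'
#' Multiplies every sample by the sagittal transform
#' `T(theta) = [cos 0 sin; 0 1 0; -sin 0 cos]`, the one-parameter rotation
#' family used for collar-rotation correction. Norms are preserved.
#'
#' @param trace An [accel_trace()].
#' @param theta_rad Rotation angle in radians.
#' @return The rotated [accel_trace()].
#' @export
apply_rotation <- function(trace, theta_rad) {
  rot <- cbind(trace$x, trace$y, trace$z) %*% t(.sagittal_matrix(theta_rad))
  new_accel_trace(tibble::tibble(x = rot[, 1L], y = rot[, 2L],
                                 z = rot[, 3L]),
                  rate_hz = trace_rate(trace),
                  start_time = trace_start(trace))
}

#' Full orientation-correction stage
#'
#' Convenience composition: gravity baseline, stable-segment selection,
#' sagittal Wahba fit, rotation. A single global rotation is estimated per
#' trace (collar shift treated as piecewise-constant with one dominant
#' correction).
#'
#' @param trace An [accel_trace()].
#' @param cfg An [orientation_config()].
#' @return The corrected [accel_trace()]; the `rotation_fit` is attached as
#'   attribute `"rotation_fit"`.
#' @export
orient_trace <- function(trace, cfg = orientation_config()) {
  baseline <- gravity_baseline(trace, cfg)
  segs <- stable_gravity_segments(baseline, cfg)
  fit <- solve_sagittal_rotation(trace, segs, cfg)
  out <- apply_rotation(trace, fit$theta_rad)
  attr(out, "rotation_fit") <- fit
  out
}

#' @export
print.rotation_fit <- function(x, ...) {
  cat(sprintf(
    "<rotation_fit> theta = %.2f deg, cost J = %.4g, %d candidate samples, %d stable segment(s)\n",
    x$theta_rad * 180 / pi, x$cost, x$n_candidate_samples,
    nrow(x$segments)))
  invisible(x)
}

#' @export
tidy.rotation_fit <- function(x, ...) {
  tibble::tibble(term = "theta",
                 estimate = x$theta_rad,
                 estimate_deg = x$theta_rad * 180 / pi)
}

#' @export
glance.rotation_fit <- function(x, ...) {
  tibble::tibble(theta_deg = x$theta_rad * 180 / pi,
                 cost = x$cost,
                 n_candidate_samples = x$n_candidate_samples,
                 n_segments = nrow(x$segments))
}
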