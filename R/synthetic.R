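#' Segment builders for the gait simulator
#'
#' A simulated recording is an ordered list of segments. `seg_walk()`
#' produces steady walking: the dorso-ventral axis oscillates harmonically
#' around 1 g at the step frequency (the inverted-pendulum "bounce" of the
#' centre of mass, one oscillation per step), with a per-step bounce drawn
#' from a normal distribution. `seg_rest()` is gravity only. `seg_shuffle()`
#' produces aperiodic zero-crossings whose intervals are drawn log-uniformly
#' from [0.05, 0.25] U [0.5, 2.0] s, outside any plausible step band by
#' construction. `seg_posture_shift()` holds gravity tilted within the
#' sagittal plane (a sit or lie). Every segment can carry its own collar
#' rotation offset; the whole segment is rotated by the inverse sagittal
#' transform so the orientation stage has to undo it.
#'
#' @param duration_s Segment duration in seconds.
#' @param step_freq_hz Step frequency of the walk (Hz).
#' @param bounce_mean_g,bounce_sd_g Mean and sd of the per-step bounce
#'   `A_max - A_min` in g.
#' @param amplitude_g Peak amplitude of shuffle lobes (g).
#' @param tilt_deg Sagittal tilt of gravity during a posture shift
#'   (degrees).
#' @param collar_theta_deg Collar rotation offset applied to the segment
#'   (degrees).
#' @return A list describing the segment.
#' @export
seg_walk <- function(duration_s, step_freq_hz, bounce_mean_g = 0.3,
                     bounce_sd_g = 0.05, collar_theta_deg = 0) {
  list(kind = "walk", duration_s = duration_s, step_freq_hz = step_freq_hz,
       bounce_mean_g = bounce_mean_g, bounce_sd_g = bounce_sd_g,
       collar_theta_deg = collar_theta_deg)
}

#' @rdname seg_walk
#' @export
seg_rest <- function(duration_s, collar_theta_deg = 0) {
  list(kind = "rest", duration_s = duration_s,
       collar_theta_deg = collar_theta_deg)
}

#' @rdname seg_walk
#' @export
seg_shuffle <- function(duration_s, amplitude_g = 0.3,
                        collar_theta_deg = 0) {
  list(kind = "shuffle", duration_s = duration_s,
       amplitude_g = amplitude_g, collar_theta_deg = collar_theta_deg)
}

#' @rdname seg_walk
#' @export
seg_posture_shift <- function(duration_s, tilt_deg = 30,
                              collar_theta_deg = 0) {
  list(kind = "posture_shift", duration_s = duration_s,
       tilt_deg = tilt_deg, collar_theta_deg = collar_theta_deg)
}

#' Specification of a simulated recording
#'
#' @param segments List of segments from [seg_walk()] and friends.
#' @param rate_hz Sampling rate (default 100 Hz, the study device).
#' @param noise_sd_g Standard deviation of iid Gaussian sensor noise added
#'   per axis in the sensor frame (default 0.02 g).
#' @param seed Integer seed; fixes all randomness so identical specs give
#'   bit-identical traces.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(segments, rate_hz = 100, noise_sd_g = 0.02, seed = 1L) {
  if (!is.list(segments) || length(segments) == 0L) {
    stop("`segments` must be a non-empty list of segment specs",
         call. = FALSE)
  }
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    if (is.null(s$kind) ||
        !s$kind %in% c("walk", "rest", "shuffle", "posture_shift")) {
      stop("segment ", i, ": unknown kind", call. = FALSE)
    }
    if (!is.numeric(s$duration_s) || s$duration_s <= 0) {
      stop("segment ", i, ": duration_s must be positive", call. = FALSE)
    }
    if (s$kind == "walk" &&
        (s$step_freq_hz <= 0 || s$step_freq_hz >= rate_hz / 2)) {
      stop("segment ", i, ": step_freq_hz must lie in (0, rate_hz/2)",
           call. = FALSE)
    }
  }
  stopifnot(rate_hz > 0, noise_sd_g >= 0)
  structure(list(segments = segments, rate_hz = rate_hz,
                 noise_sd_g = noise_sd_g, seed = as.integer(seed)),
            class = "sim_spec")
}

# evaluate code with a local, restored RNG state
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a collar-accelerometer recording with ground truth
#'
#' Walking is modelled as the simple-harmonic bounce of the centre of mass
#' about the scapulohumeral joint: the dorso-ventral axis reads
#' `1 + (b_k / 2) sin(2 pi f t)` g during step `k` (bounce `b_k`,
#' amplitude changing at the zero-crossing between steps so the signal is
#' continuous), giving one falling-flank zero-crossing per step at known
#' times. Each segment is then rotated by the inverse sagittal transform of
#' its collar offset and iid sensor noise is added per axis.
#'
#' @param spec A [sim_spec()].
#' @return A list with elements `trace` (an [accel_trace()]) and `truth`, a
#'   list holding `steps` (tibble `time_s`, `bounce_g`, `length_m`),
#'   `segments` (tibble `kind`, `start_s`, `end_s`, `collar_theta_deg`) and
#'   `total_distance_m`.
#' @examples
#' sim <- simulate_trace(sim_spec(list(seg_walk(60, 3)), seed = 42))
#' nrow(sim$truth$steps)   # 180 steps
#' @export
simulate_trace <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  .with_seed(spec$seed, {
    rate <- spec$rate_hz
    parts <- vector("list", length(spec$segments))
    truth_steps <- vector("list", length(spec$segments))
    seg_meta <- vector("list", length(spec$segments))
    offset_s <- 0
    for (i in seq_along(spec$segments)) {
      s <- spec$segments[[i]]
      n <- max(1L, round(s$duration_s * rate))
      t_local <- (seq_len(n) - 1L) / rate
      sig <- switch(
        s$kind,
        walk = .sim_walk(s, t_local),
        rest = list(dv = rep(1, n), steps = NULL),
        shuffle = .sim_shuffle(s, t_local),
        posture_shift = list(
          dv = rep(cos(s$tilt_deg * pi / 180), n),
          xs = rep(-sin(s$tilt_deg * pi / 180), n), steps = NULL)
      )
      xs <- sig$xs %||% numeric(n)
      m <- cbind(xs, numeric(n), sig$dv) %*%
        t(.sagittal_matrix(-s$collar_theta_deg * pi / 180))
      parts[[i]] <- m
      if (!is.null(sig$steps)) {
        st <- sig$steps
        st$time_s <- st$time_s + offset_s
        truth_steps[[i]] <- st
      }
      seg_meta[[i]] <- tibble::tibble(kind = s$kind, start_s = offset_s,
                                      end_s = offset_s + n / rate,
                                      collar_theta_deg = s$collar_theta_deg)
      offset_s <- offset_s + n / rate
    }
    m <- do.call(rbind, parts)
    ntot <- nrow(m)
    m <- m + matrix(stats::rnorm(3L * ntot, 0, spec$noise_sd_g), ncol = 3L)
    steps <- dplyr::bind_rows(truth_steps)
    if (nrow(steps) == 0L) {
      steps <- tibble::tibble(time_s = numeric(), bounce_g = numeric())
    }
    steps$length_m <- if (nrow(steps) > 0L) steps$bounce_g^0.25 else numeric()
    list(
      trace = accel_trace(m[, 1L], m[, 2L], m[, 3L], rate_hz = rate),
      truth = list(steps = steps,
                   segments = dplyr::bind_rows(seg_meta),
                   total_distance_m = sum(steps$length_m))
    )
  })
}

.sim_walk <- function(s, t_local) {
  f <- s$step_freq_hz
  dur <- t_local[length(t_local)] + (t_local[2L] - t_local[1L])
  n_steps <- floor(f * dur)
  if (n_steps < 1L) {
    return(list(dv = rep(1, length(t_local)), steps = NULL))
  }
  bounce <- pmax(stats::rnorm(n_steps, s$bounce_mean_g, s$bounce_sd_g),
                 0.02)
  idx <- pmin(floor(t_local * f), n_steps)  # 0-based step index per sample
  amp <- c(bounce / 2, 0)[idx + 1L]         # silence after the last step
  list(dv = 1 + amp * sin(2 * pi * f * t_local),
       steps = tibble::tibble(time_s = (seq_len(n_steps) - 0.5) / f,
                              bounce_g = bounce))
}

.sim_shuffle <- function(s, t_local) {
  dur <- t_local[length(t_local)]
  # draw intervals between falling crossings from the bimodal log-uniform
  # set; each interval holds one full oscillation starting downwards
  gaps <- numeric(0)
  while (sum(gaps) < dur) {
    lohi <- stats::runif(1) < 0.5
    g <- if (lohi) exp(stats::runif(1, log(0.05), log(0.25)))
         else exp(stats::runif(1, log(0.5), log(2.0)))
    gaps <- c(gaps, g)
  }
  bounds <- cumsum(c(0, gaps))
  j <- findInterval(t_local, bounds, rightmost.closed = TRUE)
  u <- (t_local - bounds[j]) / gaps[pmin(j, length(gaps))]
  list(dv = 1 - s$amplitude_g * sin(2 * pi * u), steps = NULL)
}

#' Benchmark the full pipeline over randomised simulated walks
#'
#' Each run draws a walk (2.3-3.7 Hz, 50-500 steps, bounce mean
#' 0.2-0.6 g, collar offset -40 to 40 degrees) flanked by 15 s rests,
#' simulates it, runs the complete detection pipeline (orientation
#' included) and scores it against ground truth: detected steps are matched
#' to truth intervals of half a step period around each true step.
#'
#' @param n_runs Number of simulated recordings (>= 1).
#' @param seed Master seed; the whole table is deterministic given it.
#' @param noise_sd_g Sensor noise level for every run.
#' @param cfg A [step_config()].
#' @return A tibble with one row per run: spec summary columns plus
#'   `n_detected`, `detection_rate`, `ppv`, `distance_error_pct` (signed,
#'   relative to the ground-truth closed-form distance).
#' @export
benchmark_suite <- function(n_runs, seed = 1L, noise_sd_g = 0.02,
                            cfg = step_config()) {
  stopifnot(n_runs >= 1)
  params <- .with_seed(seed, tibble::tibble(
    run = seq_len(n_runs),
    step_freq_hz = stats::runif(n_runs, 2.3, 3.7),
    n_true_steps = sample(50:500, n_runs, replace = TRUE),
    bounce_mean_g = stats::runif(n_runs, 0.2, 0.6),
    collar_theta_deg = stats::runif(n_runs, -40, 40),
    sim_seed = sample.int(.Machine$integer.max, n_runs)
  ))
  res <- purrr::pmap_dfr(params, function(run, step_freq_hz, n_true_steps,
                                          bounce_mean_g, collar_theta_deg,
                                          sim_seed) {
    dur <- (n_true_steps + 0.25) / step_freq_hz
    spec <- sim_spec(list(
      seg_rest(15, collar_theta_deg),
      seg_walk(dur, step_freq_hz, bounce_mean_g,
               collar_theta_deg = collar_theta_deg),
      seg_rest(15, collar_theta_deg)),
      noise_sd_g = noise_sd_g, seed = sim_seed)
    sim <- simulate_trace(spec)
    steps <- count_steps(sim$trace, cfg)
    rep <- match_steps(steps$time_s, truth_annotations(sim$truth))
    tibble::tibble(
      n_detected = nrow(steps),
      detection_rate = rep$detection_rate,
      ppv = rep$ppv,
      distance_error_pct = (walk_distance_m(steps) -
                              sim$truth$total_distance_m) /
        sim$truth$total_distance_m * 100)
  })
  dplyr::bind_cols(params[setdiff(names(params), "sim_seed")],
                   noise_sd_g = noise_sd_g, res)
}

#' Ground-truth annotation intervals for a simulated recording
#'
#' Builds swing-phase-like intervals of half a step period centred on each
#' true step time, for scoring detections with [match_steps()].
#'
#' @param truth The `truth` element of [simulate_trace()] output.
#' @return An [annotation_set()].
#' @export
truth_annotations <- function(truth) {
  st <- truth$steps
  if (nrow(st) == 0L) return(annotation_set(numeric(), numeric()))
  gap <- if (nrow(st) > 1L) min(diff(st$time_s)) else 0.5
  half <- 0.45 * gap
  annotation_set(st$time_s - half, st$time_s + half)
}
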