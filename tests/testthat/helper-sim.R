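# shared fixture builders (all generated in code; nothing on disk)

# trace whose z axis is `dv` with silent x/y, default 100 Hz
dv_trace <- function(dv, rate_hz = 100) {
  n <- length(dv)
  accel_trace(numeric(n), numeric(n), dv, rate_hz = rate_hz)
}

# constant-gravity trace rotated away from dorso-ventral by theta_deg
tilted_gravity_trace <- function(theta_deg, duration_s = 60,
                                 rate_hz = 100) {
  n <- duration_s * rate_hz
  g <- c(-sin(theta_deg * pi / 180), 0, cos(theta_deg * pi / 180))
  accel_trace(rep(g[1], n), rep(g[2], n), rep(g[3], n), rate_hz = rate_hz)
}

# dense-grid minimiser of the sagittal Wahba cost: independent oracle
grid_wahba_theta <- function(trace, cfg = orientation_config(),
                             n_grid = 3600) {
  baseline <- gravity_baseline(trace, cfg)
  segs <- stable_gravity_segments(baseline, cfg)
  t <- trace_times(baseline)
  keep <- rep(FALSE, length(t))
  for (r in seq_len(nrow(segs))) {
    keep <- keep | (t >= segs$start_s[r] & t <= segs$end_s[r])
  }
  m <- cbind(baseline$x, baseline$y, baseline$z)[keep, , drop = FALSE]
  u <- m / sqrt(rowSums(m^2))
  thetas <- seq(-pi, pi, length.out = n_grid)
  cost <- vapply(thetas, function(th) {
    ct <- cos(th); st <- sin(th)
    rx <- ct * u[, 1] + st * u[, 3]
    rz <- -st * u[, 1] + ct * u[, 3]
    0.5 * sum(rx^2 + u[, 2]^2 + (rz - 1)^2)
  }, numeric(1))
  list(theta = thetas[which.min(cost)], cost = min(cost))
}

# uniform-speed GPS track heading north: speed in km/h, one fix per fix_s
uniform_track <- function(speed_kmh, duration_s, fix_s = 5,
                          t0 = as.POSIXct("2020-01-01 10:00:00",
                                          tz = "UTC")) {
  times <- t0 + seq(0, duration_s, by = fix_s)
  step_deg <- (speed_kmh / 3.6 * fix_s) / (6371000 * pi / 180)
  gps_track(times, 50 + step_deg * seq_along(times), rep(0, length(times)))
}
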