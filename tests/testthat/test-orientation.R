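test_that("gravity baseline has unit DC gain and kills step-band content", {
  n <- 6000
  t <- (seq_len(n) - 1) / 100
  const <- dv_trace(rep(1, n))
  out <- gravity_baseline(const)
  expect_equal(out$z, rep(1, n), tolerance = 1e-9)
  expect_equal(out$x, rep(0, n))

  # steady-state attenuation at 30x the cutoff (edges excluded: the
  # magnitude-response argument is asymptotic, boundaries carry reflection
  # transients of order 1/omega_c)
  sine <- dv_trace(sin(2 * pi * 3 * t))
  ys <- gravity_baseline(sine)$z
  interior <- 1000:5000
  expect_lt(max(abs(ys[interior])), 1e-3)

  # linearity: DC + sine ~ DC
  mix <- gravity_baseline(dv_trace(1 + sin(2 * pi * 3 * t)))$z
  expect_equal(mix[interior], rep(1, length(interior)), tolerance = 1e-3)

  expect_error(gravity_baseline(dv_trace(rep(1, 100))), "30 s")
})

test_that("zero-phase contract: time reversal commutes with filtering", {
  t <- (seq_len(4000) - 1) / 100
  x <- 1 + 0.3 * sin(2 * pi * 0.05 * t) + 0.2 * sin(2 * pi * 3 * t)
  a <- lowpass_zero_phase(x, 100, 0.1)
  b <- rev(lowpass_zero_phase(rev(x), 100, 0.1))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("frequency-domain filter agrees with recursive filtfilt where the recursion is stable", {
  skip_if_not_installed("signal")
  # mid-band cutoff: direct-form recursion is well conditioned there
  t <- (seq_len(4000) - 1) / 100
  x <- sin(2 * pi * 0.5 * t) + 0.5 * sin(2 * pi * 10 * t)
  mine <- lowpass_zero_phase(x, 100, 2, order = 4)
  ref <- signal::filtfilt(signal::butter(4, 2 / 50, "low"), x)
  expect_equal(mine[500:3500], ref[500:3500], tolerance = 5e-3)
})

test_that("stable gravity segments follow the sphere and stability rules", {
  cfg <- orientation_config()
  segs <- stable_gravity_segments(gravity_baseline(dv_trace(rep(1, 6000))),
                                  cfg)
  expect_equal(nrow(segs), 1L)
  expect_lt(segs$start_s[1], 5)
  expect_gt(segs$end_s[1], 55)

  # norm far off the unit sphere: no candidates
  off <- stable_gravity_segments(
    gravity_baseline(dv_trace(rep(1.5, 6000))), cfg)
  expect_equal(nrow(off), 0L)

  # a 4 s excursion to a different orientation is a posture transition
  n1 <- 2800; n2 <- 400; n3 <- 2800
  g2 <- c(sin(45 * pi / 180), 0, cos(45 * pi / 180))
  tr <- accel_trace(c(numeric(n1), rep(g2[1], n2), numeric(n3)),
                    numeric(n1 + n2 + n3),
                    c(rep(1, n1), rep(g2[3], n2), rep(1, n3)),
                    rate_hz = 100)
  segs3 <- stable_gravity_segments(gravity_baseline(tr), cfg)
  # only the two long runs survive; nothing inside the 4 s excursion
  expect_true(all(segs3$end_s < 27 | segs3$start_s > 33))
  expect_true(all(segs3$end_s - segs3$start_s >= cfg$stability_window_s))
})

test_that("sagittal rotation solver recovers known collar angles", {
  aligned <- tilted_gravity_trace(0)
  segs <- stable_gravity_segments(gravity_baseline(aligned))
  fit <- solve_sagittal_rotation(aligned, segs)
  expect_lt(abs(fit$theta_rad), 1e-6)
  expect_gte(fit$cost, 0)

  for (deg in c(30, -60, 120)) {
    tr <- tilted_gravity_trace(deg)
    fit <- solve_sagittal_rotation(
      tr, stable_gravity_segments(gravity_baseline(tr)))
    expect_equal(fit$theta_rad * 180 / pi, deg, tolerance = 0.1)
    corrected <- apply_rotation(tr, fit$theta_rad)
    expect_equal(mean(corrected$z), 1, tolerance = 1e-6)
  }

  expect_error(
    solve_sagittal_rotation(aligned,
                            tibble::tibble(start_s = numeric(),
                                           end_s = numeric())),
    "no stable gravity reference")
})

test_that("solver matches the dense-grid Wahba oracle on noisy traces", {
  set.seed(101)
  for (i in 1:5) {
    deg <- runif(1, -170, 170)
    tr <- tilted_gravity_trace(deg)
    noisy <- accel_trace(tr$x + rnorm(nrow(tr), 0, 0.03),
                         tr$y + rnorm(nrow(tr), 0, 0.03),
                         tr$z + rnorm(nrow(tr), 0, 0.03), rate_hz = 100)
    segs <- stable_gravity_segments(gravity_baseline(noisy))
    fit <- solve_sagittal_rotation(noisy, segs)
    oracle <- grid_wahba_theta(noisy)
    expect_equal(fit$theta_rad, oracle$theta, tolerance = 0.1 * pi / 180)
    expect_lte(fit$cost, oracle$cost + 1e-9)
  }
})

test_that("sagittal transform is exact on axis vectors and preserves norms", {
  tr <- accel_trace(1, 0, 0, rate_hz = 100)
  out <- apply_rotation(tr, pi / 2)
  expect_equal(c(out$x, out$y, out$z), c(0, 0, -1), tolerance = 1e-12)

  expect_equal(tibble::as_tibble(apply_rotation(tr, 0)),
               tibble::as_tibble(tr))

  set.seed(5)
  v <- accel_trace(rnorm(50), rnorm(50), rnorm(50), rate_hz = 10)
  for (theta in runif(5, -pi, pi)) {
    rot <- apply_rotation(v, theta)
    expect_equal(sqrt(rot$x^2 + rot$y^2 + rot$z^2),
                 sqrt(v$x^2 + v$y^2 + v$z^2), tolerance = 1e-12)
    back <- apply_rotation(rot, -theta)
    expect_equal(back$z, v$z, tolerance = 1e-12)
  }
})

test_that("orientation is idempotent: correcting twice changes nothing", {
  sim <- simulate_trace(sim_spec(list(seg_rest(20, 35),
                                      seg_walk(30, 3, collar_theta_deg = 35),
                                      seg_rest(20, 35)), seed = 9))
  once <- orient_trace(sim$trace)
  twice <- orient_trace(once)
  expect_lt(abs(attr(twice, "rotation_fit")$theta_rad) * 180 / pi, 0.5)
})
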