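test_that("allometric stride frequency reproduces the published band", {
  expect_equal(round(stride_frequency_hz(64), 2), 2.50)
  expect_equal(round(stride_frequency_hz(11.3), 2), 3.19)
  expect_equal(stride_frequency_hz(1), 269 / 60)
  expect_error(stride_frequency_hz(0), "positive")
  expect_error(stride_frequency_hz(-5), "positive")
})

test_that("preprocess_dv removes gravity and posture drift, keeps the steps", {
  n <- 6000
  t <- (seq_len(n) - 1) / 100
  expect_equal(preprocess_dv(dv_trace(rep(1, n)))$dv_g, rep(0, n),
               tolerance = 1e-9)

  out <- preprocess_dv(dv_trace(1 + sin(2 * pi * 3 * t)))
  interior <- 1000:5000
  expect_equal(out$dv_g[interior], sin(2 * pi * 3 * t)[interior],
               tolerance = 0.01)

  # 0.05 Hz drift attenuated by more than 99%
  drift <- 0.5 * sin(2 * pi * 0.05 * t)
  out2 <- preprocess_dv(dv_trace(1 + drift + sin(2 * pi * 3 * t)))
  resid <- out2$dv_g[interior] - sin(2 * pi * 3 * t)[interior]
  expect_lt(max(abs(resid)), 0.005 + 0.01)

  expect_error(preprocess_dv(dv_trace(rep(1, 100))), "zero-line window")
})

test_that("adaptive zero-line sits halfway between peak and nadir", {
  t <- (seq_len(6000) - 1) / 100
  sym <- adaptive_zero_line(
    tibble::tibble(time_s = t, dv_g = sin(2 * pi * 3 * t)))
  expect_equal(sym$zero_g, rep(0, 6000), tolerance = 1e-6)

  shifted <- adaptive_zero_line(
    tibble::tibble(time_s = t, dv_g = 0.37 + sin(2 * pi * 3 * t)))
  expect_equal(shifted$zero_g, rep(0.37, 6000), tolerance = 1e-6)

  square <- adaptive_zero_line(
    tibble::tibble(time_s = t,
                   dv_g = ifelse(sin(2 * pi * 3 * t) > 0, 1.0, 0.2)))
  expect_equal(square$zero_g, rep(0.6, 6000), tolerance = 1e-9)
})

test_that("falling crossings are counted, interpolated and bounded", {
  t <- (seq_len(1000) - 1) / 100
  for (f in c(1, 2.5, 3)) {
    dv <- tibble::tibble(time_s = t, dv_g = sin(2 * pi * f * t),
                         zero_g = 0)
    cand <- falling_crossings(dv)
    expect_lte(abs(nrow(cand) - floor(f * 10)), 1)
    # analytic falling-crossing times are (k + 1/2)/f
    expected <- (seq_len(nrow(cand)) - 0.5) / f
    expect_equal(cand$time_s, expected, tolerance = 1e-3)
    expect_true(all(cand$a_max_g >= cand$a_min_g))
  }

  none <- falling_crossings(
    tibble::tibble(time_s = t, dv_g = rep(0.5, 1000), zero_g = 0))
  expect_equal(nrow(none), 0L)

  ramp <- falling_crossings(
    tibble::tibble(time_s = t, dv_g = seq(1, -1, length.out = 1000),
                   zero_g = 0))
  expect_equal(nrow(ramp), 1L)
  expect_equal(ramp$time_s, 4.995, tolerance = 1e-2)
})

test_that("cadence marking follows the inter-candidate interval rule", {
  band <- step_band(2.25, 3.75)
  mk <- function(times) {
    mark_candidates(tibble::tibble(time_s = times,
                                   a_max_g = 1, a_min_g = -1), band)
  }
  expect_false(any(mk(seq(0, 10, by = 1 / 3))$marked))      # 3.0 Hz
  expect_true(all(mk(seq(0, 10, by = 1))$marked))           # 1.0 Hz
  alt <- mk(cumsum(c(0, rep(c(0.3, 0.6), 10))))             # alternating
  # interval 0.3 in band, 0.6 out: every second candidate marked
  expect_equal(alt$marked[-1], rep(c(FALSE, TRUE), 10))
})

test_that("windowed rejection drops shuffling windows, keeps clean ones", {
  cfg <- step_config()
  cand <- function(n, marked) {
    tibble::tibble(time_s = seq_len(n) / 3, a_max_g = 1, a_min_g = -1,
                   marked = marked)
  }
  expect_equal(nrow(windowed_rejection(cand(20, rep(FALSE, 20)), cfg)), 20L)

  # exactly the printed rule: a 10-candidate window with 4 marked is out
  expect_equal(nrow(windowed_rejection(
    cand(10, c(rep(TRUE, 4), rep(FALSE, 6))), cfg)), 0L)
  # ... while 3 marked is tolerated
  expect_equal(nrow(windowed_rejection(
    cand(10, c(rep(TRUE, 3), rep(FALSE, 7))), cfg)), 7L)

  # 30 candidates, 4 consecutive marked in the middle: brute-force check
  marked <- rep(FALSE, 30); marked[14:17] <- TRUE
  got <- windowed_rejection(cand(30, marked), cfg)
  in_ok <- logical(30)
  for (s in 1:21) {
    if (sum(marked[s:(s + 9)]) <= 3) in_ok[s:(s + 9)] <- TRUE
  }
  expect_equal(got$time_s, (which(!marked & in_ok)) / 3)
})

test_that("marking more candidates never increases accepted steps", {
  cfg <- step_config()
  set.seed(77)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    marked <- runif(n) < 0.3
    base <- tibble::tibble(time_s = cumsum(runif(n, 0.27, 0.44)),
                           a_max_g = 1, a_min_g = -1, marked = marked)
    n0 <- nrow(windowed_rejection(base, cfg))
    extra <- base
    flip <- which(!extra$marked)
    if (length(flip) == 0L) next
    extra$marked[sample(flip, 1)] <- TRUE
    expect_lte(nrow(windowed_rejection(extra, cfg)), n0)
  }
})

test_that("full pipeline counts clean walks and ignores rest and shuffles", {
  walk <- simulate_trace(sim_spec(list(seg_walk((100 + 0.25) / 3, 3)),
                                  seed = 21))
  expect_equal(nrow(walk$truth$steps), 100L)
  expect_lte(abs(nrow(count_steps(walk$trace)) - 100L), 2L)

  # flanked by rest the count may pick up a few boundary crossings where
  # candidate windows straddle the rest/walk transition
  sim <- simulate_trace(sim_spec(
    list(seg_rest(15), seg_walk((100 + 0.25) / 3, 3), seg_rest(15)),
    seed = 21))
  steps <- count_steps(sim$trace)
  expect_lte(abs(nrow(steps) - 100L), 4L)

  rest <- simulate_trace(sim_spec(list(seg_rest(60)), seed = 22))
  expect_equal(nrow(count_steps(rest$trace)), 0L)

  # a 10 s shuffle inserted mid-walk contributes no steps inside its span
  shuf <- simulate_trace(sim_spec(
    list(seg_rest(15), seg_walk(30, 3), seg_shuffle(10), seg_walk(30, 3),
         seg_rest(15)), seed = 23))
  segs <- shuf$truth$segments
  span <- segs[segs$kind == "shuffle", ]
  got <- count_steps(shuf$trace)
  inside <- got$time_s > span$start_s + 0.3 & got$time_s < span$end_s - 0.3
  expect_equal(sum(inside), 0L)
})

test_that("step times are increasing, spaced above the band minimum, and scale invariant", {
  sim <- simulate_trace(sim_spec(
    list(seg_rest(15), seg_walk(40, 3.1), seg_rest(15)), seed = 31))
  steps <- count_steps(sim$trace)
  expect_true(all(diff(steps$time_s) > 0))
  expect_true(all(diff(steps$time_s) >= 1 / step_band()$f_hi_hz - 0.02))

  # positive rescaling of the DV signal: zero-line and crossings co-scale
  tr <- sim$trace
  for (c in c(0.25, 4)) {
    scaled <- accel_trace(tr$x, tr$y, tr$z * c, rate_hz = trace_rate(tr))
    s2 <- count_steps(scaled, orient = FALSE)
    s1 <- count_steps(tr, orient = FALSE)
    expect_equal(nrow(s2), nrow(s1))
    expect_equal(s2$time_s, s1$time_s, tolerance = 1e-9)
  }
})
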