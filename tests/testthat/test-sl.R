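# Stride-length estimation.

# recording whose vertical axis is the exact second derivative of
# s(t) = amp * sin(2 pi f t), with ICs at the displacement troughs
disp_rec <- function(amp = 0.02, f = 2, dur = 30, fs = 100) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  acc <- -amp * (2 * pi * f)^2 * sin(2 * pi * f * t) / 9.80665
  rec <- imu_recording(1 + acc, rep(0, length(t)), rep(0, length(t)), fs)
  ics <- ic_list(seq(0.75 / f + 5, dur - 5, by = 1 / f))
  list(rec = rec, ics = ics)
}

test_that("vertical displacement recovers the closed-form excursion", {
  z <- disp_rec(amp = 0.02, f = 2)
  h <- vertical_displacement(z$rec, z$ics)
  expect_equal(mean(h), 0.04, tolerance = 0.1)  # filter edge effects < 10%

  # zero signal: zero excursion
  z0 <- disp_rec(amp = 0, f = 2)
  expect_true(all(vertical_displacement(z0$rec, z0$ics) < 1e-12))

  # linearity: doubling the displacement doubles h
  z2 <- disp_rec(amp = 0.04, f = 2)
  h2 <- vertical_displacement(z2$rec, z2$ics)
  expect_equal(mean(h2) / mean(h), 2, tolerance = 0.02)
})

test_that("pendulum model matches its closed form and is linear in k", {
  # k * sqrt(2 l h - h^2): l = 0.9, h = 0.02, k = 4.739 -> 0.894 m
  expect_equal(4.739 * sqrt(2 * 0.9 * 0.02 - 0.02^2), 0.894, tolerance = 1e-3)

  g <- sim_one_bout(cadence = 120, stride = 0.9, n_strides = 10, seed = 8)
  gs <- bout_gs(g$truth)
  ics <- detect_icd_a(g$recording, gs)
  r1 <- sl_pendulum(g$recording, ics, subject_info(), sl_params(k = 4.99))
  r2 <- sl_pendulum(g$recording, ics, subject_info(), sl_params(k = 4.587))
  expect_equal(r1$sl_mean / r2$sl_mean, 4.99 / 4.587, tolerance = 1e-12)

  # flat signal: zero stride length, warning flag set
  ics0 <- ic_list(seq(5, 15, by = 0.5))
  r0 <- suppressWarnings(sl_pendulum(flat_rec(30), ics0))
  expect_equal(r0$sl_mean, 0)
  expect_true(r0$warning)
})

test_that("generative-constant recovery stays within ten percent", {
  for (cad in c(100, 120)) {
    g <- sim_one_bout(cadence = cad, stride = 1.0, n_strides = 12, seed = cad)
    gs <- bout_gs(g$truth)
    ics <- detect_icd_a(g$recording, gs)
    r <- estimate_stride_length(g$recording, ics, subject_info(), "a")
    expect_equal(r$sl_mean, 1.0, tolerance = 0.1)
  }
})

test_that("intensity model emits the printed formula value", {
  # alternating +-1 m/s^2: mean |a| = 1, step length = 0.93 + 0.25
  fs <- 100
  n <- 30 * fs
  e <- rep(c(1, -1), length.out = n) / 9.80665
  rec <- imu_recording(1 + e, rep(0, n), rep(0, n), fs)
  ics <- ic_list(seq(5, 25, by = 0.5))
  r <- sl_intensity(rec, ics, params = sl_params(t = 0.93, p = 0.25))
  expect_equal(mean(r$step_lengths_m), 0.93 * 1 + 0.25, tolerance = 1e-4)

  # zero acceleration: step length = p
  r0 <- sl_intensity(flat_rec(30), ics, params = sl_params(t = 0.93, p = 0.25))
  expect_equal(mean(r0$step_lengths_m), 0.25, tolerance = 1e-9)

  # cube-root homogeneity: x8 acceleration doubles (length - p)
  rec8 <- imu_recording(1 + 8 * e, rep(0, n), rep(0, n), fs)
  r8 <- sl_intensity(rec8, ics, params = sl_params(t = 0.93, p = 0.25))
  expect_equal(mean(r8$step_lengths_m) - 0.25,
               2 * (mean(r$step_lengths_m) - 0.25), tolerance = 1e-4)
})

test_that("hybrid model combines its two routes", {
  ics <- ic_list(seq(5, 25, by = 0.5))
  # rest: AP route gives 0, geometric route gives p -> mean p/2
  r0 <- sl_hybrid(flat_rec(30), ics, params = sl_params(t = 0.85, p = 0.25))
  expect_equal(mean(r0$step_lengths_m), 0.25 / 2, tolerance = 1e-9)

  # slow square-wave vertical signal (survives the 3.2 Hz band limit):
  # range 16 m/s^2 -> geometric component 0.85 * 2 + 0.25 = 1.95
  fs <- 100
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  sq <- 8 * sign(sin(2 * pi * 1 * t)) / 9.80665
  rec <- imu_recording(1 + sq, rep(0, length(t)), rep(0, length(t)), fs)
  ics1 <- ic_list(seq(5, 25, by = 1))
  r <- sl_hybrid(rec, ics1, params = sl_params(t = 0.85, p = 0.25))
  # AP route is 0, so step length = geometric / 2; square wave through the
  # band limit keeps ~the fundamental, range 4/pi * 16
  expect_equal(mean(r$step_lengths_m) * 2,
               0.85 * (16 * 4 / pi)^(1 / 4) + 0.25, tolerance = 0.05)
})

test_that("the pendulum route outperforms the hybrid on simulated gait", {
  g <- sim_one_bout(cadence = 100, stride = 1.0, n_strides = 10, seed = 2)
  gs <- bout_gs(g$truth)
  ics <- detect_icd_a(g$recording, gs)
  err <- function(algo) abs(estimate_stride_length(
    g$recording, ics, subject_info(), algo)$sl_mean - 1.0)
  expect_lt(err("a"), 0.1)
  expect_gt(err("d"), err("a"))   # hybrid is the weakest route
})

test_that("distance conservation and monotonicity hold", {
  g <- sim_one_bout(cadence = 110, stride = 0.9, n_strides = 10, seed = 12)
  gs <- bout_gs(g$truth)
  ics <- detect_icd_a(g$recording, gs)
  r <- estimate_stride_length(g$recording, ics, subject_info(), "a")
  expect_equal(r$distance_m, sum(r$step_lengths_m[is.finite(r$step_lengths_m)]))

  # monotone in k
  ks <- c(3, 4, 4.739, 5.5)
  means <- vapply(ks, function(k)
    sl_pendulum(g$recording, ics, subject_info(), sl_params(k = k))$sl_mean, 1)
  expect_true(all(diff(means) > 0))

  # monotone in h: scaling the dynamic signal up increases stride length
  rec2 <- g$recording
  rec2$acc_v <- 1 + 1.5 * (rec2$acc_v - 1)
  r2 <- sl_pendulum(rec2, ics, subject_info())
  expect_gt(r2$sl_mean, r$sl_mean)
})
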