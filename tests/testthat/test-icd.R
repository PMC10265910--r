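# Initial-contact detection.

test_that("vertical-axis detector recovers simulated initial contacts", {
  g <- sim_one_bout(cadence = 100, stride = 1.1, n_strides = 20, seed = 3)
  gs <- bout_gs(g$truth)
  ics <- detect_icd_a(g$recording, gs)
  mm <- match_ics(ics, ic_list(g$truth[[1]]$ic_times_s))
  expect_equal(mm$counts$fn, 0)
  expect_equal(mm$counts$fp, 0)
  expect_lt(mean(mm$abs_errors_s), 0.05)

  # zero signal: no events
  expect_length(detect_icd_a(flat_rec(30), gait_sequences(5, 25))$ic_times_s, 0)
})

test_that("IC count tracks cadence (10 s at 109 steps/min gives ~19 ICs)", {
  g <- sim_one_bout(cadence = 109, stride = 0.9, n_strides = 9, seed = 4)
  n_truth <- length(g$truth[[1]]$ic_times_s)
  ics <- detect_icd_a(g$recording, bout_gs(g$truth))
  expect_lte(abs(length(ics$ic_times_s) - n_truth), 1)
  # fencepost: ~10 s x 109/60 steps + 1
  expect_lte(abs(n_truth - (10 * 109 / 60 + 1)), 1)
})

test_that("AP-axis detector works and locks to the dominant frequency", {
  expect_length(detect_icd_b(flat_rec(30, v = 0), gait_sequences(5, 25))$ic_times_s, 0)

  # pure 2 Hz sinusoid: exactly one IC per cycle
  fs <- 100
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  rec <- imu_recording(rep(1, length(t)), 0.3 * cos(2 * pi * 2 * t),
                       rep(0, length(t)), fs)
  ics <- detect_icd_b(rec, gait_sequences(5, 25))
  gaps <- diff(ics$ic_times_s)
  expect_equal(stats::median(gaps), 0.5, tolerance = 0.02)

  g <- sim_one_bout(cadence = 100, stride = 1.1, n_strides = 20, seed = 3)
  mm <- match_ics(detect_icd_b(g$recording, bout_gs(g$truth)),
                  ic_list(g$truth[[1]]$ic_times_s))
  expect_lte(stats::median(mm$abs_errors_s), 0.1)
})

test_that("symmetry index grades step-to-stride regularity", {
  g <- sim_one_bout(cadence = 100, stride = 0.9, asym = 1, seed = 5)
  expect_gt(symmetry_index(g$recording, bout_gs(g$truth)), 0.5)

  # constructed two-tone signal with autocorrelation ratio 0.5:
  # x = cos(2 pi f t) + b cos(pi f t), SI = (1 - b^2)/(1 + b^2) = 0.5
  fs <- 100
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  b <- sqrt(1 / 3)
  x <- 0.1 * (cos(2 * pi * 2 * t) + b * cos(pi * 2 * t))
  rec <- imu_recording(1 + x, rep(0, length(t)), rep(0, length(t)), fs)
  expect_equal(symmetry_index(rec, gait_sequences(2, 28)), 0.5,
               tolerance = 0.07)

  # degenerate zero signal: undefined
  expect_true(is.na(symmetry_index(flat_rec(30), gait_sequences(5, 25))))
  expect_error(symmetry_index(flat_rec(30), gait_sequences(5, 7)),
               class = "gaitdmo_bounds_error")
})

test_that("impairment-adaptive detector dispatches on the symmetry index", {
  # symmetric bouts: identical to the vertical-axis detector (50 random)
  set.seed(11)
  for (i in 1:50) {
    g <- sim_one_bout(cadence = sample(seq(70, 130, 10), 1),
                      stride = runif(1, 0.6, 1.2),
                      n_strides = sample(5:12, 1), seed = i)
    gs <- bout_gs(g$truth)
    expect_identical(detect_icd_c(g$recording, gs)$ic_times_s,
                     detect_icd_a(g$recording, gs)$ic_times_s)
  }

  # strongly asymmetric bout: SI in the smoothing band, count still right
  g <- sim_one_bout(cadence = 100, stride = 0.9, asym = 0.15, seed = 9)
  gs <- bout_gs(g$truth)
  si <- symmetry_index(g$recording, gs)
  expect_lt(si, 0.5)
  ics <- detect_icd_c(g$recording, gs)
  expect_lte(abs(length(ics$ic_times_s) - length(g$truth[[1]]$ic_times_s)), 1)
})

test_that("norm-based zero-crossing detector counts cycles", {
  expect_length(detect_icd_d(flat_rec(30), gait_sequences(5, 25))$ic_times_s, 0)

  # sinusoidal norm at 1.8 Hz over 10 s: 18 upward crossings
  fs <- 100
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  rec <- imu_recording(1 + 0.2 * cos(2 * pi * 1.8 * t), rep(0, length(t)),
                       rep(0, length(t)), fs)
  ics <- detect_icd_d(rec, gait_sequences(5, 15))
  inside <- ics$ic_times_s[ics$ic_times_s >= 5 & ics$ic_times_s <= 15]
  expect_lte(abs(length(inside) - 18), 1)

  g <- sim_one_bout(cadence = 100, stride = 1.1, n_strides = 20, seed = 3)
  ics2 <- detect_icd_d(g$recording, bout_gs(g$truth))
  expect_lte(abs(length(ics2$ic_times_s) - length(g$truth[[1]]$ic_times_s)), 2)
})

test_that("sequence refinement applies the one-second rule", {
  rec <- flat_rec(100)
  r <- refine_sequence(ic_list(c(5, 5.5, 6)), rec)
  expect_equal(c(r$start_s, r$end_s), c(4, 7))
  r2 <- refine_sequence(ic_list(c(0.4, 1.0)), rec)
  expect_equal(c(r2$start_s, r2$end_s), c(0, 2))
  r3 <- refine_sequence(ic_list(99.5), rec)
  expect_equal(c(r3$start_s, r3$end_s), c(98.5, 100))
  expect_error(refine_sequence(ic_list(numeric(0)), rec),
               class = "gaitdmo_empty_sequence")
})

test_that("IC lists are strictly increasing with 0.2 s de-duplication", {
  ics <- ic_list(c(3.0, 1.0, 1.1, 2.0, 2.05, 2.5))
  expect_equal(ics$ic_times_s, c(1.0, 2.0, 2.5, 3.0))
  expect_true(all(diff(ics$ic_times_s) > 0))
})

test_that("timing accuracy holds across the cadence range", {
  for (cad in c(60, 80, 100, 120, 140)) {
    g <- sim_one_bout(cadence = cad, stride = 0.9, n_strides = 8,
                      seed = cad)
    mm <- match_ics(detect_icd_a(g$recording, bout_gs(g$truth)),
                    ic_list(g$truth[[1]]$ic_times_s))
    sens <- mm$counts$tp / (mm$counts$tp + mm$counts$fn)
    expect_gte(sens, 0.95)
    expect_lte(mean(mm$abs_errors_s), 0.05)
  }
})
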