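# Synthetic-signal generator.

test_that("protocol bookkeeping matches the stated bout geometry", {
  g <- sim_one_bout(cadence = 120, stride = 1.0, n_strides = 10, seed = 1)
  b <- g$truth[[1]]
  expect_length(b$ic_times_s, 21)            # 20 steps + fencepost
  expect_equal(b$end_s - b$start_s, 10.0)    # 10 strides x 1.0 s
  expect_equal(b$mean_speed_mps, 1.0)        # stride x cadence / 120
  expect_equal(nrow(b$strides), 19)          # both-feet strides, 2 ICs apart
})

test_that("generation is deterministic in the protocol seed", {
  p <- function(seed) sim_protocol(
    data.frame(start_s = 5, n_strides = 6, cadence_spm = 100,
               stride_length_m = 0.8), noise_sd_g = 0.03, seed = seed)
  g1 <- generate_recording(p(7))
  g2 <- generate_recording(p(7))
  g3 <- generate_recording(p(8))
  expect_identical(g1$recording$acc_v, g2$recording$acc_v)
  expect_false(identical(g1$recording$acc_v, g3$recording$acc_v))
  expect_equal(unclass(g1$truth), unclass(g3$truth))  # truth is noise-free
})

test_that("double integration of the noiseless signal recovers h", {
  for (stride in c(0.6, 0.9, 1.2)) {
    g <- sim_one_bout(cadence = 100, stride = stride, n_strides = 8, seed = 2)
    h_true <- 0.9 - sqrt(0.9^2 - (stride / 4.739)^2)
    acc <- (g$recording$acc_v - 1) * 9.80665
    fs <- g$recording$fs_hz
    ic <- g$truth[[1]]$ic_times_s
    # integrate over interior strides, detrend position over each full
    # cycle; windows start mid-step so the zero-mean impact transients are
    # fully contained instead of sliced at the window edges
    half <- (ic[2] - ic[1]) / 2
    errs <- vapply(3:6, function(k) {
      i0 <- round((ic[k] + half) * fs) + 1
      i1 <- round((ic[k + 2] + half) * fs) + 1
      pos <- gaitdmo:::cumtrapz(gaitdmo:::cumtrapz(acc[i0:i1], 1 / fs), 1 / fs)
      pos <- gaitdmo:::detrend_linear(pos)
      (max(pos) - min(pos)) / h_true - 1
    }, 1)
    expect_lt(max(abs(errs)), 0.02)
  }
})

test_that("ground-truth cadence equals the stride-frequency identity exactly", {
  g <- sim_one_bout(cadence = 96, stride = 0.8, n_strides = 7, seed = 3)
  b <- g$truth[[1]]
  cr <- cadence_from_ics(ic_list(b$ic_times_s))
  expect_equal(cr$cad_mean, 96, tolerance = 1e-9)
  expect_identical(cr$cad_mean, 2 * cr$stride_frequency)
})

test_that("symmetric bouts read as symmetric to the detectors", {
  g <- sim_one_bout(cadence = 100, stride = 0.9, asym = 1, seed = 4)
  expect_gt(symmetry_index(g$recording, bout_gs(g$truth)), 0.5)
})

test_that("infeasible protocols are rejected", {
  expect_error(sim_protocol(data.frame(start_s = 5, n_strides = 6,
                                       cadence_spm = 100,
                                       stride_length_m = 5)),
               class = "gaitdmo_protocol_error")
  expect_error(sim_protocol(data.frame(start_s = c(5, 10), n_strides = 3,
                                       cadence_spm = 120,
                                       stride_length_m = 0.8)),
               class = "gaitdmo_protocol_error")   # bouts closer than 3 s
  expect_error(sim_protocol(data.frame(start_s = 5, n_strides = 6,
                                       cadence_spm = 30,
                                       stride_length_m = 0.8)),
               class = "gaitdmo_protocol_error")   # stride duration 4 s
})

test_that("the standard fixture suite spans the stated grid", {
  suite <- get_suite(noise = 0)
  expect_length(suite, 5 * 2 * 5 * 2)   # cadence x stride x duration x asym
  speeds <- vapply(suite, function(f) f$meta$speed_mps, 1)
  expect_true(any(speeds < 0.5))        # slow-walking regime present
  expect_true(any(speeds >= 1.3))
  # all truths satisfy the walking-bout validity rules
  for (f in suite[seq(1, 100, by = 7)]) {
    expect_silent(validate_bouts(f$truth))
    expect_length(validate_bouts(f$truth), length(f$truth))
  }
})
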