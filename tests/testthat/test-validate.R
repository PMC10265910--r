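# Validation framework.

test_that("window classification matches hand-enumerated examples", {
  det <- gait_sequences(0.5, 1.5)
  ref <- gait_sequences(0, 1)
  cc <- classify_gsd_windows(det, ref, 2)
  expect_equal(c(cc$tp, cc$fp, cc$fn, cc$tn), c(5, 5, 5, 5))

  cc2 <- classify_gsd_windows(ref, ref, 2)
  expect_equal(c(cc2$fp, cc2$fn), c(0, 0))

  cc3 <- classify_gsd_windows(gait_sequences(), ref, 2)
  expect_equal(c(cc3$tp, cc3$fp), c(0, 0))
  expect_equal(cc3$fn, 10)
})

test_that("window classification properties hold on random configurations", {
  set.seed(3)
  for (i in 1:40) {
    total <- runif(1, 10, 60)
    rnd_iv <- function() {
      k <- sample(0:4, 1)
      if (k == 0) return(gait_sequences())
      cuts <- sort(runif(2 * k, 0, total))
      gait_sequences(cuts[seq(1, 2 * k, 2)], cuts[seq(2, 2 * k, 2)])
    }
    det <- rnd_iv(); ref <- rnd_iv()
    cc <- classify_gsd_windows(det, ref, total)
    expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, floor(total / 0.1 + 1e-9))
    sw <- classify_gsd_windows(ref, det, total)
    expect_equal(c(sw$tp, sw$tn, sw$fp, sw$fn), c(cc$tp, cc$tn, cc$fn, cc$fp))
  }
})

test_that("IC matching follows nearest-with-tie-to-earlier greedy rules", {
  m <- match_ics(c(1.1, 2.6), c(1.0, 2.0, 3.0))
  expect_equal(c(m$counts$tp, m$counts$fp, m$counts$fn), c(1, 1, 2))
  expect_equal(m$abs_errors_s, 0.1)

  m2 <- match_ics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m2$counts$tp, 3)
  expect_true(all(m2$abs_errors_s == 0))

  # equidistant candidates: earlier detected event wins
  m3 <- match_ics(c(0.9, 1.1), c(1.0))
  expect_equal(c(m3$counts$tp, m3$counts$fp), c(1, 1))
  expect_equal(m3$abs_errors_s, 0.1)

  # relative errors use the mean reference step duration
  m4 <- match_ics(c(1.1, 2.0), c(1.0, 2.0, 3.0))
  expect_equal(m4$rel_errors, c(0.1, 0) / 1.0)
})

test_that("confusion measures match the printed formulas", {
  m <- confusion_measures(confusion_counts(tp = 8, tn = 90, fp = 1, fn = 1))
  expect_equal(m$accuracy, 0.98)
  expect_equal(m$sensitivity, 8 / 9)
  expect_equal(m$specificity, 90 / 91)
  expect_equal(m$ppv, 8 / 9)

  perfect <- confusion_measures(confusion_counts(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_true(all(unlist(perfect) == 1))

  m0 <- confusion_measures(confusion_counts(tp = 0, tn = 3, fp = 0, fn = 2))
  expect_true(is.na(m0$ppv))
  expect_false(is.na(m0$sensitivity))
})

test_that("agreement statistics match Bland-Altman arithmetic", {
  a <- agreement_stats(c(1, 2, 3), c(1, 2, 3))
  expect_equal(a$bias, 0)
  expect_equal(c(a$loa_low, a$loa_high), c(0, 0))
  expect_equal(a$icc, 1)

  b <- agreement_stats(c(1, 2, 3), c(1, 3, 2))
  expect_equal(b$bias, 0)
  expect_equal(c(b$loa_low, b$loa_high), c(-1.96, 1.96))

  expect_warning(agreement_stats(c(1, 2, 3, 4), c(1, 2, 0, 4)),
                 class = "gaitdmo_zero_reference")
})

test_that("ICC(2,1) equals the ANOVA oracle and degrades with offset", {
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(30, 10, 2)
    y <- x + rnorm(30, 0, 1)
    expect_equal(icc21(x, y)$icc, oracle_icc21(x, y), tolerance = 1e-10)
  }
  x <- rnorm(40, 10, 2)
  y <- x + rnorm(40, 0, 0.5)
  base <- icc21(x, y)$icc
  shifted <- icc21(x, y + 2)$icc
  expect_lt(shifted, base)   # absolute agreement penalizes constant offsets
})

test_that("binned exponential fits recover constructed curves", {
  set.seed(5)
  speeds <- runif(400, 0.1, 1.5)
  errs <- 50 * exp(-4 * speeds) + rnorm(400, 0, 0.5)
  fit <- binned_error_fit(errs, speeds, 0.05)
  expect_gt(fit$fit_params["b"], -4.4)
  expect_lt(fit$fit_params["b"], -3.6)
  expect_gte(fit$r2, 0.95)
  expect_equal(sum(fit$weight), 1)

  flat <- binned_error_fit(rep(10, 100), runif(100, 0, 2), 0.05)
  expect_equal(unname(flat$fit_params["a"]), 10, tolerance = 0.1)
  expect_equal(unname(flat$fit_params["b"]), 0, tolerance = 0.05)

  # empty bins are skipped without shifting the occupied bin centers
  sp <- c(rep(0.125, 5), rep(0.625, 5), rep(1.125, 5))
  f2 <- binned_error_fit(rep(c(5, 3, 2), each = 5), sp, 0.05)
  expect_equal(f2$bin_centers, c(0.125, 0.625, 1.125))
})

test_that("total gait-duration agreement reflects constructed offsets", {
  ref <- lapply(1:5, function(i) gait_sequences(c(0, 100), c(50, 130)))
  expect_equal(gsd_duration_agreement(ref, ref)$bias, 0)

  det <- lapply(ref, function(g) gait_sequences(g$start_s, g$end_s + 30))
  a <- gsd_duration_agreement(det, ref)
  expect_equal(a$bias, 60)
  expect_equal(c(a$loa_low, a$loa_high), c(60, 60))

  set.seed(9)
  over <- runif(20, 5, 50)
  ref2 <- lapply(1:20, function(i) gait_sequences(0, 100 + i))
  det2 <- lapply(1:20, function(i)
    gait_sequences(0, 100 + i + over[i]))
  expect_equal(gsd_duration_agreement(det2, ref2)$bias, mean(over),
               tolerance = 1e-9)
})
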