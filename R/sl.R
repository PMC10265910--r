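# Stride-length estimation per gait sequence.
#
# Four routes: the inverted-pendulum model on double-integrated vertical
# acceleration with a calibration factor k (two calibrations), an
# acceleration-intensity model (cube root of the mean |acc|), and a hybrid
# combining AP double integration with a fourth-root intensity model.
# Acceleration enters the models in m/s^2; recordings are in g and are
# converted internally.

#' Stride-length model parameters
#'
#' Calibration constants from training on multi-cohort data:
#' `k = 4.739` for the default pendulum calibration (all cohorts),
#' `k = 4.99` for the alternative calibration with `4.587` for the MS
#' cohort; intensity constants `t = 0.93` (with `p` = foot length) for the
#' cube-root model and `t = 0.85` (with `p` = foot size) for the hybrid.
#'
#' @param k pendulum calibration factor, unitless (> 0).
#' @param t intensity calibration factor, unitless (> 0).
#' @param p additive offset, metres (foot length; >= 0).
#' @return list of class `sl_params`.
#' @export
sl_params <- function(k = 4.739, t = 0.93, p = 0.25) {
  if (k <= 0 || t <= 0 || p < 0) stop_data("need k > 0, t > 0, p >= 0")
  structure(list(k = k, t = t, p = p), class = "sl_params")
}

#' Alternative pendulum calibration (cohort-dependent)
#' @param cohort cohort label; MS uses `k = 4.587`, all others `4.99`.
#' @export
sl_params_b <- function(cohort = "HA") {
  sl_params(k = if (identical(cohort, "MS")) 4.587 else 4.99)
}

#' Stride-length result for one gait sequence
#'
#' @param start_s,stop_s bout boundaries, seconds.
#' @param sl_per_sec stride length per elapsed second, metres.
#' @param sl_mean,sl_std summary stride length, metres.
#' @param distance_m covered distance: sum of per-step lengths, metres.
#' @param step_lengths_m per-step lengths, metres.
#' @param warning TRUE when a degenerate step (h >= 2l or too short) was
#'   flagged.
#' @return object of class `sl_result`.
#' @export
sl_result <- function(start_s, stop_s, sl_per_sec, sl_mean, sl_std,
                      distance_m, step_lengths_m, warning = FALSE) {
  structure(list(start_s = start_s, stop_s = stop_s, sl_per_sec = sl_per_sec,
                 sl_mean = sl_mean, sl_std = sl_std, distance_m = distance_m,
                 step_lengths_m = step_lengths_m, warning = warning),
            class = "sl_result")
}

#' @export
print.sl_result <- function(x, ...) {
  cat(sprintf("<sl_result> [%g, %g] s: %.2f +/- %.2f m (distance %.1f m)%s\n",
              x$start_s, x$stop_s, x$sl_mean, x$sl_std, x$distance_m,
              if (isTRUE(x$warning)) " [warning]" else ""))
  invisible(x)
}

# double integration of an axis with the stated drift-removal cascade:
# detrend + 0.1 Hz high-pass on acceleration, integrate, 1 Hz high-pass on
# velocity, integrate to position (all zero-phase)
integrate_displacement <- function(acc_g, fs) {
  a <- detrend_linear(acc_g * STANDARD_GRAVITY)
  a <- butter2_filtfilt(a, 0.1, fs, "high")
  v <- cumtrapz(a, 1 / fs)
  v <- butter2_filtfilt(v, 1, fs, "high")
  cumtrapz(v, 1 / fs)
}

step_windows <- function(ics, t0, fs, n) {
  t <- ics$ic_times_s
  if (length(t) < 2L) stop_insufficient("need at least 2 initial contacts")
  i <- pmin(pmax(t_to_idx(t - t0, fs), 1L), n)
  list(from = i[-length(i)], to = i[-1], t = t)
}

# crop an axis to the IC span (+ pad) so long recordings are not filtered
# whole for every bout; returns the segment and its time origin
sl_crop <- function(x, ics, fs, pad_s = 2) {
  t <- ics$ic_times_s
  if (length(t) < 2L) stop_insufficient("need at least 2 initial contacts")
  i0 <- max(1L, t_to_idx(t[1] - pad_s, fs))
  i1 <- min(length(x), t_to_idx(t[length(t)] + pad_s, fs))
  list(x = x[i0:i1], t0 = idx_to_t(i0, fs))
}

#' Per-step vertical centre-of-mass excursion
#'
#' Double-integrates the vertical acceleration between consecutive initial
#' contacts (drift removed by the 0.1 Hz / 1 Hz high-pass cascade) and
#' returns the max-min vertical position per step. Steps shorter than 0.2 s
#' are skipped with a warning (NA in the output).
#'
#' @param rec an [imu_recording()].
#' @param ics an [ic_list()] with >= 2 events.
#' @return numeric vector of per-step height changes `h`, metres.
#' @export
vertical_displacement <- function(rec, ics) {
  fs <- rec$fs_hz
  seg <- sl_crop(rec$acc_v, ics, fs)
  pos <- integrate_displacement(seg$x - mean(seg$x), fs)
  sw <- step_windows(ics, seg$t0, fs, length(pos))
  h <- mapply(function(f, to) {
    if ((to - f) / fs < STRIDE_MIN_DUR_S / 2) return(NA_real_)
    seg <- pos[f:to]
    max(seg) - min(seg)
  }, sw$from, sw$to)
  if (anyNA(h))
    gd_warn("gaitdmo_short_step", sprintf("skipped %d step(s) shorter than %g s",
                                          sum(is.na(h)), STRIDE_MIN_DUR_S / 2))
  h
}

aggregate_sl <- function(step_lengths, ics, warning) {
  t <- ics$ic_times_s
  ok <- is.finite(step_lengths)
  start_s <- t[1]; stop_s <- t[length(t)]
  # stride length = sum of the two consecutive step lengths
  sl <- step_lengths[-length(step_lengths)] + step_lengths[-1]
  sl <- sl[is.finite(sl)]
  if (!length(sl)) sl <- 2 * step_lengths[ok]   # single-step fallback
  mid <- (t[-length(t)] + t[-1]) / 2
  tiles <- seq_len(max(1L, ceiling(stop_s - start_s)))
  tile_t <- start_s + tiles - 0.5
  per_sec <- if (sum(ok) > 1L)
    stats::approx(mid[ok], 2 * step_lengths[ok], xout = tile_t, rule = 2)$y
  else rep(2 * step_lengths[ok][1], length(tile_t))
  sl_result(start_s, stop_s, per_sec,
            sl_mean = mean(sl), sl_std = if (length(sl) > 1L) stats::sd(sl) else 0,
            distance_m = sum(step_lengths[ok]),
            step_lengths_m = step_lengths, warning = warning)
}

#' Inverted-pendulum stride length
#'
#' Per-step height change `h` from [vertical_displacement()]; stride length
#' `k * sqrt(2 l h - h^2)` with leg length `l`, emitted per step as half a
#' stride. Degenerate steps (`h >= 2 l`) are clipped to zero and flagged.
#'
#' @param rec an [imu_recording()].
#' @param ics an [ic_list()] with >= 2 events.
#' @param subject a [subject_info()] (leg length required).
#' @param params an [sl_params()]; `k` is the calibration.
#' @return an [sl_result()].
#' @export
sl_pendulum <- function(rec, ics, subject = subject_info(),
                        params = sl_params()) {
  l <- subject$leg_length_m
  h <- vertical_displacement(rec, ics)
  degen <- is.finite(h) & h >= 2 * l
  if (any(degen))
    gd_warn("gaitdmo_degenerate_step",
            sprintf("%d step(s) with h >= 2l clipped to zero", sum(degen)))
  arg <- pmax(2 * l * h - h^2, 0)
  stride_len <- params$k * sqrt(arg)
  step_len <- stride_len / 2
  flat <- is.finite(h) & arg == 0
  if (any(flat))
    gd_warn("gaitdmo_zero_excursion",
            sprintf("%d step(s) with no vertical excursion", sum(flat)))
  aggregate_sl(step_len, ics,
               warning = any(degen) || anyNA(h) || any(flat))
}

#' Intensity-based stride length (cube root)
#'
#' Per step: mean absolute gravity-removed vertical acceleration `a_mean`
#' (m/s^2) between consecutive initial contacts; step length
#' `t * a_mean^(1/3) + p`. The printed formula is unit-ambiguous in its
#' source; this implementation evaluates it in m/s^2 as stated.
#'
#' @inheritParams sl_pendulum
#' @export
sl_intensity <- function(rec, ics, subject = subject_info(),
                         params = sl_params(t = 0.93)) {
  fs <- rec$fs_hz
  seg <- sl_crop(rec$acc_v, ics, fs)
  av <- (seg$x - mean(seg$x)) * STANDARD_GRAVITY
  sw <- step_windows(ics, seg$t0, fs, length(av))
  a_mean <- mapply(function(f, to) mean(abs(av[f:to])), sw$from, sw$to)
  step_len <- params$t * a_mean^(1 / 3) + params$p
  aggregate_sl(step_len, ics, warning = FALSE)
}

#' Hybrid stride length (AP integration + fourth-root intensity)
#'
#' Combines, per step, the displacement travelled by the double-integrated
#' AP acceleration (same drift cascade as the vertical route) with the
#' geometric intensity model `t * (a_max - a_min)^(1/4) + p` on the vertical
#' axis; the step length is the mean of the two estimates.
#'
#' @inheritParams sl_pendulum
#' @export
sl_hybrid <- function(rec, ics, subject = subject_info(),
                      params = sl_params(t = 0.85)) {
  fs <- rec$fs_hz
  seg_ap <- sl_crop(rec$acc_ap, ics, fs)
  seg_v <- sl_crop(rec$acc_v, ics, fs)
  pos_ap <- integrate_displacement(seg_ap$x - mean(seg_ap$x), fs)
  # range on the gait-band signal: raw impact transients would dominate
  av <- fir_lowpass((seg_v$x - mean(seg_v$x)) * STANDARD_GRAVITY, 3.2, fs)
  sw <- step_windows(ics, seg_v$t0, fs, length(av))
  len_ap <- mapply(function(f, to) {
    seg <- pos_ap[f:to]
    max(seg) - min(seg)
  }, sw$from, sw$to)
  len_geo <- mapply(function(f, to) {
    seg <- av[f:to]
    params$t * max(max(seg) - min(seg), 0)^(1 / 4) + params$p
  }, sw$from, sw$to)
  step_len <- (len_ap + len_geo) / 2
  aggregate_sl(step_len, ics, warning = FALSE)
}

#' Dispatch over the stride-length estimators
#'
#' @inheritParams sl_pendulum
#' @param algo "a" (pendulum, k = 4.739), "b" (pendulum, k = 4.99 / 4.587
#'   for MS), "c" (cube-root intensity), "d" (hybrid).
#' @export
estimate_stride_length <- function(rec, ics, subject = subject_info(),
                                   algo = c("a", "b", "c", "d"),
                                   params = NULL) {
  algo <- match.arg(algo)
  switch(algo,
    a = sl_pendulum(rec, ics, subject,
                    params %||% sl_params(k = 4.739)),
    b = sl_pendulum(rec, ics, subject,
                    params %||% sl_params_b(subject$cohort)),
    c = sl_intensity(rec, ics, subject,
                     params %||% sl_params(t = 0.93, p = subject$foot_length_m)),
    d = sl_hybrid(rec, ics, subject,
                  params %||% sl_params(t = 0.85, p = subject$foot_length_m))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
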