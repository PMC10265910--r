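# Cadence estimation from initial contacts or a dedicated step segmentation.
#
# Cadence (steps/min) is twice the stride frequency; stride frequency is the
# mean over strides of 60 / stride duration, where a stride spans two
# consecutive same-side initial contacts (events k and k + 2 of the
# unlabeled IC train, so left and right strides interleave).

#' Cadence result for one gait sequence
#'
#' Fields mirror the standard per-bout cadence output: per-second cadence
#' trace, mean/SD, stride frequency and step count.
#'
#' @param start_s,stop_s bout boundaries, seconds.
#' @param cad_per_sec cadence per elapsed second of the bout, steps/min
#'   (length `ceiling(stop_s - start_s)`).
#' @param stride_frequency_hz mean stride frequency in strides/min, so that
#'   `cad_mean == 2 * stride_frequency` holds exactly.
#' @param cad_mean,cad_std summary cadence, steps/min.
#' @param n_steps number of steps (IC count - 1).
#' @return object of class `cadence_result`.
#' @export
cadence_result <- function(start_s, stop_s, cad_per_sec, stride_frequency_hz,
                           cad_mean, cad_std, n_steps) {
  structure(list(start_s = start_s, stop_s = stop_s,
                 cad_per_sec = cad_per_sec,
                 stride_frequency = stride_frequency_hz,
                 cad_mean = cad_mean, cad_std = cad_std,
                 n_steps = n_steps),
            class = "cadence_result")
}

#' @export
print.cadence_result <- function(x, ...) {
  cat(sprintf("<cadence_result> [%g, %g] s: %.1f +/- %.1f steps/min (%d steps)\n",
              x$start_s, x$stop_s, x$cad_mean, x$cad_std, x$n_steps))
  invisible(x)
}

#' Cadence from an initial-contact train
#'
#' Stride durations are `t[k+2] - t[k]` over the unlabeled IC train. Stride
#' frequency is the mean of `60 / duration` over strides; cadence is twice
#' that. The per-second trace comes from the instantaneous step rate
#' (`60 / step interval`, assigned at step midpoints, linearly interpolated)
#' averaged within each 1 s tile of the bout.
#'
#' @param ics an [ic_list()] with at least 3 events.
#' @return a [cadence_result()].
#' @export
cadence_from_ics <- function(ics) {
  t <- ics$ic_times_s
  if (length(t) < 3L)
    stop_insufficient("need at least 3 initial contacts for cadence")
  n <- length(t)
  stride_d <- t[3:n] - t[seq_len(n - 2L)]
  stride_freq_spm <- mean(60 / stride_d)    # strides/min
  cad_mean <- stride_freq_spm * 2           # steps/min
  step_d <- diff(t)
  step_rate <- 60 / step_d
  mid <- (t[-n] + t[-1]) / 2
  start_s <- t[1]; stop_s <- t[n]
  tiles <- seq_len(max(1L, ceiling(stop_s - start_s)))
  tile_t <- start_s + tiles - 0.5
  cad_per_sec <- if (length(mid) > 1L)
    stats::approx(mid, step_rate, xout = tile_t, rule = 2)$y
  else rep(step_rate, length(tile_t))
  cad_std <- if (length(stride_d) > 1L) stats::sd(2 * 60 / stride_d) else 0
  cadence_result(start_s, stop_s, cad_per_sec,
                 stride_frequency_hz = stride_freq_spm,
                 cad_mean = cad_mean, cad_std = cad_std,
                 n_steps = n - 1L)
}

#' Step detection by wavelet enhancement and morphological filtering
#'
#' Pre-processes the acceleration norm (FIR 3.2 Hz low-pass, detrend,
#' Savitzky-Golay order 7 / 21-sample frame rescaled with sampling rate,
#' Gaussian smoothing), enhances step features with a Mexican-hat wavelet at
#' scale 10, suppresses sub-step artifacts with grayscale morphological
#' opening then closing (flat 0.25 s element), and takes step times as the
#' maxima between zero-crossings.
#'
#' @param rec an [imu_recording()].
#' @param gs one-row [gait_sequences()] frame.
#' @return an [ic_list()] of step events.
#' @export
detect_cad_b_steps <- function(rec, gs) {
  fs <- rec$fs_hz
  nrm <- acc_norm(rec)
  seg <- crop_axis(nrm, gs, fs)
  if (diff(range(seg$x)) < 1e-9)   # flat signal: no steps, no numerical fuzz
    return(ic_from_indices(integer(0), seg$t0, fs, gs))
  x <- fir_lowpass(seg$x, 3.2, fs)
  x <- detrend_linear(x)
  frame <- round(21 * fs / 100)
  x <- savgol_smooth(x, order = 7L, frame = frame)
  x <- gaussian_smooth(x, sd_samples = 0.02 * fs)
  w <- cwt_gauss(x, 10 * fs / 100, deriv = 2L)
  # element must stay below the positive half-cycle of the fastest valid
  # step (0.2 s step -> 0.1 s lobe); a 0.25 s element would erase every
  # step above ~120 steps/min
  elem <- round(0.1 * fs)
  w <- morph_close(morph_open(w, elem), elem)
  idx <- peaks_between_zero_crossings(w)
  ic_from_indices(idx, seg$t0, fs, gs)
}

#' Estimate cadence for one gait sequence
#'
#' Route "a" uses the vertical-axis wavelet IC detector, "b" the dedicated
#' morphological step segmentation, "c" the norm zero-crossing detector;
#' each feeds [cadence_from_ics()].
#'
#' @inheritParams detect_cad_b_steps
#' @param algo "a", "b" or "c".
#' @return a [cadence_result()].
#' @export
estimate_cadence <- function(rec, gs, algo = c("a", "b", "c")) {
  ics <- switch(match.arg(algo),
                a = detect_icd_a(rec, gs),
                b = detect_cad_b_steps(rec, gs),
                c = detect_icd_d(rec, gs))
  cadence_from_ics(ics)
}
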