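# Initial-contact (heel-strike) detection within a gait sequence, plus the
# 1 s boundary refinement rule.
#
# Timing convention: the wavelet stage is implemented so that its output is
# (up to positive scale) the Gaussian-smoothed acceleration, whose maxima
# coincide with the IC-aligned acceleration peaks. Applying a
# second-derivative wavelet to the integrated signal instead would leave a
# net odd differentiation order and shift every event by a quarter step
# period; see the methods vignette.

CWT_IC_SCALE <- 9       # samples at 100 Hz; rescaled by fs/100 elsewhere
IC_MERGE_TOL_S <- 0.2   # events closer than the stride-validity floor merge

#' Initial-contact list
#'
#' Strictly increasing event times inside (within 1 s of) a source gait
#' sequence. Events closer than 0.2 s are merged to the earlier one.
#'
#' @param ic_times_s numeric event times, seconds.
#' @param source_sequence one-row [gait_sequences()] frame (or NULL).
#' @return object of class `ic_list`.
#' @export
ic_list <- function(ic_times_s, source_sequence = NULL) {
  t <- sort(as.numeric(ic_times_s))
  if (length(t) > 1L) {
    keep <- c(TRUE, diff(t) >= IC_MERGE_TOL_S)
    t <- t[keep]
  }
  if (!is.null(source_sequence) && length(t)) {
    lo <- source_sequence$start_s[1] - 1
    hi <- source_sequence$end_s[1] + 1
    t <- t[t >= lo & t <= hi]
  }
  structure(list(ic_times_s = t, source_sequence = source_sequence),
            class = "ic_list")
}

#' @export
print.ic_list <- function(x, ...) {
  cat(sprintf("<ic_list> %d initial contacts\n", length(x$ic_times_s)))
  invisible(x)
}

crop_axis <- function(x, gs, fs, what = "gait sequence", margin_s = 0) {
  n <- length(x)
  i0 <- t_to_idx(gs$start_s[1], fs)
  i1 <- t_to_idx(gs$end_s[1], fs)
  if (i0 < 1L || i1 > n || i0 >= i1)
    stop_bounds(sprintf("%s [%g, %g] outside recording", what,
                        gs$start_s[1], gs$end_s[1]))
  # the 1 s refinement margin: events at the sequence edge need a bracketing
  # zero-crossing on both sides
  i0 <- max(1L, i0 - as.integer(round(margin_s * fs)))
  i1 <- min(n, i1 + as.integer(round(margin_s * fs)))
  list(x = x[i0:i1], t0 = idx_to_t(i0, fs))
}

ic_from_indices <- function(idx, t0, fs, gs) {
  ic_list(t0 + (idx - 1L) / fs, source_sequence = gs)
}

#' Vertical-axis wavelet initial-contact detection
#'
#' Within the gait sequence: detrends the vertical acceleration, low-passes
#' it (FIR, 3.2 Hz), integrates (cumulative trapezoid) and differentiates
#' with a derivative-of-Gaussian wavelet at scale 9 (rescaled with sampling
#' rate). Initial contacts are the positive maxima between consecutive
#' zero-crossings of the transform.
#'
#' @param rec an [imu_recording()].
#' @param gs one-row [gait_sequences()] frame within the recording,
#'   duration >= 1 s.
#' @param n_smooth number of post-wavelet moving-average passes (used by the
#'   impairment-adaptive variant).
#' @return an [ic_list()].
#' @export
detect_icd_a <- function(rec, gs, n_smooth = 0L) {
  fs <- rec$fs_hz
  seg <- crop_axis(rec$acc_v, gs, fs, margin_s = 1)
  if (length(seg$x) < fs) stop_bounds("gait sequence shorter than 1 s")
  x <- detrend_linear(seg$x)
  x <- fir_lowpass(x, 3.2, fs)
  v <- cumtrapz(x, 1 / fs)
  w <- cwt_gauss(v, CWT_IC_SCALE * fs / 100, deriv = 1L)
  for (i in seq_len(n_smooth)) w <- moving_average(w, round(0.15 * fs))
  idx <- peaks_between_zero_crossings(w)
  ic_from_indices(idx, seg$t0, fs, gs)
}

#' Anterior-posterior-axis wavelet initial-contact detection
#'
#' As the vertical-axis detector, but on the AP axis with a zero-phase
#' 2nd-order Butterworth low-pass at 10 Hz, and a wavelet scale estimated
#' from the dominant gait frequency of the pre-processed signal
#' (`scale = fs / (2 pi f_dom)`, the scale whose smoothing bandwidth matches
#' the gait band).
#'
#' @inheritParams detect_icd_a
#' @export
detect_icd_b <- function(rec, gs) {
  fs <- rec$fs_hz
  seg <- crop_axis(rec$acc_ap, gs, fs, margin_s = 1)
  if (length(seg$x) < fs) stop_bounds("gait sequence shorter than 1 s")
  x <- detrend_linear(seg$x)
  x <- butter2_filtfilt(x, 10, fs, "low")
  fdom <- dominant_frequency(x, fs, band = c(0.5, 3))
  if (is.na(fdom)) return(ic_from_indices(integer(0), seg$t0, fs, gs))
  scale <- fs / (2 * pi * fdom)
  v <- cumtrapz(x, 1 / fs)
  w <- cwt_gauss(v, scale, deriv = 1L)
  idx <- peaks_between_zero_crossings(w)
  ic_from_indices(idx, seg$t0, fs, gs)
}

#' Step-to-stride symmetry index
#'
#' Regularity ratio from the unbiased autocorrelation of the detrended
#' vertical acceleration: the autocorrelation at the step lag (first
#' prominent peak) divided by its value at the stride lag (twice the step
#' lag), clipped to [0, 1]. Near 1 for symmetric gait; small when alternate
#' steps differ. Returns NA (undefined) for degenerate input; callers fall
#' back to 1.
#'
#' @inheritParams detect_icd_a
#' @return scalar in [0, 1], or NA.
#' @export
symmetry_index <- function(rec, gs) {
  fs <- rec$fs_hz
  if (gs$end_s[1] - gs$start_s[1] < 3) stop_bounds("sequence shorter than 3 s")
  seg <- crop_axis(rec$acc_v, gs, fs)
  x <- detrend_linear(seg$x)
  if (stats::sd(x) == 0) return(NA_real_)
  fdom <- dominant_frequency(x, fs, band = c(0.5, 3))  # step frequency
  if (is.na(fdom)) return(NA_real_)
  n <- length(x)
  step_lag <- as.integer(round(fs / fdom))
  max_lag <- min(n - 1L, as.integer(ceiling(2.4 * step_lag)))
  if (max_lag < 2L * step_lag) return(NA_real_)
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  ac <- ac * n / (n - seq_along(ac) + 1)   # unbiased estimate
  # snap to the actual autocorrelation peaks near the nominal lags
  snap <- function(lag0) {
    win <- max(1L, round(0.2 * step_lag))
    rng <- max(2L, lag0 - win):min(length(ac) - 1L, lag0 + win)
    max(ac[rng])
  }
  a_step <- snap(step_lag + 1L)
  a_stride <- snap(2L * step_lag + 1L)
  if (a_stride <= 0) return(NA_real_)
  min(max(a_step / a_stride, 0), 1)
}

#' Impairment-adaptive initial-contact detection
#'
#' Dispatches on the symmetry index: above 0.5 the vertical-axis wavelet
#' pipeline is used unchanged; between 0.25 and 0.5 one moving-average pass
#' (0.15 s) is added after the wavelet; below 0.25 two passes are added.
#'
#' @inheritParams detect_icd_a
#' @export
detect_icd_c <- function(rec, gs) {
  si <- tryCatch(symmetry_index(rec, gs), gaitdmo_bounds_error = function(e) NA_real_)
  if (is.na(si)) si <- 1
  n_smooth <- if (si > 0.5) 0L else if (si >= 0.25) 1L else 2L
  detect_icd_a(rec, gs, n_smooth = n_smooth)
}

#' Norm-based zero-crossing initial-contact detection
#'
#' Denoises the acceleration norm with a 0.1 s sliding moving sum, removes
#' the gravity baseline with a differential high-pass (subtracting a 1 s
#' moving average), and takes upward zero-crossings of the result as
#' initial contacts: the instants where the norm rises through its local
#' mean towards the impact peak.
#'
#' @inheritParams detect_icd_a
#' @export
detect_icd_d <- function(rec, gs) {
  fs <- rec$fs_hz
  nrm <- acc_norm(rec)
  seg <- crop_axis(nrm, gs, fs, margin_s = 1)
  x <- moving_sum(seg$x, round(0.1 * fs))
  d <- x - moving_average(x, fs)
  if (all(d == 0)) return(ic_from_indices(integer(0), seg$t0, fs, gs))
  idx <- upward_zero_crossings(d) + 1L
  ic_from_indices(idx, seg$t0, fs, gs)
}

#' Dispatch over the initial-contact detectors
#' @inheritParams detect_icd_a
#' @param algo one of "a", "b", "c", "d".
#' @export
detect_icd <- function(rec, gs, algo = c("a", "b", "c", "d")) {
  switch(match.arg(algo),
         a = detect_icd_a(rec, gs),
         b = detect_icd_b(rec, gs),
         c = detect_icd_c(rec, gs),
         d = detect_icd_d(rec, gs))
}

#' Refine gait-sequence boundaries from detected initial contacts
#'
#' The refined sequence starts one second before the first detected IC
#' (floored at 0) and ends one second after the last (capped at the
#' recording end).
#'
#' @param ics an [ic_list()] (non-empty).
#' @param rec the source [imu_recording()].
#' @return one-row [gait_sequences()] frame.
#' @export
refine_sequence <- function(ics, rec) {
  t <- ics$ic_times_s
  if (!length(t)) gd_stop("gaitdmo_empty_sequence", "no initial contacts")
  gait_sequences(max(0, t[1] - 1), min(rec_duration(rec), t[length(t)] + 1))
}
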