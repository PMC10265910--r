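# Gait-sequence detection from raw lower-back acceleration.
#
# Three detectors: a frequency-domain one working on the vertical and AP
# axes (sine-template convolution in the gait band) and two time-domain ones
# working on the acceleration norm (step-peak grouping with an adaptive
# inter-step threshold, at two peak thresholds).

#' Gait-sequence detector parameters
#'
#' @param win_s analysis window, seconds.
#' @param overlap_s window overlap, seconds (< `win_s`).
#' @param activity_thresh motion threshold on the convolved signal, g.
#' @param peak_thresh_g step-peak threshold on the gravity-removed norm, g
#'   (0.1 for the standard time-domain detector, 0.15 for its conservative
#'   variant).
#' @param band_hz gait band for the frequency-domain detector, Hz.
#' @param lp_cut_hz low-pass cutoff for the norm, Hz.
#' @param max_break_s rests shorter than this merge adjacent sequences,
#'   seconds.
#' @return list of class `gsd_params`.
#' @export
gsd_params <- function(win_s = 3, overlap_s = 1.5, activity_thresh = 0.01,
                       peak_thresh_g = 0.1, band_hz = c(0.5, 3),
                       lp_cut_hz = 3.2, max_break_s = 3) {
  if (overlap_s <= 0 || overlap_s >= win_s)
    stop_data("need 0 < overlap_s < win_s")
  if (peak_thresh_g <= 0) stop_data("peak_thresh_g must be positive")
  if (band_hz[1] >= band_hz[2]) stop_data("band lower edge must be below upper")
  structure(list(win_s = win_s, overlap_s = overlap_s,
                 activity_thresh = activity_thresh,
                 peak_thresh_g = peak_thresh_g, band_hz = band_hz,
                 lp_cut_hz = lp_cut_hz, max_break_s = max_break_s),
            class = "gsd_params")
}

#' Frequency-domain gait-sequence detection
#'
#' Band-passes the vertical and AP axes to the gait band, convolves each
#' with a one-cycle 2 Hz sine template, and flags 3 s windows (hopped by
#' `win_s - overlap_s`) whose template response exceeds the activity
#' threshold and shows repeated gait-band maxima. Contiguous flagged windows
#' are merged; sequences separated by less than `max_break_s` are merged.
#'
#' @param rec an [imu_recording()].
#' @param params a [gsd_params()].
#' @return a [gait_sequences()] frame.
#' @export
detect_gsd_a <- function(rec, params = gsd_params()) {
  fs <- rec$fs_hz
  n <- length(rec$acc_v)
  if (n < params$win_s * fs) {
    gd_warn("gaitdmo_short_recording", "recording shorter than one window")
    return(gait_sequences())
  }
  tmpl_t <- seq(0, 0.5 - 1 / fs, by = 1 / fs)
  tmpl <- sin(2 * pi * 2 * tmpl_t)
  tmpl <- tmpl * 2 / length(tmpl)  # unit gain for a matching 2 Hz sine
  score <- function(x) {
    bp <- fir_bandpass(x, params$band_hz[1], params$band_hz[2], fs)
    conv_same(bp, tmpl)
  }
  cv <- score(rec$acc_v)
  ca <- score(rec$acc_ap)
  hop <- params$win_s - params$overlap_s
  starts <- seq(0, n / fs - params$win_s, by = hop)
  if (!length(starts)) starts <- 0
  wlen <- as.integer(round(params$win_s * fs))
  min_gap <- as.integer(round(fs / params$band_hz[2]))  # shortest step spacing
  flagged <- vapply(starts, function(s0) {
    i0 <- t_to_idx(s0, fs)
    seg <- i0:min(n, i0 + wlen - 1L)
    act <- max(stats::sd(cv[seg]), stats::sd(ca[seg]))
    if (act <= params$activity_thresh) return(FALSE)
    pk <- max(length(find_peaks(cv[seg], height = params$activity_thresh,
                                min_dist = min_gap)),
              length(find_peaks(ca[seg], height = params$activity_thresh,
                                min_dist = min_gap)))
    # a gait window at >= 0.5 Hz steps holds at least 2 cycles
    pk >= 2L
  }, logical(1))
  if (!any(flagged)) return(gait_sequences())
  gs <- union_intervals(starts[flagged],
                        pmin(n / fs, starts[flagged] + params$win_s),
                        gap_s = params$max_break_s)
  # windows are hop-quantized; trim each sequence to where the template
  # response actually exceeds the activity threshold (with hysteresis at
  # one third of the sequence peak, so filter ringing does not pad edges)
  env <- sqrt(pmax(moving_average(pmax(cv, ca)^2, round(0.5 * fs)), 0))
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(nrow(gs))) {
    i0 <- t_to_idx(gs$start_s[i], fs); i1 <- min(n, t_to_idx(gs$end_s[i], fs))
    thr <- max(params$activity_thresh, max(env[i0:i1]) / 3)
    act <- which(env[i0:i1] > thr)
    if (!length(act)) next
    out_s <- c(out_s, idx_to_t(i0 + act[1] - 1L, fs))
    out_e <- c(out_e, idx_to_t(i0 + act[length(act)] - 1L, fs))
  }
  if (!length(out_s)) return(gait_sequences())
  union_intervals(out_s, out_e, gap_s = params$max_break_s)
}

# adaptive inter-step threshold: scale-free grouping based on the running
# median of recent inter-peak intervals, floored at 0.5 s, capped at the
# 3 s bout-break rule
adaptive_break_threshold <- function(intervals) {
  recent <- utils::tail(intervals, 5L)
  if (!length(recent)) return(BOUT_BREAK_S)
  min(max(1.5 * stats::median(recent), 0.5), BOUT_BREAK_S)
}

#' Time-domain gait-sequence detection by step-peak grouping
#'
#' Low-passes the acceleration norm (FIR, `lp_cut_hz`), removes the gravity
#' offset (recording-median norm), detects peaks above `peak_thresh_g`, and
#' groups consecutive peaks into sequences while the inter-peak interval
#' stays under an adaptive step-duration threshold. Sequences need at least
#' 4 step peaks; sequences separated by less than `max_break_s` are merged.
#'
#' @inheritParams detect_gsd_a
#' @export
detect_gsd_peaks <- function(rec, params = gsd_params()) {
  fs <- rec$fs_hz
  n <- length(rec$acc_v)
  if (n < params$win_s * fs) {
    gd_warn("gaitdmo_short_recording", "recording shorter than one window")
    return(gait_sequences())
  }
  nrm <- acc_norm(rec)
  lp <- fir_lowpass(nrm, params$lp_cut_hz, fs)
  lp <- lp - stats::median(lp)
  min_gap <- as.integer(round(STRIDE_MIN_DUR_S / 2 * fs))  # shortest step
  pk <- find_peaks(lp, height = params$peak_thresh_g, min_dist = min_gap)
  if (length(pk) < 4L) return(gait_sequences())
  pt <- idx_to_t(pk, fs)
  groups <- list()
  cur <- pt[1]
  for (i in 2:length(pt)) {
    gap <- pt[i] - pt[i - 1L]
    thr <- adaptive_break_threshold(diff(cur))
    if (gap <= thr) cur <- c(cur, pt[i])
    else { groups <- c(groups, list(cur)); cur <- pt[i] }
  }
  groups <- c(groups, list(cur))
  groups <- Filter(function(g) length(g) >= 4L, groups)
  if (!length(groups)) return(gait_sequences())
  # fixed half-step margin: a data-driven margin would grow when weak peaks
  # drop out and break threshold monotonicity
  margin <- 0.3
  gs <- union_intervals(
    pmax(0, vapply(groups, min, 1) - margin),
    pmin(n / fs, vapply(groups, max, 1) + margin)
  )
  merge_sequences(gs, gap_s = params$max_break_s)
}

#' Dispatch over the three gait-sequence detectors
#'
#' @inheritParams detect_gsd_a
#' @param algo "a" (frequency-domain), "b" (peak grouping, 0.1 g threshold)
#'   or "c" (peak grouping, 0.15 g threshold).
#' @export
detect_gsd <- function(rec, algo = c("a", "b", "c"), params = NULL) {
  algo <- match.arg(algo)
  if (is.null(params))
    params <- gsd_params(peak_thresh_g = if (algo == "c") 0.15 else 0.1)
  if (algo == "a") detect_gsd_a(rec, params) else detect_gsd_peaks(rec, params)
}
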