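# Signal-processing primitives shared by the detectors.
#
# All FIR kernels are symmetric and applied by centred convolution, so they
# are zero-phase by construction. The one IIR filter (2nd-order Butterworth)
# is applied forward-backward. Zero phase matters: initial-contact validation
# works with a 0.25 s half-tolerance, so filters must not shift event times.

#' Centred convolution with reflection padding
#'
#' FFT-based convolution returning a signal of the same length as `x`,
#' aligned so that a symmetric kernel introduces no phase shift. Edges are
#' reflection-padded to suppress boundary transients.
#'
#' @param x numeric signal.
#' @param k numeric kernel (odd length for exact centring).
#' @return numeric vector, `length(x)`.
#' @keywords internal
conv_same <- function(x, k) {
  n <- length(x)
  m <- length(k)
  if (m == 1L) return(x * k)
  pad <- min(n - 1L, m)
  xp <- c(2 * x[1] - x[pad:1 + 1], x, 2 * x[n] - x[n - seq_len(pad)])
  full <- stats::convolve(xp, rev(k), type = "open")
  half <- (m - 1L) %/% 2L
  full[(pad + half + 1L):(pad + half + n)]
}

#' Windowed-sinc FIR low-pass kernel
#'
#' Linear-phase low-pass of order `order` (default `ceiling(fs)` taps + 1),
#' Hamming-windowed, unit DC gain.
#'
#' @param fc cutoff frequency, Hz.
#' @param fs sampling rate, Hz.
#' @param order filter order; the kernel has `order + 1` taps (forced odd).
#' @return numeric kernel.
#' @keywords internal
fir_lowpass_kernel <- function(fc, fs, order = ceiling(fs)) {
  ntaps <- order + 1L
  if (ntaps %% 2L == 0L) ntaps <- ntaps + 1L
  m <- (ntaps - 1L) / 2L
  i <- seq(-m, m)
  h <- 2 * fc / fs * sinc(2 * fc / fs * i)
  w <- 0.54 + 0.46 * cos(pi * i / m)
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Zero-phase FIR low-pass filter
#' @inheritParams fir_lowpass_kernel
#' @param x numeric signal.
#' @keywords internal
fir_lowpass <- function(x, fc, fs, order = ceiling(fs)) {
  conv_same(x, fir_lowpass_kernel(fc, fs, order))
}

#' Zero-phase FIR band-pass filter (difference of two windowed-sinc low-passes)
#' @param x numeric signal.
#' @param f_lo,f_hi band edges, Hz.
#' @param fs sampling rate, Hz.
#' @param order filter order; defaults to 3 * fs for a usable 0.5 Hz edge.
#' @keywords internal
fir_bandpass <- function(x, f_lo, f_hi, fs, order = ceiling(3 * fs)) {
  k <- fir_lowpass_kernel(f_hi, fs, order) - fir_lowpass_kernel(f_lo, fs, order)
  conv_same(x, k)
}

#' Second-order Butterworth coefficients (bilinear transform)
#'
#' @param fc cutoff, Hz; `fs` sampling rate, Hz.
#' @param type "low" or "high".
#' @return list with `b` (length 3) and `a` (length 3, `a[1] == 1`).
#' @keywords internal
butter2_coef <- function(fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(fc > 0, fc < fs / 2)
  if (type == "low") {
    cc <- 1 / tan(pi * fc / fs)
    b0 <- 1 / (1 + sqrt(2) * cc + cc^2)
    b <- c(b0, 2 * b0, b0)
    a <- c(1, 2 * (1 - cc^2) * b0, (1 - sqrt(2) * cc + cc^2) * b0)
  } else {
    cc <- tan(pi * fc / fs)
    b0 <- 1 / (1 + sqrt(2) * cc + cc^2)
    b <- c(b0, -2 * b0, b0)
    a <- c(1, 2 * (cc^2 - 1) * b0, (1 - sqrt(2) * cc + cc^2) * b0)
  }
  list(b = b, a = a)
}

iir_filter <- function(x, b, a) {
  v <- as.numeric(stats::filter(x, b, method = "convolution", sides = 1))
  # warm-up taps the one-sided convolution leaves as NA
  for (i in seq_len(min(length(b) - 1L, length(x)))) {
    idx <- seq_len(i)
    v[i] <- sum(b[idx] * x[i - idx + 1L])
  }
  as.numeric(stats::filter(v, -a[-1], method = "recursive"))
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Reflection-pads, filters forward, reverses, filters again. Magnitude
#' response is squared; phase is zero.
#'
#' @param x numeric signal.
#' @param coef list with `b`, `a` as from [butter2_coef()].
#' @keywords internal
filtfilt2 <- function(x, coef) {
  n <- length(x)
  pad <- min(n - 1L, 3L * 100L)
  xp <- c(2 * x[1] - x[pad:1 + 1], x, 2 * x[n] - x[n - seq_len(pad)])
  y <- iir_filter(xp, coef$b, coef$a)
  y <- rev(iir_filter(rev(y), coef$b, coef$a))
  y[(pad + 1L):(pad + n)]
}

#' Zero-phase 2nd-order Butterworth filter
#' @inheritParams butter2_coef
#' @param x numeric signal.
#' @keywords internal
butter2_filtfilt <- function(x, fc, fs, type = c("low", "high")) {
  filtfilt2(x, butter2_coef(fc, fs, match.arg(type)))
}

#' Remove mean and linear trend
#' @param x numeric signal.
#' @keywords internal
detrend_linear <- function(x) {
  n <- length(x)
  if (n < 3L) return(x - mean(x))
  t <- seq_len(n) - (n + 1) / 2
  x - mean(x) - t * sum(t * (x - mean(x))) / sum(t * t)
}

#' Cumulative trapezoidal integration
#' @param x numeric signal; `dt` sample interval, seconds.
#' @keywords internal
cumtrapz <- function(x, dt) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum((x[-1] + x[-n]) / 2)) * dt
}

#' Single-scale Gaussian-derivative continuous wavelet transform
#'
#' Convolution with an n-th derivative-of-Gaussian kernel at the given scale
#' (in samples). `deriv = 1` uses +g', so the output is the derivative of the
#' Gaussian-smoothed signal (differentiator). `deriv = 2` uses the
#' Mexican-hat orientation -g'', whose output peaks where the smoothed signal
#' peaks (band-pass at the scale frequency, zero phase).
#'
#' @param x numeric signal.
#' @param scale wavelet scale in samples (> 0).
#' @param deriv derivative order, 1 or 2.
#' @return numeric vector, `length(x)`.
#' @keywords internal
cwt_gauss <- function(x, scale, deriv = 1L) {
  stopifnot(scale > 0)
  m <- max(3L, ceiling(5 * scale))
  u <- seq(-m, m) / scale
  k <- switch(as.character(deriv),
    "1" = -u * exp(-u^2 / 2),
    "2" = (1 - u^2) * exp(-u^2 / 2),
    stop("deriv must be 1 or 2")
  )
  conv_same(x, k / sqrt(scale))
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial smoother applied by convolution with the
#' projection weights of the window centre.
#'
#' @param x numeric signal.
#' @param order polynomial order.
#' @param frame window length in samples (forced odd, > order).
#' @keywords internal
savgol_smooth <- function(x, order = 7L, frame = 21L) {
  frame <- as.integer(frame)
  if (frame %% 2L == 0L) frame <- frame + 1L
  if (frame <= order + 1L) frame <- as.integer(order) + 2L + (order %% 2L)
  m <- (frame - 1L) %/% 2L
  A <- outer(seq(-m, m), 0:order, `^`)
  # weights reproducing the fitted value at the window centre
  w <- A %*% solve(crossprod(A), A[m + 1L, ])
  conv_same(x, rev(as.numeric(w)))
}

#' Gaussian smoothing kernel convolution
#' @param x numeric signal; `sd_samples` kernel standard deviation in samples.
#' @keywords internal
gaussian_smooth <- function(x, sd_samples) {
  m <- max(1L, ceiling(4 * sd_samples))
  k <- exp(-0.5 * (seq(-m, m) / sd_samples)^2)
  conv_same(x, k / sum(k))
}

#' Centred moving average / moving sum
#' @param x numeric signal; `width` window length in samples.
#' @keywords internal
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  conv_same(x, rep(1 / width, width))
}

#' @rdname moving_average
#' @keywords internal
moving_sum <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  conv_same(x, rep(1, width))
}

# Running min/max via shifted pmin/pmax: O(n * width) but fully vectorised;
# morphology windows are ~25 samples so this is cheap.
running_extreme <- function(x, width, fun) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  m <- (width - 1L) %/% 2L
  n <- length(x)
  out <- x
  for (s in seq_len(m)) {
    out <- fun(out,
               c(x[-seq_len(s)], rep(x[n], s)),
               c(rep(x[1], s), x[seq_len(n - s)]))
  }
  out
}

#' Grayscale morphological operators on 1-D signals
#'
#' Flat structuring element of `width` samples. `morph_open` removes narrow
#' positive spikes, `morph_close` fills narrow dips.
#'
#' @param x numeric signal; `width` element length in samples.
#' @keywords internal
morph_open <- function(x, width) {
  running_extreme(running_extreme(x, width, pmin), width, pmax)
}

#' @rdname morph_open
#' @keywords internal
morph_close <- function(x, width) {
  running_extreme(running_extreme(x, width, pmax), width, pmin)
}

#' Local maxima above a threshold
#'
#' @param x numeric signal.
#' @param height minimum value for a peak.
#' @param min_dist minimum separation between kept peaks, samples; when two
#'   candidates are closer, the larger wins (ties: earlier).
#' @return integer vector of peak indices, increasing.
#' @keywords internal
find_peaks <- function(x, height = -Inf, min_dist = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  idx <- idx[x[idx] > height]
  if (length(idx) < 2L || min_dist <= 1L) return(idx)
  ord <- idx[order(-x[idx], idx)]
  keep <- logical(n)
  blocked <- logical(n)
  for (i in ord) {
    if (!blocked[i]) {
      keep[i] <- TRUE
      lo <- max(1L, i - min_dist + 1L)
      hi <- min(n, i + min_dist - 1L)
      blocked[lo:hi] <- TRUE
    }
  }
  which(keep)
}

#' Positive maxima between consecutive zero-crossings
#'
#' Splits the signal at sign changes and returns, for every run where the
#' signal is positive, the index of its maximum.
#'
#' @param x numeric signal.
#' @return integer vector of indices, increasing.
#' @keywords internal
peaks_between_zero_crossings <- function(x) {
  sgn <- sign(x)
  sgn[sgn == 0] <- 1
  runs <- rle(as.integer(sgn))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  pos <- which(runs$values > 0)
  # drop leading/trailing half-runs: a maximum needs a crossing on both sides
  pos <- pos[pos > 1L & pos < length(runs$values)]
  if (!length(pos)) return(integer(0))
  vapply(pos, function(r) {
    seg <- starts[r]:ends[r]
    seg[which.max(x[seg])]
  }, integer(1))
}

#' Upward zero-crossings
#' @param x numeric signal.
#' @return integer indices i where `x[i] < 0` and `x[i+1] >= 0`.
#' @keywords internal
upward_zero_crossings <- function(x) {
  n <- length(x)
  if (n < 2L) return(integer(0))
  which(x[-n] < 0 & x[-1] >= 0)
}

#' Dominant frequency by periodogram maximum within a band
#' @param x numeric signal; `fs` rate Hz; `band` c(lo, hi) Hz.
#' @return frequency in Hz, or NA if degenerate.
#' @keywords internal
dominant_frequency <- function(x, fs, band = c(0.5, 3)) {
  x <- x - mean(x)
  if (stats::sd(x) == 0 || length(x) < 8L) return(NA_real_)
  nfft <- 2^ceiling(log2(max(256L, length(x))))
  X <- stats::fft(c(x * 0.5 * (1 - cos(2 * pi * seq_along(x) / (length(x) + 1))),
                    rep(0, nfft - length(x))))
  f <- (seq_len(nfft %/% 2) - 1) * fs / nfft
  p <- Mod(X[seq_len(nfft %/% 2)])^2
  sel <- which(f >= band[1] & f <= band[2])
  if (!length(sel)) return(NA_real_)
  f[sel[which.max(p[sel])]]
}
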