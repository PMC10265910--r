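# Synthetic lower-back gait signals with exact ground truth.
#
# Forward model: during a bout the centre of mass follows a sinusoidal
# vertical trajectory at step frequency whose peak-to-peak excursion h is
# solved from the inverted-pendulum relation for the requested stride
# length (stride = k_gen * sqrt(2 l h - h^2)); vertical acceleration is the
# exact second derivative plus a zero-mean impact transient at every
# initial contact. The CoM is lowest at initial contact, so the vertical
# acceleration peaks at each IC - the timing feature every detector keys
# on. AP acceleration oscillates at step frequency (braking peak at IC) and
# ML sway at stride frequency. Asymmetry modulates all amplitudes with a
# stride-frequency envelope so alternate steps keep the requested amplitude
# ratio while the mean is preserved. Rest is gravity plus noise.

IMPACT_PEAK_G <- 0.3
IMPACT_SIGMA_S <- 0.005   # Ricker width; 30 ms support, zero mean & moment

#' Simulation protocol
#'
#' @param bouts data frame with columns `start_s`, `n_strides` (gait
#'   cycles, >= 3), `cadence_spm`, `stride_length_m`, `asymmetry` (ratio of
#'   alternate step amplitudes in (0, 1]). Bouts must be separated by >= 3 s
#'   of rest.
#' @param noise_sd_g additive white accelerometer noise SD, g.
#' @param seed RNG seed (part of the protocol: same seed, same recording).
#' @param leg_length_m subject leg length, metres.
#' @param k_gen generative pendulum constant; default 4.739, the standard
#'   pendulum calibration, so the matching stride-length estimator is the
#'   exact inverse of the generator.
#' @param trail_s rest appended before the first and after the last bout,
#'   seconds.
#' @return list of class `sim_protocol`.
#' @export
sim_protocol <- function(bouts, noise_sd_g = 0, seed = 1L,
                         leg_length_m = 0.9, k_gen = 4.739, trail_s = 8) {
  bouts <- as.data.frame(bouts)
  need <- c("start_s", "n_strides", "cadence_spm", "stride_length_m")
  if (!all(need %in% names(bouts)))
    stop_protocol(paste("bouts need columns:", paste(need, collapse = ", ")))
  if (is.null(bouts$asymmetry)) bouts$asymmetry <- 1
  if (any(bouts$n_strides < 3)) stop_protocol("bouts need n_strides >= 3")
  if (any(bouts$asymmetry <= 0 | bouts$asymmetry > 1))
    stop_protocol("asymmetry must be in (0, 1]")
  if (any(bouts$stride_length_m < STRIDE_MIN_LEN_M))
    stop_protocol("stride length below the 0.15 m validity floor")
  step_d <- 60 / bouts$cadence_spm
  stride_d <- 2 * step_d
  if (any(stride_d < STRIDE_MIN_DUR_S | stride_d > STRIDE_MAX_DUR_S))
    stop_protocol("stride duration outside the 0.2-3 s validity range")
  if (any(bouts$stride_length_m / k_gen >= leg_length_m))
    stop_protocol("infeasible stride length for the given leg length (h >= 2l)")
  ends <- bouts$start_s + 2 * bouts$n_strides * step_d
  o <- order(bouts$start_s)
  bouts <- bouts[o, , drop = FALSE]; ends <- ends[o]
  if (nrow(bouts) > 1L &&
      any(bouts$start_s[-1] - ends[-length(ends)] < BOUT_BREAK_S))
    stop_protocol("bouts must be separated by rests of at least 3 s")
  bouts$end_s <- ends
  bouts$speed_mps <- bouts$stride_length_m * bouts$cadence_spm / 120
  structure(list(bouts = bouts, noise_sd_g = noise_sd_g, seed = as.integer(seed),
                 leg_length_m = leg_length_m, k_gen = k_gen, trail_s = trail_s),
            class = "sim_protocol")
}

# peak-to-peak CoM excursion from the pendulum relation
solve_h <- function(stride_length_m, leg_length_m, k_gen) {
  leg_length_m - sqrt(leg_length_m^2 - (stride_length_m / k_gen)^2)
}

ricker_pulse <- function(t_rel, sigma) {
  u <- t_rel / sigma
  p <- (1 - u^2) * exp(-u^2 / 2)
  # the continuous Ricker is zero-mean with zero first moment, but at
  # 100 Hz the 30 ms support holds only ~3 samples; project out the
  # constant and linear components so the *sampled* pulse carries no net
  # impulse either
  if (length(p) > 2L) {
    X <- cbind(1, t_rel)
    p <- p - X %*% solve(crossprod(X), crossprod(X, p))
  } else if (length(p) > 0L) {
    p <- p - mean(p)
  }
  as.numeric(p)
}

#' Generate a synthetic recording with ground truth
#'
#' @param protocol a [sim_protocol()].
#' @param fs_hz sampling rate, Hz.
#' @return list with `recording` (an [imu_recording()]), `truth` (a
#'   `walking_bouts` list with exact IC times, per-stride
#'   durations/lengths/feet and per-bout speed) and `protocol`.
#' @export
generate_recording <- function(protocol, fs_hz = 100) {
  p <- protocol
  total_s <- max(p$bouts$end_s) + p$trail_s
  n <- as.integer(round(total_s * fs_hz))
  t <- (seq_len(n) - 1L) / fs_hz
  acc_v <- rep(1, n); acc_ap <- rep(0, n); acc_ml <- rep(0, n)
  truth <- list()
  for (i in seq_len(nrow(p$bouts))) {
    b <- p$bouts[i, ]
    step_d <- 60 / b$cadence_spm
    f_step <- 1 / step_d
    h <- solve_h(b$stride_length_m, p$leg_length_m, p$k_gen)
    amp_v <- (h / 2) * (2 * pi * f_step)^2 / STANDARD_GRAVITY  # g units
    n_ic <- 2L * b$n_strides + 1L
    ic_t <- b$start_s + (seq_len(n_ic) - 1L) * step_d
    # stride-frequency asymmetry envelope, mean 1, alternate-step ratio asym
    m <- (1 - b$asymmetry) / (1 + b$asymmetry)
    # active window with a short cosine taper outside the bout
    taper <- 0.3 * step_d
    lo <- b$start_s - taper; hi <- b$end_s + taper
    sel <- which(t >= lo & t <= hi)
    tt <- t[sel]
    ramp <- pmin(1, pmin((tt - lo) / taper, (hi - tt) / taper))
    env <- (1 + m * cos(2 * pi * f_step / 2 * (tt - b$start_s))) * ramp
    ph <- 2 * pi * f_step * (tt - b$start_s)
    acc_v[sel] <- acc_v[sel] + amp_v * cos(ph) * env
    amp_ap <- 0.6 * amp_v + 0.02
    acc_ap[sel] <- acc_ap[sel] + amp_ap * cos(ph) * env
    acc_ml[sel] <- acc_ml[sel] + 0.02 * sin(pi * f_step * (tt - b$start_s)) * ramp
    # zero-mean impact transient at each IC, scaled by the local envelope
    for (j in seq_len(n_ic)) {
      w <- which(abs(t - ic_t[j]) <= 3 * IMPACT_SIGMA_S)
      if (length(w)) {
        e_ic <- 1 + m * cos(2 * pi * f_step / 2 * (ic_t[j] - b$start_s))
        acc_v[w] <- acc_v[w] +
          IMPACT_PEAK_G * e_ic * ricker_pulse(t[w] - ic_t[j], IMPACT_SIGMA_S)
      }
    }
    ns <- n_ic - 2L
    st <- strides(start_s = ic_t[seq_len(ns)], end_s = ic_t[seq_len(ns) + 2L],
                  length_m = rep(b$stride_length_m, ns),
                  foot = rep(c("left", "right"), length.out = ns))
    truth[[i]] <- walking_bout(ic_t[1], ic_t[n_ic], st,
                               mean_speed_mps = b$speed_mps,
                               ic_times_s = ic_t)
  }
  if (p$noise_sd_g > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
    set.seed(p$seed)
    acc_v <- acc_v + stats::rnorm(n, 0, p$noise_sd_g)
    acc_ap <- acc_ap + stats::rnorm(n, 0, p$noise_sd_g)
    acc_ml <- acc_ml + stats::rnorm(n, 0, p$noise_sd_g)
  }
  list(recording = imu_recording(acc_v, acc_ap, acc_ml, fs_hz = fs_hz),
       truth = structure(truth, class = "walking_bouts"),
       protocol = p)
}

#' Standard deterministic fixture suite
#'
#' Factorial grid over cadence (60-140 steps/min), stride length (0.45 m
#' "slow" and 1.2 m "fast", giving walking speeds 0.225-1.4 m/s), nominal
#' bout duration (5-120 s), asymmetry (1.0, 0.5) and noise (0, 0.02,
#' 0.05 g). One bout per recording, 8 s rest margins. Slow fixtures below
#' 0.5 m/s are present by construction.
#'
#' @param seed base seed; each fixture derives its own.
#' @param durations_s,noise_levels_g optional subsetting of the grid (used
#'   to scale test runtime; defaults are the full grid).
#' @return list of `(recording, truth, protocol, meta)` entries; `meta`
#'   holds cadence, speed, nominal duration, asymmetry, noise.
#' @export
standard_fixture_suite <- function(seed = 1L,
                                   durations_s = c(5, 10, 30, 60, 120),
                                   noise_levels_g = c(0, 0.02, 0.05)) {
  grid <- expand.grid(cadence = c(60, 80, 100, 120, 140),
                      stride = c(0.45, 1.2),
                      duration = durations_s,
                      asymmetry = c(1.0, 0.5),
                      noise = noise_levels_g,
                      KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    n_strides <- max(3L, as.integer(round(g$duration * g$cadence / 120)))
    prot <- sim_protocol(
      data.frame(start_s = 8, n_strides = n_strides, cadence_spm = g$cadence,
                 stride_length_m = g$stride, asymmetry = g$asymmetry),
      noise_sd_g = g$noise,
      seed = (as.integer(seed) * 1009L + i) %% 2147483647L
    )
    out <- generate_recording(prot)
    out$meta <- list(cadence_spm = g$cadence,
                     speed_mps = g$stride * g$cadence / 120,
                     duration_s = g$duration, asymmetry = g$asymmetry,
                     noise_sd_g = g$noise)
    out
  })
}
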