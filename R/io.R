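# Data model: recordings, gait sequences, strides, walking bouts, subjects.
# On-disk formats: CSV + flat key:value sidecar for recordings, JSON for
# reference annotations.

STANDARD_GRAVITY <- 9.80665

# Reference-side stride validity (also used by the simulator):
STRIDE_MIN_DUR_S <- 0.2
STRIDE_MAX_DUR_S <- 3
STRIDE_MIN_LEN_M <- 0.15
BOUT_BREAK_S <- 3

#' Triaxial lower-back acceleration recording
#'
#' Container for a vertical / anterior-posterior / medio-lateral acceleration
#' stream in g units. The vertical axis is positive upward and includes the
#' +1 g gravity component; AP is positive forward.
#'
#' @param acc_v,acc_ap,acc_ml numeric vectors of equal length, acceleration
#'   in g.
#' @param fs_hz sampling rate, Hz (nominally 100).
#' @param start_time_s recording-time offset of sample 1, seconds.
#' @return object of class `imu_recording`.
#' @export
imu_recording <- function(acc_v, acc_ap, acc_ml, fs_hz = 100, start_time_s = 0) {
  n <- length(acc_v)
  if (n < 1L || length(acc_ap) != n || length(acc_ml) != n)
    stop_data("axis series must have identical length >= 1")
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0)
    stop_data("fs_hz must be a positive scalar")
  bad <- which(!is.finite(acc_v) | !is.finite(acc_ap) | !is.finite(acc_ml))
  if (length(bad))
    stop_data(sprintf("non-finite samples at indices: %s",
                      paste(utils::head(bad, 10L), collapse = ", ")),
              indices = bad)
  structure(
    list(acc_v = as.numeric(acc_v), acc_ap = as.numeric(acc_ap),
         acc_ml = as.numeric(acc_ml), fs_hz = as.numeric(fs_hz),
         start_time_s = as.numeric(start_time_s)),
    class = "imu_recording"
  )
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %d samples @ %g Hz (%.1f s)\n",
              length(x$acc_v), x$fs_hz, rec_duration(x)))
  invisible(x)
}

#' Number of samples / duration of a recording
#' @param rec an [imu_recording()].
#' @export
rec_duration <- function(rec) length(rec$acc_v) / rec$fs_hz

#' Euclidean norm of the three acceleration axes
#' @param rec an [imu_recording()].
#' @return numeric vector in g; near 1 at rest.
#' @export
acc_norm <- function(rec) sqrt(rec$acc_v^2 + rec$acc_ap^2 + rec$acc_ml^2)

# convert times to 0-based sample indices and back (1-based in R)
t_to_idx <- function(t_s, fs) as.integer(round(t_s * fs)) + 1L
idx_to_t <- function(idx, fs) (idx - 1L) / fs

#' Gait sequence list
#'
#' Intervals of detected or annotated gait as a data frame with columns
#' `start_s` and `end_s`, validated sorted and non-overlapping.
#'
#' @param start_s,end_s numeric vectors, seconds relative to recording start.
#' @return data frame of class `gait_sequences`.
#' @export
gait_sequences <- function(start_s = numeric(0), end_s = numeric(0)) {
  if (length(start_s) != length(end_s))
    stop_data("start_s and end_s must have equal length")
  if (length(start_s)) {
    if (any(start_s < 0) || any(end_s <= start_s))
      stop_data("gait sequences need 0 <= start_s < end_s")
    o <- order(start_s)
    start_s <- start_s[o]; end_s <- end_s[o]
    if (any(start_s[-1] < end_s[-length(end_s)]))
      stop_data("gait sequences overlap")
  }
  structure(data.frame(start_s = as.numeric(start_s),
                       end_s = as.numeric(end_s)),
            class = c("gait_sequences", "data.frame"))
}

# union of possibly overlapping intervals, merging gaps below gap_s
union_intervals <- function(start_s, end_s, gap_s = 0) {
  if (!length(start_s)) return(gait_sequences())
  o <- order(start_s)
  st <- start_s[o]; en <- end_s[o]
  ks <- st[1]; ke <- en[1]; out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(st)[-1]) {
    if (st[i] - ke < gap_s) {
      ke <- max(ke, en[i])
    } else {
      out_s <- c(out_s, ks); out_e <- c(out_e, ke)
      ks <- st[i]; ke <- en[i]
    }
  }
  gait_sequences(c(out_s, ks), c(out_e, ke))
}

# merge sequences separated by less than gap_s, keep sorted/non-overlapping
merge_sequences <- function(gs, gap_s = 0) {
  if (nrow(gs) < 2L) return(gs)
  st <- gs$start_s; en <- gs$end_s
  ks <- st[1]; ke <- en[1]; out_s <- numeric(0); out_e <- numeric(0)
  for (i in 2:length(st)) {
    if (st[i] - ke < gap_s) {
      ke <- max(ke, en[i])
    } else {
      out_s <- c(out_s, ks); out_e <- c(out_e, ke)
      ks <- st[i]; ke <- en[i]
    }
  }
  gait_sequences(c(out_s, ks), c(out_e, ke))
}

#' Stride table
#'
#' @param start_s,end_s stride boundary times (same-foot initial contacts),
#'   seconds.
#' @param length_m stride length in metres (NA allowed for device strides).
#' @param foot "left", "right" or "unknown".
#' @return data frame of class `stride_table`.
#' @export
strides <- function(start_s = numeric(0), end_s = numeric(0),
                    length_m = rep(NA_real_, length(start_s)),
                    foot = rep("unknown", length(start_s))) {
  if (length(start_s) && any(end_s <= start_s))
    stop_data("stride duration must be positive")
  foot <- match.arg(foot, c("left", "right", "unknown"), several.ok = TRUE)
  structure(data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                       length_m = as.numeric(length_m),
                       foot = as.character(foot)),
            class = c("stride_table", "data.frame"))
}

stride_valid <- function(s) {
  dur <- s$end_s - s$start_s
  dur >= STRIDE_MIN_DUR_S & dur <= STRIDE_MAX_DUR_S &
    (is.na(s$length_m) | s$length_m >= STRIDE_MIN_LEN_M)
}

#' Walking bout
#'
#' A reference-defined walking interval: at least two strides per foot when
#' foot labels are present (otherwise at least four strides), inter-stride
#' gaps under 3 s.
#'
#' @param start_s,end_s bout boundaries, seconds (first/last initial contact).
#' @param strides a [strides()] table ordered in time.
#' @param mean_speed_mps reference mean walking speed, m/s (NA allowed).
#' @param ic_times_s optional reference initial-contact times within the bout.
#' @return object of class `walking_bout`.
#' @export
walking_bout <- function(start_s, end_s, strides, mean_speed_mps = NA_real_,
                         ic_times_s = NULL) {
  if (end_s <= start_s) stop_data("bout end must exceed start")
  structure(list(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                 strides = strides, mean_speed_mps = as.numeric(mean_speed_mps),
                 ic_times_s = if (is.null(ic_times_s)) NULL else
                   as.numeric(ic_times_s)),
            class = "walking_bout")
}

bout_n_strides <- function(b) nrow(b$strides)

bout_meets_minimum <- function(b) {
  s <- b$strides
  if (nrow(s) == 0L) return(FALSE)
  if (all(s$foot %in% c("left", "right")))
    sum(s$foot == "left") >= 2L && sum(s$foot == "right") >= 2L
  else
    nrow(s) >= 4L
}

#' Subject anthropometrics
#' @param leg_length_m,foot_length_m metres, > 0.
#' @param cohort cohort label (HA, PD, MS, COPD, CHF, PFF).
#' @export
subject_info <- function(leg_length_m = 0.9, foot_length_m = 0.25,
                         cohort = c("HA", "PD", "MS", "COPD", "CHF", "PFF")) {
  if (leg_length_m <= 0 || foot_length_m <= 0)
    stop_data("leg and foot lengths must be positive")
  structure(list(leg_length_m = leg_length_m, foot_length_m = foot_length_m,
                 cohort = match.arg(cohort)),
            class = "subject_info")
}

# ---- recording reader/writer --------------------------------------------

parse_flat_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop_format(sprintf("cannot parse config line: '%s'",
                                    lines[bad][1]))
  out <- lapply(kv, function(m) {
    v <- trimws(m[3])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- vapply(kv, `[`, "", 2L)
  out
}

#' Load a recording from CSV (+ optional sidecar config)
#'
#' Expects a header `time_s,acc_v,acc_ap,acc_ml` (aliases `acc_is`/`acc_pa`
#' accepted). The config, given as a list or as a flat `key: value` sidecar
#' file, may declare `units` (`g` or `ms2`), `fs_hz` (otherwise inferred from
#' `time_s`), and axis sign flips `flip_v`/`flip_ap`/`flip_ml` (0/1), since
#' device mounting is not standardized.
#'
#' @param path CSV file path.
#' @param config list of options, or path to a sidecar config file, or NULL.
#' @return an [imu_recording()].
#' @export
load_recording <- function(path, config = NULL) {
  if (!file.exists(path)) stop_format(sprintf("no such file: %s", path))
  if (is.character(config)) config <- parse_flat_config(config)
  if (is.null(config)) config <- list()
  df <- utils::read.csv(path, check.names = FALSE)
  names(df)[names(df) == "acc_is"] <- "acc_v"
  names(df)[names(df) == "acc_pa"] <- "acc_ap"
  for (col in c("acc_v", "acc_ap", "acc_ml")) {
    if (!col %in% names(df))
      stop_format(sprintf("missing required column '%s'", col), column = col)
  }
  fs <- config$fs_hz
  if (is.null(fs)) {
    if (!"time_s" %in% names(df))
      stop_format("missing required column 'time_s' (or provide fs_hz)")
    if (nrow(df) < 2L) stop_format("cannot infer sampling rate from one row")
    fs <- 1 / stats::median(diff(df$time_s))
  }
  units <- if (is.null(config$units)) "g" else config$units
  scl <- switch(units, g = 1, ms2 = 1 / STANDARD_GRAVITY,
                stop_format(sprintf("unknown units '%s'", units)))
  sgn <- function(flag) if (isTRUE(flag == 1)) -1 else 1
  start <- if ("time_s" %in% names(df)) df$time_s[1] else 0
  imu_recording(df$acc_v * scl * sgn(config$flip_v),
                df$acc_ap * scl * sgn(config$flip_ap),
                df$acc_ml * scl * sgn(config$flip_ml),
                fs_hz = fs, start_time_s = start)
}

#' Write a recording to CSV
#' @param rec an [imu_recording()]; `path` output CSV.
#' @export
write_recording <- function(rec, path) {
  t <- rec$start_time_s + (seq_along(rec$acc_v) - 1L) / rec$fs_hz
  utils::write.csv(data.frame(time_s = t, acc_v = rec$acc_v,
                              acc_ap = rec$acc_ap, acc_ml = rec$acc_ml),
                   path, row.names = FALSE)
  invisible(path)
}

# ---- reference reader/writer --------------------------------------------

bout_from_list <- function(bl) {
  ss <- bl$strides
  st <- strides(
    start_s = vapply(ss, function(s) as.numeric(s$start_s), 1),
    end_s = vapply(ss, function(s) as.numeric(s$end_s), 1),
    length_m = vapply(ss, function(s)
      if (is.null(s$length_m)) NA_real_ else as.numeric(s$length_m), 1),
    foot = vapply(ss, function(s)
      if (is.null(s$foot)) "unknown" else as.character(s$foot), "")
  )
  walking_bout(bl$start_s, bl$end_s, st,
               mean_speed_mps = if (is.null(bl$mean_speed_mps)) NA_real_
                                else bl$mean_speed_mps,
               ic_times_s = if (is.null(bl$ic_times_s)) NULL
                            else unlist(bl$ic_times_s))
}

#' Load reference walking bouts from JSON
#'
#' The file holds `{"bouts": [{start_s, end_s, mean_speed_mps, ic_times_s,
#' strides: [{start_s, end_s, length_m, foot}]}]}`. Strides violating the
#' validity rules (duration 0.2-3 s, length >= 0.15 m) are dropped with a
#' warning; bouts left under the stride minimum are dropped; overlapping
#' bouts are an error.
#'
#' @param path JSON file path.
#' @return list of [walking_bout()] objects, class `walking_bouts`.
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("no such file: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$bouts)) stop_format("reference JSON must contain 'bouts'")
  bouts <- lapply(raw$bouts, bout_from_list)
  validate_bouts(bouts)
}

#' Validate a walking-bout list against the bout/stride rules
#' @param bouts list of [walking_bout()] objects.
#' @return validated `walking_bouts` list.
#' @export
validate_bouts <- function(bouts) {
  cleaned <- list()
  for (b in bouts) {
    ok <- stride_valid(b$strides)
    if (any(!ok)) {
      gd_warn("gaitdmo_stride_dropped",
              sprintf("dropped %d stride(s) violating validity rules in bout [%g, %g]",
                      sum(!ok), b$start_s, b$end_s))
      b$strides <- b$strides[ok, , drop = FALSE]
    }
    if (bout_meets_minimum(b)) cleaned <- c(cleaned, list(b))
    else gd_warn("gaitdmo_bout_dropped",
                 sprintf("dropped bout [%g, %g]: below stride minimum",
                         b$start_s, b$end_s))
  }
  if (length(cleaned) > 1L) {
    o <- order(vapply(cleaned, `[[`, 1, "start_s"))
    cleaned <- cleaned[o]
    st <- vapply(cleaned, `[[`, 1, "start_s")
    en <- vapply(cleaned, `[[`, 1, "end_s")
    if (any(st[-1] < en[-length(en)])) stop_data("walking bouts overlap")
  }
  structure(cleaned, class = "walking_bouts")
}

#' Write reference walking bouts to JSON
#' @param bouts a `walking_bouts` list; `path` output file.
#' @export
write_reference <- function(bouts, path) {
  enc <- list(bouts = lapply(bouts, function(b) {
    s <- b$strides
    list(start_s = b$start_s, end_s = b$end_s,
         mean_speed_mps = b$mean_speed_mps,
         ic_times_s = if (is.null(b$ic_times_s)) NULL else b$ic_times_s,
         strides = lapply(seq_len(nrow(s)), function(i)
           list(start_s = s$start_s[i], end_s = s$end_s[i],
                length_m = s$length_m[i], foot = s$foot[i])))
  }))
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Convert walking bouts to plain gait sequences
#' @param bouts a `walking_bouts` list.
#' @return a [gait_sequences()] frame of the bout intervals.
#' @export
bouts_to_sequences <- function(bouts) {
  gait_sequences(vapply(bouts, `[[`, 1, "start_s"),
                 vapply(bouts, `[[`, 1, "end_s"))
}
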