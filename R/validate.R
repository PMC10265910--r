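# Technical-validation framework: windowed gait/non-gait classification,
# tolerance-based initial-contact matching, the four confusion measures,
# Bland-Altman / ICC(2,1) agreement, and binned error-versus-covariate
# exponential fits.

#' Confusion counts
#'
#' @param tp,tn,fp,fn non-negative event counts; `tn` may be NA where true
#'   negatives are not defined (initial-contact matching).
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp = 0, tn = NA_real_, fp = 0, fn = 0) {
  vals <- c(tp, fp, fn)
  if (any(vals < 0, na.rm = TRUE) || (!is.na(tn) && tn < 0))
    stop_data("counts must be non-negative")
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_counts")
}

# overlap of [a0,a1] windows with a set of intervals, vectorised:
# returns, for window k = 1..nwin of width w starting at (k-1)*w, the
# seconds of overlap with the interval union
window_overlap <- function(start_s, end_s, nwin, w) {
  cov <- numeric(nwin)
  for (j in seq_along(start_s)) {
    a <- start_s[j]; b <- end_s[j]
    k0 <- max(1L, floor(a / w) + 1L)
    k1 <- min(nwin, ceiling(b / w))
    if (k0 > k1) next
    ks <- k0:k1
    lo <- (ks - 1L) * w
    cov[ks] <- cov[ks] + pmax(0, pmin(b, lo + w) - pmax(a, lo))
  }
  cov
}

#' Windowed gait/non-gait classification
#'
#' Tiles `[0, total_duration_s)` into `window_s` windows and labels each
#' window gait or non-gait for the device and the reference by majority
#' overlap (more than half the window inside a gait interval). TP = both
#' gait, TN = both non-gait, FP = device only, FN = reference only.
#'
#' @param detected a [gait_sequences()] frame (device side).
#' @param reference a `walking_bouts` list or [gait_sequences()] frame.
#' @param total_duration_s recording duration, seconds.
#' @param window_s window width, seconds (default 0.1).
#' @return a [confusion_counts()]; tp+tn+fp+fn equals the window count.
#' @export
classify_gsd_windows <- function(detected, reference, total_duration_s,
                                 window_s = 0.1) {
  if (inherits(reference, "walking_bouts"))
    reference <- bouts_to_sequences(reference)
  nwin <- floor(total_duration_s / window_s + 1e-9)
  dev <- window_overlap(detected$start_s, detected$end_s, nwin, window_s) >
    window_s / 2
  ref <- window_overlap(reference$start_s, reference$end_s, nwin, window_s) >
    window_s / 2
  confusion_counts(tp = sum(dev & ref), tn = sum(!dev & !ref),
                   fp = sum(dev & !ref), fn = sum(!dev & ref))
}

#' Tolerance-window initial-contact matching
#'
#' For each reference IC (in time order), detected events within half the
#' tolerance window on each side are candidates; the nearest unused one
#' becomes a true positive (ties to the earlier detected event). Unmatched
#' reference events are false negatives, unmatched detected events false
#' positives; true negatives are not defined. Absolute timing errors are
#' recorded per true positive; relative errors divide them by the mean
#' reference step duration.
#'
#' @param detected,reference [ic_list()] objects (or numeric time vectors).
#' @param tol_s total tolerance window width centred on the reference event,
#'   seconds (default 0.5, i.e. +/- 0.25 s).
#' @return list with `counts` (a [confusion_counts()]), `abs_errors_s`, and
#'   `rel_errors` (fraction of the mean reference step duration).
#' @export
match_ics <- function(detected, reference, tol_s = 0.5) {
  det <- if (inherits(detected, "ic_list")) detected$ic_times_s else
    sort(as.numeric(detected))
  ref <- if (inherits(reference, "ic_list")) reference$ic_times_s else
    sort(as.numeric(reference))
  half <- tol_s / 2
  used <- logical(length(det))
  errs <- numeric(0)
  tp <- 0L
  for (r in ref) {
    d <- abs(det - r)
    cand <- which(d <= half & !used)
    if (length(cand)) {
      best <- cand[order(d[cand], det[cand])][1]  # nearest; tie -> earlier
      used[best] <- TRUE
      tp <- tp + 1L
      errs <- c(errs, d[best])
    }
  }
  counts <- confusion_counts(tp = tp, tn = NA_real_,
                             fp = sum(!used), fn = length(ref) - tp)
  mean_step <- if (length(ref) > 1L) mean(diff(ref)) else NA_real_
  list(counts = counts, abs_errors_s = errs, rel_errors = errs / mean_step)
}

#' Accuracy, sensitivity, specificity and positive predictive value
#'
#' Undefined measures (zero denominator, or NA true negatives) are reported
#' as NA, not 0.
#'
#' @param c a [confusion_counts()].
#' @return named list with `accuracy`, `sensitivity`, `specificity`, `ppv`.
#' @export
confusion_measures <- function(c) {
  safe <- function(num, den) if (is.na(den) || den == 0) NA_real_ else num / den
  list(
    accuracy = safe(c$tp + c$tn, c$tp + c$tn + c$fp + c$fn),
    sensitivity = safe(c$tp, c$tp + c$fn),
    specificity = safe(c$tn, c$tn + c$fp),
    ppv = safe(c$tp, c$tp + c$fp)
  )
}

#' Two-way random-effects single-measure intraclass correlation, ICC(2,1)
#'
#' Absolute-agreement ICC from the two-way ANOVA mean squares
#' (subjects x raters), with the standard F-based confidence interval.
#'
#' @param x matrix with one row per subject and one column per rater, or two
#'   equal-length vectors via `y`.
#' @param y optional second rater vector.
#' @param conf confidence level (default 0.95).
#' @return list with `icc`, `lower`, `upper`.
#' @export
icc21 <- function(x, y = NULL, conf = 0.95) {
  m <- if (is.null(y)) as.matrix(x) else cbind(as.numeric(x), as.numeric(y))
  n <- nrow(m); k <- ncol(m)
  if (n < 3L) stop_data("ICC needs at least 3 subjects")
  gm <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sst <- sum((m - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf
  # McGraw & Wong F-based interval for ICC(A,1)
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  list(icc = icc, lower = lower, upper = upper)
}

#' Agreement statistics between device and reference outcomes
#'
#' Bland-Altman bias and 95% limits of agreement, mean absolute error,
#' per-bout relative error (mean and t-based 95% CI) and ICC(2,1) with CI.
#' Pairs with a zero reference value are excluded from the relative error
#' with a warning.
#'
#' @param device_values,reference_values matched numeric vectors,
#'   length >= 3.
#' @param conf confidence level.
#' @return object of class `agreement_stats`.
#' @export
agreement_stats <- function(device_values, reference_values, conf = 0.95) {
  d <- as.numeric(device_values); r <- as.numeric(reference_values)
  if (length(d) != length(r)) stop_data("value vectors must be matched")
  if (length(d) < 3L) stop_data("need at least 3 pairs")
  diffs <- d - r
  bias <- mean(diffs)
  sdd <- stats::sd(diffs)
  nz <- r != 0
  if (any(!nz))
    gd_warn("gaitdmo_zero_reference",
            sprintf("%d pair(s) with zero reference excluded from relative error",
                    sum(!nz)))
  rel <- (d[nz] - r[nz]) / r[nz] * 100
  tq <- stats::qt(1 - (1 - conf) / 2, df = max(1L, length(rel) - 1L))
  rel_ci <- mean(rel) + c(-1, 1) * tq * stats::sd(rel) / sqrt(length(rel))
  icc <- icc21(d, r, conf = conf)
  structure(list(
    bias = bias,
    loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
    abs_error_mean = mean(abs(diffs)),
    rel_error_pct = mean(rel), rel_error_ci = rel_ci,
    icc = icc$icc, icc_ci = c(icc$lower, icc$upper),
    n = length(d)
  ), class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "<agreement_stats> n=%d bias=%.3g LoA=[%.3g, %.3g] |err|=%.3g rel=%.3g%% ICC(2,1)=%.3f\n",
    x$n, x$bias, x$loa_low, x$loa_high, x$abs_error_mean, x$rel_error_pct,
    x$icc))
  invisible(x)
}

#' Binned median error curve with weighted exponential fit
#'
#' Bins per-bout relative errors by a covariate (walking speed in 0.05 m/s
#' bins or bout duration in 2 s bins), takes the median absolute error per
#' bin, weights bins by their share of observations, and fits
#' `y = a * exp(b * x)` by weighted least squares (log-linear start,
#' Gauss-Newton refinement via `nls`).
#'
#' @param rel_errors_pct per-bout relative errors, percent.
#' @param covariate per-bout covariate (m/s or s).
#' @param bin_width bin width in covariate units.
#' @return object of class `binned_error_curve` with `bin_centers`,
#'   `median_rel_error_pct`, `weight`, `fit_params` (a, b) and `r2`
#'   (weighted), or NA fit when fewer than 3 non-empty bins.
#' @export
binned_error_fit <- function(rel_errors_pct, covariate, bin_width) {
  e <- abs(as.numeric(rel_errors_pct))
  x <- as.numeric(covariate)
  stopifnot(length(e) == length(x))
  bin <- floor(x / bin_width)
  agg <- tapply(e, bin, stats::median)
  cnt <- tapply(e, bin, length)
  centers <- (as.numeric(names(agg)) + 0.5) * bin_width
  w <- as.numeric(cnt) / sum(cnt)
  med <- as.numeric(agg)
  out <- list(bin_centers = centers, median_rel_error_pct = med, weight = w,
              fit_params = c(a = NA_real_, b = NA_real_), r2 = NA_real_)
  if (length(centers) >= 3L) {
    pos <- med > 0
    lf <- stats::lm(log(med[pos]) ~ centers[pos], weights = w[pos])
    start <- list(a = exp(stats::coef(lf)[1]), b = stats::coef(lf)[2])
    fit <- tryCatch(
      stats::nls(med ~ a * exp(b * centers), start = start, weights = w,
                 control = stats::nls.control(warnOnly = TRUE)),
      error = function(e) NULL)
    cf <- if (!is.null(fit)) stats::coef(fit) else c(a = NA_real_, b = NA_real_)
    if (!all(is.finite(cf)))   # nls degenerates on flat curves
      cf <- c(a = unname(start$a), b = unname(start$b))
    pred <- cf["a"] * exp(cf["b"] * centers)
    wm <- sum(w * med) / sum(w)
    r2 <- 1 - sum(w * (med - pred)^2) / sum(w * (med - wm)^2)
    out$fit_params <- c(a = unname(cf["a"]), b = unname(cf["b"]))
    out$r2 <- r2
  }
  structure(out, class = "binned_error_curve")
}

#' Agreement on total accumulated gait duration per recording
#'
#' For each recording, sums detected and reference gait seconds, then runs
#' [agreement_stats()] over recordings.
#'
#' @param detected_list list of [gait_sequences()] frames, one per recording.
#' @param reference_list matched list of `walking_bouts` or
#'   [gait_sequences()].
#' @return an `agreement_stats` object over recordings.
#' @export
gsd_duration_agreement <- function(detected_list, reference_list) {
  if (length(detected_list) != length(reference_list))
    stop_pairing("detected and reference lists must be matched")
  total <- function(x) {
    if (inherits(x, "walking_bouts")) x <- bouts_to_sequences(x)
    sum(x$end_s - x$start_s)
  }
  agreement_stats(vapply(detected_list, total, 1),
                  vapply(reference_list, total, 1))
}
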