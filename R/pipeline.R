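# End-to-end technical validation at desk scale: gait-sequence detectors
# see the full recording; IC, cadence and stride-length algorithms are run
# inside the reference walking bouts, mirroring the standardized-input
# evaluation design.

REPORT_SCHEMA <- "gaitdmo-report/1"

safe_try <- function(expr) {
  tryCatch(suppressWarnings(expr), gaitdmo_error = function(e) NULL)
}

bout_ref_cadence <- function(b) {
  if (!is.null(b$ic_times_s) && length(b$ic_times_s) >= 3L)
    cadence_from_ics(ic_list(b$ic_times_s))$cad_mean
  else {
    d <- b$strides$end_s - b$strides$start_s
    2 * mean(60 / d)
  }
}

bout_ref_sl <- function(b) mean(b$strides$length_m)

#' Run the technical-validation pipeline on matched recording/reference pairs
#'
#' Per pair: gait-sequence detectors run on the full recording and are
#' scored by 0.1 s window classification and total-duration agreement;
#' IC detectors run inside each reference bout and are scored by
#' tolerance-window matching; cadence and stride-length estimators run
#' inside each bout and are scored per bout against the reference values.
#' Performance indices (equal weights within each outcome, costs inverted
#' by min-max) and rankings are appended.
#'
#' @param pairs list of `list(recording =, truth =)` entries (e.g. elements
#'   of [standard_fixture_suite()]).
#' @param subject a [subject_info()] used by the stride-length models.
#' @param gsd_algos,icd_algos,cad_algos,sl_algos algorithm subsets to run.
#' @param sl_k optional pendulum calibration override (e.g. the generative
#'   constant of a simulation).
#' @param inject_truth when TRUE the reference annotations are fed back as
#'   the device output (oracle pass-through; all sensitivities 1, errors 0).
#' @return nested report list (schema `gaitdmo-report/1`).
#' @export
run_technical_validation <- function(pairs, subject = subject_info(),
                                     gsd_algos = c("a", "b", "c"),
                                     icd_algos = c("a", "b", "c", "d"),
                                     cad_algos = c("a", "b", "c"),
                                     sl_algos = c("a", "b", "c", "d"),
                                     sl_k = NULL,
                                     inject_truth = FALSE) {
  for (p in pairs) {
    if (is.null(p$recording) || is.null(p$truth))
      stop_pairing("every pair needs a recording and a matched reference")
  }
  report <- list(schema = REPORT_SCHEMA, n_recordings = length(pairs),
                 outcomes = list())

  # ---- gait sequence detection -----------------------------------------
  gsd_block <- list()
  for (algo in gsd_algos) {
    counts <- confusion_counts(0, 0, 0, 0)
    det_list <- list(); ref_list <- list()
    for (k in seq_along(pairs)) {
      rec <- pairs[[k]]$recording; truth <- pairs[[k]]$truth
      det <- if (inject_truth) bouts_to_sequences(truth) else
        safe_try(detect_gsd(rec, algo)) %||% gait_sequences()
      cc <- classify_gsd_windows(det, truth, rec_duration(rec))
      counts <- confusion_counts(counts$tp + cc$tp, counts$tn + cc$tn,
                                 counts$fp + cc$fp, counts$fn + cc$fn)
      det_list[[k]] <- det; ref_list[[k]] <- truth
    }
    meas <- confusion_measures(counts)
    dur <- if (length(pairs) >= 3L)
      safe_try(gsd_duration_agreement(det_list, ref_list)) else NULL
    gsd_block[[algo]] <- list(
      counts = counts[c("tp", "tn", "fp", "fn")], measures = meas,
      duration_abs_error_s = if (!is.null(dur)) dur$abs_error_mean else NA,
      duration_icc = if (!is.null(dur)) dur$icc else NA)
  }
  report$outcomes$gsd <- gsd_block

  # ---- per-bout device outcomes inside reference bouts ------------------
  icd_block <- list()
  for (algo in icd_algos) {
    tp <- fp <- fn <- 0
    abs_err <- rel_err <- numeric(0)
    for (p in pairs) {
      for (b in p$truth) {
        gs <- gait_sequences(b$start_s, b$end_s)
        ics <- if (inject_truth) ic_list(b$ic_times_s) else
          safe_try(detect_icd(p$recording, gs, algo))
        if (is.null(ics)) ics <- ic_list(numeric(0))
        mm <- match_ics(ics, ic_list(b$ic_times_s))
        tp <- tp + mm$counts$tp; fp <- fp + mm$counts$fp
        fn <- fn + mm$counts$fn
        abs_err <- c(abs_err, mm$abs_errors_s)
        rel_err <- c(rel_err, mm$rel_errors)
      }
    }
    meas <- confusion_measures(confusion_counts(tp, NA_real_, fp, fn))
    icd_block[[algo]] <- list(
      counts = list(tp = tp, fp = fp, fn = fn),
      sensitivity = meas$sensitivity, ppv = meas$ppv,
      abs_error_s = mean(abs_err),
      rel_error_pct = mean(rel_err) * 100)
  }
  report$outcomes$icd <- icd_block

  per_bout_block <- function(algos, dev_fun, ref_fun, unit) {
    block <- list()
    for (algo in algos) {
      dev <- ref <- numeric(0)
      covar_speed <- covar_dur <- numeric(0)
      for (p in pairs) {
        for (b in p$truth) {
          rv <- ref_fun(b)
          dv <- if (inject_truth) rv else dev_fun(p$recording, b, algo)
          if (is.null(dv) || !is.finite(dv)) next
          dev <- c(dev, dv); ref <- c(ref, rv)
          covar_speed <- c(covar_speed, b$mean_speed_mps)
          covar_dur <- c(covar_dur, b$end_s - b$start_s)
        }
      }
      agr <- if (length(dev) >= 3L) safe_try(agreement_stats(dev, ref)) else NULL
      block[[algo]] <- list(
        n_bouts = length(dev), unit = unit,
        device_mean = if (length(dev)) mean(dev) else NA,
        reference_mean = if (length(ref)) mean(ref) else NA,
        bias = if (!is.null(agr)) agr$bias else NA,
        loa = if (!is.null(agr)) c(agr$loa_low, agr$loa_high) else c(NA, NA),
        abs_error = if (!is.null(agr)) agr$abs_error_mean else NA,
        rel_error_pct = if (length(dev)) mean(abs(dev - ref) / ref * 100) else NA,
        icc = if (!is.null(agr)) agr$icc else NA,
        per_bout = list(device = dev, reference = ref,
                        speed_mps = covar_speed, duration_s = covar_dur))
    }
    block
  }

  report$outcomes$cad <- per_bout_block(
    cad_algos,
    function(rec, b, algo)
      safe_try(estimate_cadence(rec, gait_sequences(b$start_s, b$end_s),
                                algo))$cad_mean,
    bout_ref_cadence, "steps/min")

  sl_par <- if (is.null(sl_k)) NULL else sl_params(k = sl_k)
  report$outcomes$sl <- per_bout_block(
    sl_algos,
    function(rec, b, algo) {
      gs <- gait_sequences(b$start_s, b$end_s)
      ics <- safe_try(detect_icd_a(rec, gs))
      if (is.null(ics) || length(ics$ic_times_s) < 2L) return(NULL)
      safe_try(estimate_stride_length(rec, ics, subject, algo,
                                      params = sl_par))$sl_mean
    },
    bout_ref_sl, "m")

  # ---- ranking ---------------------------------------------------------
  rank_block <- list()
  add_rank <- function(name, values, kind) {
    if (nrow(values) < 1L || !any(is.finite(values))) return()
    pi <- safe_try(performance_index(decision_matrix(values, kind)))
    if (!is.null(pi)) rank_block[[name]] <<- pi
  }
  named_rbind <- function(block, f) {
    m <- do.call(rbind, lapply(block, f))
    if (!is.null(m)) rownames(m) <- names(block)
    m
  }
  gsd_mat <- named_rbind(gsd_block, function(x)
    c(accuracy = x$measures$accuracy, sensitivity = x$measures$sensitivity,
      specificity = x$measures$specificity, ppv = x$measures$ppv,
      abs_error = x$duration_abs_error_s))
  if (!is.null(gsd_mat))
    add_rank("gsd", gsd_mat, c(rep("benefit", 4), "cost"))
  icd_mat <- named_rbind(icd_block, function(x)
    c(sensitivity = x$sensitivity, ppv = x$ppv,
      abs_error = x$abs_error_s, rel_error = x$rel_error_pct))
  if (!is.null(icd_mat))
    add_rank("icd", icd_mat, c("benefit", "benefit", "cost", "cost"))
  for (nm in c("cad", "sl")) {
    mat <- named_rbind(report$outcomes[[nm]], function(x)
      c(icc = x$icc, abs_error = x$abs_error, rel_error = x$rel_error_pct))
    if (!is.null(mat)) add_rank(nm, mat, c("benefit", "cost", "cost"))
  }
  report$ranking <- rank_block
  report
}

#' Write a validation report as JSON
#' @param report output of [run_technical_validation()]; `path` target file.
#' @export
write_report <- function(report, path) {
  slim <- report
  for (nm in c("cad", "sl"))
    for (a in names(slim$outcomes[[nm]]))
      slim$outcomes[[nm]][[a]]$per_bout <- NULL
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
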