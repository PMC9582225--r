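#' Average trial traces for one ROI x stimulus
#'
#' Pointwise arithmetic mean across trials. Trials acquired with one frame of
#' slack are trimmed to the shortest before averaging.
#'
#' @param traces Numeric matrix (samples x trials) or list of numeric
#'   vectors.
#' @return Numeric vector, the trial-averaged trace.
#' @export
average_trials <- function(traces) {
  if (is.list(traces)) {
    if (!length(traces)) stop("empty trial group", call. = FALSE)
    len <- min(lengths(traces))
    traces <- vapply(traces, function(v) v[seq_len(len)], numeric(len))
  }
  if (!is.matrix(traces)) traces <- matrix(traces, ncol = 1)
  if (ncol(traces) == 0 || nrow(traces) == 0) {
    stop("empty trial group", call. = FALSE)
  }
  rowMeans(traces)
}

#' Response metrics for one trial-averaged trace
#'
#' Computes the fluorescence response metrics for one ROI x stimulus from the
#' trial-averaged trace and its schedule entry:
#' * baseline mean and SD over the `baseline_window_s` immediately preceding
#'   stimulus onset;
#' * peak = maximum sample within `peak_window_s` after onset (earliest frame
#'   on ties); `delta_f` = peak - baseline mean;
#' * responder if `delta_f` exceeds `responder_sd_multiple` baseline SDs
#'   (if the baseline SD is exactly zero, as in noise-free synthetic input,
#'   the test degrades to `delta_f > 0`);
#' * `dff_pct` = 100 * delta_f / baseline mean for responders, 0 otherwise;
#' * latency = time from onset to the first post-onset frame exceeding
#'   baseline mean + `responder_sd_multiple` * baseline SD (whole frames, no
#'   interpolation);
#' * time to peak = peak time - onset;
#' * response integral = sum of 100 * (F - baseline)/baseline over samples
#'   from onset to trial end, times the sample interval (%% x s).
#' Latency, time to peak and integral are reported only for responders.
#'
#' @param avg_trace Trial-averaged trace (numeric vector).
#' @param sched_row One-row schedule entry for this stimulus.
#' @param cfg An [analysis_config()].
#' @return One-row data.frame of response metrics.
#' @export
compute_response <- function(avg_trace, sched_row, cfg = analysis_config()) {
  onset <- sched_row$onset_s
  rate <- sched_row$sampling_rate_hz
  t <- sample_times(sched_row, length(avg_trace))
  if (onset - cfg$baseline_window_s < -1e-9) {
    stop("baseline window does not fit before stimulus onset", call. = FALSE)
  }
  base_idx <- which(t >= onset - cfg$baseline_window_s - 1e-9 & t < onset - 1e-9)
  peak_idx <- which(t > onset + 1e-9 & t <= onset + cfg$peak_window_s + 1e-9)
  if (!length(base_idx) || !length(peak_idx)) {
    stop("baseline or peak window contains no samples", call. = FALSE)
  }
  baseline_mean <- mean(avg_trace[base_idx])
  baseline_sd <- stats::sd(avg_trace[base_idx])
  if (baseline_mean <= 0) {
    stop("degenerate baseline: baseline mean <= 0, ratio metrics undefined",
         call. = FALSE)
  }
  peak_rel <- which.max(avg_trace[peak_idx])  # earliest frame on ties
  peak_i <- peak_idx[peak_rel]
  peak <- avg_trace[peak_i]
  delta_f <- peak - baseline_mean
  threshold <- cfg$responder_sd_multiple * baseline_sd
  is_responder <- if (baseline_sd == 0) delta_f > 0 else delta_f > threshold

  latency_s <- NA_real_
  time_to_peak_s <- NA_real_
  integral_pct_s <- NA_real_
  dff_pct <- 0
  if (is_responder) {
    dff_pct <- 100 * delta_f / baseline_mean
    post_idx <- which(t > onset + 1e-9)
    cross <- post_idx[avg_trace[post_idx] > baseline_mean + threshold]
    latency_s <- t[cross[1]] - onset
    time_to_peak_s <- t[peak_i] - onset
    resp_idx <- which(t >= onset - 1e-9)
    integral_pct_s <- sum(100 * (avg_trace[resp_idx] - baseline_mean) /
                            baseline_mean) / rate
  }
  data.frame(
    stimulus_label = sched_row$stimulus_label,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    delta_f = delta_f, dff_pct = dff_pct, is_responder = is_responder,
    latency_s = latency_s, time_to_peak_s = time_to_peak_s,
    integral_pct_s = integral_pct_s, stringsAsFactors = FALSE
  )
}

#' Blank-subtract response amplitudes for one ROI
#'
#' Subtracts the dF/F of the blank (deodorized air) stimulus from the dF/F of
#' every odorant stimulus of the same ROI, writing `dff_blanksub_pct`.
#' Responder status is re-evaluated as responder AND positive blank-
#' subtracted amplitude; the blank row itself keeps `dff_blanksub_pct = NA`.
#'
#' @param metrics ResponseMetrics rows for one ROI (one row per stimulus).
#' @param blank_label Stimulus label of the blank.
#' @return `metrics` with `dff_blanksub_pct` set and `is_responder`
#'   re-evaluated for non-blank stimuli.
#' @export
blank_subtract <- function(metrics, blank_label) {
  i_blank <- which(metrics$stimulus_label == blank_label)
  if (length(i_blank) != 1) {
    stop(sprintf("blank stimulus '%s' missing from ROI metrics", blank_label),
         call. = FALSE)
  }
  blank_dff <- metrics$dff_pct[i_blank]
  metrics$dff_blanksub_pct <- metrics$dff_pct - blank_dff
  metrics$dff_blanksub_pct[i_blank] <- NA_real_
  odor <- seq_len(nrow(metrics)) != i_blank
  metrics$is_responder[odor] <- metrics$is_responder[odor] &
    metrics$dff_blanksub_pct[odor] > 0
  metrics
}

#' Response metrics for every ROI x stimulus of a dataset
#'
#' Trial-averages each group, computes [compute_response()] metrics, and, if
#' the schedule contains a blank stimulus, applies [blank_subtract()] per
#' ROI. Without a blank, `dff_blanksub_pct` equals `dff_pct`.
#'
#' @param dataset An [roi_dataset()].
#' @param cfg An [analysis_config()].
#' @return data.frame with one row per ROI x stimulus (all ResponseMetrics
#'   fields plus `roi_id` and `mouse_id`).
#' @export
compute_response_metrics <- function(dataset, cfg = analysis_config()) {
  stopifnot(inherits(dataset, "roi_dataset"))
  blank_label <- dataset$schedule$stimulus_label[dataset$schedule$is_blank]
  mouse_of <- stats::setNames(dataset$roi_meta$mouse_id,
                              dataset$roi_meta$roi_id)
  rows <- lapply(names(dataset$traces), function(roi) {
    stims <- dataset$traces[[roi]]
    m <- do.call(rbind, lapply(names(stims), function(lab) {
      avg <- average_trials(stims[[lab]])
      compute_response(avg, schedule_row(dataset$schedule, lab), cfg)
    }))
    if (length(blank_label) == 1) {
      m <- blank_subtract(m, blank_label)
    } else {
      m$dff_blanksub_pct <- m$dff_pct
    }
    cbind(data.frame(roi_id = roi, mouse_id = unname(mouse_of[roi]),
                     stringsAsFactors = FALSE), m)
  })
  do.call(rbind, rows)
}

#' Fraction of ROIs responding to each odorant, per mouse
#'
#' @param metrics Output of [compute_response_metrics()].
#' @param schedule The matching [stim_schedule()]; blank stimuli are
#'   excluded.
#' @return data.frame `mouse_id, odorant, stimulus_label, n_responders,
#'   n_rois, fraction`.
#' @export
responder_fraction <- function(metrics, schedule) {
  sched <- schedule[!schedule$is_blank, , drop = FALSE]
  m <- metrics[metrics$stimulus_label %in% sched$stimulus_label, ]
  if (!nrow(m)) stop("no odorant stimuli in metrics", call. = FALSE)
  odorant_of <- stats::setNames(sched$odorant, sched$stimulus_label)
  m$odorant <- unname(odorant_of[m$stimulus_label])
  agg <- do.call(rbind, lapply(
    split(m, list(m$mouse_id, m$stimulus_label), drop = TRUE),
    function(d) data.frame(
      mouse_id = d$mouse_id[1], odorant = d$odorant[1],
      stimulus_label = d$stimulus_label[1],
      n_responders = sum(d$is_responder), n_rois = nrow(d),
      fraction = mean(d$is_responder), stringsAsFactors = FALSE
    )))
  rownames(agg) <- NULL
  agg
}

#' Glomerular density
#'
#' Number of glomeruli per square millimetre of imaged field.
#'
#' @param n_rois Glomerulus count.
#' @param field_area_um2 Field area in square microns.
#' @return Density per mm^2.
#' @export
#' @examples
#' glomerular_density(30, 266^2)  # ~424 per mm^2
glomerular_density <- function(n_rois, field_area_um2) {
  if (!is.finite(field_area_um2) || field_area_um2 <= 0) {
    stop("field_area_um2 must be positive", call. = FALSE)
  }
  n_rois / (field_area_um2 * 1e-6)
}
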