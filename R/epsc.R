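#' Baseline-subtract one voltage-clamp sweep
#'
#' Subtracts the mean current over the `cfg$epsc_baseline_window_s`
#' (default 350 ms) window immediately preceding light onset.
#'
#' @param current Current trace in pA.
#' @param time_s Sample times (s), parallel to `current`.
#' @param light_onset_s Light onset on the `time_s` base.
#' @param cfg An [analysis_config()].
#' @return Baseline-subtracted current trace.
#' @export
baseline_subtract <- function(current, time_s, light_onset_s,
                              cfg = analysis_config()) {
  idx <- which(time_s >= light_onset_s - cfg$epsc_baseline_window_s - 1e-12 &
                 time_s < light_onset_s - 1e-12)
  if (!length(idx) ||
      light_onset_s - time_s[1] < cfg$epsc_baseline_window_s - 1e-12) {
    stop("insufficient pre-stimulus recording for baseline subtraction",
         call. = FALSE)
  }
  current - mean(current[idx])
}

# Onset index on the rising edge into the peak: walk back from peak_i to the
# first sample of the contiguous run with value <= level (level and peak are
# negative for inward currents). Returns NA if the trace never reaches the
# level at the peak itself.
onset_index_toward_peak <- function(trace, peak_i, level) {
  if (trace[peak_i] > level) return(NA_integer_)
  i <- peak_i
  while (i > 1 && trace[i - 1] <= level) i <- i - 1
  i
}

#' EPSC kinetics for one sweep set
#'
#' Implements the kinetic analysis of light-evoked EPSCs for one cell and
#' stimulus condition:
#' 1. each sweep is baseline-subtracted over the 350 ms pre-stimulus window
#'    and the sweeps are averaged;
#' 2. peak amplitude = most negative value of the averaged trace within
#'    `cfg$epsc_peak_window_s` (250 ms) after light onset;
#' 3. the cell responds if the peak magnitude exceeds
#'    `cfg$responder_sd_multiple` (3) SDs of the averaged trace's baseline;
#' 4. per-sweep onset latencies: the time from light onset to each sweep
#'    reaching `cfg$epsc_onset_fraction` (5%) of the averaged-trace peak on
#'    the rising edge into that sweep's peak (first sample at or beyond the
#'    level, no interpolation); sweeps that never reach the level carry no
#'    onset;
#' 5. the reported onset latency is the mean of the per-sweep onsets and
#'    jitter is their sample SD (n-1). (Averaging the sweeps first would
#'    bias the onset early by roughly one jitter SD, because the smeared
#'    rising edge of the average crosses the 5% level as soon as the
#'    earliest trials have risen.)
#' 6. time to peak = averaged-trace peak time - onset time;
#' 7. the cell is classified monosynaptic if it responds with onset latency
#'    below `cfg$monosynaptic_max_latency_s` (2 ms).
#'
#' @param ss A [sweep_set()].
#' @param cfg An [analysis_config()].
#' @return One-row data.frame with EPSC metrics.
#' @export
epsc_kinetics <- function(ss, cfg = analysis_config()) {
  stopifnot(inherits(ss, "sweep_set"))
  t <- ss$time_s
  onset <- ss$light_onset_s
  corrected <- apply(ss$sweeps, 2, baseline_subtract, time_s = t,
                     light_onset_s = onset, cfg = cfg)
  avg <- rowMeans(corrected)
  base_idx <- which(t >= onset - cfg$epsc_baseline_window_s - 1e-12 &
                      t < onset - 1e-12)
  win <- which(t > onset + 1e-12 & t <= onset + cfg$epsc_peak_window_s + 1e-12)
  if (!length(win)) stop("peak window contains no samples", call. = FALSE)
  peak_rel <- which.min(avg[win])
  peak_i <- win[peak_rel]
  peak <- avg[peak_i]
  base_sd <- stats::sd(avg[base_idx])
  is_response <- if (base_sd == 0) abs(peak) > 0 else
    abs(peak) > cfg$responder_sd_multiple * base_sd

  onset_latency_s <- NA_real_
  jitter_s <- NA_real_
  time_to_peak_s <- NA_real_
  n_onsets <- 0L
  if (is_response) {
    if (peak >= 0) {
      stop(sprintf(
        "cell %s / %s: responding cell has no inward peak; onset undefined",
        ss$cell_id, ss$condition_label), call. = FALSE)
    }
    level <- cfg$epsc_onset_fraction * peak
    # the response cannot precede the stimulus: clamp the rising-edge walk
    # to post-onset samples (relevant only when noise runs below the 5%
    # level across light onset)
    first_post <- which(t > onset + 1e-12)[1]
    trial_onsets <- apply(corrected, 2, function(sw) {
      pk_rel <- which.min(sw[win])
      pk_i <- win[pk_rel]
      if (sw[pk_i] > level) return(NA_real_)  # no detectable crossing
      ti <- max(onset_index_toward_peak(sw, pk_i, level), first_post)
      t[ti] - onset
    })
    trial_onsets <- trial_onsets[!is.na(trial_onsets)]
    n_onsets <- length(trial_onsets)
    if (n_onsets == 0) {
      stop(sprintf(
        "cell %s / %s: responding cell has no detectable 5%%-of-peak crossing on any sweep",
        ss$cell_id, ss$condition_label), call. = FALSE)
    }
    # jitter smears the averaged rising edge (its 5% crossing sits about one
    # jitter-SD early), so the reported onset is the mean of the per-trial
    # onsets, which is unbiased for the true onset
    onset_latency_s <- mean(trial_onsets)
    time_to_peak_s <- max(t[peak_i] - onset - onset_latency_s, 0)
    if (n_onsets >= 2) jitter_s <- stats::sd(trial_onsets)
    if (n_onsets == 1) jitter_s <- 0
  }
  data.frame(
    cell_id = ss$cell_id, condition_label = ss$condition_label,
    light_duration_ms = ss$light_duration_ms,
    light_intensity_pct = ss$light_intensity_pct,
    n_sweeps = ncol(ss$sweeps),
    peak_amplitude_pA = peak, baseline_sd_pA = base_sd,
    is_response = is_response, onset_latency_s = onset_latency_s,
    jitter_s = jitter_s, n_onsets = n_onsets,
    time_to_peak_s = time_to_peak_s,
    is_monosynaptic = is_response && !is.na(onset_latency_s) &&
      onset_latency_s < cfg$monosynaptic_max_latency_s,
    stringsAsFactors = FALSE
  )
}

#' Power curve for one cell
#'
#' One row of EPSC metrics per recorded stimulus condition (light duration x
#' intensity). Conditions not recorded for a cell are simply absent from the
#' output (incomplete power curves are reported as missing, never as zero);
#' a message lists them when a full condition grid is supplied.
#'
#' @param sweep_sets List of [sweep_set()] objects for one cell.
#' @param cfg An [analysis_config()].
#' @param expected_conditions Optional character vector of condition labels
#'   the protocol intended; missing ones are reported.
#' @return data.frame with one row per condition.
#' @export
power_curve <- function(sweep_sets, cfg = analysis_config(),
                        expected_conditions = NULL) {
  if (inherits(sweep_sets, "sweep_set")) sweep_sets <- list(sweep_sets)
  if (!length(sweep_sets)) stop("no sweep sets supplied", call. = FALSE)
  cells <- unique(vapply(sweep_sets, `[[`, character(1), "cell_id"))
  if (length(cells) != 1) {
    stop("power_curve expects sweep sets from a single cell", call. = FALSE)
  }
  out <- do.call(rbind, lapply(sweep_sets, epsc_kinetics, cfg = cfg))
  if (!is.null(expected_conditions)) {
    absent <- setdiff(expected_conditions, out$condition_label)
    if (length(absent)) {
      message(sprintf("cell %s: condition(s) absent from recording: %s",
                      cells, paste(absent, collapse = ", ")))
    }
  }
  rownames(out) <- NULL
  out
}
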