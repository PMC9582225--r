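# Shared fixtures and independent oracles. Oracles are written in plain
# loop/formula style, deliberately not sharing code paths with the package.

# Single-stimulus (or small multi-stimulus) schedule: 20 s trial, onset 4 s,
# 1 s stimulus, 15 frames/s unless overridden.
make_schedule <- function(labels = "stimA",
                          odorants = labels,
                          concentrations = rep(0.01, length(labels)),
                          blanks = rep(FALSE, length(labels)),
                          rate = 15, trial_length = 20, onset = 4) {
  stim_schedule(stimulus_label = labels, odorant = odorants,
                concentration = concentrations, is_blank = blanks,
                onset_s = onset, duration_s = 1,
                trial_length_s = trial_length, sampling_rate_hz = rate)
}

# Trace with constant baseline and a rectangular step over the stimulus.
make_step_trace <- function(sched_row, baseline = 100, step = 50,
                            step_from = NULL, step_len = 1) {
  n <- round(sched_row$trial_length_s * sched_row$sampling_rate_hz)
  t <- (seq_len(n) - 1) / sched_row$sampling_rate_hz
  from <- step_from %||% sched_row$onset_s
  tr <- rep(baseline, n)
  tr[t > from & t <= from + step_len] <- baseline + step
  tr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force responder oracle: trial average by explicit
# summation, baseline mean/SD by formula, max-over-window comparison.
oracle_is_responder <- function(mat, onset_s, rate, baseline_window,
                                peak_window, sd_multiple) {
  n <- nrow(mat)
  avg <- numeric(n)
  for (i in seq_len(n)) avg[i] <- sum(mat[i, ]) / ncol(mat)
  t <- (0:(n - 1)) / rate
  b <- avg[t >= onset_s - baseline_window & t < onset_s]
  mu <- sum(b) / length(b)
  sdev <- sqrt(sum((b - mu)^2) / (length(b) - 1))
  w <- avg[t > onset_s & t <= onset_s + peak_window]
  peak <- w[1]
  for (v in w) if (v > peak) peak <- v
  if (sdev == 0) (peak - mu) > 0 else (peak - mu) > sd_multiple * sdev
}

# Independent latency oracle: scan samples after onset for the first
# crossing of mean + k * sd of the baseline window.
oracle_latency <- function(avg, onset_s, rate, baseline_window, sd_multiple) {
  t <- (seq_along(avg) - 1) / rate
  b <- avg[t >= onset_s - baseline_window & t < onset_s]
  mu <- mean(b)
  thr <- mu + sd_multiple * sqrt(sum((b - mu)^2) / (length(b) - 1))
  for (i in seq_along(avg)) {
    if (t[i] > onset_s && avg[i] > thr) return(t[i] - onset_s)
  }
  NA_real_
}

# One-line sparseness oracle: direct evaluation of the defining formula.
oracle_sparseness <- function(r) {
  n <- length(r)
  (1 - (mean(r))^2 / mean(r^2)) / (1 - 1 / n)
}

# Noiseless alpha-function sweep set with per-sweep onset shifts (s).
make_alpha_sweep_set <- function(amDuring = -50, onsets_s = rep(1e-3, 10),
                                 tau = 2e-3, rate = 1e4,
                                 light_onset = 0.4, length_s = 0.7,
                                 noise_sd = 0, baseline_offset = 0,
                                 cell_id = "c1", label = "1ms_100pct") {
  n <- round(length_s * rate)
  t <- (0:(n - 1)) / rate
  mat <- vapply(onsets_s, function(o) {
    trel <- t - light_onset - o
    a <- ifelse(trel > 0, (trel / tau) * exp(1 - trel / tau), 0)
    if (max(a) > 0) a <- a / max(a)
    amDuring * a + baseline_offset +
      if (noise_sd > 0) rnorm(n, sd = noise_sd) else 0
  }, numeric(n))
  sweep_set(cell_id, label, t, mat, light_onset, 1, 100)
}
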