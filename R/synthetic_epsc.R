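#' Generate synthetic light-evoked EPSC sweeps
#'
#' Simulates voltage-clamp recordings of light-evoked EPSCs for `n_cells`
#' cells. Each cell draws a peak amplitude (negative, inward), a true onset
#' latency after light onset, a trial-to-trial onset jitter SD and a
#' baseline noise RMS from uniform ranges. Each sweep is an alpha-function
#' EPSC `A * (t/tau) * exp(1 - t/tau)` starting at `true onset +
#' Normal(0, jitter)`, normalised per sweep to attain the configured peak
#' exactly on the sampling grid, plus Gaussian baseline noise. Condition
#' amplitudes scale with light intensity and duration (monotone in both).
#'
#' @param n_cells Number of simulated cells.
#' @param amplitude_range_pA Range of peak amplitudes (negative pA) at the
#'   strongest condition.
#' @param onset_range_s Range of true onset latencies (s after light onset).
#' @param jitter_range_s Range of trial-to-trial onset jitter SDs (s).
#' @param noise_range_pA Range of baseline noise RMS (pA).
#' @param n_sweeps Sweeps per cell and condition (10 in the protocol this
#'   emulates).
#' @param sampling_rate_hz Acquisition rate (default 10 kHz).
#' @param conditions data.frame `duration_ms, intensity_pct`; default the
#'   single 1 ms / 100% condition used for kinetic analysis. Pass the full
#'   3 x 5 grid to simulate complete power curves.
#' @param alpha_tau_s Alpha-function time constant (time to peak).
#' @param light_onset_s,sweep_length_s Sweep timing (s); at least 350 ms of
#'   pre-stimulus recording.
#' @param seed Integer seed (single stream: per-cell parameters first, then
#'   per-sweep onsets and noise in cell/condition/sweep order).
#' @return List with `sweep_sets` (list of [sweep_set()]), `truth`
#'   (data.frame of true amplitude, onset, jitter, noise RMS and SNR per
#'   cell x condition) and the call parameters.
#' @export
generate_epsc_dataset <- function(n_cells,
                                  amplitude_range_pA = c(-200, -10),
                                  onset_range_s = c(0.5e-3, 3e-3),
                                  jitter_range_s = c(0.05e-3, 0.5e-3),
                                  noise_range_pA = c(2, 10),
                                  n_sweeps = 10L,
                                  sampling_rate_hz = 10000,
                                  conditions = data.frame(
                                    duration_ms = 1, intensity_pct = 100),
                                  alpha_tau_s = 2e-3,
                                  light_onset_s = 0.4,
                                  sweep_length_s = 0.7,
                                  seed = 1L) {
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  for (rg in list(amplitude_range_pA, onset_range_s, jitter_range_s,
                  noise_range_pA)) {
    if (length(rg) != 2 || any(!is.finite(rg)) || rg[1] > rg[2]) {
      stop("parameter ranges must be finite length-2 vectors (low, high)",
           call. = FALSE)
    }
  }
  if (any(amplitude_range_pA >= 0)) {
    stop("EPSC amplitudes must be negative (inward current)", call. = FALSE)
  }
  if (any(noise_range_pA < 0) || any(jitter_range_s < 0)) {
    stop("noise and jitter ranges must be non-negative", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n_samples <- as.integer(round(sweep_length_s * sampling_rate_hz))
  t <- (seq_len(n_samples) - 1) / sampling_rate_hz

  amp <- stats::runif(n_cells, amplitude_range_pA[1], amplitude_range_pA[2])
  onset <- stats::runif(n_cells, onset_range_s[1], onset_range_s[2])
  sigma <- stats::runif(n_cells, jitter_range_s[1], jitter_range_s[2])
  noise <- stats::runif(n_cells, noise_range_pA[1], noise_range_pA[2])

  max_dur <- max(conditions$duration_ms)
  sweep_sets <- list()
  truth <- list()
  for (ci in seq_len(n_cells)) {
    cell_id <- sprintf("cell%03d", ci)
    for (k in seq_len(nrow(conditions))) {
      dur <- conditions$duration_ms[k]
      int <- conditions$intensity_pct[k]
      label <- sprintf("%gms_%gpct", dur, int)
      scale <- (int / 100) * (dur / max_dur)
      a_cond <- amp[ci] * scale
      mat <- matrix(0, nrow = n_samples, ncol = n_sweeps)
      for (j in seq_len(n_sweeps)) {
        o_j <- onset[ci] + stats::rnorm(1, sd = sigma[ci])
        trel <- t - light_onset_s - o_j
        a <- ifelse(trel > 0, (trel / alpha_tau_s) *
                      exp(1 - trel / alpha_tau_s), 0)
        m <- max(a)
        if (m > 0) a <- a / m
        mat[, j] <- a_cond * a +
          if (noise[ci] > 0) stats::rnorm(n_samples, sd = noise[ci]) else 0
      }
      sweep_sets[[length(sweep_sets) + 1L]] <-
        sweep_set(cell_id, label, t, mat, light_onset_s, dur, int)
      truth[[length(truth) + 1L]] <- data.frame(
        cell_id = cell_id, condition_label = label,
        light_duration_ms = dur, light_intensity_pct = int,
        true_amplitude_pA = a_cond, true_onset_s = onset[ci],
        true_jitter_s = sigma[ci], noise_rms_pA = noise[ci],
        snr = abs(a_cond) / max(noise[ci], .Machine$double.eps),
        stringsAsFactors = FALSE
      )
    }
  }
  list(sweep_sets = sweep_sets, truth = do.call(rbind, truth),
       sampling_rate_hz = sampling_rate_hz, seed = as.integer(seed))
}
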