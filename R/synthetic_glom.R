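#' Configuration for the synthetic glomerular imaging generator
#'
#' Describes a simulated in vivo imaging experiment: trial structure
#' (20 s trials, 4 s baseline, 1 s stimulus, 3 trials per stimulus),
#' odorant panel and concentration ladder (0.5/1/5/10% v/v), sparse odorant
#' tuning, a population Hill amplitude model with per-glomerulus lognormal
#' gain, a concentration-dependent latency model, a GCaMP6s-like
#' difference-of-exponentials response kernel, Gaussian acquisition noise, a
#' small mechanosensory blank response and an optional hard fluorescence
#' ceiling emulating indicator saturation.
#'
#' Two presets capture the concentration-coding contrast between mature and
#' immature OSN input: `"mature_like"` uses a steep Hill curve saturating by
#' the second ladder step (amplitudes rise sharply from 0.5% to 1% and are
#' flat above), `"immature_like"` a shallow graded curve that keeps rising
#' across the whole ladder.
#'
#' @param preset `"immature_like"` or `"mature_like"`.
#' @param n_mice,n_glomeruli_per_mouse Simulated cohort size.
#' @param odorant_panel Character vector of odorant names.
#' @param concentration_ladder Ascending v/v fractions.
#' @param tuning_sparsity Probability that a given odorant drives a given
#'   glomerulus.
#' @param a_max_pct,ec50,hill_n Population Hill amplitude model (dF/F % at
#'   saturation, half-max concentration, Hill coefficient).
#' @param gain_sdlog SD (log scale) of the per-glomerulus lognormal gain;
#'   the gain has mean 1.
#' @param latency_base_s Response latency at the lowest ladder step.
#' @param latency_step_s Additive latency change per ascending ladder step
#'   (negative = faster responses at higher concentration).
#' @param latency_jitter_sd_s SD of the per-glomerulus, per-stimulus latency
#'   dispersion around the ladder value (s). Real response latencies vary
#'   across glomeruli; dispersing them also prevents the latency ladder from
#'   aliasing against the frame clock.
#' @param rise_tau_s,decay_tau_s Kernel time constants (rise < decay).
#' @param baseline_f0 Baseline fluorescence, arbitrary units.
#' @param noise_sd Gaussian sample noise SD, arbitrary units.
#' @param mechanosensory_blank_amp_pct Blank-stimulus amplitude (dF/F %).
#' @param ceiling Optional hard fluorescence ceiling (a.u.); `NULL` for no
#'   clipping.
#' @param sampling_rate_hz Frames per second (10.17 and 15 were used in
#'   vivo).
#' @param trial_length_s,onset_s,duration_s Trial timing, seconds.
#' @param trials_per_stimulus Trials averaged per stimulus.
#' @param include_blank Include a blank (deodorized air) stimulus.
#' @param seed Integer seed; the generator consumes one seeded stream in a
#'   fixed documented order (tuning flags, then gains, then per glomerulus
#'   and stimulus a latency draw followed by that stimulus's trial noise).
#' @return A list of class `"glom_gen_config"`.
#' @export
glom_gen_config <- function(preset = c("immature_like", "mature_like"),
                            n_mice = 6L,
                            n_glomeruli_per_mouse = 30L,
                            odorant_panel = c("ethyl_butyrate",
                                              "isoamyl_acetate", "hexanal",
                                              "propionic_acid",
                                              "hexanone_2"),
                            concentration_ladder = c(0.005, 0.01, 0.05, 0.10),
                            tuning_sparsity = 0.3,
                            a_max_pct = NULL, ec50 = NULL, hill_n = NULL,
                            gain_sdlog = 0.4,
                            latency_base_s = 0.4,
                            latency_step_s = -0.1,
                            latency_jitter_sd_s = 0.03,
                            rise_tau_s = 0.2, decay_tau_s = 1.0,
                            baseline_f0 = 100, noise_sd = 2,
                            mechanosensory_blank_amp_pct = 2,
                            ceiling = NULL,
                            sampling_rate_hz = 15,
                            trial_length_s = 20, onset_s = 4,
                            duration_s = 1,
                            trials_per_stimulus = 3L,
                            include_blank = TRUE,
                            seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(a_max_pct)) a_max_pct <- switch(preset, mature_like = 150,
                                              immature_like = 80)
  if (is.null(ec50)) ec50 <- switch(preset, mature_like = 0.007,
                                    immature_like = 0.05)
  if (is.null(hill_n)) hill_n <- switch(preset, mature_like = 4,
                                        immature_like = 1)
  cfg <- list(preset = preset, n_mice = as.integer(n_mice),
              n_glomeruli_per_mouse = as.integer(n_glomeruli_per_mouse),
              odorant_panel = odorant_panel,
              concentration_ladder = sort(concentration_ladder),
              tuning_sparsity = tuning_sparsity,
              a_max_pct = a_max_pct, ec50 = ec50, hill_n = hill_n,
              gain_sdlog = gain_sdlog,
              latency_base_s = latency_base_s,
              latency_step_s = latency_step_s,
              latency_jitter_sd_s = latency_jitter_sd_s,
              rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s,
              baseline_f0 = baseline_f0, noise_sd = noise_sd,
              mechanosensory_blank_amp_pct = mechanosensory_blank_amp_pct,
              ceiling = ceiling,
              sampling_rate_hz = sampling_rate_hz,
              trial_length_s = trial_length_s, onset_s = onset_s,
              duration_s = duration_s,
              trials_per_stimulus = as.integer(trials_per_stimulus),
              include_blank = isTRUE(include_blank),
              seed = as.integer(seed))
  class(cfg) <- "glom_gen_config"
  validate_glom_gen_config(cfg)
  cfg
}

validate_glom_gen_config <- function(cfg) {
  ladder <- cfg$concentration_ladder
  if (length(ladder) >= 2 &&
      (cfg$ec50 < min(ladder) / 10 || cfg$ec50 > max(ladder) * 10)) {
    stop("ec50 must lie within (an order of magnitude of) the ladder span",
         call. = FALSE)
  }
  if (cfg$rise_tau_s >= cfg$decay_tau_s) {
    stop("rise tau must be smaller than decay tau", call. = FALSE)
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (cfg$latency_jitter_sd_s < 0) {
    stop("latency_jitter_sd_s must be >= 0", call. = FALSE)
  }
  if (cfg$tuning_sparsity < 0 || cfg$tuning_sparsity > 1) {
    stop("tuning_sparsity must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(cfg$ceiling) && cfg$ceiling <= cfg$baseline_f0) {
    stop("ceiling must exceed the baseline fluorescence", call. = FALSE)
  }
  invisible(cfg)
}

# Difference-of-exponentials response kernel evaluated at times `t_rel`
# (seconds after response onset), normalised to unit peak on the sampling
# grid so a configured amplitude is attained exactly at zero noise.
response_kernel <- function(t_rel, rise_tau_s, decay_tau_s) {
  k <- ifelse(t_rel > 0,
              exp(-t_rel / decay_tau_s) - exp(-t_rel / rise_tau_s), 0)
  m <- max(k)
  if (m > 0) k / m else k
}

#' Generate a synthetic glomerular imaging dataset
#'
#' Simulates trial traces for every mouse, glomerulus and stimulus of a
#' [glom_gen_config()]: `F(t) = F0 * (1 + A/100 * K(t - onset - latency)) +
#' noise`, clipped at the ceiling if one is set, where K is the
#' difference-of-exponentials kernel (unit peak on the sampling grid) and A
#' follows the population Hill curve times a per-glomerulus lognormal gain
#' for tuned odorants (0 for untuned ones). Blank trials carry only the
#' mechanosensory amplitude. The population latency decreases along the
#' ladder by the configured per-step decrement, with per-glomerulus
#' dispersion around it; realized latencies are recorded in the truth
#' table. Fully reproducible from the seed.
#'
#' @param cfg A [glom_gen_config()].
#' @return List with `dataset` (an [roi_dataset()]), `truth` (data.frame of
#'   true amplitude, latency and responder flag per ROI x stimulus) and
#'   `config`.
#' @export
generate_glom_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "glom_gen_config"))
  set.seed(cfg$seed)
  ladder <- cfg$concentration_ladder
  odorants <- cfg$odorant_panel

  stim <- expand.grid(concentration = ladder, odorant = odorants,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stim <- stim[, c("odorant", "concentration")]
  stim$stimulus_label <- sprintf("%s_%gpct", stim$odorant,
                                 stim$concentration * 100)
  stim$is_blank <- FALSE
  if (cfg$include_blank) {
    stim <- rbind(stim, data.frame(odorant = "blank", concentration = 0,
                                   stimulus_label = "blank",
                                   is_blank = TRUE))
  }
  schedule <- stim_schedule(
    stimulus_label = stim$stimulus_label, odorant = stim$odorant,
    concentration = stim$concentration, is_blank = stim$is_blank,
    onset_s = cfg$onset_s, duration_s = cfg$duration_s,
    trial_length_s = cfg$trial_length_s,
    sampling_rate_hz = cfg$sampling_rate_hz
  )
  n_samples <- schedule_n_samples(schedule[1, ])
  t <- (seq_len(n_samples) - 1) / cfg$sampling_rate_hz

  # population latency per ladder position; each glomerulus disperses
  # around it (drawn per ROI x stimulus below)
  latency_of <- stats::setNames(
    cfg$latency_base_s + (seq_along(ladder) - 1) * cfg$latency_step_s,
    as.character(ladder))
  pop_latency <- vapply(seq_len(nrow(stim)), function(i) {
    if (stim$is_blank[i]) cfg$latency_base_s else
      latency_of[[as.character(stim$concentration[i])]]
  }, numeric(1))

  n_roi <- cfg$n_mice * cfg$n_glomeruli_per_mouse
  roi_ids <- as.vector(t(outer(seq_len(cfg$n_mice),
                               seq_len(cfg$n_glomeruli_per_mouse),
                               function(m, g) sprintf("m%d_g%03d", m, g))))
  mouse_ids <- rep(sprintf("m%d", seq_len(cfg$n_mice)),
                   each = cfg$n_glomeruli_per_mouse)

  # fixed stream order: tuning flags, then gains, then trace noise
  tuned <- matrix(stats::runif(n_roi * length(odorants)) < cfg$tuning_sparsity,
                  nrow = n_roi, dimnames = list(roi_ids, odorants))
  gains <- stats::setNames(
    stats::rlnorm(n_roi, meanlog = -cfg$gain_sdlog^2 / 2,
                  sdlog = cfg$gain_sdlog), roi_ids)

  pop_amp <- hill_amplitude(stim$concentration, cfg$a_max_pct, cfg$ec50,
                            cfg$hill_n)

  traces <- vector("list", n_roi)
  names(traces) <- roi_ids
  truth <- vector("list", n_roi)
  for (r in seq_len(n_roi)) {
    roi <- roi_ids[r]
    stims <- vector("list", nrow(stim))
    names(stims) <- stim$stimulus_label
    amp <- numeric(nrow(stim))
    lat <- numeric(nrow(stim))
    for (i in seq_len(nrow(stim))) {
      amp[i] <- if (stim$is_blank[i]) {
        cfg$mechanosensory_blank_amp_pct
      } else if (tuned[roi, stim$odorant[i]]) {
        pop_amp[i] * gains[[roi]]
      } else 0
      lat[i] <- max(0, pop_latency[i] +
                      if (cfg$latency_jitter_sd_s > 0) {
                        stats::rnorm(1, sd = cfg$latency_jitter_sd_s)
                      } else 0)
      k <- response_kernel(t - cfg$onset_s - lat[i], cfg$rise_tau_s,
                           cfg$decay_tau_s)
      signal <- cfg$baseline_f0 * (1 + amp[i] / 100 * k)
      mat <- matrix(signal, nrow = n_samples,
                    ncol = cfg$trials_per_stimulus) +
        if (cfg$noise_sd > 0) {
          matrix(stats::rnorm(n_samples * cfg$trials_per_stimulus,
                              sd = cfg$noise_sd),
                 nrow = n_samples)
        } else 0
      if (!is.null(cfg$ceiling)) mat <- pmin(mat, cfg$ceiling)
      stims[[i]] <- mat
    }
    traces[[roi]] <- stims
    truth[[r]] <- data.frame(
      roi_id = roi, mouse_id = mouse_ids[r],
      stimulus_label = stim$stimulus_label, odorant = stim$odorant,
      concentration = stim$concentration,
      true_amplitude_pct = amp,
      true_latency_s = lat,
      true_responder = !stim$is_blank &
        tuned[roi, ifelse(stim$is_blank, odorants[1], stim$odorant)] &
        amp > 0,
      gain = unname(gains[[roi]]),
      stringsAsFactors = FALSE
    )
  }
  roi_meta <- data.frame(roi_id = roi_ids, mouse_id = mouse_ids,
                         roi_kind = "glomerulus", stringsAsFactors = FALSE)
  list(dataset = roi_dataset(traces, schedule, roi_meta),
       truth = do.call(rbind, truth), config = cfg)
}
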