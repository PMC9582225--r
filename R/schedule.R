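#' Stimulus schedule
#'
#' A stimulus schedule describes, per stimulus label, what was delivered and
#' when within the trial: odorant identity (or the blank), concentration as a
#' v/v fraction, stimulus onset and duration, total trial length, and the
#' acquisition frame rate. Time is in seconds from trial start; sample index
#' 0 corresponds to t = 0, so the two acquisition rates used in vivo
#' (10.17 and 15 frames/s) are handled uniformly.
#'
#' @param stimulus_label Character vector of unique stimulus keys.
#' @param odorant Odorant name per stimulus ("blank" for the blank stimulus).
#' @param concentration Concentration as a v/v fraction (0.01 for 1%); 0 for
#'   the blank.
#' @param is_blank Logical; at most one blank per schedule.
#' @param onset_s Stimulus onset, seconds from trial start.
#' @param duration_s Stimulus duration in seconds.
#' @param trial_length_s Trial length in seconds.
#' @param sampling_rate_hz Acquisition rate in frames per second.
#'
#' @return A data.frame of class `"stim_schedule"`.
#' @export
#' @examples
#' stim_schedule(
#'   stimulus_label = c("EB_1pct", "blank"),
#'   odorant = c("ethyl_butyrate", "blank"),
#'   concentration = c(0.01, 0),
#'   is_blank = c(FALSE, TRUE),
#'   onset_s = 4, duration_s = 1, trial_length_s = 20,
#'   sampling_rate_hz = 15
#' )
stim_schedule <- function(stimulus_label, odorant, concentration, is_blank,
                          onset_s, duration_s, trial_length_s,
                          sampling_rate_hz) {
  sched <- data.frame(
    stimulus_label = as.character(stimulus_label),
    odorant = as.character(odorant),
    concentration = as.numeric(concentration),
    is_blank = as.logical(is_blank),
    onset_s = as.numeric(onset_s),
    duration_s = as.numeric(duration_s),
    trial_length_s = as.numeric(trial_length_s),
    sampling_rate_hz = as.numeric(sampling_rate_hz),
    stringsAsFactors = FALSE
  )
  class(sched) <- c("stim_schedule", "data.frame")
  validate_stim_schedule(sched)
  sched
}

validate_stim_schedule <- function(sched) {
  required <- c("stimulus_label", "odorant", "concentration", "is_blank",
                "onset_s", "duration_s", "trial_length_s", "sampling_rate_hz")
  missing <- setdiff(required, names(sched))
  if (length(missing)) {
    stop(sprintf("schedule is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(sched$stimulus_label)) {
    stop("schedule must have exactly one entry per stimulus_label",
         call. = FALSE)
  }
  if (sum(sched$is_blank) > 1) {
    stop("a stimulus panel may contain at most one blank stimulus",
         call. = FALSE)
  }
  if (any(sched$onset_s < 0)) {
    stop("onset_s must be >= 0", call. = FALSE)
  }
  if (any(sched$onset_s + sched$duration_s > sched$trial_length_s + 1e-9)) {
    stop("onset_s + duration_s must not exceed trial_length_s", call. = FALSE)
  }
  if (any(sched$sampling_rate_hz <= 0)) {
    stop("sampling_rate_hz must be positive", call. = FALSE)
  }
  invisible(sched)
}

#' Read a stimulus schedule from CSV
#'
#' @param path CSV with columns `stimulus_label, odorant, concentration,
#'   is_blank, onset_s, duration_s, trial_length_s, sampling_rate_hz`.
#' @return A `stim_schedule`.
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stop(sprintf("schedule file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("stimulus_label", "odorant", "concentration", "is_blank",
                "onset_s", "duration_s", "trial_length_s", "sampling_rate_hz")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("schedule CSV is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  do.call(stim_schedule, df[required])
}

# Expected number of samples for one schedule row (sample 0 at t = 0, last
# sample just before trial_length_s).
schedule_n_samples <- function(sched_row) {
  as.integer(round(sched_row$trial_length_s * sched_row$sampling_rate_hz))
}

# Sample times (s from trial start) for one schedule row and n samples.
sample_times <- function(sched_row, n) {
  (seq_len(n) - 1) / sched_row$sampling_rate_hz
}

schedule_row <- function(schedule, label) {
  i <- match(label, schedule$stimulus_label)
  if (is.na(i)) {
    stop(sprintf("stimulus_label '%s' not present in the schedule", label),
         call. = FALSE)
  }
  schedule[i, , drop = FALSE]
}
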