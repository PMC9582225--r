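#' Analysis configuration
#'
#' Bundles every tunable constant of the pipeline in one validated list.
#' Defaults follow the acquisition and analysis conventions of in vivo
#' glomerular GCaMP imaging and slice optogenetics: a 1 s pre-stimulus
#' baseline, a 3 s peak-search window, a 3-SD responder criterion, a 1000%
#' dF/F screen for the indicator-saturation diagnostic, a 350 ms EPSC
#' baseline and 250 ms peak window, onset at 5% of peak, a 2 ms monosynaptic
#' latency bound, a 0.75 investigation-ratio detection threshold and a 600 s
#' buried-food timeout.
#'
#' @param baseline_window_s Seconds of trace immediately before stimulus
#'   onset used for the fluorescence baseline mean and SD.
#' @param peak_window_s Seconds after stimulus onset searched for the peak.
#' @param responder_sd_multiple Responder threshold, in baseline SDs.
#' @param saturation_dff_threshold_pct dF/F (%) above which a response is
#'   screened by the saturation diagnostic.
#' @param saturation_max_frames Maximum number of frames between maximal rise
#'   and first non-positive frame difference for a response to be flagged as
#'   saturated.
#' @param epsc_baseline_window_s Pre-stimulus window (s) for EPSC baseline
#'   subtraction and baseline SD.
#' @param epsc_peak_window_s Post-stimulus window (s) searched for the EPSC
#'   peak (most negative value).
#' @param epsc_onset_fraction Fraction of peak magnitude defining response
#'   onset.
#' @param monosynaptic_max_latency_s Onset latency (s) below which a
#'   responding cell is classified as receiving monosynaptic input.
#' @param detection_ratio_threshold Investigation ratio at or above which a
#'   two-choice trial counts as odor detection.
#' @param buried_food_timeout_s Time limit (s) for the buried-food assay.
#' @param random_seed Integer seed recorded alongside results.
#'
#' @return A list of class `"analysis_config"`.
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$responder_sd_multiple
analysis_config <- function(baseline_window_s = 1.0,
                            peak_window_s = 3.0,
                            responder_sd_multiple = 3.0,
                            saturation_dff_threshold_pct = 1000,
                            saturation_max_frames = 2L,
                            epsc_baseline_window_s = 0.350,
                            epsc_peak_window_s = 0.250,
                            epsc_onset_fraction = 0.05,
                            monosynaptic_max_latency_s = 0.002,
                            detection_ratio_threshold = 0.75,
                            buried_food_timeout_s = 600,
                            random_seed = 1L) {
  cfg <- list(
    baseline_window_s = baseline_window_s,
    peak_window_s = peak_window_s,
    responder_sd_multiple = responder_sd_multiple,
    saturation_dff_threshold_pct = saturation_dff_threshold_pct,
    saturation_max_frames = as.integer(saturation_max_frames),
    epsc_baseline_window_s = epsc_baseline_window_s,
    epsc_peak_window_s = epsc_peak_window_s,
    epsc_onset_fraction = epsc_onset_fraction,
    monosynaptic_max_latency_s = monosynaptic_max_latency_s,
    detection_ratio_threshold = detection_ratio_threshold,
    buried_food_timeout_s = buried_food_timeout_s,
    random_seed = as.integer(random_seed)
  )
  class(cfg) <- "analysis_config"
  validate_analysis_config(cfg)
  cfg
}

validate_analysis_config <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  windows <- c("baseline_window_s", "peak_window_s", "epsc_baseline_window_s",
               "epsc_peak_window_s")
  for (w in windows) {
    if (!is.numeric(cfg[[w]]) || cfg[[w]] <= 0) {
      stop(sprintf("config field '%s' must be a positive number", w),
           call. = FALSE)
    }
  }
  if (cfg$epsc_onset_fraction <= 0 || cfg$epsc_onset_fraction >= 1) {
    stop("epsc_onset_fraction must lie strictly between 0 and 1",
         call. = FALSE)
  }
  if (cfg$detection_ratio_threshold <= 0.5 ||
      cfg$detection_ratio_threshold >= 1) {
    stop("detection_ratio_threshold must lie strictly between 0.5 and 1",
         call. = FALSE)
  }
  if (cfg$responder_sd_multiple <= 0) {
    stop("responder_sd_multiple must be positive", call. = FALSE)
  }
  invisible(cfg)
}

#' Read an analysis configuration from a YAML-like key/value file
#'
#' Accepts a plain `key: value` text file (one field per line, `#` comments
#' allowed) overriding any subset of [analysis_config()] defaults.
#'
#' @param path Path to the configuration file.
#' @return An `analysis_config` list.
#' @export
read_analysis_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  overrides <- list()
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(kv) != 2) {
      stop(sprintf("malformed config line: '%s'", ln), call. = FALSE)
    }
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    overrides[[key]] <- if (!is.na(num)) num else val
  }
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(overrides), known)
  if (length(unknown)) {
    stop(sprintf("unknown config field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  do.call(analysis_config, overrides)
}
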