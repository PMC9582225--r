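#' Construct an ROI dataset
#'
#' An `roi_dataset` holds the trial traces for one imaging experiment:
#' a nested list of sample-by-trial matrices (`traces[[roi_id]][[stimulus]]`),
#' the stimulus schedule, and per-ROI metadata (mouse assignment and ROI
#' kind). ROIs are glomeruli for in vivo imaging or OSN somata for ex vivo
#' imaging; both carry mean-intensity traces already extracted from pixel
#' data.
#'
#' @param traces Named list: `traces[[roi_id]][[stimulus_label]]` is a
#'   numeric matrix with one column per trial and one row per sample.
#' @param schedule A [stim_schedule()].
#' @param roi_meta data.frame with columns `roi_id`, `mouse_id` and
#'   optionally `roi_kind` (`"glomerulus"` or `"soma"`).
#' @param field_area_um2 Optional imaged-field area in square microns, used
#'   by [glomerular_density()].
#' @return A list of class `"roi_dataset"`.
#' @export
roi_dataset <- function(traces, schedule, roi_meta, field_area_um2 = NA_real_) {
  if (is.null(roi_meta$roi_kind)) roi_meta$roi_kind <- "glomerulus"
  ds <- list(traces = traces, schedule = schedule, roi_meta = roi_meta,
             field_area_um2 = field_area_um2)
  class(ds) <- "roi_dataset"
  validate_roi_dataset(ds)
  ds
}

validate_roi_dataset <- function(ds) {
  stopifnot(inherits(ds, "roi_dataset"))
  validate_stim_schedule(ds$schedule)
  if (!all(names(ds$traces) %in% ds$roi_meta$roi_id)) {
    stop("every ROI in traces must appear in roi_meta", call. = FALSE)
  }
  for (roi in names(ds$traces)) {
    stims <- ds$traces[[roi]]
    if (!length(stims)) stop(sprintf("ROI '%s' has no traces", roi),
                             call. = FALSE)
    for (lab in names(stims)) {
      row <- schedule_row(ds$schedule, lab)
      mat <- stims[[lab]]
      if (!is.matrix(mat) || ncol(mat) < 1) {
        stop(sprintf("trace group %s/%s must be a matrix with >= 1 trial",
                     roi, lab), call. = FALSE)
      }
      if (any(!is.finite(mat))) {
        stop(sprintf("non-finite sample in trace group %s/%s", roi, lab),
             call. = FALSE)
      }
      n_expected <- schedule_n_samples(row)
      if (abs(nrow(mat) - n_expected) > 1) {
        stop(sprintf(
          "trace group %s/%s has %d samples; schedule implies %d (+/- 1)",
          roi, lab, nrow(mat), n_expected), call. = FALSE)
      }
    }
  }
  invisible(ds)
}

#' @export
print.roi_dataset <- function(x, ...) {
  n_roi <- length(x$traces)
  n_stim <- nrow(x$schedule)
  n_trials <- sum(vapply(x$traces,
                         function(s) sum(vapply(s, ncol, integer(1))),
                         numeric(1)))
  cat(sprintf("<roi_dataset> %d ROIs x %d stimuli, %d trial traces\n",
              n_roi, n_stim, n_trials))
  invisible(x)
}

#' Read a long-format trial-trace table
#'
#' Reads `traces.csv` (columns `roi_id, stimulus_label, trial_index,
#' sample_index, fluorescence`) together with its stimulus schedule and
#' returns a validated [roi_dataset()]. Every `stimulus_label` must resolve
#' to a schedule entry and every fluorescence value must be finite.
#'
#' @param path Path to the trace CSV.
#' @param schedule_path Path to the schedule CSV (see [read_schedule()]).
#' @param roi_meta Optional data.frame mapping `roi_id` to `mouse_id`;
#'   when omitted all ROIs are assigned to mouse `"m1"`.
#' @param field_area_um2 Optional imaged-field area in square microns.
#' @return An `roi_dataset`.
#' @export
read_trace_table <- function(path, schedule_path, roi_meta = NULL,
                             field_area_um2 = NA_real_) {
  if (!file.exists(path)) stop(sprintf("trace file not found: %s", path),
                               call. = FALSE)
  schedule <- read_schedule(schedule_path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("roi_id", "stimulus_label", "trial_index", "sample_index",
                "fluorescence")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("trace CSV is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  unknown <- setdiff(unique(df$stimulus_label), schedule$stimulus_label)
  if (length(unknown)) {
    stop(sprintf("stimulus_label(s) absent from schedule: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!is.finite(df$fluorescence))
  if (length(bad)) {
    stop(sprintf("non-finite fluorescence at row %d of %s", bad[1], path),
         call. = FALSE)
  }
  traces <- trace_table_to_list(df)
  if (is.null(roi_meta)) {
    roi_meta <- data.frame(roi_id = names(traces), mouse_id = "m1",
                           stringsAsFactors = FALSE)
  }
  roi_dataset(traces, schedule, roi_meta, field_area_um2)
}

trace_table_to_list <- function(df) {
  df <- df[order(df$roi_id, df$stimulus_label, df$trial_index,
                 df$sample_index), ]
  traces <- list()
  for (roi in unique(df$roi_id)) {
    droi <- df[df$roi_id == roi, ]
    stims <- list()
    for (lab in unique(droi$stimulus_label)) {
      dsl <- droi[droi$stimulus_label == lab, ]
      trials <- split(dsl$fluorescence, dsl$trial_index)
      len <- min(lengths(trials))
      stims[[lab]] <- vapply(trials, function(v) v[seq_len(len)],
                             numeric(len))
    }
    traces[[roi]] <- stims
  }
  traces
}

#' Flatten an ROI dataset into the long trace-table format
#'
#' Inverse of [read_trace_table()]: one row per sample, `sample_index`
#' starting at 0.
#'
#' @param dataset An `roi_dataset`.
#' @return A data.frame with the `traces.csv` columns.
#' @export
as_trace_table <- function(dataset) {
  stopifnot(inherits(dataset, "roi_dataset"))
  out <- vector("list", 0L)
  k <- 0L
  for (roi in names(dataset$traces)) {
    for (lab in names(dataset$traces[[roi]])) {
      mat <- dataset$traces[[roi]][[lab]]
      for (j in seq_len(ncol(mat))) {
        k <- k + 1L
        out[[k]] <- data.frame(
          roi_id = roi, stimulus_label = lab, trial_index = j,
          sample_index = seq_len(nrow(mat)) - 1L,
          fluorescence = mat[, j], stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Write a result table to CSV
#'
#' Writes any non-empty result table with a single header row; numeric
#' columns keep full double precision (>= 6 significant digits) so that a
#' write/read round trip is the identity to within 1e-9 relative.
#'
#' @param table A non-empty data.frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_results <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0) {
    stop("refusing to write an empty result table", call. = FALSE)
  }
  ok <- tryCatch({
    utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop(sprintf("could not write results to '%s': %s", path,
                 conditionMessage(ok)), call. = FALSE)
  }
  invisible(path)
}

#' Construct a voltage-clamp sweep set
#'
#' All sweeps of one cell under one optogenetic stimulus condition
#' (light duration x intensity), on a shared time base.
#'
#' @param cell_id,condition_label Identifiers.
#' @param time_s Sample times in seconds (shared across sweeps).
#' @param sweeps Numeric matrix, one column per sweep, current in pA
#'   (inward currents negative).
#' @param light_onset_s Light onset in seconds on the `time_s` base.
#' @param light_duration_ms,light_intensity_pct Stimulus parameters.
#' @param cfg An [analysis_config()]; used to check the pre-stimulus window.
#' @return A list of class `"sweep_set"`.
#' @export
sweep_set <- function(cell_id, condition_label, time_s, sweeps,
                      light_onset_s, light_duration_ms, light_intensity_pct,
                      cfg = analysis_config()) {
  if (!is.matrix(sweeps) || ncol(sweeps) < 1) {
    stop("sweeps must be a matrix with >= 1 sweep column", call. = FALSE)
  }
  if (nrow(sweeps) != length(time_s)) {
    stop("time_s length must equal the number of samples per sweep",
         call. = FALSE)
  }
  if (light_onset_s - time_s[1] < cfg$epsc_baseline_window_s - 1e-12) {
    stop(sprintf(
      "light onset must be preceded by >= %.3f s of recording",
      cfg$epsc_baseline_window_s), call. = FALSE)
  }
  structure(list(cell_id = cell_id, condition_label = condition_label,
                 time_s = time_s, sweeps = sweeps,
                 light_onset_s = light_onset_s,
                 light_duration_ms = light_duration_ms,
                 light_intensity_pct = light_intensity_pct),
            class = "sweep_set")
}

#' Read voltage-clamp sweeps from a long-format CSV
#'
#' Expects columns `cell_id, condition_label, sweep_index, time_s,
#' current_pA, light_onset_s, light_duration_ms, light_intensity_pct` and
#' returns one [sweep_set()] per cell x condition.
#'
#' @param path Path to `sweeps.csv`.
#' @param cfg An [analysis_config()].
#' @return A list of `sweep_set` objects.
#' @export
read_sweep_table <- function(path, cfg = analysis_config()) {
  if (!file.exists(path)) stop(sprintf("sweep file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell_id", "condition_label", "sweep_index", "time_s",
                "current_pA", "light_onset_s", "light_duration_ms",
                "light_intensity_pct")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("sweep CSV is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  key <- interaction(df$cell_id, df$condition_label, drop = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$sweep_index, d$time_s), ]
    trials <- split(d$current_pA, d$sweep_index)
    len <- min(lengths(trials))
    mat <- vapply(trials, function(v) v[seq_len(len)], numeric(len))
    t0 <- d$time_s[d$sweep_index == d$sweep_index[1]][seq_len(len)]
    sweep_set(d$cell_id[1], d$condition_label[1], t0, mat,
              d$light_onset_s[1], d$light_duration_ms[1],
              d$light_intensity_pct[1], cfg)
  })
}

#' Flatten sweep sets into the long sweep-table format
#'
#' @param sweep_sets A list of [sweep_set()] objects.
#' @return A data.frame with the `sweeps.csv` columns.
#' @export
as_sweep_table <- function(sweep_sets) {
  if (inherits(sweep_sets, "sweep_set")) sweep_sets <- list(sweep_sets)
  do.call(rbind, lapply(sweep_sets, function(ss) {
    do.call(rbind, lapply(seq_len(ncol(ss$sweeps)), function(j) {
      data.frame(cell_id = ss$cell_id, condition_label = ss$condition_label,
                 sweep_index = j, time_s = ss$time_s,
                 current_pA = ss$sweeps[, j],
                 light_onset_s = ss$light_onset_s,
                 light_duration_ms = ss$light_duration_ms,
                 light_intensity_pct = ss$light_intensity_pct,
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Read a behavioral event table
#'
#' Expects columns `assay, subject_id, group, trial_index, odorant, value_s`.
#' Recognised assays: `buried_food` (rows with `odorant` in
#' `latency`/`digging`), `two_choice` (rows with `odorant` in
#' `odor`/`mineral_oil`), and `habituation` (one row per odorant x trial).
#'
#' @param path Path to `behavior.csv`.
#' @return A data.frame.
#' @export
read_behavior_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("behavior file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("assay", "subject_id", "group", "trial_index", "odorant",
                "value_s")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("behavior CSV is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(df$value_s) | df$value_s < 0)) {
    stop("behavior value_s must be finite and non-negative", call. = FALSE)
  }
  df
}
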