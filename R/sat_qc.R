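#' GCaMP saturation diagnostic for one averaged trace
#'
#' Indicator saturation produces a characteristic signature in the
#' frame-difference series of a fluorescence response: a rapid rise that
#' transitions to a zero or negative frame difference within 1-2 frames
#' (a hard plateau), where an unsaturated transient decays gradually.
#' The diagnostic computes per-frame differences d_t = F_t - F_{t-1},
#' locates the maximal rise (earliest frame on ties), and counts frames
#' from the frame after the maximal rise to the first non-positive
#' difference. A response is flagged when that count is at most
#' `cfg$saturation_max_frames` (default 2).
#'
#' @param avg_trace Trial-averaged fluorescence trace (>= 3 samples).
#' @param cfg An [analysis_config()].
#' @return One-row data.frame `max_rise_frame` (1-based index into the
#'   difference series), `frames_to_nonpositive`, `flagged`.
#' @export
saturation_check <- function(avg_trace, cfg = analysis_config()) {
  if (length(avg_trace) < 3) {
    stop("saturation check requires >= 3 samples", call. = FALSE)
  }
  d <- diff(avg_trace)
  max_rise <- which.max(d)  # earliest frame on ties
  after <- which(seq_along(d) > max_rise & d <= 0)
  if (length(after)) {
    frames <- after[1] - max_rise
    flagged <- frames <= cfg$saturation_max_frames
  } else {
    frames <- length(d) - max_rise
    flagged <- FALSE
    warning("trace rises monotonically to the end; no non-positive frame difference found",
            call. = FALSE)
  }
  data.frame(max_rise_frame = as.integer(max_rise),
             frames_to_nonpositive = as.integer(frames),
             flagged = flagged)
}

#' Saturation QC report for a dataset
#'
#' Applies [saturation_check()] to the trial-averaged trace of every
#' ROI x stimulus whose dF/F exceeds the screening threshold
#' (`cfg$saturation_dff_threshold_pct`, default 1000%), the regime in which
#' indicator saturation is plausible. Smaller responses are not evaluated.
#'
#' @param dataset An [roi_dataset()].
#' @param metrics Output of [compute_response_metrics()] for `dataset`;
#'   computed if omitted.
#' @param cfg An [analysis_config()].
#' @return data.frame `roi_id, stimulus_label, dff_pct, max_rise_frame,
#'   frames_to_nonpositive, flagged`, one row per screened response
#'   (zero rows if none exceeds the screen).
#' @export
saturation_report <- function(dataset, metrics = NULL,
                              cfg = analysis_config()) {
  stopifnot(inherits(dataset, "roi_dataset"))
  if (is.null(metrics)) metrics <- compute_response_metrics(dataset, cfg)
  screened <- metrics[metrics$dff_pct > cfg$saturation_dff_threshold_pct, ]
  if (!nrow(screened)) {
    return(data.frame(roi_id = character(), stimulus_label = character(),
                      dff_pct = numeric(), max_rise_frame = integer(),
                      frames_to_nonpositive = integer(), flagged = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(screened)), function(i) {
    roi <- screened$roi_id[i]
    lab <- screened$stimulus_label[i]
    avg <- average_trials(dataset$traces[[roi]][[lab]])
    chk <- saturation_check(avg, cfg)
    cbind(data.frame(roi_id = roi, stimulus_label = lab,
                     dff_pct = screened$dff_pct[i],
                     stringsAsFactors = FALSE), chk)
  }))
  rownames(out) <- NULL
  out
}
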