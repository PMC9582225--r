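#' Build a concentration-series table
#'
#' Joins response metrics with the schedule's odorant/concentration labels
#' and applies the inclusion rule of the concentration analysis: a
#' glomerulus enters the series for an odorant only if it responds to at
#' least one concentration of that odorant. At concentrations where an
#' included glomerulus did not respond, its amplitude is an explicit zero.
#'
#' @param metrics Output of [compute_response_metrics()].
#' @param schedule The matching [stim_schedule()] (blank excluded
#'   automatically); concentrations must be a shared ladder per odorant.
#' @return data.frame `roi_id, mouse_id, odorant, concentration, dff,
#'   responded, latency_s, time_to_peak_s, integral_pct_s` containing
#'   included glomeruli only, ordered by concentration within ROI x odorant.
#' @export
concentration_series <- function(metrics, schedule) {
  sched <- schedule[!schedule$is_blank, , drop = FALSE]
  m <- merge(metrics,
             sched[, c("stimulus_label", "odorant", "concentration")],
             by = "stimulus_label")
  if (!nrow(m)) stop("no odorant stimuli in metrics", call. = FALSE)
  m$dff <- ifelse(m$is_responder, pmax(m$dff_blanksub_pct, 0), 0)
  m$responded <- m$is_responder
  keys <- interaction(m$roi_id, m$odorant, drop = TRUE)
  include <- ave(m$responded, keys, FUN = any) > 0
  out <- m[include, c("roi_id", "mouse_id", "odorant", "concentration",
                      "dff", "responded", "latency_s", "time_to_peak_s",
                      "integral_pct_s")]
  out <- out[order(out$roi_id, out$odorant, out$concentration), ]
  rownames(out) <- NULL
  out
}

#' Per-mouse mean response amplitude by concentration
#'
#' Mean blank-subtracted dF/F per mouse x odorant x concentration over all
#' included glomeruli, zeros included for concentrations at which an
#' included glomerulus did not respond.
#'
#' @param series Output of [concentration_series()].
#' @return data.frame `mouse_id, odorant, concentration, mean_dff,
#'   n_glomeruli`.
#' @export
mouse_mean_amplitude <- function(series) {
  agg <- do.call(rbind, lapply(
    split(series,
          list(series$mouse_id, series$odorant, series$concentration),
          drop = TRUE),
    function(d) data.frame(
      mouse_id = d$mouse_id[1], odorant = d$odorant[1],
      concentration = d$concentration[1], mean_dff = mean(d$dff),
      n_glomeruli = nrow(d), stringsAsFactors = FALSE
    )))
  agg <- agg[order(agg$mouse_id, agg$odorant, agg$concentration), ]
  rownames(agg) <- NULL
  agg
}

#' Normalize amplitudes to the top concentration
#'
#' Divides each glomerulus's amplitudes by its response to the highest
#' concentration of that odorant, so every odorant-responsive glomerulus
#' contributes equally to per-mouse means. Glomeruli that do not respond
#' (or respond with non-positive amplitude) at the top concentration are
#' excluded for that odorant, with a message reporting the count.
#'
#' @param series Output of [concentration_series()].
#' @return `series` restricted to eligible glomeruli, with a `norm_dff`
#'   column (1 at the top concentration by construction).
#' @export
normalize_to_top <- function(series) {
  top <- max(series$concentration)
  keys <- interaction(series$roi_id, series$odorant, drop = TRUE)
  parts <- split(series, keys)
  excluded <- 0L
  parts <- lapply(parts, function(d) {
    i_top <- which(d$concentration == top)
    if (!length(i_top) || !d$responded[i_top] || d$dff[i_top] <= 0) {
      excluded <<- excluded + 1L
      return(NULL)
    }
    d$norm_dff <- d$dff / d$dff[i_top]
    d
  })
  if (excluded > 0) {
    message(sprintf(
      "normalize_to_top: %d glomerulus-odorant series excluded (no positive response at the top concentration)",
      excluded))
  }
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    stop("no glomerulus responds at the top concentration", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Per-mouse mean normalized amplitude by concentration
#'
#' @param series Output of [normalize_to_top()].
#' @return data.frame `mouse_id, odorant, concentration, mean_norm_dff,
#'   n_glomeruli`.
#' @export
mouse_mean_normalized <- function(series) {
  agg <- do.call(rbind, lapply(
    split(series,
          list(series$mouse_id, series$odorant, series$concentration),
          drop = TRUE),
    function(d) data.frame(
      mouse_id = d$mouse_id[1], odorant = d$odorant[1],
      concentration = d$concentration[1], mean_norm_dff = mean(d$norm_dff),
      n_glomeruli = nrow(d), stringsAsFactors = FALSE
    )))
  agg <- agg[order(agg$mouse_id, agg$odorant, agg$concentration), ]
  rownames(agg) <- NULL
  agg
}

#' Ascending concentration-pair differences
#'
#' For each adjacent ascending pair of the concentration ladder (e.g.
#' 0.5-1%, 1-5%, 5-10%) and each glomerulus responding at both
#' concentrations of the pair, computes metric(high) - metric(low), then the
#' per-mouse mean over glomeruli for which the difference is available.
#' With this sign convention a latency shortening at higher concentration is
#' negative.
#'
#' @param series Output of [concentration_series()].
#' @param metric One of `"dff"`, `"latency"`, `"time_to_peak"`,
#'   `"integral"`.
#' @return List with `per_glomerulus` (one row per ROI x odorant x pair) and
#'   `per_mouse` (mean and n per mouse x odorant x pair).
#' @export
ascending_pair_diffs <- function(series,
                                 metric = c("dff", "latency",
                                            "time_to_peak", "integral")) {
  metric <- match.arg(metric)
  col <- switch(metric, dff = "dff", latency = "latency_s",
                time_to_peak = "time_to_peak_s", integral = "integral_pct_s")
  ladder <- sort(unique(series$concentration))
  if (length(ladder) < 2) stop("ladder must have >= 2 concentrations",
                               call. = FALSE)
  pairs <- data.frame(c_low = ladder[-length(ladder)], c_high = ladder[-1])
  keys <- interaction(series$roi_id, series$odorant, drop = TRUE)
  per_glom <- do.call(rbind, lapply(split(series, keys), function(d) {
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
      lo <- d[d$concentration == pairs$c_low[k] & d$responded, ]
      hi <- d[d$concentration == pairs$c_high[k] & d$responded, ]
      if (nrow(lo) != 1 || nrow(hi) != 1) return(NULL)
      data.frame(roi_id = d$roi_id[1], mouse_id = d$mouse_id[1],
                 odorant = d$odorant[1],
                 pair = sprintf("%g-%g", pairs$c_low[k], pairs$c_high[k]),
                 c_low = pairs$c_low[k], c_high = pairs$c_high[k],
                 metric = metric, diff = hi[[col]] - lo[[col]],
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(per_glom)) {
    return(list(per_glomerulus = data.frame(), per_mouse = data.frame()))
  }
  rownames(per_glom) <- NULL
  per_mouse <- do.call(rbind, lapply(
    split(per_glom, list(per_glom$mouse_id, per_glom$odorant, per_glom$pair),
          drop = TRUE),
    function(d) data.frame(
      mouse_id = d$mouse_id[1], odorant = d$odorant[1], pair = d$pair[1],
      c_low = d$c_low[1], c_high = d$c_high[1], metric = metric,
      mean_diff = mean(d$diff), n_glomeruli = nrow(d),
      stringsAsFactors = FALSE
    )))
  rownames(per_mouse) <- NULL
  list(per_glomerulus = per_glom, per_mouse = per_mouse)
}
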