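#' Lifetime sparseness
#'
#' Lifetime sparseness S_L measures how concentrated a unit's responses are
#' across an n-stimulus panel:
#'
#' \deqn{S_L = \frac{1 - (\sum_i r_i / n)^2 / (\sum_i r_i^2 / n)}{1 - 1/n}}
#'
#' with r_i the (non-negative) response amplitude to stimulus i. S_L = 0 for
#' a unit responding equally to all stimuli and S_L = 1 for a unit responding
#' to exactly one.
#'
#' @param r Numeric vector of non-negative response amplitudes, length >= 2,
#'   at least one positive.
#' @return S_L in `[0, 1]`.
#' @export
#' @examples
#' lifetime_sparseness(rep(5, 7))            # 0
#' lifetime_sparseness(c(5, rep(0, 6)))      # 1
lifetime_sparseness <- function(r) {
  n <- length(r)
  if (n < 2) stop("S_L requires >= 2 stimuli", call. = FALSE)
  if (any(!is.finite(r))) stop("non-finite response amplitude", call. = FALSE)
  if (any(r < 0)) stop("S_L is defined for non-negative amplitudes",
                       call. = FALSE)
  if (all(r == 0)) {
    stop("S_L is undefined for an all-zero response vector", call. = FALSE)
  }
  (1 - (sum(r) / n)^2 / (sum(r^2) / n)) / (1 - 1 / n)
}

#' Odorant tuning profiles per ROI
#'
#' Builds, for every ROI, the blank-subtracted response vector over the
#' odorant panel (floored at 0, with non-responders contributing 0), the
#' responsive-odorant count and the lifetime sparseness. S_L is reported
#' only for ROIs responding to at least one odorant.
#'
#' @param metrics Output of [compute_response_metrics()].
#' @param schedule The matching [stim_schedule()]; blank stimuli are
#'   excluded from the panel.
#' @return data.frame `roi_id, mouse_id, n_odorants, n_responsive,
#'   lifetime_sparseness` plus an attribute `"response_vectors"` (matrix,
#'   ROI x odorant).
#' @export
tuning_profiles <- function(metrics, schedule) {
  sched <- schedule[!schedule$is_blank, , drop = FALSE]
  if (nrow(sched) < 2) stop("tuning requires a panel of >= 2 odorant stimuli",
                            call. = FALSE)
  m <- metrics[metrics$stimulus_label %in% sched$stimulus_label, ]
  labels <- sched$stimulus_label
  rois <- unique(m$roi_id)
  vecs <- matrix(0, nrow = length(rois), ncol = length(labels),
                 dimnames = list(rois, labels))
  out <- do.call(rbind, lapply(rois, function(roi) {
    d <- m[m$roi_id == roi, ]
    r <- stats::setNames(rep(0, length(labels)), labels)
    resp <- d$is_responder
    r[d$stimulus_label] <- ifelse(resp, pmax(d$dff_blanksub_pct, 0), 0)
    vecs[roi, ] <<- r
    n_responsive <- sum(resp & d$dff_blanksub_pct > 0)
    s_l <- if (any(r > 0)) lifetime_sparseness(r) else NA_real_
    data.frame(roi_id = roi, mouse_id = d$mouse_id[1],
               n_odorants = length(labels), n_responsive = n_responsive,
               lifetime_sparseness = s_l, stringsAsFactors = FALSE)
  }))
  attr(out, "response_vectors") <- vecs
  out
}

#' Per-mouse mean of a per-ROI statistic
#'
#' Arithmetic mean of a per-ROI statistic within each mouse; ROIs with a
#' missing value (e.g. undefined sparseness) are dropped, and mice left with
#' no qualifying ROI are excluded with a warning.
#'
#' @param values Numeric per-ROI statistic.
#' @param mouse_id Mouse assignment, parallel to `values`.
#' @return data.frame `mouse_id, mean_value, n_rois`.
#' @export
per_mouse_mean <- function(values, mouse_id) {
  stopifnot(length(values) == length(mouse_id))
  keep <- is.finite(values)
  dropped <- setdiff(unique(mouse_id), unique(mouse_id[keep]))
  if (length(dropped)) {
    warning(sprintf("mouse/mice with no qualifying ROIs excluded: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  v <- values[keep]
  g <- mouse_id[keep]
  means <- tapply(v, g, mean)
  data.frame(mouse_id = names(means), mean_value = as.numeric(means),
             n_rois = as.integer(table(g)[names(means)]),
             stringsAsFactors = FALSE, row.names = NULL)
}
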