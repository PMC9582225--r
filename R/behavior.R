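#' Score a two-choice odor detection trial
#'
#' Investigation ratio = time sniffing the odor stimulus divided by total
#' sniffing time (odor + mineral oil). A ratio of 0.5 indicates no
#' detection; a ratio at or above the detection threshold (default 0.75,
#' i.e. odor sniffing three times mineral-oil sniffing) indicates
#' significant odor detection. If no sniffing occurred at all the ratio is
#' undefined and the trial scores as not detected.
#'
#' @param sniff_odor_s Seconds spent sniffing the odor stimulus.
#' @param sniff_mo_s Seconds spent sniffing the mineral-oil control.
#' @param cfg An [analysis_config()].
#' @return One-row data.frame `sniff_odor_s, sniff_mo_s,
#'   investigation_ratio, detected`.
#' @export
#' @examples
#' score_two_choice(30, 10)  # ratio 0.75, detected
score_two_choice <- function(sniff_odor_s, sniff_mo_s,
                             cfg = analysis_config()) {
  if (!is.finite(sniff_odor_s) || !is.finite(sniff_mo_s) ||
      sniff_odor_s < 0 || sniff_mo_s < 0) {
    stop("sniffing durations must be finite and non-negative", call. = FALSE)
  }
  total <- sniff_odor_s + sniff_mo_s
  if (total == 0) {
    message("no sniffing recorded; investigation ratio undefined")
    ratio <- NA_real_
    detected <- FALSE
  } else {
    ratio <- sniff_odor_s / total
    detected <- ratio >= cfg$detection_ratio_threshold
  }
  data.frame(sniff_odor_s = sniff_odor_s, sniff_mo_s = sniff_mo_s,
             investigation_ratio = ratio, detected = detected)
}

#' Score a habituation-dishabituation series
#'
#' Takes the 4-odorant x 3-trial sniffing-time grid (odorants presented in a
#' fixed order, water first) and computes, per odorant, habituation =
#' sniff(trial 1) - sniff(trial 2), and per odorant transition,
#' dishabituation = sniff(next odorant, trial 1) - sniff(previous odorant,
#' trial 3). Per-subject summaries are the arithmetic means across odorants
#' (habituation) and across the three transitions (dishabituation).
#'
#' @param sniff_s Numeric matrix or data.frame of sniffing times, rows =
#'   odorants in presentation order (rownames used as odorant labels),
#'   columns = trials 1..3.
#' @return List with `habituation_s` (named per odorant),
#'   `dishabituation_s` (named per transition), `mean_habituation_s`,
#'   `mean_dishabituation_s`.
#' @export
score_habituation <- function(sniff_s) {
  sniff_s <- as.matrix(sniff_s)
  if (ncol(sniff_s) != 3) {
    stop("habituation scoring requires exactly 3 trials per odorant",
         call. = FALSE)
  }
  if (nrow(sniff_s) < 2) {
    stop("habituation scoring requires >= 2 odorants", call. = FALSE)
  }
  if (any(!is.finite(sniff_s))) {
    bad <- which(!is.finite(sniff_s), arr.ind = TRUE)[1, ]
    stop(sprintf("missing sniffing time for odorant '%s', trial %d",
                 rownames(sniff_s)[bad[1]] %||% as.character(bad[1]),
                 bad[2]), call. = FALSE)
  }
  odorants <- rownames(sniff_s) %||% paste0("odorant", seq_len(nrow(sniff_s)))
  hab <- sniff_s[, 1] - sniff_s[, 2]
  names(hab) <- odorants
  n <- nrow(sniff_s)
  dishab <- sniff_s[-1, 1] - sniff_s[-n, 3]
  names(dishab) <- paste(odorants[-n], odorants[-1], sep = "->")
  list(habituation_s = hab, dishabituation_s = dishab,
       mean_habituation_s = mean(hab), mean_dishabituation_s = mean(dishab))
}

#' Score a buried-food trial
#'
#' A mouse passes if it locates the buried food within the timeout
#' (default 600 s). Failures carry the timeout as a censored latency.
#' Acclimation digging time is carried through for the motivation control.
#'
#' @param latency_s Time to locate the food, seconds; values beyond the
#'   timeout (or `Inf`) denote failure.
#' @param acclimation_digging_s Seconds spent digging during acclimation.
#' @param cfg An [analysis_config()].
#' @return One-row data.frame `latency_s` (censored at the timeout),
#'   `passed, acclimation_digging_s`.
#' @export
score_buried_food <- function(latency_s, acclimation_digging_s = NA_real_,
                              cfg = analysis_config()) {
  if (is.na(latency_s) || latency_s <= 0) {
    stop("latency_s must be positive (use Inf or > timeout for failures)",
         call. = FALSE)
  }
  passed <- latency_s <= cfg$buried_food_timeout_s
  data.frame(latency_s = min(latency_s, cfg$buried_food_timeout_s),
             passed = passed,
             acclimation_digging_s = acclimation_digging_s)
}

#' Score a full behavioral event table
#'
#' Dispatches each assay of a long-format behavior table (see
#' [read_behavior_table()]) to its scorer and returns one row per subject
#' with every derived value.
#'
#' @param behavior data.frame in `behavior.csv` layout.
#' @param cfg An [analysis_config()].
#' @return data.frame keyed by `assay, subject_id, group` with assay-specific
#'   score columns (`NA` where not applicable).
#' @export
score_behavior_table <- function(behavior, cfg = analysis_config()) {
  rows <- list()
  for (assay in unique(behavior$assay)) {
    d <- behavior[behavior$assay == assay, ]
    for (subj in unique(d$subject_id)) {
      ds <- d[d$subject_id == subj, ]
      grp <- ds$group[1]
      row <- data.frame(assay = assay, subject_id = subj, group = grp,
                        stringsAsFactors = FALSE)
      if (assay == "two_choice") {
        odor <- ds$value_s[ds$odorant == "odor"]
        mo <- ds$value_s[ds$odorant == "mineral_oil"]
        if (length(odor) != 1 || length(mo) != 1) {
          stop(sprintf("two_choice subject %s needs one odor and one mineral_oil row",
                       subj), call. = FALSE)
        }
        row <- cbind(row, score_two_choice(odor, mo, cfg))
      } else if (assay == "buried_food") {
        lat <- ds$value_s[ds$odorant == "latency"]
        dig <- ds$value_s[ds$odorant == "digging"]
        if (length(lat) != 1) {
          stop(sprintf("buried_food subject %s needs one latency row", subj),
               call. = FALSE)
        }
        row <- cbind(row, score_buried_food(
          lat, if (length(dig) == 1) dig else NA_real_, cfg))
      } else if (assay == "habituation") {
        odorants <- unique(ds$odorant)
        mat <- matrix(NA_real_, nrow = length(odorants), ncol = 3,
                      dimnames = list(odorants, NULL))
        for (i in seq_len(nrow(ds))) {
          mat[ds$odorant[i], ds$trial_index[i]] <- ds$value_s[i]
        }
        sc <- score_habituation(mat)
        row$mean_habituation_s <- sc$mean_habituation_s
        row$mean_dishabituation_s <- sc$mean_dishabituation_s
      } else {
        stop(sprintf("unknown assay '%s'", assay), call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind_fill, list(rows))
  rownames(out) <- NULL
  out
}
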