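#' Generate a synthetic behavioral event table
#'
#' Simulates the three assays for a set of subject groups with known ground
#' truth:
#' * habituation-dishabituation: per odorant block the three sniffing times
#'   follow `(t1, t1 * rho, t1 - J)` plus truncated Gaussian noise, so the
#'   recovered habituation is `t1 * (1 - rho)` and the recovered
#'   dishabituation is `J` exactly at zero noise;
#' * two-choice detection: mineral-oil sniffing is a baseline duration and
#'   odor sniffing is `preference_ratio` times it (ratio 3 reproduces the
#'   0.75 detection threshold exactly at zero noise);
#' * buried food: log-normal search latencies (subjects whose draw exceeds
#'   the timeout fail) and Gaussian acclimation digging times.
#'
#' @param n_subjects_per_group Subjects per group.
#' @param groups Named list of group parameter lists with fields
#'   `t1` (first-trial sniffing, s), `rho` (habituation decay factor in
#'   `[0, 1]`), `J` (dishabituation jump, s), `preference_ratio`
#'   (odor : mineral-oil sniffing ratio), `buried_meanlog`, `buried_sdlog`
#'   (log-latency of the buried-food search) and `digging_mean_s`.
#' @param sniff_noise_sd Gaussian noise SD on sniffing times (s); times are
#'   floored at 0.
#' @param mo_base_s Baseline mineral-oil sniffing time (s).
#' @param odorant_order Habituation odorant sequence (fixed order, water
#'   first).
#' @param seed Integer seed (single stream, subject-major order).
#' @return List with `behavior` (long table in `behavior.csv` layout) and
#'   `truth` (per-subject generating parameters and true detection status).
#' @export
generate_behavior_dataset <- function(
    n_subjects_per_group = 12L,
    groups = list(
      saline = list(t1 = 10, rho = 0.4, J = 6, preference_ratio = 3,
                    buried_meanlog = log(60), buried_sdlog = 0.5,
                    digging_mean_s = 20),
      mmz_3d = list(t1 = 4, rho = 1.0, J = 0, preference_ratio = 1,
                    buried_meanlog = log(900), buried_sdlog = 0.3,
                    digging_mean_s = 20)),
    sniff_noise_sd = 1,
    mo_base_s = 20,
    odorant_order = c("water", "almond", "mint", "vanilla"),
    seed = 1L) {
  if (n_subjects_per_group < 1) stop("need >= 1 subject per group",
                                     call. = FALSE)
  for (g in names(groups)) {
    p <- groups[[g]]
    if (p$rho < 0 || p$rho > 1) {
      stop(sprintf("group '%s': rho must lie in [0, 1]", g), call. = FALSE)
    }
    if (p$t1 <= 0 || p$J < 0 || p$preference_ratio < 0) {
      stop(sprintf("group '%s': invalid t1/J/preference_ratio", g),
           call. = FALSE)
    }
  }
  if (sniff_noise_sd < 0) stop("sniff_noise_sd must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))

  noisy <- function(x) pmax(0, x + if (sniff_noise_sd > 0)
    stats::rnorm(length(x), sd = sniff_noise_sd) else 0)

  rows <- list()
  truth <- list()
  for (g in names(groups)) {
    p <- groups[[g]]
    for (s in seq_len(n_subjects_per_group)) {
      subj <- sprintf("%s_s%02d", g, s)
      # habituation: 4 odorants x 3 trials, model (t1, t1*rho, t1 - J)
      for (od in odorant_order) {
        vals <- noisy(c(p$t1, p$t1 * p$rho, p$t1 - p$J))
        rows[[length(rows) + 1L]] <- data.frame(
          assay = "habituation", subject_id = subj, group = g,
          trial_index = 1:3, odorant = od, value_s = vals,
          stringsAsFactors = FALSE)
      }
      # two-choice: odor = preference_ratio x mineral-oil baseline
      mo <- noisy(mo_base_s)
      od_t <- noisy(mo_base_s * p$preference_ratio)
      rows[[length(rows) + 1L]] <- data.frame(
        assay = "two_choice", subject_id = subj, group = g,
        trial_index = 1L, odorant = c("odor", "mineral_oil"),
        value_s = c(od_t, mo), stringsAsFactors = FALSE)
      # buried food
      lat <- stats::rlnorm(1, p$buried_meanlog, p$buried_sdlog)
      dig <- pmax(0, stats::rnorm(1, p$digging_mean_s, 5))
      rows[[length(rows) + 1L]] <- data.frame(
        assay = "buried_food", subject_id = subj, group = g,
        trial_index = 1L, odorant = c("latency", "digging"),
        value_s = c(lat, dig), stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        subject_id = subj, group = g, t1 = p$t1, rho = p$rho, J = p$J,
        preference_ratio = p$preference_ratio,
        true_habituation_s = p$t1 * (1 - p$rho),
        true_dishabituation_s = p$J,
        true_detected = p$preference_ratio / (1 + p$preference_ratio) >= 0.75,
        true_buried_latency_s = lat,
        stringsAsFactors = FALSE)
    }
  }
  list(behavior = do.call(rbind, rows), truth = do.call(rbind, truth),
       seed = as.integer(seed))
}
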