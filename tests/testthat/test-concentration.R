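# Helper: hand-built metrics table for one odorant over the 4-step ladder.
conc_metrics <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(roi_id = r$roi, mouse_id = r$mouse,
               stimulus_label = sprintf("eb_%gpct", r$conc * 100),
               dff_blanksub_pct = r$dff, is_responder = r$resp,
               latency_s = r$lat %||% NA_real_,
               time_to_peak_s = r$ttp %||% NA_real_,
               integral_pct_s = r$int %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
  df
}

conc_schedule <- function(ladder = c(0.005, 0.01, 0.05, 0.10)) {
  make_schedule(sprintf("eb_%gpct", ladder * 100),
                odorants = "eb", concentrations = ladder)
}

test_that("series inclusion requires a response at >= 1 concentration", {
  sched <- conc_schedule()
  rows <- list(
    list(roi = "g1", mouse = "m1", conc = 0.005, dff = 0, resp = FALSE),
    list(roi = "g1", mouse = "m1", conc = 0.10, dff = 12, resp = TRUE),
    list(roi = "g2", mouse = "m1", conc = 0.005, dff = 0, resp = FALSE),
    list(roi = "g2", mouse = "m1", conc = 0.10, dff = 0, resp = FALSE))
  ser <- concentration_series(conc_metrics(rows), sched)
  expect_setequal(unique(ser$roi_id), "g1")       # g2 never responds
  # the non-responding concentration of an included glomerulus is a zero
  expect_equal(ser$dff[ser$concentration == 0.005], 0)
  expect_true(all(tapply(ser$responded,
                         interaction(ser$roi_id, ser$odorant), any)))
})

test_that("per-mouse amplitude means include zeros for non-responders", {
  sched <- conc_schedule(c(0.01, 0.10))
  rows <- list(
    list(roi = "g1", mouse = "m1", conc = 0.01, dff = 10, resp = TRUE),
    list(roi = "g1", mouse = "m1", conc = 0.10, dff = 20, resp = TRUE),
    list(roi = "g2", mouse = "m1", conc = 0.01, dff = 0, resp = FALSE),
    list(roi = "g2", mouse = "m1", conc = 0.10, dff = 14, resp = TRUE))
  mm <- mouse_mean_amplitude(concentration_series(conc_metrics(rows), sched))
  expect_equal(mm$mean_dff[mm$concentration == 0.01], 5)   # (10 + 0) / 2
  expect_equal(mm$mean_dff[mm$concentration == 0.10], 17)  # (20 + 14) / 2
})

test_that("top-concentration normalization rescales per glomerulus", {
  sched <- conc_schedule()
  rows <- list(
    list(roi = "g1", mouse = "m1", conc = 0.005, dff = 2, resp = TRUE),
    list(roi = "g1", mouse = "m1", conc = 0.01, dff = 4, resp = TRUE),
    list(roi = "g1", mouse = "m1", conc = 0.05, dff = 8, resp = TRUE),
    list(roi = "g1", mouse = "m1", conc = 0.10, dff = 10, resp = TRUE),
    list(roi = "g2", mouse = "m1", conc = 0.005, dff = 3, resp = TRUE),
    list(roi = "g2", mouse = "m1", conc = 0.01, dff = 5, resp = TRUE),
    list(roi = "g2", mouse = "m1", conc = 0.05, dff = 0, resp = FALSE),
    list(roi = "g2", mouse = "m1", conc = 0.10, dff = 6, resp = TRUE))
  ser <- concentration_series(conc_metrics(rows), sched)
  nrm <- normalize_to_top(ser)
  g1 <- nrm[nrm$roi_id == "g1", ]
  expect_equal(g1$norm_dff[order(g1$concentration)],
               c(0.2, 0.4, 0.8, 1.0))
  # a non-responder at an intermediate concentration normalizes to 0
  g2 <- nrm[nrm$roi_id == "g2", ]
  expect_equal(g2$norm_dff[g2$concentration == 0.05], 0)
  expect_equal(g2$norm_dff[g2$concentration == 0.10], 1)

  # a glomerulus without a positive top-concentration response is excluded
  rows2 <- c(rows, list(
    list(roi = "g3", mouse = "m1", conc = 0.005, dff = 7, resp = TRUE),
    list(roi = "g3", mouse = "m1", conc = 0.10, dff = 0, resp = FALSE)))
  expect_message(nrm2 <- normalize_to_top(
    concentration_series(conc_metrics(rows2), sched)), "excluded")
  expect_false("g3" %in% nrm2$roi_id)

  # per-mouse mean normalized amplitude is invariant to per-glomerulus gains
  set.seed(77)
  ser_gained <- ser
  for (roi in unique(ser$roi_id)) {
    gain <- runif(1, 0.2, 5)
    ser_gained$dff[ser_gained$roi_id == roi] <-
      ser_gained$dff[ser_gained$roi_id == roi] * gain
  }
  expect_equal(mouse_mean_normalized(normalize_to_top(ser_gained))$mean_norm_dff,
               mouse_mean_normalized(nrm)$mean_norm_dff, tolerance = 1e-12)
})

test_that("ascending pair differences follow the respond-at-both rule", {
  sched <- conc_schedule(c(0.005, 0.01))
  rows <- list(
    list(roi = "g1", mouse = "m1", conc = 0.005, dff = 5, resp = TRUE,
         lat = 0.8),
    list(roi = "g1", mouse = "m1", conc = 0.01, dff = 9, resp = TRUE,
         lat = 0.5),
    # responds at only one concentration: contributes to no pair
    list(roi = "g2", mouse = "m1", conc = 0.005, dff = 0, resp = FALSE),
    list(roi = "g2", mouse = "m1", conc = 0.01, dff = 7, resp = TRUE,
         lat = 0.6))
  ser <- concentration_series(conc_metrics(rows), sched)
  pd <- ascending_pair_diffs(ser, "latency")
  expect_equal(nrow(pd$per_glomerulus), 1)
  expect_equal(pd$per_glomerulus$diff, -0.3)   # 0.5 - 0.8: shortening < 0
  expect_equal(pd$per_mouse$n_glomeruli, 1)

  # strictly monotone synthetic metric gives single-signed diffs everywhere
  sched4 <- conc_schedule()
  ladder <- c(0.005, 0.01, 0.05, 0.10)
  rows3 <- unlist(lapply(c("a", "b", "c"), function(roi) {
    lapply(seq_along(ladder), function(i) {
      list(roi = roi, mouse = "m1", conc = ladder[i],
           dff = 2 * i + match(roi, c("a", "b", "c")), resp = TRUE)
    })
  }), recursive = FALSE)
  pd3 <- ascending_pair_diffs(
    concentration_series(conc_metrics(rows3), sched4), "dff")
  expect_true(all(pd3$per_glomerulus$diff > 0))
  expect_equal(sort(unique(pd3$per_glomerulus$pair)),
               sort(c("0.005-0.01", "0.01-0.05", "0.05-0.1")))
})

test_that("preset concentration-response contrast emerges at small scale", {
  run_preset <- function(preset, seed) {
    cfg <- glom_gen_config(preset, n_mice = 2, n_glomeruli_per_mouse = 15,
                           odorant_panel = "eb", tuning_sparsity = 1,
                           noise_sd = 1, seed = seed)
    gen <- generate_glom_dataset(cfg)
    m <- compute_response_metrics(gen$dataset)
    ser <- concentration_series(m, gen$dataset$schedule)
    pd <- ascending_pair_diffs(ser, "dff")
    sapply(split(pd$per_glomerulus$diff, pd$per_glomerulus$pair), mean)
  }
  mature <- run_preset("mature_like", 31)
  immature <- run_preset("immature_like", 31)
  # mature-like: large first step, negligible last step
  expect_gt(mature[["0.005-0.01"]], 10 * abs(mature[["0.05-0.1"]]))
  # immature-like: every step clearly positive
  expect_true(all(immature > 1))
})
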