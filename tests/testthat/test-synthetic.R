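test_that("generation is byte-for-byte deterministic in the seed", {
  cfg <- glom_gen_config("mature_like", n_mice = 1,
                         n_glomeruli_per_mouse = 3,
                         odorant_panel = c("eb", "hex"), seed = 12)
  a <- generate_glom_dataset(cfg)
  b <- generate_glom_dataset(cfg)
  expect_identical(a$truth, b$truth)
  td <- withr::local_tempdir()
  write_results(as_trace_table(a$dataset), file.path(td, "a.csv"))
  write_results(as_trace_table(b$dataset), file.path(td, "b.csv"))
  expect_identical(readBin(file.path(td, "a.csv"), "raw", 1e7),
                   readBin(file.path(td, "b.csv"), "raw", 1e7))
  c_ <- generate_glom_dataset(glom_gen_config("mature_like", n_mice = 1,
                                              n_glomeruli_per_mouse = 3,
                                              odorant_panel = c("eb", "hex"),
                                              seed = 13))
  expect_false(identical(a$dataset$traces, c_$dataset$traces))

  e1 <- generate_epsc_dataset(2, seed = 4, sweep_length_s = 0.5)
  e2 <- generate_epsc_dataset(2, seed = 4, sweep_length_s = 0.5)
  expect_identical(e1$truth, e2$truth)
  expect_identical(e1$sweep_sets[[1]]$sweeps, e2$sweep_sets[[1]]$sweeps)

  b1 <- generate_behavior_dataset(3, seed = 9)
  b2 <- generate_behavior_dataset(3, seed = 9)
  expect_identical(b1$behavior, b2$behavior)
})

test_that("every emitted record joins exactly one ground-truth row", {
  cfg <- glom_gen_config("immature_like", n_mice = 2,
                         n_glomeruli_per_mouse = 4,
                         odorant_panel = c("eb", "hex"), seed = 21)
  gen <- generate_glom_dataset(cfg)
  emitted <- expand.grid(roi_id = names(gen$dataset$traces),
                         stimulus_label = gen$dataset$schedule$stimulus_label,
                         stringsAsFactors = FALSE)
  joined <- merge(emitted, gen$truth, by = c("roi_id", "stimulus_label"))
  expect_equal(nrow(joined), nrow(emitted))
  expect_equal(anyDuplicated(gen$truth[, c("roi_id", "stimulus_label")]), 0)

  ep <- generate_epsc_dataset(3, seed = 22, sweep_length_s = 0.5)
  keys <- vapply(ep$sweep_sets,
                 function(s) paste(s$cell_id, s$condition_label),
                 character(1))
  expect_setequal(keys, paste(ep$truth$cell_id, ep$truth$condition_label))

  bh <- generate_behavior_dataset(4, seed = 23)
  expect_setequal(unique(bh$behavior$subject_id), bh$truth$subject_id)
})

test_that("configuration invariants are enforced", {
  expect_error(glom_gen_config(rise_tau_s = 2, decay_tau_s = 1), "tau")
  expect_error(glom_gen_config(noise_sd = -1), "noise_sd")
  expect_error(glom_gen_config(tuning_sparsity = 1.5), "tuning_sparsity")
  expect_error(glom_gen_config(ceiling = 50), "ceiling")
  expect_error(glom_gen_config(ec50 = 30), "ladder")
  expect_error(generate_epsc_dataset(2, amplitude_range_pA = c(10, 50)),
               "negative")
  expect_error(generate_epsc_dataset(2, jitter_range_s = c(-1e-3, 0)),
               "non-negative")
  expect_error(generate_behavior_dataset(
    2, groups = list(g = list(t1 = 10, rho = 1.4, J = 0,
                              preference_ratio = 1, buried_meanlog = 1,
                              buried_sdlog = 1, digging_mean_s = 1))),
    "rho")
})

test_that("zero-noise generation closes the loop through the pipeline", {
  # calcium: configured amplitude recovered exactly, latency within a frame
  cfg <- glom_gen_config("immature_like", n_mice = 1,
                         n_glomeruli_per_mouse = 2, odorant_panel = "eb",
                         tuning_sparsity = 1, gain_sdlog = 0, noise_sd = 0,
                         mechanosensory_blank_amp_pct = 0, seed = 30)
  gen <- generate_glom_dataset(cfg)
  m <- compute_response_metrics(gen$dataset)
  j <- merge(m, gen$truth, by = c("roi_id", "stimulus_label"))
  odor <- j[j$odorant != "blank", ]
  expect_equal(odor$dff_pct, odor$true_amplitude_pct, tolerance = 1e-12)
  expect_true(all(odor$is_responder == odor$true_responder))
  frame <- 1 / cfg$sampling_rate_hz
  expect_true(all(abs(odor$latency_s - odor$true_latency_s) <= frame + 1e-9))

  # EPSC: configured peak to 1e-9, zero jitter
  ep <- generate_epsc_dataset(3, amplitude_range_pA = c(-80, -30),
                              onset_range_s = c(1e-3, 1.5e-3),
                              jitter_range_s = c(0, 0),
                              noise_range_pA = c(0, 0),
                              sweep_length_s = 0.5, seed = 31)
  met <- do.call(rbind, lapply(ep$sweep_sets, epsc_kinetics))
  cmp <- merge(met, ep$truth, by = c("cell_id", "condition_label"))
  expect_equal(cmp$peak_amplitude_pA, cmp$true_amplitude_pA,
               tolerance = 1e-9)
  expect_equal(cmp$jitter_s, rep(0, 3))
})
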