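#!/usr/bin/env Rscript

# Step 1: simulate the three data modalities with known ground truth.
#
# Emulates the study design the package analyses: 20 s imaging trials
# (4 s baseline, 1 s odorant, 15 s post-stimulus, 3 trials per stimulus)
# over a 4-step concentration ladder for two OSN populations -- a
# "mature_like" preset whose amplitudes saturate by the 1% ladder step and
# an "immature_like" preset with graded amplitudes -- plus light-evoked
# EPSC sweeps and behavioral assay tables. Writes the stimulus schedule,
# per-glomerulus ground truth and small example trace tables under
# results/. Later steps regenerate the full datasets from the same seeds;
# generation is byte-for-byte deterministic.

library(osnresponse)

dir.create("results", showWarnings = FALSE)
seed <- 20260924

presets <- list(
  mature_like = glom_gen_config("mature_like", n_mice = 5,
                                n_glomeruli_per_mouse = 50, seed = seed),
  immature_like = glom_gen_config("immature_like", n_mice = 5,
                                  n_glomeruli_per_mouse = 50, seed = seed)
)

for (name in names(presets)) {
  gen <- generate_glom_dataset(presets[[name]])
  message(sprintf(
    "%s: %d ROIs x %d stimuli x %d trials (%.0f%% of glomerulus-odorant pairs tuned)",
    name, length(gen$dataset$traces), nrow(gen$dataset$schedule),
    presets[[name]]$trials_per_stimulus,
    100 * mean(gen$truth$true_amplitude_pct[gen$truth$odorant != "blank"] > 0)))
  truth_by_mouse <- aggregate(
    cbind(true_amplitude_pct, true_responder) ~ mouse_id + concentration,
    data = gen$truth[gen$truth$odorant != "blank", ], FUN = mean)
  names(truth_by_mouse)[3:4] <- c("mean_true_amplitude_pct",
                                  "true_responder_fraction")
  write_results(truth_by_mouse,
                sprintf("results/truth_summary_%s.csv", name))
}
write_results(as.data.frame(generate_glom_dataset(
  presets$immature_like)$dataset$schedule), "results/schedule.csv")

# one example glomerulus, single-trial trace table (inspection aid)
small <- glom_gen_config("immature_like", n_mice = 1,
                         n_glomeruli_per_mouse = 1, odorant_panel = "eb",
                         tuning_sparsity = 1, trials_per_stimulus = 1,
                         seed = seed)
write_results(as_trace_table(generate_glom_dataset(small)$dataset),
              "results/example_traces.csv")

ep <- generate_epsc_dataset(60, seed = seed)
message(sprintf("EPSC: %d cells, %d sweeps each, %d-sample sweeps",
                nrow(ep$truth), ncol(ep$sweep_sets[[1]]$sweeps),
                nrow(ep$sweep_sets[[1]]$sweeps)))
write_results(ep$truth, "results/truth_epsc.csv")

bh <- generate_behavior_dataset(12, seed = seed)
message(sprintf("behavior: %d subjects, %d event rows",
                nrow(bh$truth), nrow(bh$behavior)))
write_results(bh$truth, "results/truth_behavior.csv")

message("simulation parameters and ground truth written under results/")
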