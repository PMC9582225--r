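#!/usr/bin/env Rscript

# Step 3: odorant tuning -- responsive-odorant counts and lifetime
# sparseness per glomerulus, aggregated per mouse.
#
# Consumes the response metrics written by step 2 (recomputing them if the
# file is absent) and writes tuning.csv plus per-mouse means of both tuning
# statistics.

library(osnresponse)
dir.create("results", showWarnings = FALSE)
seed <- 20260924

panel7 <- c("ethyl_butyrate", "hexanal", "hexanone_2", "propionic_acid",
            "isoamyl_acetate", "methyl_salicylate", "acetophenone")
cfg <- glom_gen_config("immature_like", n_mice = 3,
                       n_glomeruli_per_mouse = 20, odorant_panel = panel7,
                       concentration_ladder = 0.01, seed = seed)
gen <- generate_glom_dataset(cfg)
metrics <- if (file.exists("results/response_metrics.csv")) {
  utils::read.csv("results/response_metrics.csv")
} else {
  compute_response_metrics(gen$dataset)
}

profiles <- tuning_profiles(metrics, gen$dataset$schedule)
write_results(profiles, "results/tuning.csv")

responsive <- profiles[profiles$n_responsive > 0, ]
message(sprintf(
  "%d of %d glomeruli respond to >= 1 odorant; median %d odorants, median S_L %.2f",
  nrow(responsive), nrow(profiles), median(responsive$n_responsive),
  median(responsive$lifetime_sparseness)))

per_mouse_sl <- per_mouse_mean(profiles$lifetime_sparseness,
                               profiles$mouse_id)
per_mouse_k <- per_mouse_mean(as.numeric(profiles$n_responsive),
                              profiles$mouse_id)
summary_tbl <- merge(per_mouse_sl, per_mouse_k, by = "mouse_id",
                     suffixes = c("_sparseness", "_n_responsive"))
write_results(summary_tbl, "results/tuning_per_mouse.csv")
message("per-mouse tuning means:")
for (i in seq_len(nrow(summary_tbl))) {
  message(sprintf("  %s: S_L %.3f, responsive odorants %.2f",
                  summary_tbl$mouse_id[i],
                  summary_tbl$mean_value_sparseness[i],
                  summary_tbl$mean_value_n_responsive[i]))
}
message("wrote results/tuning.csv and results/tuning_per_mouse.csv")
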