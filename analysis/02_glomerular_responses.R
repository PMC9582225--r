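#!/usr/bin/env Rscript

# Step 2: per-glomerulus response metrics on a 7-odorant panel.
#
# Runs the response pipeline (trial averaging, dF/F with the 3-SD responder
# criterion, blank subtraction, latency / time-to-peak / integral) on a
# simulated 7-odorant, single-concentration panel -- the tuning experiment
# layout -- and reports responder fractions per odorant and the glomerular
# density of the simulated field.

library(osnresponse)
dir.create("results", showWarnings = FALSE)
seed <- 20260924

panel7 <- c("ethyl_butyrate", "hexanal", "hexanone_2", "propionic_acid",
            "isoamyl_acetate", "methyl_salicylate", "acetophenone")
cfg <- glom_gen_config("immature_like", n_mice = 3,
                       n_glomeruli_per_mouse = 20,
                       odorant_panel = panel7,
                       concentration_ladder = 0.01,  # all odorants at 1% v/v
                       seed = seed)
gen <- generate_glom_dataset(cfg)
metrics <- compute_response_metrics(gen$dataset)
write_results(metrics, "results/response_metrics.csv")

n_resp <- sum(metrics$is_responder)
message(sprintf("%d of %d glomerulus-stimulus pairs are responders (%.1f%%)",
                n_resp, nrow(metrics), 100 * n_resp / nrow(metrics)))

fractions <- responder_fraction(metrics, gen$dataset$schedule)
write_results(fractions, "results/responder_fractions.csv")
by_odorant <- aggregate(fraction ~ odorant, data = fractions, FUN = mean)
message("mean responder fraction per odorant across mice:")
for (i in seq_len(nrow(by_odorant))) {
  message(sprintf("  %-18s %.2f", by_odorant$odorant[i],
                  by_odorant$fraction[i]))
}

# density of the simulated field: 20 glomeruli in a 266 x 266 um field
message(sprintf("glomerular density: %.0f per mm^2 (20 glomeruli, 266 um field)",
                glomerular_density(20, 266^2)))
message("wrote results/response_metrics.csv and results/responder_fractions.csv")
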