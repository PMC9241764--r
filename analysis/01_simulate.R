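#!/usr/bin/env Rscript
# Generate the study cohort: 11 exacerbating (AE) and 13 stable (AS)
# asthmatic children followed over six visits, plus 9 one-off controls,
# with the six profile-defining genera, subject-level MPG persistence,
# genus trends and transient exacerbation blooms. Writes the count table,
# metadata and ground truth used by the downstream analysis scripts.

suppressMessages(library(npmdyn))

cfg <- sim_config(seed = 20170901)   # cohort master seed
sim <- simulate_cohort(cfg)
write_simulation(sim, "results/simulated")

rep <- truth_report(sim$truth)
cat("Simulated cohort written to results/simulated/\n")
cat(sprintf("  samples: %d (%d exacerbation)\n", rep$n_samples, rep$n_events))
cat(sprintf("  subjects: %d AE, %d AS, %d controls\n",
            cfg$n_subjects_AE, cfg$n_subjects_AS, cfg$n_controls))
cat("  per-genus generating parameters:\n")
print(rep$genus_params, row.names = FALSE)
cat("\nThe Moraxella and Dolosigranulum states persist (self-probability 0.9);",
    "\nMoraxella trends up, Corynebacterium 1 and Anoxybacillus trend down.\n")
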