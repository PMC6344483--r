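#!/usr/bin/env Rscript
# Stage 1: simulate the standard study — one behavioral session (~2000
# counterbalanced trials, logistic chooser with action-cost sensitivity and
# choice hysteresis) plus a 50-neuron cohort: 10 neurons each tuned to
# offer value A, offer value -, chosen value and chosen juice at SNR 2,
# and 10 untuned, all Poisson with 10 spikes/s baseline.
#
# Writes results/data/ (trials.csv, spikes.csv, manifest.json,
# ground_truth.csv).

suppressPackageStartupMessages(library(goodspace))

seed <- 20260926L
gen <- generator_config(seed = seed)
specs <- recovery_specs(generate_session(gen))
cohort <- generate_cohort(gen, specs)

dir.create("results", showWarnings = FALSE)
write_cohort(cohort, "results/data")

s <- cohort$session
cat(sprintf("session '%s': %d trials, %d neurons, %d spikes\n",
            s$session_id, nrow(s$trials),
            length(session_neurons(s)), nrow(s$spikes)))
cat("ground truth families:\n")
print(table(cohort$ground_truth$family))
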