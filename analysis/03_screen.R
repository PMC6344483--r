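#!/usr/bin/env Rscript
# Stage 3: task-related responses. Builds the neuron x window x trial
# response matrix and runs the two three-way ANOVAs (trial type x offer A
# location x target A location; trial type x chosen offer location x chosen
# target location) at p < 0.001.
#
# Reads results/data/; writes results/screen_tally.csv (window x factor
# counts) and results/task_related_responses.csv.

suppressPackageStartupMessages(library(goodspace))

s <- read_session("results/data")
rmat <- windowed_rates(s)
rel <- anova_screen(rmat, s)
trs <- task_related_set(rel)

n_neurons <- length(session_neurons(s))
cat(sprintf("%d of %d x 9 responses task-related; %d of %d cells (%.1f%%)\n",
            nrow(trs$responses), n_neurons, length(trs$cells), n_neurons,
            100 * length(trs$cells) / n_neurons))
cat("cells significant per factor and window:\n")
print(trs$tally)

write.csv(cbind(window = rownames(trs$tally), as.data.frame(trs$tally)),
          "results/screen_tally.csv", row.names = FALSE)
write.csv(trs$responses, "results/task_related_responses.csv",
          row.names = FALSE)
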