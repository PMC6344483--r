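#!/usr/bin/env Rscript
# Stage 5: choice signals before target presentation. Labels quantity pairs
# as cost-overt or cost-covert, computes per-cell ROC choice probabilities
# for chosen-juice cells over the three post-offer windows (cost-overt
# pairs only), and tests the population mean AUC against chance.
#
# Reads results/data/ and results/classification.csv; writes
# results/cost_overt_labels.csv, results/cell_auc.csv,
# results/population_auc.csv.

suppressPackageStartupMessages(library(goodspace))

s <- read_session("results/data")
cl <- read.csv("results/classification.csv", stringsAsFactors = FALSE)

labels <- label_cost_overt(s)
cat("cost-overt labeling of quantity pairs:\n")
print(labels, digits = 2)

cj <- cl[!is.na(cl$assigned) & cl$assigned == "chosen juice", ]
cat(sprintf("%d chosen-juice cells\n", nrow(cj)))

windows <- c("post_offer_1", "post_offer_2", "post_offer_3")
cell_auc <- do.call(rbind, lapply(seq_len(nrow(cj)), function(i) {
  data.frame(neuron_id = cj$neuron_id[i], window = windows,
             auc = vapply(windows, function(w)
               cell_choice_probability(s, cj$neuron_id[i], w, labels,
                                       "chosen juice",
                                       cj$encoded_level[i])$mean_auc,
               numeric(1)))
}))

pop <- do.call(rbind, lapply(windows, function(w) {
  res <- population_auc_test(cell_auc$auc[cell_auc$window == w])
  data.frame(window = w, mean_auc = res$mean_auc, p = res$p, n = res$n)
}))
cat("population choice probability (chosen-juice cells, cost-overt pairs):\n")
print(pop, digits = 3)

write.csv(labels, "results/cost_overt_labels.csv", row.names = FALSE)
write.csv(cell_auc, "results/cell_auc.csv", row.names = FALSE)
write.csv(pop, "results/population_auc.csv", row.names = FALSE)
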