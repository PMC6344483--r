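#!/usr/bin/env Rscript
# Stage 4: variable selection. Regresses every task-related response on the
# 19-variable catalog (at the trial-type level), collapses component
# variables into families, and identifies the encoded variables with the
# stepwise and best-subset procedures, separately for pre- and post-target
# epochs. Classifies cells by their dominant variable and recovers the
# ground-truth labels.
#
# Reads results/data/ and results/task_related_responses.csv; writes
# results/explained_counts.csv, results/best_fit_counts.csv,
# results/encoding_percentages.csv, results/selection.json,
# results/classification.csv.

suppressPackageStartupMessages(library(goodspace))

s <- read_session("results/data")
truth <- read.csv("results/data/ground_truth.csv", stringsAsFactors = FALSE)
responses <- read.csv("results/task_related_responses.csv",
                      stringsAsFactors = FALSE)

rmat <- windowed_rates(s)
fit <- fit_choice_model(s)
reg <- response_regressions(rmat, s, fit, responses)
col <- collapse_r2(reg)

# explained / best-fit counts per window and family
bf <- best_fit_assignment(col$r2_eff)
fams <- colnames(col$r2_eff)
explained <- sapply(fams, function(f) vapply(
  window_specs()$name, function(w)
    sum(responses$window == w & col$r2_eff[, f] > 0), 0L))
best_fit <- sapply(fams, function(f) vapply(
  window_specs()$name, function(w)
    sum(responses$window == w & !is.na(bf) & bf == f), 0L))

selection <- list()
for (ep in c("pre_target", "post_target")) {
  sw <- stepwise_selection(col$r2_eff, responses$window, ep)
  bs <- best_subset_selection(col$r2_eff, responses$window, ep,
                              n_select = length(sw$selected))
  cat(sprintf("%s: stepwise {%s}; best-subset {%s}; identical: %s\n", ep,
              paste(sw$selected, collapse = ", "),
              paste(bs$selected, collapse = ", "),
              setequal(sw$selected, bs$selected)))
  selection[[ep]] <- list(stepwise = sw$selected, best_subset = bs$selected,
                          trace = sw$trace, per_n = bs$per_n)
}
selected_union <- unique(unlist(lapply(selection, `[[`, "stepwise")))

cl <- classify_cells(reg, col, selected_union)
n_cells <- length(unique(responses$neuron_id))
pct <- 100 * best_fit[, selected_union, drop = FALSE] / n_cells
m <- merge(cl, truth[, c("neuron_id", "family")], by = "neuron_id")
tuned <- m$family != "untuned"
cat(sprintf("label recovery: %.0f%% of %d tuned task-related cells\n",
            100 * mean(m$assigned[tuned] == m$family[tuned]), sum(tuned)))
print(table(assigned = m$assigned, truth = m$family))

write.csv(cbind(window = rownames(explained), as.data.frame(explained)),
          "results/explained_counts.csv", row.names = FALSE)
write.csv(cbind(window = rownames(best_fit), as.data.frame(best_fit)),
          "results/best_fit_counts.csv", row.names = FALSE)
write.csv(cbind(window = rownames(pct), as.data.frame(pct)),
          "results/encoding_percentages.csv", row.names = FALSE)
jsonlite::write_json(selection, "results/selection.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
write.csv(cl, "results/classification.csv", row.names = FALSE)
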