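#!/usr/bin/env Rscript
# Stage 2: behavioral analysis. Fits the full logistic choice model to the
# simulated session, screens it for target-side bias, summarizes the choice
# pattern split by cost configuration, and characterizes the sampling
# distribution of the normalized indices over 50 replicate sessions.
#
# Reads results/data/; writes results/behavior_fit.json,
# results/choice_pattern.csv, results/population_indices.csv.

suppressPackageStartupMessages(library(goodspace))

s <- read_session("results/data")
fit <- fit_choice_model(s)
scr <- screen_session(fit)
cat("session fit:\n"); print(fit)
cat(sprintf("screen: %s (%s)\n", if (scr$keep) "keep" else "exclude",
            scr$reason))

pattern <- summarize_choice_pattern(s)
cat(sprintf("indifference points: A low cost %.2f, A high cost %.2f\n",
            pattern$indifference[["A_low"]],
            pattern$indifference[["A_high"]]))

# sampling distribution of the indices across replicate sessions
fits <- lapply(1:50, function(i)
  fit_choice_model(generate_session(generator_config(seed = 3000L + i))))
pop <- population_summary(fits)
cat("population indices over 50 replicate sessions:\n")
print(pop, digits = 3)

jsonlite::write_json(
  list(coefficients = as.list(fit$coefficients),
       se = as.list(fit$se), p_values = as.list(fit$p_values),
       indices = as.list(fit$indices), screen = scr),
  "results/behavior_fit.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
write.csv(pattern$table, "results/choice_pattern.csv", row.names = FALSE)
write.csv(pop, "results/population_indices.csv", row.names = FALSE)
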