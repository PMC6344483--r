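#!/usr/bin/env Rscript
# Stage 6: dimensional integration in value signals. For each value family
# (offer value (juice), offer value (cost), chosen value) responses are
# identified without variant bias (max R^2 over the two variants), the
# per-response difference delta R^2 = R^2_affected - R^2_independent is
# summarized across the population, and offer-value responses are probed
# with the parallel-model ANCOVA grouped by the action cost.
#
# Reads results/data/ and results/task_related_responses.csv; writes
# results/delta_r2.csv and results/integration_summary.json.

suppressPackageStartupMessages(library(goodspace))

s <- read_session("results/data")
responses <- read.csv("results/task_related_responses.csv",
                      stringsAsFactors = FALSE)
sel <- jsonlite::read_json("results/selection.json", simplifyVector = TRUE)
selected <- unique(c(sel$pre_target$stepwise, sel$post_target$stepwise))

rmat <- windowed_rates(s)
fit <- fit_choice_model(s)
ra <- response_regressions(rmat, s, fit, responses, variant = "affected")
ri <- response_regressions(rmat, s, fit, responses, variant = "independent")

all_ident <- list()
summary <- list()
for (fam in intersect(c("offer value (juice)", "offer value (cost)",
                        "chosen value"), selected)) {
  ident <- unbiased_identify(ra, ri, selected, fam)
  ident$family <- fam
  all_ident[[fam]] <- ident
  if (nrow(ident) >= 6L) {
    pop <- delta_r2_population(ident)
    cat(sprintf("%-22s n=%2d  mean(dR2)=%+.4f  p=%.3g\n", fam, pop$n,
                pop$mean_delta_r2, pop$p_signed_rank))
    summary[[fam]] <- pop
  }
}
cv <- all_ident[["chosen value"]]
if (!is.null(cv)) {
  e <- cv$delta_r2[cv$window == "post_offer"]
  l <- cv$delta_r2[cv$window == "post_target"]
  if (length(e) >= 2L && length(l) >= 2L) {
    ctr <- epoch_contrast(e, l)
    cat(sprintf("chosen value early vs late: diff=%+.4f, p=%.3g\n",
                ctr$mean_diff, ctr$p_rank_sum))
    summary[["chosen value early_late_contrast"]] <- ctr
  }
}

# ANCOVA on offer value (juice) responses, grouped by the cost of the
# encoded juice
ovj <- all_ident[["offer value (juice)"]]
if (!is.null(ovj) && nrow(ovj) > 0L) {
  tt <- interaction(s$trials$qA, s$trials$qB, s$trials$costA,
                    s$trials$chosen_juice, drop = TRUE, lex.order = TRUE)
  n_sig <- 0L
  for (i in seq_len(nrow(ovj))) {
    juice <- if (ovj$component[i] == "offer value A") "A" else "B"
    vals <- evaluate_variable(ovj$component[i], s$trials, fit)
    rates <- rmat$rates[ovj$neuron_id[i], ovj$window[i], ]
    grp <- if (juice == "A") s$trials$costA else s$trials$costB
    y <- tapply(rates, tt, mean); x <- tapply(vals, tt, mean)
    g <- tapply(grp, tt, function(v) v[1])
    ok <- tryCatch({
      anc <- ancova_parallel(y, x, g)
      !is.na(anc$p_group) && anc$p_group < 0.05
    }, error = function(e) NA)
    if (isTRUE(ok)) n_sig <- n_sig + 1L
  }
  cat(sprintf("ANCOVA: cost-group effect significant in %d of %d offer value (juice) responses\n",
              n_sig, nrow(ovj)))
  summary[["ancova_offer_value_juice"]] <-
    list(n_significant = n_sig, n = nrow(ovj))
}

write.csv(do.call(rbind, all_ident), "results/delta_r2.csv",
          row.names = FALSE)
jsonlite::write_json(summary, "results/integration_summary.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
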