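# End-to-end orchestration: simulate -> fit behavior -> ANOVA screen ->
# variable selection -> choice signal -> dimensional integration, with all
# thresholds in one config and deterministic seeding.

#' Pipeline configuration
#'
#' Bundles the generator settings, the neuron cohort, and every analysis
#' threshold. Defaults are the analysis' standard values: ANOVA screen
#' alpha 0.001, regression alpha 0.05, session spatial-bias screen alpha
#' 0.01, stepwise stop at 5% marginal explanatory power, cost-overt margin
#' 10%.
#'
#' @param generator A `gs_generator_config`.
#' @param neuron_specs List of `gs_neuron_spec`; `NULL` builds the standard
#'   recovery cohort via [recovery_specs()].
#' @param anova_alpha,regression_alpha,session_alpha Significance thresholds.
#' @param stepwise_stop Stepwise stop fraction.
#' @param overt_margin Cost-overt choice-shift margin.
#' @param variant Variant for the main selection run.
#' @return List of class `gs_pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            neuron_specs = NULL,
                            anova_alpha = 0.001, regression_alpha = 0.05,
                            session_alpha = 0.01, stepwise_stop = 0.05,
                            overt_margin = 0.10, variant = "affected") {
  structure(
    list(generator = generator, neuron_specs = neuron_specs,
         anova_alpha = anova_alpha, regression_alpha = regression_alpha,
         session_alpha = session_alpha, stepwise_stop = stepwise_stop,
         overt_margin = overt_margin, variant = variant),
    class = "gs_pipeline_config"
  )
}

# Cheap content hash for provenance records (djb2 over the deparsed config).
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 5381
  for (code in utf8ToInt(s)) h <- (h * 33 + code) %% 2^31
  sprintf("%08x", h)
}

# window x family matrices of explained / best-fit response counts
selection_matrices <- function(r2c, responses) {
  fams <- colnames(r2c)
  explained <- sapply(fams, function(f)
    vapply(WINDOW_NAMES, function(w)
      sum(responses$window == w & r2c[, f] > 0), 0L))
  bf <- best_fit_assignment(r2c)
  best_fit <- sapply(fams, function(f)
    vapply(WINDOW_NAMES, function(w)
      sum(responses$window == w & !is.na(bf) & bf == f), 0L))
  list(explained = explained, best_fit = best_fit)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes every stage in order and (optionally) writes per-stage artifacts
#' as CSV/JSON under `out_dir`. Fully reproducible from the config.
#'
#' @param config A `gs_pipeline_config`.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return List with the per-stage results: `cohort`, `behavior`, `screen`,
#'   `selection`, `classification`, `choice_signal`, `integration`,
#'   `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "gs_pipeline_config"))
  gen <- config$generator
  specs <- config$neuron_specs
  if (is.null(specs)) {
    specs <- recovery_specs(generate_session(gen))
  }
  cohort <- generate_cohort(gen, specs)
  s <- cohort$session

  # -- behavior ---------------------------------------------------------
  fit_full <- fit_choice_model(s)
  fit_simple <- fit_simplified_model(s)
  screen_b <- screen_session(fit_full, alpha = config$session_alpha)
  pattern <- summarize_choice_pattern(s, fit_simple)
  behavior <- list(fit = fit_full, fit_simplified = fit_simple,
                   screen = screen_b, pattern = pattern)

  # -- neural screen ----------------------------------------------------
  rmat <- windowed_rates(s)
  rel <- anova_screen(rmat, s, alpha = config$anova_alpha)
  trs <- task_related_set(rel)

  # -- variable selection ----------------------------------------------
  reg_aff <- response_regressions(rmat, s, fit_full, trs$responses,
                                  variant = "affected",
                                  alpha = config$regression_alpha)
  reg_ind <- response_regressions(rmat, s, fit_full, trs$responses,
                                  variant = "independent",
                                  alpha = config$regression_alpha)
  reg <- if (config$variant == "affected") reg_aff else reg_ind
  col <- collapse_r2(reg)
  mats <- selection_matrices(col$r2_eff, trs$responses)
  sel <- list()
  for (ep in c("pre_target", "post_target")) {
    sw <- stepwise_selection(col$r2_eff, trs$responses$window, ep,
                             stop_frac = config$stepwise_stop)
    bs <- best_subset_selection(col$r2_eff, trs$responses$window, ep,
                                stop_frac = config$stepwise_stop,
                                n_select = length(sw$selected))
    sel[[ep]] <- list(stepwise = sw, best_subset = bs)
  }
  selected_union <- unique(c(sel$pre_target$stepwise$selected,
                             sel$post_target$stepwise$selected))
  classification <- if (length(selected_union))
    classify_cells(reg, col, selected_union) else NULL

  # -- choice signal ----------------------------------------------------
  labels <- label_cost_overt(s, margin = config$overt_margin)
  choice_sig <- NULL
  if (!is.null(classification)) {
    cells_cj <- classification[!is.na(classification$assigned) &
                               classification$assigned == "chosen juice", ]
    if (nrow(cells_cj) >= 3L) {
      aucs <- lapply(POST_OFFER_ROC$name, function(w) {
        vals <- vapply(seq_len(nrow(cells_cj)), function(i)
          cell_choice_probability(s, cells_cj$neuron_id[i], w, labels,
                                  "chosen juice",
                                  cells_cj$encoded_level[i])$mean_auc,
          numeric(1))
        c(list(window = w),
          population_auc_test(vals, min_cells = 3L))
      })
      choice_sig <- list(labels = labels, n_cells = nrow(cells_cj),
                         population = do.call(rbind,
                                              lapply(aucs, as.data.frame)))
    } else {
      choice_sig <- list(labels = labels, n_cells = nrow(cells_cj),
                         population = NULL)
    }
  }

  # -- dimensional integration -----------------------------------------
  integration <- list()
  for (fam in c("offer value (juice)", "offer value (cost)", "chosen value")) {
    if (!fam %in% selected_union) next
    ident <- unbiased_identify(reg_aff, reg_ind, selected_union, fam)
    res <- list(identified = ident)
    if (nrow(ident) >= 6L)
      res$population <- delta_r2_population(ident)
    if (fam == "chosen value") {
      early <- ident$delta_r2[ident$window == "post_offer"]
      late <- ident$delta_r2[ident$window == "post_target"]
      if (length(early) >= 2L && length(late) >= 2L)
        res$contrast <- epoch_contrast(early, late)
    }
    integration[[fam]] <- res
  }

  provenance <- list(
    config_hash = config_hash(config),
    seed = gen$seed,
    thresholds = config[c("anova_alpha", "regression_alpha", "session_alpha",
                          "stepwise_stop", "overt_margin")],
    n_trials = nrow(s$trials),
    n_neurons = length(session_neurons(s)),
    n_task_related_responses = nrow(trs$responses),
    n_task_related_cells = length(trs$cells)
  )

  out <- list(cohort = cohort, behavior = behavior,
              screen = list(relatedness = rel, task_related = trs),
              regressions = list(affected = reg_aff, independent = reg_ind),
              selection = c(sel, list(matrices = mats,
                                      selected_union = selected_union)),
              classification = classification,
              choice_signal = choice_sig,
              integration = integration,
              provenance = provenance)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

# Write CSV/JSON artifacts of a pipeline run.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(df, file.path(out_dir, name),
                                           row.names = FALSE)
  fit <- result$behavior$fit
  jsonlite::write_json(
    list(coefficients = as.list(fit$coefficients),
         p_values = as.list(fit$p_values),
         indices = as.list(fit$indices),
         screen = result$behavior$screen,
         provenance = result$provenance),
    file.path(out_dir, "behavior.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  w(result$behavior$pattern$table, "choice_pattern.csv")
  w(as.data.frame(result$screen$task_related$tally), "screen_tally.csv")
  w(result$screen$task_related$responses, "task_related_responses.csv")
  w(as.data.frame(result$selection$matrices$explained), "explained_counts.csv")
  w(as.data.frame(result$selection$matrices$best_fit), "best_fit_counts.csv")
  for (ep in c("pre_target", "post_target")) {
    jsonlite::write_json(
      list(stepwise = result$selection[[ep]]$stepwise$selected,
           best_subset = result$selection[[ep]]$best_subset$selected,
           per_n = result$selection[[ep]]$best_subset$per_n),
      file.path(out_dir, paste0("selection_", ep, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(result$classification))
    w(result$classification, "classification.csv")
  if (!is.null(result$choice_signal)) {
    w(result$choice_signal$labels, "cost_overt_labels.csv")
    if (!is.null(result$choice_signal$population))
      w(result$choice_signal$population, "population_auc.csv")
  }
  if (length(result$integration)) {
    for (fam in names(result$integration)) {
      tag <- gsub("[^a-z]+", "_", fam)
      w(result$integration[[fam]]$identified,
        paste0("delta_r2_", tag, ".csv"))
    }
    summ <- lapply(result$integration, function(r)
      c(r$population, if (!is.null(r$contrast)) list(contrast = r$contrast)))
    jsonlite::write_json(summ, file.path(out_dir, "integration.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out_dir)
}
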