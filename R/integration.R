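# Delta R^2 comparisons between variable variants (does a value signal
# integrate the action cost? the juice type?) and the parallel-model ANCOVA.

# Windows over which each value family's integration is assessed: the
# post-offer window, where offer-value responses are most prevalent; chosen
# value is additionally examined post-target, where its cost dependence may
# emerge.
integration_windows <- function(family) {
  switch(family,
    "offer value (juice)" = "post_offer",
    "offer value (cost)" = "post_offer",
    "chosen value" = c("post_offer", "post_target"),
    stop("no integration analysis defined for family: ", family)
  )
}

#' Identify responses of a value family without biasing the variant contrast
#'
#' For each response and each family, the larger of the two effective
#' R-squared values obtained from the two variants is assigned to the
#' response; responses are then assigned to selected variables by best fit
#' under this max rule. Responses assigned to `family` within its analysis
#' windows are returned, each with its winning component variable and the
#' raw-R-squared difference `delta_r2 = R2_affected - R2_independent`
#' computed on that component.
#'
#' @param reg_affected,reg_independent `gs_regressions` computed with the
#'   two variants over the same responses.
#' @param selected Character vector of selected families.
#' @param family Family under test (`"offer value (juice)"`,
#'   `"offer value (cost)"` or `"chosen value"`).
#' @param windows Analysis windows; defaults per family (post-offer; chosen
#'   value also post-target).
#' @return data.frame: `neuron_id`, `window`, `component`, `r2_affected`,
#'   `r2_independent`, `delta_r2`.
#' @export
unbiased_identify <- function(reg_affected, reg_independent, selected, family,
                              windows = NULL) {
  stopifnot(identical(reg_affected$responses, reg_independent$responses))
  if (is.null(windows)) windows <- integration_windows(family)
  ca <- collapse_r2(reg_affected)
  ci <- collapse_r2(reg_independent)
  mx <- pmax(ca$r2_eff, ci$r2_eff)
  assigned <- best_fit_assignment(mx[, selected, drop = FALSE])
  resp <- reg_affected$responses
  idx <- which(!is.na(assigned) & assigned == family & resp$window %in% windows)
  if (length(idx) == 0L)
    return(data.frame(neuron_id = character(0), window = character(0),
                      component = character(0), r2_affected = numeric(0),
                      r2_independent = numeric(0), delta_r2 = numeric(0)))
  # winning component under the max rule
  comp <- ifelse(ca$r2_eff[idx, family] >= ci$r2_eff[idx, family],
                 ca$winner[idx, family], ci$winner[idx, family])
  # fall back to the affected winner when both variants are zero
  comp[is.na(comp)] <- ca$winner[idx, family][is.na(comp)]
  r2a <- reg_affected$r2_raw[cbind(idx, match(comp, colnames(reg_affected$r2_raw)))]
  r2i <- reg_independent$r2_raw[cbind(idx, match(comp, colnames(reg_independent$r2_raw)))]
  data.frame(neuron_id = resp$neuron_id[idx], window = resp$window[idx],
             component = comp, r2_affected = r2a, r2_independent = r2i,
             delta_r2 = r2a - r2i, stringsAsFactors = FALSE)
}

#' Population summary of delta R-squared
#'
#' Mean of the per-response `delta_r2` with a two-sided Wilcoxon signed-rank
#' test against zero.
#'
#' @param identified Output of [unbiased_identify()] (optionally filtered to
#'   one window).
#' @param min_responses Minimum population size (default 6).
#' @return List with `mean_delta_r2`, `p_signed_rank`, `n`.
#' @export
delta_r2_population <- function(identified, min_responses = 6L) {
  d <- identified$delta_r2
  d <- d[!is.na(d)]
  if (length(d) < min_responses)
    stop("delta R^2 population requires at least ", min_responses,
         " responses")
  p <- if (all(d == 0)) 1 else
    suppressWarnings(stats::wilcox.test(d, mu = 0, exact = FALSE)$p.value)
  list(mean_delta_r2 = mean(d), p_signed_rank = p, n = length(d))
}

#' Early-late contrast of delta R-squared
#'
#' Difference of mean `delta_r2` between two epochs with a two-sample
#' Wilcoxon rank-sum test.
#'
#' @param early,late Numeric vectors of per-response `delta_r2`.
#' @return List with `mean_diff` (late - early), `p_rank_sum`, `n_early`,
#'   `n_late`.
#' @export
epoch_contrast <- function(early, late) {
  early <- early[!is.na(early)]; late <- late[!is.na(late)]
  if (length(early) < 2L || length(late) < 2L)
    stop("both epochs need at least 2 responses")
  p <- suppressWarnings(
    stats::wilcox.test(late, early, exact = FALSE)$p.value)
  list(mean_diff = mean(late) - mean(early), p_rank_sum = p,
       n_early = length(early), n_late = length(late))
}

#' Parallel-model ANCOVA of a response on a value variable
#'
#' Fits a single common slope with group-specific intercepts and tests the
#' group factor with an F test against the slope-only model. With a single
#' group this reduces exactly to the simple linear regression.
#'
#' @param rates Numeric response vector.
#' @param values Numeric value-variable vector.
#' @param groups Grouping factor (e.g. action cost of the encoded offer).
#' @param min_per_group Minimum observations per group (default 3).
#' @return List of class `gs_ancova`: `slope`, `intercepts` (per group),
#'   `p_group`, `n`.
#' @export
ancova_parallel <- function(rates, values, groups, min_per_group = 3L) {
  groups <- as.factor(groups)
  if (any(table(groups) < min_per_group))
    stop("each group needs at least ", min_per_group, " observations")
  groups <- droplevels(groups)
  if (stats::var(values) == 0) stop("singular design: constant value variable")
  base <- stats::lm(rates ~ values)
  if (nlevels(groups) < 2L) {
    co <- stats::coef(base)
    return(structure(list(slope = co[["values"]],
                          intercepts = c(co[["(Intercept)"]]),
                          p_group = NA_real_, n = length(rates)),
                     class = "gs_ancova"))
  }
  full <- stats::lm(rates ~ values + groups)
  co <- stats::coef(full)
  if (anyNA(co)) stop("singular design in ANCOVA")
  intercepts <- co[["(Intercept)"]] +
    c(0, co[grep("^groups", names(co))])
  names(intercepts) <- levels(groups)
  p_group <- stats::anova(base, full)[2, "Pr(>F)"]
  structure(list(slope = co[["values"]], intercepts = intercepts,
                 p_group = p_group, n = length(rates)),
            class = "gs_ancova")
}
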