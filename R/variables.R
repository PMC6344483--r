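# The catalog of candidate encoded variables, defined in multiple reference
# frames (commodity, cost, visual, action), their "collapsed" families, and
# the per-trial evaluators. Value variables are expressed in units of juice B
# using the session's behavioral estimates rho (relative value) and xi
# (action cost).

#' Catalog of candidate encoded variables
#'
#' Nineteen variables spanning four reference frames. Offer-value variables
#' come in pairs (A/B, -/+, L/R, target L/target R) that are "collapsed" into
#' a family credited with the larger of the two R-squared values; binary
#' variables and `chosen value` are their own family.
#'
#' @return data.frame with columns `id`, `name`, `frame`, `family`.
#' @export
variable_catalog <- function() {
  data.frame(
    id = 1:19,
    name = c("offer value A", "offer value B", "chosen juice",
             "offer value -", "offer value +", "chosen cost",
             "offer value L", "offer value R", "chosen location",
             "offer value target L", "offer value target R", "chosen target",
             "cost of A", "offer A location", "target A location",
             "offer + location", "target + location", "spatial congruence",
             "chosen value"),
    frame = c("commodity", "commodity", "commodity",
              "cost", "cost", "cost",
              "visual", "visual", "visual",
              "action", "action", "action",
              "mixed", "mixed", "mixed", "mixed", "mixed", "mixed",
              "mixed"),
    family = c("offer value (juice)", "offer value (juice)", "chosen juice",
               "offer value (cost)", "offer value (cost)", "chosen cost",
               "offer value (location)", "offer value (location)",
               "chosen location",
               "offer value (target)", "offer value (target)", "chosen target",
               "cost of A", "offer A location", "target A location",
               "offer + location", "target + location", "spatial congruence",
               "chosen value"),
    stringsAsFactors = FALSE
  )
}

#' Collapsed variable families, in catalog order
#' @return Character vector of the 15 family names.
#' @export
collapsed_families <- function() unique(variable_catalog()$family)

# Component offer values per trial. use_rho = FALSE sets rho to 1 (raw
# quantities; the commodity-independent variant); use_cost = FALSE drops the
# xi term (the cost-independent variant).
component_offer_values <- function(trials, rho, xi,
                                   use_rho = TRUE, use_cost = TRUE) {
  r <- if (use_rho) rho else 1
  x <- if (use_cost) xi else 0
  list(
    A = r * trials$qA + x * (trials$costA == "low"),
    B = trials$qB + x * (trials$costB == "low")
  )
}

# Indices of the pair (rho, xi) extracted from a behavioral fit or a bare list
fit_indices <- function(fit) {
  if (inherits(fit, "gs_logistic_fit")) {
    list(rho = fit$indices[["rho"]], xi = fit$indices[["xi"]])
  } else {
    stopifnot(!is.null(fit$rho), !is.null(fit$xi))
    list(rho = fit$rho, xi = fit$xi)
  }
}

#' Evaluate a catalog variable on every trial
#'
#' @param variable Variable id (1-19) or name from [variable_catalog()].
#' @param trials Trial table of a `gs_session` (after derivation of chosen
#'   cost/sides; any table from a session object qualifies).
#' @param fit A behavioral fit (`gs_logistic_fit`) or a list with elements
#'   `rho` and `xi` supplying the value parameters.
#' @param variant `"affected"` evaluates the full definition; `"independent"`
#'   removes the determinant under test: the xi term for commodity-, visual-
#'   and action-frame values and for `chosen value`; the rho weighting (raw
#'   quantities) for the cost-frame values. Binary variables are unaffected.
#' @return Numeric vector, one value per trial.
#' @export
evaluate_variable <- function(variable, trials, fit,
                              variant = c("affected", "independent")) {
  variant <- match.arg(variant)
  cat_ <- variable_catalog()
  if (is.character(variable)) {
    id <- match(variable, cat_$name)
    if (is.na(id)) stop("unknown variable: ", variable)
  } else {
    id <- as.integer(variable)
    if (is.na(id) || id < 1L || id > 19L) stop("unknown variable id: ", variable)
  }
  idx <- fit_indices(fit)
  fam <- cat_$family[id]
  cost_frame <- fam == "offer value (cost)"
  ov <- component_offer_values(
    trials, idx$rho, idx$xi,
    use_rho = !(variant == "independent" && cost_frame),
    use_cost = !(variant == "independent" && !cost_frame)
  )
  pickA <- function(cond) ifelse(cond, ov$A, ov$B)
  switch(as.character(id),
    "1" = ov$A,
    "2" = ov$B,
    "3" = as.numeric(trials$chosen_juice == "B"),
    "4" = pickA(trials$costA == "high"),
    "5" = pickA(trials$costA == "low"),
    "6" = as.numeric(trials$chosen_cost == "low"),
    "7" = pickA(trials$offerA_side == "L"),
    "8" = pickA(trials$offerA_side == "R"),
    "9" = as.numeric(trials$chosen_offer_side == "L"),
    "10" = pickA(trials$targetA_side == "L"),
    "11" = pickA(trials$targetA_side == "R"),
    "12" = as.numeric(trials$chosen_target_side == "L"),
    "13" = as.numeric(trials$costA == "low"),
    "14" = as.numeric(trials$offerA_side == "L"),
    "15" = as.numeric(trials$targetA_side == "L"),
    "16" = as.numeric(ifelse(trials$costA == "low",
                             trials$offerA_side, trials$offerB_side) == "L"),
    "17" = as.numeric(ifelse(trials$costA == "low",
                             trials$targetA_side, trials$targetB_side) == "L"),
    "18" = as.numeric(trials$offerA_side == trials$targetA_side),
    "19" = pickA(trials$chosen_juice == "A"),
    stop("unknown variable id: ", id)
  )
}

#' Per-trial values of all 19 catalog variables
#'
#' @inheritParams evaluate_variable
#' @return Numeric matrix, trials in rows, variables in columns (named).
#' @export
variable_value_matrix <- function(trials, fit, variant = "affected") {
  cat_ <- variable_catalog()
  m <- vapply(cat_$id, function(id)
    evaluate_variable(id, trials, fit, variant), numeric(nrow(trials)))
  colnames(m) <- cat_$name
  m
}
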