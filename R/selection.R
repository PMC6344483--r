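# Linear regressions of responses on catalog variables, collapsed-variable
# R-squared, best-fit assignment, stepwise and best-subset selection, and
# cell classification.

# Vectorized simple OLS of each column of Y on x. Returns slope, intercept,
# p-value of the slope (t test) and R^2 per column.
ols_many <- function(x, Y) {
  Y <- as.matrix(Y)
  n <- length(x)
  mx <- mean(x)
  xc <- x - mx
  sxx <- sum(xc^2)
  my <- colMeans(Y)
  if (sxx <= 0) {
    k <- ncol(Y)
    return(list(slope = rep(NA_real_, k), intercept = my,
                p = rep(NA_real_, k), r2 = rep(0, k), constant_x = TRUE))
  }
  sxy <- drop(crossprod(xc, Y))
  syy <- colSums(sweep(Y, 2L, my)^2)
  slope <- sxy / sxx
  r2 <- ifelse(syy > 0, slope^2 * sxx / syy, 0)
  df <- n - 2L
  s2 <- pmax(0, syy - slope^2 * sxx) / df
  se <- sqrt(s2 / sxx)
  tstat <- slope / se
  p <- 2 * stats::pt(-abs(tstat), df)   # exact fits: t = Inf, p = 0
  p[is.nan(tstat)] <- NA_real_          # constant responses: undefined
  list(slope = slope, intercept = my - slope * mx, p = p, r2 = r2,
       constant_x = FALSE)
}

#' Regress one response on one variable
#'
#' By default the regression is performed at the trial-type level: the
#' response is the mean rate per trial type, regressed on the variable's mean
#' value per trial type (a "response" is activity as a function of the trial
#' type). A variable explains the response if the slope differs from zero at
#' `alpha`; otherwise the effective R-squared is set to 0.
#'
#' @param rates Numeric vector of rates, one per trial.
#' @param values Numeric vector of the variable, one per trial.
#' @param trial_types Factor of trial types (required for
#'   `level = "trial_type"`).
#' @param level `"trial_type"` (default) or `"trial"`.
#' @param alpha Slope significance threshold (default 0.05).
#' @return List with `slope`, `intercept`, `p`, `r2_raw`, `r2_eff`, `n`.
#' @export
regress_response <- function(rates, values, trial_types = NULL,
                             level = c("trial_type", "trial"), alpha = 0.05) {
  level <- match.arg(level)
  if (level == "trial_type") {
    if (is.null(trial_types)) stop("trial_types required at trial-type level")
    y <- tapply(rates, trial_types, mean)
    x <- tapply(values, trial_types, mean)
  } else {
    y <- rates; x <- values
  }
  if (length(y) < 3L) stop("regression requires at least 3 points")
  o <- ols_many(x, matrix(y, ncol = 1L))
  explained <- !o$constant_x && !is.na(o$p[1]) && o$p[1] < alpha
  list(slope = o$slope[1], intercept = o$intercept[1], p = o$p[1],
       r2_raw = o$r2[1], r2_eff = if (explained) o$r2[1] else 0,
       n = length(y), constant_x = o$constant_x)
}

#' Regress every task-related response on every catalog variable
#'
#' @param rmat A `gs_response_matrix`.
#' @param session The matching `gs_session`.
#' @param fit Behavioral fit (or list with `rho`, `xi`).
#' @param responses data.frame with columns `neuron_id`, `window` selecting
#'   the responses (typically `task_related_set(...)$responses`); defaults to
#'   all responses.
#' @param variant Variable variant (see [evaluate_variable()]).
#' @param alpha Slope significance threshold.
#' @param level Aggregation level of the regression.
#' @return List of class `gs_regressions`: matrices `r2_raw`, `r2_eff`,
#'   `slope`, `p` (response x 19 variables) plus the response table.
#' @export
response_regressions <- function(rmat, session, fit, responses = NULL,
                                 variant = "affected", alpha = 0.05,
                                 level = "trial_type") {
  trials <- session$trials
  if (is.null(responses)) {
    responses <- expand.grid(neuron_id = rmat$neurons, window = WINDOW_NAMES,
                             stringsAsFactors = FALSE)
  }
  V <- variable_value_matrix(trials, fit, variant)
  tt <- trial_type_factor(trials)
  ni <- match(responses$neuron_id, rmat$neurons)
  wi <- match(responses$window, rmat$windows)
  R <- vapply(seq_len(nrow(responses)), function(j) rmat$rates[ni[j], wi[j], ],
              numeric(dim(rmat$rates)[3]))
  if (level == "trial_type") {
    g <- as.integer(tt)
    agg <- function(M) apply(M, 2L, function(col) tapply(col, g, mean))
    R <- agg(R); V <- agg(V)
  }
  k <- ncol(V)
  m <- nrow(responses)
  r2_raw <- r2_eff <- slope <- pmat <- matrix(
    NA_real_, m, k, dimnames = list(NULL, colnames(V)))
  for (v in seq_len(k)) {
    o <- ols_many(V[, v], R)
    slope[, v] <- o$slope
    pmat[, v] <- o$p
    r2_raw[, v] <- o$r2
    expl <- !o$constant_x & !is.na(o$p) & o$p < alpha
    r2_eff[, v] <- ifelse(expl, o$r2, 0)
  }
  structure(
    list(responses = responses, r2_raw = r2_raw, r2_eff = r2_eff,
         slope = slope, p = pmat, alpha = alpha, variant = variant),
    class = "gs_regressions"
  )
}

#' Collapse component R-squared values into variable families
#'
#' Each family is credited with the larger effective R-squared of its
#' component variables; the winning component is recorded.
#'
#' @param reg A `gs_regressions`, or a numeric matrix of effective R-squared
#'   with the 19 catalog variables as columns.
#' @return List with matrix `r2_eff` (response x 15 families) and character
#'   matrix `winner` (winning component name, `NA` where the family R-squared
#'   is 0).
#' @export
collapse_r2 <- function(reg) {
  M <- if (inherits(reg, "gs_regressions")) reg$r2_eff else as.matrix(reg)
  cat_ <- variable_catalog()
  fams <- collapsed_families()
  out <- matrix(0, nrow(M), length(fams), dimnames = list(NULL, fams))
  winner <- matrix(NA_character_, nrow(M), length(fams),
                   dimnames = list(NULL, fams))
  for (f in fams) {
    comp <- cat_$name[cat_$family == f]
    sub <- M[, comp, drop = FALSE]
    j <- max.col(sub, ties.method = "first")
    best <- sub[cbind(seq_len(nrow(sub)), j)]
    out[, f] <- best
    winner[, f] <- ifelse(best > 0, comp[j], NA_character_)
  }
  list(r2_eff = out, winner = winner)
}

#' Best-fit variable of each response
#'
#' The family with the largest effective R-squared; `NA` if no family
#' explains the response. Ties are broken by catalog order.
#'
#' @param r2c Response x family matrix of effective R-squared (from
#'   [collapse_r2()]).
#' @return Character vector of family names (or `NA`).
#' @export
best_fit_assignment <- function(r2c) {
  j <- max.col(r2c, ties.method = "first")
  best <- r2c[cbind(seq_len(nrow(r2c)), j)]
  ifelse(best > 0, colnames(r2c)[j], NA_character_)
}

#' Windows belonging to each selection epoch
#'
#' Variables are selected separately before and after target presentation;
#' the pre-offer window is baseline and belongs to neither epoch.
#' @param epoch `"pre_target"` or `"post_target"`.
#' @return Character vector of window names.
#' @export
epoch_windows <- function(epoch = c("pre_target", "post_target")) {
  epoch <- match.arg(epoch)
  if (epoch == "pre_target")
    c("post_offer", "late_delay", "mem_delay", "pre_target")
  else
    c("post_target", "pre_go", "pre_juice", "post_juice")
}

#' Stepwise variable selection
#'
#' At each step the variable providing the highest number of best fits
#' within any single time window is selected; the responses it accounts for
#' are removed, and the procedure repeats on the residual responses.
#' Selection stops when the marginal explanatory power of the next variable
#' — newly accounted-for responses as a fraction of all task-related
#' responses in the epoch — falls below `stop_frac`. Ties are broken by the
#' total number of best fits across windows, then by catalog order, so the
#' procedure is deterministic.
#'
#' `removal` controls which responses a selected variable accounts for:
#' `"best_fit"` (default) removes the responses for which it provides the
#' best fit; `"explained"` removes every response it explains at p < 0.05.
#' With near-collinear value variables the explained-removal rule lets the
#' first value variable absorb the responses of its siblings (e.g. chosen
#' value responses are almost always explained by an offer-value variable),
#' so the best-fit rule is the default.
#'
#' @param r2c Response x family effective R-squared matrix.
#' @param windows Character vector: window of each response (rows of `r2c`).
#' @param epoch Selection epoch (see [epoch_windows()]); `NULL` uses all
#'   supplied responses.
#' @param stop_frac Stop threshold on marginal explanatory power
#'   (default 0.05).
#' @param removal Removal rule, `"best_fit"` or `"explained"`.
#' @return List of class `gs_selection`: `selected` (family names in order),
#'   `trace` (per-step best-fit score, newly accounted count, marginal
#'   fraction), `epoch`, `n_total`.
#' @export
stepwise_selection <- function(r2c, windows, epoch = "pre_target",
                               stop_frac = 0.05,
                               removal = c("best_fit", "explained")) {
  removal <- match.arg(removal)
  if (!is.null(epoch)) {
    keep <- windows %in% epoch_windows(epoch)
    r2c <- r2c[keep, , drop = FALSE]
    windows <- windows[keep]
  }
  n_total <- nrow(r2c)
  selected <- character(0)
  trace <- data.frame(step = integer(0), variable = character(0),
                      best_fit_score = integer(0), n_new = integer(0),
                      marginal_frac = numeric(0))
  if (n_total == 0L)
    return(structure(list(selected = selected, trace = trace, epoch = epoch,
                          n_total = 0L, procedure = "stepwise"),
                     class = "gs_selection"))
  remaining <- rep(TRUE, n_total)
  candidates <- colnames(r2c)
  repeat {
    if (!any(remaining) || length(candidates) == 0L) break
    sub <- r2c[remaining, candidates, drop = FALSE]
    bf <- best_fit_assignment(sub)
    w <- windows[remaining]
    # per candidate: best-fit count in its best window, and total
    per_win <- vapply(candidates, function(v) {
      hits <- !is.na(bf) & bf == v
      if (!any(hits)) return(c(0L, 0L))
      tab <- table(w[hits])
      c(max(tab), sum(tab))
    }, integer(2))
    score <- per_win[1L, ]; total_bf <- per_win[2L, ]
    ord <- order(-score, -total_bf, match(candidates, colnames(r2c)))
    pick <- candidates[ord[1]]
    newly <- remaining
    if (removal == "explained") {
      newly <- newly & r2c[, pick] > 0
    } else {
      hit <- rep(FALSE, n_total)
      hit[which(remaining)[!is.na(bf) & bf == pick]] <- TRUE
      newly <- newly & hit
    }
    n_new <- sum(newly)
    marg <- n_new / n_total
    if (n_new == 0L || marg < stop_frac) break
    selected <- c(selected, pick)
    trace <- rbind(trace, data.frame(
      step = length(selected), variable = pick,
      best_fit_score = score[[ord[1]]], n_new = n_new, marginal_frac = marg))
    remaining <- remaining & !newly
    candidates <- setdiff(candidates, pick)
  }
  structure(list(selected = selected, trace = trace, epoch = epoch,
                 n_total = n_total, procedure = "stepwise"),
            class = "gs_selection")
}

#' Best-subset variable selection
#'
#' For each subset size n = 1, 2, ... the subset of n families that
#' collectively explains the largest number of responses (a response is
#' explained by the subset if any member explains it). Optimality is
#' guaranteed by exhaustive enumeration. Ties are broken by the larger summed
#' effective R-squared (sum over responses of the best member's R-squared),
#' then by catalog order.
#'
#' @inheritParams stepwise_selection
#' @param n_max Largest subset size examined (clipped to the catalog size).
#' @param n_select Subset size reported as `selected`; typically the size of
#'   the stepwise selection, so the two procedures are compared at matched
#'   size. `NULL` picks the smallest n whose increment over n - 1 falls
#'   below `stop_frac` of the total (mirroring the stepwise stop rule).
#' @return List of class `gs_selection` with `per_n` (one row per n: subset,
#'   responses explained, summed R-squared) and `selected` (see `n_select`).
#' @export
best_subset_selection <- function(r2c, windows, epoch = "pre_target",
                                  n_max = 6L, stop_frac = 0.05,
                                  n_select = NULL) {
  if (!is.null(epoch)) {
    keep <- windows %in% epoch_windows(epoch)
    r2c <- r2c[keep, , drop = FALSE]
  }
  vars <- colnames(r2c)
  n_max <- min(n_max, length(vars))
  n_total <- nrow(r2c)
  explained <- r2c > 0
  per_n <- list()
  for (k in seq_len(n_max)) {
    combos <- utils::combn(length(vars), k)
    best <- NULL
    for (j in seq_len(ncol(combos))) {
      S <- combos[, j]
      cov_ <- sum(apply(explained[, S, drop = FALSE], 1L, any))
      sum_r2 <- sum(apply(r2c[, S, drop = FALSE], 1L, max))
      cand <- list(S = S, coverage = cov_, sum_r2 = sum_r2)
      if (is.null(best) || cov_ > best$coverage ||
          (cov_ == best$coverage && sum_r2 > best$sum_r2 + 1e-12))
        best <- cand
    }
    per_n[[k]] <- data.frame(
      n = k, subset = paste(vars[best$S], collapse = " | "),
      n_explained = best$coverage, sum_r2 = best$sum_r2)
  }
  per_n <- do.call(rbind, per_n)
  sel_n <- if (!is.null(n_select)) {
    min(as.integer(n_select), nrow(per_n))
  } else if (nrow(per_n) == 0L) 0L else {
    # stop rule mirroring the stepwise criterion
    inc <- diff(c(0L, per_n$n_explained)) / max(n_total, 1L)
    k <- which(inc < stop_frac)
    if (length(k) == 0L) nrow(per_n) else max(k[1] - 1L, 0L)
  }
  selected <- if (sel_n > 0L)
    strsplit(per_n$subset[sel_n], " \\| ")[[1]] else character(0)
  structure(list(selected = selected, per_n = per_n, epoch = epoch,
                 n_total = n_total, procedure = "best_subset",
                 n_selected = sel_n),
            class = "gs_selection")
}

#' @export
print.gs_selection <- function(x, ...) {
  cat(sprintf("<gs_selection %s, epoch %s>: %s\n", x$procedure,
              if (is.null(x$epoch)) "all" else x$epoch,
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Classify cells by their dominant encoded variable
#'
#' Each cell is assigned the selected variable with the largest summed
#' effective R-squared across all its task-related responses (all nine
#' windows). For `chosen juice` cells the encoded juice E (the juice
#' eliciting higher firing) is read from the sign of the chosen-juice
#' regression slope; `chosen cost` cells get the analogous encoded cost
#' level.
#'
#' @param reg A `gs_regressions` over the task-related responses.
#' @param collapsed Output of [collapse_r2()] on `reg`.
#' @param selected Character vector of selected families (typically the
#'   union of the two epochs' selections).
#' @return data.frame with one row per cell: `neuron_id`, `assigned`
#'   (`NA` if unclassified), `sum_r2`, `encoded_level`.
#' @export
classify_cells <- function(reg, collapsed, selected) {
  stopifnot(length(selected) > 0L)
  resp <- reg$responses
  cells <- sort(unique(resp$neuron_id))
  r2c <- collapsed$r2_eff[, selected, drop = FALSE]
  out <- do.call(rbind, lapply(cells, function(id) {
    rows <- which(resp$neuron_id == id)
    sums <- colSums(r2c[rows, , drop = FALSE])
    if (all(sums == 0))
      return(data.frame(neuron_id = id, assigned = NA_character_,
                        sum_r2 = 0, encoded_level = NA_character_))
    assigned <- selected[which.max(sums)]
    level <- NA_character_
    if (assigned %in% c("chosen juice", "chosen cost")) {
      comp <- if (assigned == "chosen juice") "chosen juice" else "chosen cost"
      sl <- reg$slope[rows, comp]
      r2 <- reg$r2_eff[rows, comp]
      msl <- if (any(r2 > 0)) stats::weighted.mean(sl, r2) else mean(sl)
      level <- if (assigned == "chosen juice") {
        if (isTRUE(msl > 0)) "B" else "A"   # variable is 1 when B chosen
      } else {
        if (isTRUE(msl > 0)) "low" else "high"  # 1 when low cost chosen
      }
    }
    data.frame(neuron_id = id, assigned = assigned,
               sum_r2 = max(sums), encoded_level = level)
  }))
  rownames(out) <- NULL
  out
}
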