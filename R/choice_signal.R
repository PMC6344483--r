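# Cost-overt/covert labeling of offer types, spike-density profiles, E/O
# trial grouping, and ROC choice probability for cells encoding the binary
# choice outcome.

#' Label quantity pairs as cost-overt or cost-covert
#'
#' A pair is cost-overt when the animal chose the low-cost offer more
#' frequently (by more than `margin`) than the high-cost offer — i.e. the
#' fraction of A choices when A was low-cost exceeds the fraction when A was
#' high-cost by more than `margin` — conditioned on each option (A and B,
#' pooled across the two cost configurations) being chosen at least
#' `min_choices` times. A pair in which the same option was chosen on every
#' trial of both configurations is cost-covert regardless of the choice
#' counts, as is a pair whose choice shift stays within `margin` with both
#' options chosen at least `min_choices` times. Remaining pairs — seen in a
#' single cost configuration, or shifting but with too few choices of one
#' option to certify it — are `insufficient`.
#'
#' @param session A `gs_session`.
#' @param margin Choice-shift threshold (default 0.10).
#' @param min_choices Minimum times each option must be chosen (default 2).
#' @return data.frame with one row per quantity pair: `qA`, `qB`, `pA_low`,
#'   `pA_high`, `n_A_chosen`, `n_B_chosen`, `label`.
#' @export
label_cost_overt <- function(session, margin = 0.10, min_choices = 2L) {
  trials <- session$trials
  key <- interaction(trials$qA, trials$qB, drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(trials)), key), function(i) {
    tr <- trials[i, , drop = FALSE]
    low <- tr$costA == "low"
    nA <- sum(tr$chosen_juice == "A"); nB <- sum(tr$chosen_juice == "B")
    pA_low <- if (any(low)) mean(tr$chosen_juice[low] == "A") else NA_real_
    pA_high <- if (any(!low)) mean(tr$chosen_juice[!low] == "A") else NA_real_
    label <- if (is.na(pA_low) || is.na(pA_high)) "insufficient"
    else if (nA == 0L || nB == 0L) "covert"   # consistent choice throughout
    else if (nA < min_choices || nB < min_choices) "insufficient"
    else if (pA_low - pA_high > margin) "overt"
    else "covert"
    data.frame(qA = tr$qA[1], qB = tr$qB[1], pA_low = pA_low,
               pA_high = pA_high, n_A_chosen = nA, n_B_chosen = nB,
               label = label, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$qB / pmax(out$qA, 1e-9)), ]
}

#' Spike-density function of one spike train
#'
#' Spike times are convolved with a Gaussian kernel (sigma = `sigma`
#' seconds) on a 1 ms grid spanning `window` around the alignment time. The
#' kernel is truncated at the grid edges without renormalization, so the
#' integral of the profile equals the spike count up to edge effects.
#'
#' @param spikes Numeric spike times (seconds, trial clock).
#' @param align Alignment event time (seconds, trial clock).
#' @param window Length-2 numeric: grid span relative to `align`.
#' @param sigma Kernel standard deviation in seconds (default 0.040).
#' @return List with `time` (grid, s relative to align) and `rate`
#'   (spikes/s).
#' @export
sdf <- function(spikes, align, window = c(-0.5, 1.0), sigma = 0.040) {
  grid <- seq(window[1], window[2], by = 0.001)
  if (length(grid) == 0L) stop("empty time grid")
  rate <- numeric(length(grid))
  for (t in spikes - align) {
    rate <- rate + stats::dnorm(grid, mean = t, sd = sigma)
  }
  list(time = grid, rate = rate)
}

#' Normalize an activity profile
#'
#' Subtracts the cell's mean pre-offer activity and divides by its mean
#' activity averaged across the other eight time windows.
#'
#' @param rate Numeric profile (spikes/s).
#' @param pre_offer_mean Mean rate in the pre-offer window.
#' @param other_mean Mean rate across the other eight windows; must be > 0.
#' @return Normalized profile, or `NULL` (with a warning) when the divisor
#'   is not positive — such cells are excluded from population averages.
#' @export
normalize_profile <- function(rate, pre_offer_mean, other_mean) {
  if (!is.finite(other_mean) || other_mean <= 0) {
    warning("zero divisor in profile normalization; profile excluded")
    return(NULL)
  }
  (rate - pre_offer_mean) / other_mean
}

#' Area under the ROC curve from two groups of spike counts
#'
#' The probability that a random draw from `x1` exceeds one from `x2`, ties
#' counted half: the probability with which an ideal observer infers the
#' choice from the spike count.
#'
#' @param x1,x2 Numeric vectors of raw spike counts (both non-empty).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(x1, x2) {
  if (length(x1) == 0L || length(x2) == 0L)
    stop("both groups must be non-empty")
  cmp <- outer(x1, x2, ">") + 0.5 * outer(x1, x2, "==")
  mean(cmp)
}

POST_OFFER_ROC <- data.frame(
  name = c("post_offer_1", "post_offer_2", "post_offer_3"),
  start = c(0, 0.25, 0.5), end = c(0.25, 0.5, 0.75))

# Spike counts of one neuron in a sub-window after offer onset, per trial.
post_offer_counts <- function(session, neuron_id, start, end) {
  trials <- session$trials
  sp <- session$spikes
  sp <- sp[sp$neuron_id == neuron_id, , drop = FALSE]
  s <- trials$offer_on[sp$trial] + start
  e <- trials$offer_on[sp$trial] + end
  inw <- sp$spike_time_s >= s & sp$spike_time_s < e
  tabulate(sp$trial[inw], nbins = nrow(trials))
}

#' Choice probability of one cell in one post-offer window
#'
#' Restricted to cost-overt quantity pairs: within each eligible pair,
#' trials are split by the choice outcome relevant to the cell — chose the
#' encoded juice E vs the other juice O for `chosen juice` cells, chose the
#' low- vs high-cost offer for `chosen cost` cells — and the ROC AUC is
#' computed on raw spike counts. The cell's AUC is the mean across eligible
#' pairs (both outcome groups non-empty).
#'
#' @param session A `gs_session`.
#' @param neuron_id Neuron to analyze.
#' @param window One of `"post_offer_1"` (0-250 ms), `"post_offer_2"`
#'   (250-500 ms), `"post_offer_3"` (500-750 ms after offer onset).
#' @param labels Output of [label_cost_overt()].
#' @param cell_type `"chosen juice"` or `"chosen cost"`.
#' @param encoded_level Juice E (`"A"`/`"B"`) for chosen-juice cells; the
#'   preferred cost (`"low"`/`"high"`) for chosen-cost cells.
#' @return List with `mean_auc`, `per_pair` (data.frame), `n_pairs`;
#'   `mean_auc` is `NA` when no pair is eligible.
#' @export
cell_choice_probability <- function(session, neuron_id, window, labels,
                                    cell_type = "chosen juice",
                                    encoded_level = "B") {
  wi <- match(window, POST_OFFER_ROC$name)
  if (is.na(wi)) stop("unknown ROC window: ", window)
  counts <- post_offer_counts(session, neuron_id,
                              POST_OFFER_ROC$start[wi], POST_OFFER_ROC$end[wi])
  trials <- session$trials
  grp_E <- if (cell_type == "chosen juice") trials$chosen_juice == encoded_level
  else trials$chosen_cost == encoded_level
  overt <- labels[labels$label == "overt", , drop = FALSE]
  per_pair <- do.call(rbind, lapply(seq_len(nrow(overt)), function(j) {
    sel <- trials$qA == overt$qA[j] & trials$qB == overt$qB[j]
    x1 <- counts[sel & grp_E]; x2 <- counts[sel & !grp_E]
    if (length(x1) == 0L || length(x2) == 0L) return(NULL)
    data.frame(qA = overt$qA[j], qB = overt$qB[j], auc = auc(x1, x2),
               n_E = length(x1), n_O = length(x2))
  }))
  if (is.null(per_pair) || nrow(per_pair) == 0L)
    return(list(mean_auc = NA_real_, per_pair = NULL, n_pairs = 0L))
  list(mean_auc = mean(per_pair$auc), per_pair = per_pair,
       n_pairs = nrow(per_pair))
}

#' Population test of choice probability against chance
#'
#' One-sample t test of the per-cell mean AUC against 0.5 (two-sided).
#'
#' @param auc_values Numeric vector of per-cell mean AUC (NAs dropped).
#' @param min_cells Minimum number of cells (default 3).
#' @return List with `mean_auc`, `p`, `n`.
#' @export
population_auc_test <- function(auc_values, min_cells = 3L) {
  x <- auc_values[!is.na(auc_values)]
  if (length(x) < min_cells)
    stop("population AUC test requires at least ", min_cells, " cells")
  p <- if (stats::sd(x) == 0) {
    if (isTRUE(all.equal(mean(x), 0.5))) 1 else NA_real_
  } else stats::t.test(x, mu = 0.5)$p.value
  list(mean_auc = mean(x), p = p, n = length(x))
}

#' Grouped, normalized activity traces for one choice-outcome cell
#'
#' Trials are divided into four groups by the choice outcome (encoded E vs
#' other O) and the cost-overt/covert label of the trial's quantity pair;
#' the per-group trial-averaged spike-density profile is computed at each
#' alignment (offer on, target on, juice delivery) and normalized by the
#' cell's window statistics. Cells lacking `min_trials` trials in any group
#' are excluded.
#'
#' @inheritParams cell_choice_probability
#' @param min_trials Minimum trials per group (default 2).
#' @param sigma Kernel width (s).
#' @return List with `included` (logical), per-alignment lists of four
#'   traces (`Ec`, `Eo`, `Oc`, `Oo`; each with `time` and `rate`), and the
#'   group trial counts. `NULL` traces when excluded.
#' @export
group_traces <- function(session, neuron_id, labels,
                         cell_type = "chosen juice", encoded_level = "B",
                         min_trials = 2L, sigma = 0.040) {
  trials <- session$trials
  grp_E <- if (cell_type == "chosen juice") trials$chosen_juice == encoded_level
  else trials$chosen_cost == encoded_level
  lab_of_pair <- labels$label[match(paste(trials$qA, trials$qB),
                                    paste(labels$qA, labels$qB))]
  groups <- list(
    Ec = grp_E & lab_of_pair == "covert",
    Eo = grp_E & lab_of_pair == "overt",
    Oc = !grp_E & lab_of_pair == "covert",
    Oo = !grp_E & lab_of_pair == "overt"
  )
  counts <- vapply(groups, sum, 0L)
  if (any(counts < min_trials))
    return(list(included = FALSE, counts = counts, traces = NULL))
  spl <- neuron_spike_list(session, neuron_id)
  rmat <- windowed_rates(session, neurons = neuron_id)
  mean_rates <- apply(rmat$rates[1, , , drop = TRUE], 1L, mean)
  pre <- mean_rates[["pre_offer"]]
  other <- mean(mean_rates[setdiff(WINDOW_NAMES, "pre_offer")])
  aligns <- c(offer_on = "offer_on", target_on = "target_on",
              juice = "juice_time")
  traces <- lapply(aligns, function(ev) {
    lapply(groups, function(g) {
      idx <- which(g)
      prof <- NULL
      for (i in idx) {
        s <- sdf(spl[[i]], trials[[ev]][i], window = c(-0.5, 1.0),
                 sigma = sigma)
        prof <- if (is.null(prof)) s$rate else prof + s$rate
      }
      rate <- prof / length(idx)
      norm <- normalize_profile(rate, pre, other)
      list(time = seq(-0.5, 1.0, by = 0.001),
           rate = rate, normalized = norm)
    })
  })
  list(included = TRUE, counts = counts, traces = traces)
}
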