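# Response matrix (neuron x window x trial spike counts/rates) and the
# two three-way ANOVAs that identify task-related responses.

#' Build the neuron x window x trial response matrix
#'
#' Counts spikes of each neuron in each of the nine task-aligned windows of
#' every trial; rates are counts divided by the window duration (0.5 s for
#' all windows).
#'
#' @param session A `gs_session` with spikes.
#' @param neurons Optional subset of neuron ids.
#' @return A list of class `gs_response_matrix` with 3-d arrays `counts` and
#'   `rates` (neuron x window x trial) and the id/name vectors.
#' @export
windowed_rates <- function(session, neurons = NULL) {
  if (is.null(session$spikes)) stop("session carries no spikes")
  if (is.null(neurons)) neurons <- session_neurons(session)
  trials <- session$trials
  n_tr <- nrow(trials)
  wb <- window_bounds(trials)
  counts <- array(0L, dim = c(length(neurons), 9L, n_tr),
                  dimnames = list(neurons, WINDOW_NAMES, NULL))
  sp <- session$spikes
  sp <- sp[sp$neuron_id %in% neurons, , drop = FALSE]
  by_neuron <- split(sp[, c("trial", "spike_time_s")], sp$neuron_id)
  for (id in names(by_neuron)) {
    d <- by_neuron[[id]]
    i <- match(id, neurons)
    tr <- d$trial
    tt <- d$spike_time_s
    for (w in 1:9) {
      inw <- tt >= wb$start[cbind(tr, w)] & tt < wb$end[cbind(tr, w)]
      counts[i, w, ] <- tabulate(tr[inw], nbins = n_tr)
    }
  }
  dur <- window_specs()$end_offset - window_specs()$start_offset
  rates <- sweep(counts, 2L, dur, "/")
  structure(
    list(neurons = neurons, windows = WINDOW_NAMES, counts = counts,
         rates = rates, session_id = session$session_id),
    class = "gs_response_matrix"
  )
}

SCREEN_FACTORS <- c("trial_type", "offerA_loc", "targetA_loc",
                    "chosen_offer_loc", "chosen_target_loc")

# Trial-type factor: one level per (offer type, chosen juice) tuple.
trial_type_factor <- function(trials) {
  interaction(trials$qA, trials$qB, trials$costA, trials$chosen_juice,
              drop = TRUE, lex.order = TRUE)
}

# Residual sums of squares of Y (matrix, columns = responses) under a
# precomputed QR; returns a vector over columns.
rss_under <- function(qr_obj, Y) colSums(qr.resid(qr_obj, Y)^2)

#' Screen responses for task-relatedness with two three-way ANOVAs
#'
#' Each response (one neuron in one window, rates as a function of trial) is
#' submitted to two main-effects-only three-way ANOVAs:
#' (trial type x offer A location x target A location) and
#' (trial type x chosen offer location x chosen target location). Main-effect
#' p-values are type-II F tests; the trial-type factor is shared between the
#' two models and computed once (from the first). A response is task-related
#' if any factor's p-value is below `alpha`. Trial-type levels with fewer
#' than two trials are dropped; factors collapsed to a single level yield an
#' undefined p excluded from the minimum.
#'
#' @param rmat A `gs_response_matrix`.
#' @param session The matching `gs_session`.
#' @param alpha Significance threshold (default 0.001).
#' @return data.frame of class `gs_relatedness` with one row per response:
#'   `neuron_id`, `window`, the five factor p-values and `task_related`.
#' @export
anova_screen <- function(rmat, session, alpha = 0.001) {
  trials <- session$trials
  tt <- trial_type_factor(trials)
  keep <- tt %in% names(which(table(tt) >= 2L))
  trials <- trials[keep, , drop = FALSE]
  tt <- droplevels(tt[keep])
  facs <- list(
    trial_type = tt,
    offerA_loc = factor(trials$offerA_side),
    targetA_loc = factor(trials$targetA_side),
    chosen_offer_loc = factor(trials$chosen_offer_side),
    chosen_target_loc = factor(trials$chosen_target_side)
  )
  models <- list(
    m1 = c("trial_type", "offerA_loc", "targetA_loc"),
    m2 = c("trial_type", "chosen_offer_loc", "chosen_target_loc")
  )
  n <- sum(keep)
  # responses as columns: (neuron, window) pairs
  nr <- length(rmat$neurons); nw <- 9L
  if (n < 3L) {
    # no analyzable design (e.g. every trial-type level dropped)
    out <- data.frame(neuron_id = rep(rmat$neurons, times = nw),
                      window = rep(WINDOW_NAMES, each = nr),
                      stringsAsFactors = FALSE)
    for (f in SCREEN_FACTORS) out[[f]] <- NA_real_
    out$task_related <- FALSE
    attr(out, "alpha") <- alpha
    class(out) <- c("gs_relatedness", class(out))
    return(out)
  }
  Y <- matrix(aperm(rmat$rates[, , keep, drop = FALSE], c(3L, 1L, 2L)),
              nrow = n)
  # column j corresponds to neuron (j-1) %% nr + 1, window (j-1) %/% nr + 1
  pvals <- matrix(NA_real_, ncol(Y), length(SCREEN_FACTORS),
                  dimnames = list(NULL, SCREEN_FACTORS))
  tt_done <- FALSE
  for (m in models) {
    usable <- m[vapply(facs[m], nlevels, 0L) >= 2L]
    if (length(usable) == 0L) next
    X_full <- stats::model.matrix(
      ~ ., data = as.data.frame(facs[usable], optional = TRUE))
    qr_full <- qr(X_full)
    rss_full <- rss_under(qr_full, Y)
    df_res <- n - qr_full$rank
    for (f in usable) {
      if (f == "trial_type" && tt_done) next
      if (f == "trial_type") tt_done <- TRUE
      others <- setdiff(usable, f)
      X_red <- if (length(others))
        stats::model.matrix(~ ., data = as.data.frame(facs[others],
                                                      optional = TRUE))
      else matrix(1, n, 1L)
      qr_red <- qr(X_red)
      df_f <- qr_full$rank - qr_red$rank
      if (df_f <= 0L || df_res <= 0L) next
      rss_red <- rss_under(qr_red, Y)
      Fstat <- ((rss_red - rss_full) / df_f) / (rss_full / df_res)
      p <- stats::pf(Fstat, df_f, df_res, lower.tail = FALSE)
      p[!is.finite(Fstat)] <- NA_real_  # zero-variance responses
      pvals[, f] <- p
    }
  }
  out <- data.frame(
    neuron_id = rep(rmat$neurons, times = nw),
    window = rep(WINDOW_NAMES, each = nr),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(pvals))
  pmin_row <- suppressWarnings(
    apply(pvals, 1L, function(p) if (all(is.na(p))) Inf else min(p, na.rm = TRUE)))
  out$task_related <- pmin_row < alpha
  attr(out, "alpha") <- alpha
  class(out) <- c("gs_relatedness", class(out))
  out
}

#' Task-related responses and cells
#'
#' @param relatedness Output of [anova_screen()].
#' @return List with `responses` (task-related rows), `cells` (neurons with
#'   at least one task-related response) and `tally`, a window x factor table
#'   of the number of cells significant for each factor in each window.
#' @export
task_related_set <- function(relatedness) {
  alpha <- attr(relatedness, "alpha")
  responses <- relatedness[relatedness$task_related, , drop = FALSE]
  cells <- sort(unique(responses$neuron_id))
  tally <- sapply(SCREEN_FACTORS, function(f)
    vapply(WINDOW_NAMES, function(w) {
      p <- relatedness[[f]][relatedness$window == w]
      sum(!is.na(p) & p < alpha)
    }, 0L))
  list(responses = responses, cells = cells, tally = tally)
}
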