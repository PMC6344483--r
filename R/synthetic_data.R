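# Synthetic sessions and spike trains with known ground truth. Choices are
# drawn from the logistic choice model (see behavior.R) with configurable
# indices; neurons fire as Poisson processes whose window-wise rate is linear
# in any catalog variable.

#' Configuration of the session generator
#'
#' Defaults reproduce the study conditions used throughout the test suite:
#' steepness a0 = 2, relative value rho = 2.5, action cost xi = 0.25, juice
#' hysteresis eta = 0.2, remaining indices 0, and an offer menu spanning
#' #B:#A ratios 1:3 to 4:1 (forced choices excluded). Each (quantity pair x
#' cost configuration x offer side) cell receives `trials_per_condition`
#' trials, fully counterbalanced; 83 trials per cell yields 1992 trials,
#' the closest counterbalanced design to a 2000-trial session.
#'
#' @param a0 Logistic steepness (inverse temperature), must be > 0.
#' @param rho,xi,eta,phi,delta,epsilon Normalized indices; the generating
#'   coefficients are `a_k = a0 * index`.
#' @param offer_types Two-column matrix or data.frame of quantity pairs
#'   (`qA`, `qB`).
#' @param trials_per_condition Trials per (pair x cost x side) cell.
#' @param seed Integer seed; sessions are deterministic given the seed.
#' @param go_jitter Range (s) of the randomly variable delay between target
#'   onset and the go signal.
#' @param reaction_time Constant saccade latency after the go signal (s).
#' @return A list of class `gs_generator_config`.
#' @export
generator_config <- function(a0 = 2, rho = 2.5, xi = 0.25, eta = 0.2,
                             phi = 0, delta = 0, epsilon = 0,
                             offer_types = default_offer_types(),
                             trials_per_condition = 83L, seed = 1L,
                             go_jitter = c(0.6, 1.2), reaction_time = 0.2) {
  offer_types <- as.data.frame(offer_types)
  if (nrow(offer_types) == 0L || ncol(offer_types) != 2L)
    stop("offer_types must be a non-empty two-column table")
  names(offer_types) <- c("qA", "qB")
  if (any(offer_types$qA < 0 | offer_types$qB < 0) ||
      any(offer_types$qA == 0 & offer_types$qB == 0))
    stop("invalid quantity pair in offer_types")
  stopifnot(a0 > 0, trials_per_condition >= 1L)
  structure(
    list(a0 = a0, rho = rho, xi = xi, eta = eta, phi = phi, delta = delta,
         epsilon = epsilon, offer_types = offer_types,
         trials_per_condition = as.integer(trials_per_condition),
         seed = as.integer(seed), go_jitter = go_jitter,
         reaction_time = reaction_time),
    class = "gs_generator_config"
  )
}

#' Default offer-type menu
#'
#' Quantity pairs covering #B:#A ratios 1:3, 1:2, 1:1, 2:1, 3:1 and 4:1.
#' @return data.frame with columns `qA`, `qB`.
#' @export
default_offer_types <- function() {
  data.frame(qA = c(3L, 2L, 1L, 1L, 1L, 1L),
             qB = c(1L, 1L, 1L, 2L, 3L, 4L))
}

#' Generate a synthetic behavioral session
#'
#' Builds a counterbalanced, shuffled trial sequence; samples target angles
#' (the two targets always in opposite hemifields); samples event times
#' within the task's bounds; and draws each choice from the logistic model,
#' sequentially, so that the hysteresis terms depend on the realized previous
#' choice.
#'
#' @param cfg A `gs_generator_config`.
#' @return A `gs_session` with the generator configuration attached as
#'   element `generator`.
#' @export
generate_session <- function(cfg) {
  stopifnot(inherits(cfg, "gs_generator_config"))
  set.seed(cfg$seed)
  grid <- expand.grid(pair = seq_len(nrow(cfg$offer_types)),
                      costA = c("low", "high"), offerA_side = c("L", "R"),
                      stringsAsFactors = FALSE)
  grid <- grid[rep(seq_len(nrow(grid)), each = cfg$trials_per_condition), ]
  grid <- grid[sample.int(nrow(grid)), ]
  n <- nrow(grid)
  angleA <- sample(TASK_ANGLES, n, replace = TRUE)
  sideA <- hemifield_of_angle(angleA)
  opposite <- list(L = TASK_ANGLES[!TASK_ANGLES %in% LEFT_ANGLES],
                   R = LEFT_ANGLES)
  angleB <- vapply(sideA, function(s) sample(opposite[[s]], 1L), numeric(1))
  offer_on <- rep(1.5, n)
  target_on <- offer_on + 2.0
  go <- target_on + stats::runif(n, cfg$go_jitter[1], cfg$go_jitter[2])
  saccade <- go + cfg$reaction_time
  trials <- data.frame(
    trial = seq_len(n),
    qA = cfg$offer_types$qA[grid$pair],
    qB = cfg$offer_types$qB[grid$pair],
    costA = grid$costA,
    costB = ifelse(grid$costA == "low", "high", "low"),
    offerA_side = grid$offerA_side,
    angleA = angleA, angleB = angleB,
    offer_on = offer_on, offer_off = offer_on + 1.0,
    target_on = target_on, go = go, saccade = saccade,
    juice_time = saccade + 0.75,
    stringsAsFactors = FALSE
  )
  a <- cfg$a0 * c(1, cfg$rho, cfg$xi, cfg$eta, cfg$phi, cfg$delta, cfg$epsilon)
  targetA_side <- hemifield_of_angle(angleA)
  targetB_side <- hemifield_of_angle(angleB)
  offerB_side <- ifelse(trials$offerA_side == "L", "R", "L")
  x_static <- a[1] * trials$qB - a[2] * trials$qA +
    a[3] * ((trials$costB == "low") - (trials$costA == "low")) +
    a[6] * ((offerB_side == "L") - (trials$offerA_side == "L")) +
    a[7] * ((targetB_side == "L") - (targetA_side == "L"))
  u <- stats::runif(n)
  choice <- character(n)
  prevj <- "none"; prevc <- "none"
  for (t in seq_len(n)) {
    x <- x_static[t]
    if (prevj != "none") {
      x <- x + a[4] * ((prevj == "B") - (prevj == "A")) +
        a[5] * ((trials$costB[t] == prevc) - (trials$costA[t] == prevc))
    }
    choice[t] <- if (u[t] < stats::plogis(x)) "B" else "A"
    prevj <- choice[t]
    prevc <- if (choice[t] == "A") trials$costA[t] else trials$costB[t]
  }
  trials$chosen_juice <- choice
  s <- session(trials, session_id = sprintf("sim-seed%d", cfg$seed))
  s$generator <- cfg
  s
}

#' Specify a simulated neuron
#'
#' A neuron fires as a Poisson process at `baseline_rate` everywhere; within
#' each tuned window its rate is `max(0, baseline + sign * slope * v(trial))`
#' where `v` is the encoded catalog variable (rate floored at zero by
#' truncation). Multi-component tunings (different variables in different
#' windows) can be supplied through `tunings`.
#'
#' @param neuron_id Character id, unique within a cohort.
#' @param encoded_variable Catalog variable name, or `"untuned"`.
#' @param baseline_rate Baseline firing rate, spikes/s, >= 0.
#' @param slope Tuning slope, spikes/s per unit of the variable.
#' @param sign `+1` or `-1`.
#' @param tuned_windows Windows in which the tuning applies; default all
#'   windows after the pre-offer baseline.
#' @param variant Variable variant used to drive the rate (`"affected"` or
#'   `"independent"`, see [evaluate_variable()]).
#' @param tunings Optional list of lists with elements `variable`, `slope`,
#'   `sign`, `windows`, `variant`, overriding the single-variable fields.
#' @return A list of class `gs_neuron_spec`.
#' @export
neuron_spec <- function(neuron_id, encoded_variable = "untuned",
                        baseline_rate = 10, slope = 0, sign = 1,
                        tuned_windows = setdiff(WINDOW_NAMES, "pre_offer"),
                        variant = "affected", tunings = NULL) {
  if (baseline_rate < 0) stop("baseline_rate must be >= 0")
  if (is.null(tunings)) {
    if (identical(encoded_variable, "untuned")) {
      if (slope != 0) stop("untuned neurons must have slope 0")
      tunings <- list()
    } else {
      tunings <- list(list(variable = encoded_variable, slope = slope,
                           sign = sign, windows = tuned_windows,
                           variant = variant))
    }
  }
  for (tu in tunings) {
    if (!all(tu$windows %in% WINDOW_NAMES))
      stop("unknown tuned window for neuron ", neuron_id)
    if (!tu$variable %in% variable_catalog()$name)
      stop("unknown encoded variable: ", tu$variable)
  }
  structure(
    list(neuron_id = as.character(neuron_id),
         encoded_variable = if (length(tunings)) tunings[[1]]$variable
                            else "untuned",
         baseline_rate = baseline_rate, tunings = tunings),
    class = "gs_neuron_spec"
  )
}

#' Tuning slope for a target signal-to-noise ratio
#'
#' SNR is defined as `slope * range(v) / sqrt(baseline)`; this solves for the
#' slope.
#'
#' @param snr Target SNR.
#' @param baseline_rate Baseline rate, spikes/s.
#' @param variable_range Range of the encoded variable over the session.
#' @return Slope in spikes/s per unit of the variable.
#' @export
slope_for_snr <- function(snr, baseline_rate, variable_range) {
  if (variable_range <= 0) stop("variable range must be positive")
  snr * sqrt(baseline_rate) / variable_range
}

# Window start/end times per trial, as n x 9 matrices.
window_bounds <- function(trials) {
  ws <- window_specs()
  anchors <- vapply(ws$anchor, function(a) trials[[a]], numeric(nrow(trials)))
  if (nrow(trials) == 1L) anchors <- matrix(anchors, nrow = 1L)
  list(start = sweep(anchors, 2L, ws$start_offset, "+"),
       end = sweep(anchors, 2L, ws$end_offset, "+"),
       names = ws$name)
}

#' Generate spike trains for one neuron across a session
#'
#' Homogeneous Poisson spiking at the baseline rate over the recorded span of
#' each trial, modified inside tuned windows by superposition (rate above
#' baseline) or thinning (rate below baseline). Spike times are reported at
#' 0.1 ms resolution.
#'
#' @param spec A `gs_neuron_spec`.
#' @param session A `gs_session`.
#' @param seed Integer seed.
#' @param fit Value parameters (`rho`, `xi`) used to evaluate the encoded
#'   variable; defaults to the session's generating indices.
#' @return data.frame with columns `neuron_id`, `trial`, `spike_time_s`.
#' @export
generate_neuron <- function(spec, session, seed = 1L, fit = NULL) {
  stopifnot(inherits(spec, "gs_neuron_spec"), inherits(session, "gs_session"))
  if (is.null(fit)) {
    if (is.null(session$generator))
      stop("supply `fit`: session carries no generating indices")
    fit <- list(rho = session$generator$rho, xi = session$generator$xi)
  }
  set.seed(seed)
  trials <- session$trials
  n <- nrow(trials)
  span <- trial_span_end(trials)
  b <- spec$baseline_rate
  # per-trial rate offset in each of the nine windows
  delta <- matrix(0, n, 9L, dimnames = list(NULL, WINDOW_NAMES))
  for (tu in spec$tunings) {
    v <- evaluate_variable(tu$variable, trials, fit, tu$variant)
    delta[, tu$windows] <- delta[, tu$windows] + tu$sign * tu$slope * v
  }
  counts0 <- stats::rpois(n, b * span)
  trial_of <- rep.int(seq_len(n), counts0)
  t_all <- stats::runif(sum(counts0)) * span[trial_of]
  wb <- window_bounds(trials)
  active <- which(colSums(delta != 0) > 0)
  for (w in active) {
    rate <- pmax(0, b + delta[, w])
    dur <- wb$end[, w] - wb$start[, w]
    # superposition above baseline
    lam <- pmax(0, rate - b) * dur
    add <- stats::rpois(n, lam)
    if (any(add > 0)) {
      tr_add <- rep.int(seq_len(n), add)
      t_add <- wb$start[cbind(tr_add, w)] + stats::runif(sum(add)) * dur[tr_add]
      trial_of <- c(trial_of, tr_add)
      t_all <- c(t_all, t_add)
    }
    # thinning below baseline
    if (b > 0 && any(rate < b)) {
      keep_p <- rate / b
      in_w <- t_all >= wb$start[cbind(trial_of, rep(w, length(trial_of)))] &
        t_all < wb$end[cbind(trial_of, rep(w, length(trial_of)))]
      drop <- in_w & stats::runif(length(t_all)) > keep_p[trial_of]
      trial_of <- trial_of[!drop]
      t_all <- t_all[!drop]
    }
  }
  ord <- order(trial_of, t_all)
  data.frame(neuron_id = rep(spec$neuron_id, length(ord)),
             trial = trial_of[ord],
             spike_time_s = round(t_all[ord], 4L),
             stringsAsFactors = FALSE)
}

#' Generate a labeled cohort of neurons over one session
#'
#' @param cfg A `gs_generator_config` for the behavioral session.
#' @param neuron_specs List of `gs_neuron_spec` with unique ids.
#' @return A list of class `gs_cohort` with elements `session` (spikes
#'   attached) and `ground_truth` (neuron id, encoded variable, family,
#'   baseline, slope, sign, tuned windows).
#' @export
generate_cohort <- function(cfg, neuron_specs) {
  ids <- vapply(neuron_specs, `[[`, character(1), "neuron_id")
  if (anyDuplicated(ids)) stop("duplicate neuron ids in cohort")
  s <- generate_session(cfg)
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(neuron_specs))
  spikes <- do.call(rbind, lapply(seq_along(neuron_specs), function(i)
    generate_neuron(neuron_specs[[i]], s, seed = seeds[i])))
  s$spikes <- spikes
  cat_ <- variable_catalog()
  truth <- do.call(rbind, lapply(neuron_specs, function(sp) {
    tu <- if (length(sp$tunings)) sp$tunings[[1]] else
      list(variable = "untuned", slope = 0, sign = 1, windows = character(0))
    fam <- if (tu$variable == "untuned") "untuned" else
      cat_$family[match(tu$variable, cat_$name)]
    data.frame(neuron_id = sp$neuron_id, encoded_variable = tu$variable,
               family = fam, baseline_rate = sp$baseline_rate,
               slope = tu$slope, sign = tu$sign,
               tuned_windows = paste(tu$windows, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  structure(list(session = s, ground_truth = truth), class = "gs_cohort")
}

#' Write a cohort to plain-text files
#' @param cohort A `gs_cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  write_session(cohort$session, dir)
  utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Standard recovery cohort specification
#'
#' Builds neuron specs for a label-recovery benchmark: `n_per_group` neurons
#' for each entry of `variables` plus `n_untuned` untuned neurons, all at a
#' common baseline and signal-to-noise ratio (slopes solved per variable from
#' its range over the session).
#'
#' @param session A generated `gs_session` (provides variable ranges).
#' @param variables Character vector of catalog variable names.
#' @param n_per_group Neurons per tuned variable.
#' @param n_untuned Untuned neurons.
#' @param snr Signal-to-noise ratio (`slope * range / sqrt(baseline)`).
#' @param baseline_rate Baseline rate, spikes/s.
#' @return List of `gs_neuron_spec`.
#' @export
recovery_specs <- function(session,
                           variables = c("offer value A", "offer value -",
                                         "chosen value", "chosen juice"),
                           n_per_group = 10L, n_untuned = 10L, snr = 2,
                           baseline_rate = 10) {
  fit <- list(rho = session$generator$rho, xi = session$generator$xi)
  specs <- list()
  for (v in variables) {
    vals <- evaluate_variable(v, session$trials, fit)
    sl <- slope_for_snr(snr, baseline_rate, diff(range(vals)))
    for (i in seq_len(n_per_group)) {
      specs[[length(specs) + 1L]] <- neuron_spec(
        sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "_", v), i),
        encoded_variable = v, baseline_rate = baseline_rate, slope = sl,
        sign = if (i %% 2L == 0L) -1 else 1
      )
    }
  }
  for (i in seq_len(n_untuned)) {
    specs[[length(specs) + 1L]] <- neuron_spec(
      sprintf("untuned_%02d", i), baseline_rate = baseline_rate)
  }
  specs
}
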