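# Data model for the juice-choice task with variable saccadic action costs:
# offer types, trial events, the nine analysis windows, spike-count bookkeeping
# and plain-text session I/O.

TASK_ANGLES <- c(22.5, 157.5, 202.5, 337.5)
LEFT_ANGLES <- c(157.5, 202.5)

#' The nine task-aligned analysis windows
#'
#' Each window is 0.5 s long and anchored to a behavioral event. Intervals are
#' half-open `[start, end)`: a spike exactly at the window start is counted,
#' one at the end is not, so adjacent windows never double-count.
#'
#' @return A data.frame with columns `name`, `anchor` (event column in the
#'   trial table), `start_offset` and `end_offset` (seconds relative to the
#'   anchor).
#' @export
window_specs <- function() {
  data.frame(
    name = c("pre_offer", "post_offer", "late_delay", "mem_delay",
             "pre_target", "post_target", "pre_go", "pre_juice", "post_juice"),
    anchor = c("offer_on", "offer_on", "offer_on", "offer_off",
               "target_on", "target_on", "go", "juice_time", "juice_time"),
    start_offset = c(-0.5, 0, 0.5, 0, -0.5, 0, -0.5, -0.5, 0),
    end_offset = c(0, 0.5, 1.0, 0.5, 0, 0.5, 0, 0, 0.5),
    stringsAsFactors = FALSE
  )
}

WINDOW_NAMES <- c("pre_offer", "post_offer", "late_delay", "mem_delay",
                  "pre_target", "post_target", "pre_go", "pre_juice",
                  "post_juice")

#' Parse an offer-type label
#'
#' Offer types are written `"1A+:3B-"`: integer quantities of juices A and B,
#' each flagged with its action cost (`+` low cost, short saccade; `-` high
#' cost, long saccade). Exactly one offer is low-cost. Either juice may come
#' first in the label.
#'
#' @param label Character scalar such as `"1A+:3B-"`. A unicode minus is
#'   accepted in place of `-`.
#' @return A list with integer `qA`, `qB` and `costA`, `costB` in
#'   `c("low", "high")`.
#' @examples
#' parse_offer_type("1A+:3B-")
#' @export
parse_offer_type <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  lab <- gsub("−", "-", gsub("\\s", "", label))
  m <- regmatches(lab, regexec("^([0-9]+)([AB])([+-]):([0-9]+)([AB])([+-])$", lab))[[1]]
  if (length(m) == 0L)
    stop("malformed offer-type label: ", label)
  j1 <- m[3]; j2 <- m[6]
  if (j1 == j2)
    stop("offer-type label must name both juices: ", label)
  q <- as.integer(c(m[2], m[5]))
  cost <- ifelse(c(m[4], m[7]) == "+", "low", "high")
  ord <- order(c(j1, j2))  # put A first
  q <- q[ord]; cost <- cost[ord]
  if (cost[1] == cost[2])
    stop("exactly one offer must be low-cost: ", label)
  if (q[1] == 0L && q[2] == 0L)
    stop("offer quantities cannot both be zero: ", label)
  list(qA = q[1], qB = q[2], costA = cost[1], costB = cost[2])
}

#' Format an offer type as a label
#'
#' Inverse of [parse_offer_type()]; always writes juice A first.
#'
#' @param offer List with `qA`, `qB`, `costA`, `costB`.
#' @return Character scalar label.
#' @export
format_offer_type <- function(offer) {
  sgn <- function(cost) if (cost == "low") "+" else "-"
  sprintf("%dA%s:%dB%s", offer$qA, sgn(offer$costA), offer$qB, sgn(offer$costB))
}

#' Hemifield of a saccade target angle
#'
#' Target angles take one of four task values (22.5, 157.5, 202.5, 337.5
#' degrees from azimuth); for all analyses the angle is collapsed to the
#' binary left/right hemifield.
#'
#' @param angle Numeric vector of angles in degrees.
#' @return Character vector in `c("L", "R")`.
#' @export
hemifield_of_angle <- function(angle) {
  if (!all(angle %in% TASK_ANGLES))
    stop("angle must be one of ", paste(TASK_ANGLES, collapse = ", "))
  ifelse(angle %in% LEFT_ANGLES, "L", "R")
}

#' Time interval of an analysis window in one trial
#'
#' @param window Window name (see [window_specs()]).
#' @param events Named list or one-row data.frame with the trial's event times
#'   (`offer_on`, `offer_off`, `target_on`, `go`, `saccade`, `juice_time`),
#'   in seconds from fixation onset.
#' @return Numeric `c(start, end)`; the interval is half-open `[start, end)`.
#' @export
window_interval <- function(window, events) {
  ws <- window_specs()
  i <- match(window, ws$name)
  if (is.na(i)) stop("unknown window: ", window)
  anchor <- events[[ws$anchor[i]]]
  if (is.null(anchor) || length(anchor) != 1L || is.na(anchor))
    stop("missing anchor event '", ws$anchor[i], "' for window ", window)
  c(anchor + ws$start_offset[i], anchor + ws$end_offset[i])
}

#' Count spikes in a half-open interval
#'
#' @param spikes Sorted numeric vector of spike times (seconds).
#' @param interval Numeric `c(start, end)`; counts spikes with
#'   `start <= t < end`.
#' @return Integer count.
#' @export
count_spikes <- function(spikes, interval) {
  if (is.unsorted(spikes)) stop("spike times must be sorted ascending")
  if (length(spikes) == 0L) return(0L)
  # findInterval with left.open = FALSE counts t < end and t < start boundaries
  sum(spikes >= interval[1] & spikes < interval[2])
}

# Derived trial columns: chosen cost/sides, offer B side, target B side,
# previous-trial outcome. Called on any trial table before analysis.
finalize_trials <- function(trials) {
  stopifnot(all(c("trial", "qA", "qB", "costA", "costB", "offerA_side",
                  "angleA", "angleB", "chosen_juice") %in% names(trials)))
  trials$targetA_side <- hemifield_of_angle(trials$angleA)
  trials$targetB_side <- hemifield_of_angle(trials$angleB)
  trials$offerB_side <- ifelse(trials$offerA_side == "L", "R", "L")
  a <- trials$chosen_juice == "A"
  trials$chosen_cost <- ifelse(a, trials$costA, trials$costB)
  trials$chosen_offer_side <- ifelse(a, trials$offerA_side, trials$offerB_side)
  trials$chosen_target_side <- ifelse(a, trials$targetA_side, trials$targetB_side)
  n <- nrow(trials)
  trials$prev_chosen_juice <- c("none", trials$chosen_juice[-n])
  trials$prev_chosen_cost <- c("none", trials$chosen_cost[-n])
  trials
}

#' Construct a session object
#'
#' A session bundles an ordered trial table with per-neuron spike-time
#' records. Trial times are absolute within each trial, with origin at
#' fixation onset.
#'
#' @param trials data.frame with columns `trial`, `qA`, `qB`, `costA`,
#'   `costB`, `offerA_side`, `angleA`, `angleB`, `chosen_juice`, `offer_on`,
#'   `offer_off`, `target_on`, `go`, `saccade`, `juice_time`.
#' @param spikes data.frame with columns `neuron_id`, `trial`,
#'   `spike_time_s`, or `NULL` for a behavior-only session.
#' @param session_id Character identifier.
#' @param juice_labels Length-2 character vector naming the juices.
#' @return An object of class `gs_session`.
#' @export
session <- function(trials, spikes = NULL, session_id = "session",
                    juice_labels = c("A", "B")) {
  if (nrow(trials) == 0L) stop("session must contain at least one trial")
  if (any(diff(trials$trial) != 1L) || trials$trial[1] != 1L)
    stop("trial indices must be consecutive starting at 1")
  ev <- trials[, c("offer_on", "offer_off", "target_on", "go", "saccade",
                   "juice_time")]
  if (any(apply(ev, 1L, function(x) any(diff(x) <= 0))))
    stop("event times must be strictly increasing within each trial")
  trials <- finalize_trials(trials)
  if (any(trials$costA == trials$costB))
    stop("exactly one offer must be low-cost in every trial")
  if (!is.null(spikes)) {
    stopifnot(all(c("neuron_id", "trial", "spike_time_s") %in% names(spikes)))
    if (any(!spikes$trial %in% trials$trial))
      stop("spike record refers to an unknown trial")
  }
  structure(
    list(session_id = session_id, juice_labels = juice_labels,
         trials = trials, spikes = spikes),
    class = "gs_session"
  )
}

#' @export
print.gs_session <- function(x, ...) {
  n_neu <- if (is.null(x$spikes)) 0L else length(unique(x$spikes$neuron_id))
  cat(sprintf("<gs_session '%s'>: %d trials, %d neurons\n",
              x$session_id, nrow(x$trials), n_neu))
  invisible(x)
}

#' Neuron ids recorded in a session
#' @param session A `gs_session`.
#' @return Character vector (possibly empty).
#' @export
session_neurons <- function(session) {
  if (is.null(session$spikes)) return(character(0))
  sort(unique(session$spikes$neuron_id))
}

#' End of the recorded span of each trial
#'
#' Trials are considered recorded from fixation onset (time 0) to 0.5 s after
#' juice delivery (the end of the post-juice window).
#' @param trials Trial table.
#' @return Numeric vector of span ends.
#' @export
trial_span_end <- function(trials) trials$juice_time + 0.5

# Spike times of one neuron split by trial, each sorted ascending.
neuron_spike_list <- function(session, neuron_id) {
  sp <- session$spikes
  sp <- sp[sp$neuron_id == neuron_id, , drop = FALSE]
  out <- split(sp$spike_time_s, factor(sp$trial, levels = session$trials$trial))
  lapply(out, sort)
}

#' Write a session to plain-text files
#'
#' Writes `trials.csv`, `spikes.csv` (if present) and `manifest.json` into
#' `dir`.
#'
#' @param session A `gs_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(session$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  if (!is.null(session$spikes))
    utils::write.csv(session$spikes, file.path(dir, "spikes.csv"),
                     row.names = FALSE)
  manifest <- list(session_id = session$session_id,
                   juice_labels = session$juice_labels,
                   n_trials = nrow(session$trials),
                   neurons = session_neurons(session))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir Directory containing `trials.csv` and optionally `spikes.csv`
#'   and `manifest.json`.
#' @return A `gs_session`.
#' @export
read_session <- function(dir) {
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  spike_path <- file.path(dir, "spikes.csv")
  spikes <- if (file.exists(spike_path))
    utils::read.csv(spike_path, stringsAsFactors = FALSE) else NULL
  man_path <- file.path(dir, "manifest.json")
  if (file.exists(man_path)) {
    man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
    session(trials, spikes, session_id = man$session_id,
            juice_labels = man$juice_labels)
  } else {
    session(trials, spikes, session_id = basename(dir))
  }
}
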