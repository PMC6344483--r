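# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# A small behavioral session (288 trials) with the default generator indices.
small_session <- function() {
  cached("small_session", function()
    generate_session(generator_config(seed = 301, trials_per_condition = 12L)))
}

# A tiny hand-built session: 4 trials, deterministic events, no jitter.
tiny_trials <- function() {
  data.frame(
    trial = 1:4,
    qA = c(1L, 1L, 2L, 1L), qB = c(2L, 3L, 1L, 1L),
    costA = c("low", "high", "low", "high"),
    costB = c("high", "low", "high", "low"),
    offerA_side = c("L", "R", "L", "R"),
    angleA = c(157.5, 22.5, 202.5, 337.5),
    angleB = c(22.5, 157.5, 337.5, 202.5),
    chosen_juice = c("B", "A", "A", "B"),
    offer_on = 1.5, offer_off = 2.5, target_on = 3.5,
    go = 4.2, saccade = 4.4, juice_time = 5.15,
    stringsAsFactors = FALSE
  )
}

tiny_session <- function(spikes = NULL) {
  session(tiny_trials(), spikes, session_id = "tiny")
}

# Slope giving a target SNR for a variable on a session
snr_slope <- function(session, variable, snr = 2, baseline = 10,
                      fit = NULL) {
  if (is.null(fit))
    fit <- list(rho = session$generator$rho, xi = session$generator$xi)
  vals <- evaluate_variable(variable, session$trials, fit)
  slope_for_snr(snr, baseline, diff(range(vals)))
}

# Brute-force oracle for best-subset selection: enumerate every subset of
# size k and score by (coverage, summed best R^2).
brute_force_best <- function(r2c, k) {
  vars <- seq_len(ncol(r2c))
  best <- NULL
  for (S in utils::combn(vars, k, simplify = FALSE)) {
    cov_ <- sum(apply(r2c[, S, drop = FALSE] > 0, 1L, any))
    s2 <- sum(apply(r2c[, S, drop = FALSE], 1L, max))
    if (is.null(best) || cov_ > best$cov ||
        (cov_ == best$cov && s2 > best$s2 + 1e-12))
      best <- list(cov = cov_, s2 = s2, S = S)
  }
  best
}

# Random selection instances for oracle tests: an effective-R^2 matrix with
# the given sparsity.
random_instance <- function(n_resp, n_var, p_explained = 0.3) {
  m <- matrix(0, n_resp, n_var,
              dimnames = list(NULL, paste0("v", seq_len(n_var))))
  hit <- matrix(stats::runif(n_resp * n_var) < p_explained, n_resp, n_var)
  m[hit] <- stats::runif(sum(hit))
  m
}
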