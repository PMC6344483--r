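# Logistic analysis of choice patterns. The model expresses the log odds of
# choosing juice B as
#
#   X = a0*#B - a1*#A + a2*(d[B low cost] - d[A low cost])
#     + a3*(d[prev chose B] - d[prev chose A])
#     + a4*(d[cost of B = prev chosen cost] - d[cost of A = prev chosen cost])
#     + a5*(d[offer B left] - d[offer A left])
#     + a6*(d[target B left] - d[target A left])
#
# with d[.] 0/1 indicators. Normalized indices, all in units of juice B:
# rho = a1/a0 (relative value), xi = a2/a0 (action cost), eta = a3/a0 (choice
# hysteresis, juice), phi = a4/a0 (choice hysteresis, cost), delta = a5/a0
# (offer-side bias), epsilon = a6/a0 (target-side bias).

COEF_NAMES <- paste0("a", 0:6)
INDEX_NAMES <- c("rho", "xi", "eta", "phi", "delta", "epsilon")

#' Design matrix of the logistic choice model
#'
#' One column per coefficient a0..a6; the a1 column carries `-#A` so that all
#' fitted coefficients are the positively-signed model constants.
#' Previous-trial indicators are 0 on the first trial of a session.
#'
#' @param trials Trial table of a `gs_session`.
#' @return List with matrix `X` (n x 7) and response `y` (1 = B chosen).
#' @export
choice_design <- function(trials) {
  prevj <- trials$prev_chosen_juice
  prevc <- trials$prev_chosen_cost
  X <- cbind(
    a0 = trials$qB,
    a1 = -trials$qA,
    a2 = (trials$costB == "low") - (trials$costA == "low"),
    a3 = (prevj == "B") - (prevj == "A"),
    a4 = (prevc != "none") *
      ((trials$costB == prevc) - (trials$costA == prevc)),
    a5 = (trials$offerB_side == "L") - (trials$offerA_side == "L"),
    a6 = (trials$targetB_side == "L") - (trials$targetA_side == "L")
  )
  list(X = X, y = as.numeric(trials$chosen_juice == "B"))
}

# Penalized logistic log-likelihood fit used as a fallback under separation.
ridge_logistic <- function(X, y, lambda = 1e-3) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta))) + lambda * sum(b^2) / 2
  }
  gr <- function(b) {
    p <- stats::plogis(drop(X %*% b))
    -drop(crossprod(X, y - p)) + lambda * b
  }
  opt <- stats::optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
                      hessian = TRUE, control = list(maxit = 500))
  se <- tryCatch(sqrt(diag(solve(opt$hessian))),
                 error = function(e) rep(NA_real_, ncol(X)))
  list(coef = opt$par, se = se,
       loglik = -(opt$value - lambda * sum(opt$par^2) / 2),
       converged = opt$convergence == 0)
}

fit_logistic_design <- function(X, y, degenerate_a0 = 0.05) {
  if (length(unique(y)) < 2L)
    stop("session must contain at least two distinct choice outcomes")
  # drop all-constant columns (e.g. a4 in a session with a single cost
  # configuration); their coefficients are unidentifiable
  keep <- apply(X, 2L, function(v) stats::var(v) > 0)
  fit <- suppressWarnings(
    stats::glm.fit(X[, keep, drop = FALSE], y,
                   family = stats::binomial())
  )
  co <- se <- rep(NA_real_, ncol(X))
  names(co) <- names(se) <- colnames(X)
  co[keep] <- fit$coefficients
  # Wald SEs from the IRLS weighted crossproduct
  w <- fit$weights
  Xk <- X[, keep, drop = FALSE]
  info <- crossprod(Xk * sqrt(w))
  cov_ok <- tryCatch({se[keep] <- sqrt(diag(solve(info))); TRUE},
                     error = function(e) FALSE)
  separated <- !fit$converged || !cov_ok ||
    any(abs(co[keep]) > 15) || any(!is.finite(se[keep]))
  if (separated) {
    rf <- ridge_logistic(Xk, y)
    co[keep] <- rf$coef
    se[keep] <- rf$se
    loglik <- rf$loglik
    converged <- rf$converged
  } else {
    eta <- drop(Xk %*% co[keep])
    loglik <- sum(y * eta - log1p(exp(eta)))
    converged <- TRUE
  }
  z <- co / se
  p <- 2 * stats::pnorm(-abs(z))
  a0 <- co[["a0"]]
  degenerate <- is.na(a0) || a0 < degenerate_a0
  indices <- if (degenerate) rep(NA_real_, 6) else co[2:7] / a0
  names(indices) <- INDEX_NAMES
  structure(
    list(coefficients = co, se = se, p_values = p, loglik = loglik,
         indices = indices, converged = converged, separated = separated,
         degenerate = degenerate, n = length(y)),
    class = "gs_logistic_fit"
  )
}

#' Fit the full logistic choice model
#'
#' Maximum-likelihood fit of a0..a6 with Wald standard errors and p-values.
#' When separation is detected (deterministic choosers) the fit falls back to
#' a lightly ridge-penalized likelihood and is flagged `separated`. Fits with
#' `a0` below `degenerate_a0` are flagged degenerate and their indices
#' (ratios with denominator a0) are reported as `NA`.
#'
#' @param session A `gs_session`, or a trial table.
#' @param degenerate_a0 Threshold on a0 below which indices are undefined.
#' @return A `gs_logistic_fit` with elements `coefficients`, `se`,
#'   `p_values`, `indices` (rho, xi, eta, phi, delta, epsilon), `loglik` and
#'   flags.
#' @export
fit_choice_model <- function(session, degenerate_a0 = 0.05) {
  trials <- if (inherits(session, "gs_session")) session$trials else session
  d <- choice_design(trials)
  fit_logistic_design(d$X, d$y, degenerate_a0)
}

#' Fit the simplified choice model (a0, a1, a2 only)
#'
#' The hysteresis and spatial-bias terms are removed; this is the model
#' behind the two cost-conditioned sigmoids of the choice-pattern summary.
#'
#' @inheritParams fit_choice_model
#' @return A `gs_logistic_fit` with a3..a6 equal to `NA`.
#' @export
fit_simplified_model <- function(session, degenerate_a0 = 0.05) {
  trials <- if (inherits(session, "gs_session")) session$trials else session
  if (nrow(trials) == 0L) stop("no trials")
  d <- choice_design(trials)
  f <- fit_logistic_design(d$X[, 1:3, drop = FALSE], d$y, degenerate_a0)
  pad <- function(v) {
    out <- rep(NA_real_, 7); names(out) <- COEF_NAMES
    out[1:3] <- v; out
  }
  f$coefficients <- pad(f$coefficients)
  f$se <- pad(f$se)
  f$p_values <- pad(f$p_values)
  ind <- rep(NA_real_, 6); names(ind) <- INDEX_NAMES
  ind[1:2] <- f$indices[1:2]
  f$indices <- ind
  f$simplified <- TRUE
  f
}

#' @export
print.gs_logistic_fit <- function(x, ...) {
  cat("<gs_logistic_fit> n =", x$n,
      if (x$degenerate) "(degenerate)" else "", "\n")
  print(round(rbind(coef = x$coefficients, se = x$se, p = x$p_values), 4))
  if (!x$degenerate) {
    cat("indices:\n")
    print(round(x$indices, 4))
  }
  invisible(x)
}

#' Screen a session on the target-side spatial bias
#'
#' Sessions in which the target-position bias term is statistically
#' significant are excluded from the neuronal analyses: an unexplained
#' side preference confounds the question of interest.
#'
#' @param fit A full-model `gs_logistic_fit`.
#' @param alpha Significance threshold on the a6 Wald p-value.
#' @return List with logical `keep` and character `reason`.
#' @export
screen_session <- function(fit, alpha = 0.01) {
  if (fit$degenerate)
    return(list(keep = FALSE, reason = "degenerate fit (a0 below threshold)"))
  p6 <- fit$p_values[["a6"]]
  if (!is.na(p6) && p6 < alpha)
    return(list(keep = FALSE,
                reason = sprintf("significant target-side bias (p = %.3g)", p6)))
  list(keep = TRUE, reason = "no significant target-side bias")
}

#' Summarize the choice pattern of a session
#'
#' Percent B choices per quantity pair, split by the cost configuration (A
#' low cost vs A high cost), with the indifference points of the simplified
#' model. The indifference point of a configuration is the #B:#A ratio at
#' which the simplified model (evaluated at #A = 1) predicts P(B) = 0.5:
#' rho + xi for A-low-cost trials and rho - xi for A-high-cost trials, so the
#' A-low-cost sigmoid sits at higher ratios exactly when xi > 0.
#'
#' @param session A `gs_session`.
#' @param fit Optional simplified fit (computed if missing).
#' @return List of class `gs_choice_pattern` with a per-(pair, configuration)
#'   table and the two indifference points.
#' @export
summarize_choice_pattern <- function(session, fit = NULL) {
  trials <- session$trials
  if (is.null(fit)) fit <- fit_simplified_model(session)
  cfg <- ifelse(trials$costA == "low", "A_low", "A_high")
  key <- interaction(trials$qA, trials$qB, cfg, drop = TRUE)
  tab <- do.call(rbind, lapply(split(seq_len(nrow(trials)), key), function(i) {
    data.frame(qA = trials$qA[i[1]], qB = trials$qB[i[1]],
               config = cfg[i[1]], n = length(i),
               frac_B = mean(trials$chosen_juice[i] == "B"))
  }))
  tab$ratio <- tab$qB / pmax(tab$qA, 1e-9)
  tab <- tab[order(tab$ratio, tab$config), ]
  rownames(tab) <- NULL
  rho <- fit$indices[["rho"]]; xi <- fit$indices[["xi"]]
  structure(
    list(table = tab,
         indifference = c(A_low = rho + xi, A_high = rho - xi),
         fit = fit),
    class = "gs_choice_pattern"
  )
}

#' Population summary of behavioral indices
#'
#' Median of each normalized index across session fits with a two-sided
#' Wilcoxon signed-rank test against zero.
#'
#' @param fits List of `gs_logistic_fit` objects (kept sessions).
#' @param min_sessions Minimum number of fits required.
#' @return data.frame with columns `index`, `median`, `p_signed_rank`, `n`.
#' @export
population_summary <- function(fits, min_sessions = 6L) {
  if (length(fits) < min_sessions)
    stop("population summary requires at least ", min_sessions, " sessions")
  idx <- t(vapply(fits, function(f) f$indices, numeric(6)))
  do.call(rbind, lapply(INDEX_NAMES, function(nm) {
    x <- idx[, nm]
    x <- x[!is.na(x)]
    p <- if (length(x) == 0L || all(x == 0)) 1 else
      suppressWarnings(stats::wilcox.test(x, mu = 0, exact = FALSE)$p.value)
    data.frame(index = nm, median = stats::median(x), p_signed_rank = p,
               n = length(x))
  }))
}
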