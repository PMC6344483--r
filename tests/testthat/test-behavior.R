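test_that("the full model recovers generating indices on a long session", {
  cfg <- generator_config(a0 = 2, rho = 2.5, xi = 0.2, eta = 0.2,
                          phi = 0, delta = 0, epsilon = 0, seed = 11,
                          trials_per_condition = 84L)
  f <- fit_choice_model(generate_session(cfg))
  expect_true(f$converged)
  expect_false(f$degenerate)
  truth <- c(rho = 2.5, xi = 0.2, eta = 0.2, phi = 0, delta = 0, epsilon = 0)
  expect_true(all(abs(f$indices - truth) < 0.1))
  # indices are the coefficient ratios by definition
  expect_equal(unname(f$indices),
               unname(f$coefficients[2:7] / f$coefficients[1]))
})

test_that("fair-coin choices produce a degenerate fit", {
  cfg <- generator_config(a0 = 2, rho = 1, xi = 0, eta = 0,
                          offer_types = data.frame(qA = 1L, qB = 1L),
                          trials_per_condition = 100L, seed = 12)
  f <- fit_choice_model(generate_session(cfg))
  expect_true(f$degenerate)
  expect_true(all(is.na(f$indices)))
})

test_that("the simplified model agrees with the full fit when a3..a6 are 0", {
  cfg <- generator_config(eta = 0, seed = 13, trials_per_condition = 42L)
  s <- generate_session(cfg)
  f <- fit_choice_model(s)
  fs <- fit_simplified_model(s)
  for (a in c("a0", "a1", "a2")) {
    expect_lt(abs(f$coefficients[[a]] - fs$coefficients[[a]]),
              2 * (f$se[[a]] + fs$se[[a]]))
  }
  expect_true(all(is.na(fs$coefficients[4:7])))
  expect_error(fit_simplified_model(tiny_trials()[0, ]), "trials")
})

test_that("a deterministic chooser yields a step choice pattern without crashing", {
  cfg <- generator_config(a0 = 50, rho = 2.5, xi = 0, eta = 0, seed = 14,
                          trials_per_condition = 10L)
  s <- generate_session(cfg)
  f <- fit_simplified_model(s)
  expect_true(f$separated)
  cp <- summarize_choice_pattern(s, f)
  tab <- cp$table
  expect_true(all(tab$frac_B[tab$ratio < 2.5] == 0))
  expect_true(all(tab$frac_B[tab$ratio > 2.5] == 1))
})

test_that("session screening excludes significant target-side bias", {
  f <- fit_choice_model(small_session())
  expect_true(screen_session(f)$keep)
  # threshold edges on a synthetic fit object
  f_edge <- f
  f_edge$p_values[["a6"]] <- 0.5
  expect_true(screen_session(f_edge)$keep)
  f_edge$p_values[["a6"]] <- 0.009
  expect_false(screen_session(f_edge)$keep)
  # a real generating bias is detected
  cfg <- generator_config(epsilon = 0.5, seed = 15, trials_per_condition = 84L)
  fb <- fit_choice_model(generate_session(cfg))
  expect_false(screen_session(fb)$keep)
  # degenerate fits are excluded with a reason
  fd <- f; fd$degenerate <- TRUE
  expect_false(screen_session(fd)$keep)
  expect_match(screen_session(fd)$reason, "degenerate")
})

test_that("choice patterns split by cost shift in the direction of xi", {
  cfg <- generator_config(xi = 0.3, eta = 0, seed = 16,
                          trials_per_condition = 42L)
  s <- generate_session(cfg)
  cp <- summarize_choice_pattern(s)
  expect_gt(cp$indifference[["A_low"]], cp$indifference[["A_high"]])
  # at matched quantity pairs, B is chosen more when A is the costly offer
  tab <- cp$table
  wide <- merge(tab[tab$config == "A_high", c("qA", "qB", "frac_B")],
                tab[tab$config == "A_low", c("qA", "qB", "frac_B")],
                by = c("qA", "qB"), suffixes = c("_high", "_low"))
  expect_gt(mean(wide$frac_B_high - wide$frac_B_low), 0)
})

test_that("relabeling the juices maps rho to 1/rho", {
  s <- small_session()
  f <- fit_choice_model(s)
  tr <- s$trials
  sw <- tr
  sw$qA <- tr$qB; sw$qB <- tr$qA
  sw$costA <- tr$costB; sw$costB <- tr$costA
  sw$offerA_side <- tr$offerB_side
  sw$angleA <- tr$angleB; sw$angleB <- tr$angleA
  sw$chosen_juice <- ifelse(tr$chosen_juice == "A", "B", "A")
  f2 <- fit_choice_model(session(sw[names(tiny_trials())]))
  # the relabeled model is the same likelihood with a0 and a1 swapped, so
  # all indices transform exactly: rho -> 1/rho, and the value-unit indices
  # are re-expressed in units of the other juice (divided by rho)
  expect_equal(f2$indices[["rho"]], 1 / f$indices[["rho"]], tolerance = 1e-4)
  expect_equal(f2$indices[["eta"]],
               f$indices[["eta"]] / f$indices[["rho"]], tolerance = 1e-3)
  expect_equal(f2$indices[["xi"]],
               f$indices[["xi"]] / f$indices[["rho"]], tolerance = 1e-3)
})

test_that("population summaries report medians and signed-rank tests", {
  set.seed(33)
  mk <- function(xi) {
    ind <- c(rho = 2.5, xi = xi, eta = 0, phi = 0, delta = 0, epsilon = 0)
    structure(list(indices = ind), class = "gs_logistic_fit")
  }
  fits <- lapply(rnorm(100, 0.2, 0.05), mk)
  ps <- population_summary(fits)
  xi_row <- ps[ps$index == "xi", ]
  expect_lt(abs(xi_row$median - 0.2), 0.02)
  expect_lt(xi_row$p_signed_rank, 0.001)
  # all-zero index vector: no evidence against zero
  expect_equal(ps[ps$index == "eta", "p_signed_rank"], 1)
  expect_error(population_summary(fits[1:3]), "at least")
})
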