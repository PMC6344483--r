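# Minimal gs_regressions pair for identification tests: one family with two
# components and a singleton family.
fake_reg <- function(r2_eff_19, r2_raw_19 = r2_eff_19, windows) {
  resp <- data.frame(neuron_id = paste0("n", seq_len(nrow(r2_eff_19))),
                     window = windows, stringsAsFactors = FALSE)
  structure(list(responses = resp, r2_eff = r2_eff_19, r2_raw = r2_raw_19,
                 slope = r2_eff_19 * 0, p = r2_eff_19 * 0),
            class = "gs_regressions")
}

empty19 <- function(n) {
  matrix(0, n, 19, dimnames = list(NULL, variable_catalog()$name))
}

test_that("unbiased identification assigns the max variant R^2", {
  aff <- empty19(2); ind <- empty19(2)
  aff[1, "offer value A"] <- 0.4
  ind[1, "offer value A"] <- 0.5     # independent variant fits better
  aff[2, "chosen juice"] <- 0.6      # a response of a different family
  ra <- fake_reg(aff, windows = c("post_offer", "post_offer"))
  ri <- fake_reg(ind, windows = c("post_offer", "post_offer"))
  out <- unbiased_identify(ra, ri,
                           selected = c("offer value (juice)", "chosen juice"),
                           family = "offer value (juice)")
  expect_equal(nrow(out), 1L)
  expect_equal(out$component, "offer value A")
  expect_equal(out$r2_affected, 0.4)
  expect_equal(out$r2_independent, 0.5)
  expect_equal(out$delta_r2, -0.1)
  # responses outside the family's window are not identified
  ra2 <- fake_reg(aff, windows = c("pre_go", "post_offer"))
  ri2 <- fake_reg(ind, windows = c("pre_go", "post_offer"))
  out2 <- unbiased_identify(ra2, ri2,
                            selected = c("offer value (juice)", "chosen juice"),
                            family = "offer value (juice)")
  expect_equal(nrow(out2), 0L)
})

test_that("delta R^2 population statistics behave at the boundaries", {
  d0 <- data.frame(delta_r2 = rep(0, 10))
  res <- delta_r2_population(d0)
  expect_equal(res$mean_delta_r2, 0)
  expect_equal(res$p_signed_rank, 1)
  expect_error(delta_r2_population(data.frame(delta_r2 = 1:3)), "at least")
})

test_that("epoch contrasts compare early and late populations", {
  set.seed(91)
  x <- rnorm(20, 0, 0.01)
  res <- epoch_contrast(x, x)
  expect_equal(res$mean_diff, 0)
  expect_gt(res$p_rank_sum, 0.9)
  res2 <- epoch_contrast(rnorm(30, 0, 0.005), rnorm(30, 0.02, 0.005))
  expect_gt(res2$mean_diff, 0.01)
  expect_lt(res2$p_rank_sum, 0.001)
  expect_error(epoch_contrast(1, 2), "at least 2")
})

test_that("the parallel ANCOVA recovers group offsets and reduces to OLS", {
  set.seed(92)
  x <- runif(40, 0, 5)
  g <- rep(c("low", "high"), each = 20)
  y <- 1 * x + 2 * (g == "low") + rnorm(40, 0, 0.5)
  res <- ancova_parallel(y, x, g)
  expect_lt(abs(res$slope - 1), 0.15)
  expect_lt(abs(abs(diff(res$intercepts)) - 2), 0.5)
  expect_lt(res$p_group, 0.05)
  # single group: identical to the simple regression
  res1 <- ancova_parallel(y[g == "low"], x[g == "low"],
                          rep("low", 20))
  ols <- regress_response(y[g == "low"], x[g == "low"],
                          trial_types = factor(1:20))
  expect_equal(res1$slope, ols$slope, tolerance = 1e-10)
  expect_true(is.na(res1$p_group))
  # an empty group level is an error, as is a constant covariate
  g2 <- factor(rep("low", 40), levels = c("low", "high"))
  expect_error(ancova_parallel(y, x, g2), "at least 3")
  expect_error(ancova_parallel(y, rep(1, 40), g), "singular")
})

test_that("identical lines produce the nominal ANCOVA false-positive rate", {
  set.seed(93)
  n_rep <- 200L
  hits <- vapply(seq_len(n_rep), function(i) {
    x <- runif(40, 0, 5)
    y <- 2 * x + rnorm(40)
    g <- rep(c("a", "b"), each = 20)
    ancova_parallel(y, x, g)$p_group < 0.05
  }, logical(1))
  band <- qbinom(c(0.005, 0.995), n_rep, 0.05)
  expect_gte(sum(hits), band[1])
  expect_lte(sum(hits), band[2])
})

test_that("with xi fixed to 0 the variant contrast vanishes identically", {
  s <- small_session()
  fit0 <- list(rho = s$generator$rho, xi = 0)
  sl <- snr_slope(s, "chosen value", snr = 2, fit = fit0)
  sp <- generate_neuron(neuron_spec("cv", "chosen value", 10, sl), s,
                        seed = 3, fit = fit0)
  s$spikes <- sp
  rmat <- windowed_rates(s)
  resp <- data.frame(neuron_id = "cv",
                     window = c("post_offer", "post_target"),
                     stringsAsFactors = FALSE)
  ra <- response_regressions(rmat, s, fit0, resp, variant = "affected")
  ri <- response_regressions(rmat, s, fit0, resp, variant = "independent")
  cost_vars <- c("offer value A", "offer value B", "chosen value",
                 "offer value L", "offer value R",
                 "offer value target L", "offer value target R")
  expect_lt(max(abs(ra$r2_raw[, cost_vars] - ri$r2_raw[, cost_vars])), 1e-10)
})
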