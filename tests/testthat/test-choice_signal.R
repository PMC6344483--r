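# Build a minimal session with a prescribed number of A/B choices per cost
# configuration for one quantity pair.
pair_session <- function(nA_low, nB_low, nA_high, nB_high, qA = 1L, qB = 2L) {
  n <- nA_low + nB_low + nA_high + nB_high
  costA <- c(rep("low", nA_low + nB_low), rep("high", nA_high + nB_high))
  chosen <- c(rep("A", nA_low), rep("B", nB_low),
              rep("A", nA_high), rep("B", nB_high))
  tr <- data.frame(
    trial = seq_len(n), qA = qA, qB = qB,
    costA = costA, costB = ifelse(costA == "low", "high", "low"),
    offerA_side = "L", angleA = 157.5, angleB = 22.5,
    chosen_juice = chosen,
    offer_on = 1.5, offer_off = 2.5, target_on = 3.5, go = 4.2,
    saccade = 4.4, juice_time = 5.15, stringsAsFactors = FALSE
  )
  session(tr)
}

test_that("cost-overt labeling follows the choice-shift rule", {
  # 8/10 A when A low cost, 5/10 when high: shift 0.3 > 0.1, both options
  # chosen at least twice -> overt
  lab <- label_cost_overt(pair_session(8, 2, 5, 5))
  expect_equal(lab$label, "overt")
  expect_equal(lab$pA_low, 0.8)
  expect_equal(lab$pA_high, 0.5)
  # the same option always chosen -> covert
  expect_equal(label_cost_overt(pair_session(10, 0, 10, 0))$label, "covert")
  # an option chosen once overall -> insufficient
  expect_equal(label_cost_overt(pair_session(9, 1, 10, 0))$label,
               "insufficient")
  # shift at exactly the margin is not overt
  expect_equal(label_cost_overt(pair_session(6, 4, 5, 5))$label, "covert")
})

test_that("spike density functions conserve mass and peak correctly", {
  z <- sdf(numeric(0), align = 0)
  expect_true(all(z$rate == 0))
  one <- sdf(0.25, align = 0, window = c(-0.5, 1.0), sigma = 0.040)
  expect_equal(max(one$rate), 1 / (0.040 * sqrt(2 * pi)), tolerance = 1e-3)
  expect_equal(one$time[which.max(one$rate)], 0.25)
  # integral over the grid equals the spike count (kernel well inside)
  set.seed(8)
  sp <- runif(20, 0.2, 0.6)
  prof <- sdf(sp, align = 0, window = c(-0.5, 1.5))
  expect_equal(sum(prof$rate) * 0.001, 20, tolerance = 0.001 * 20)
})

test_that("profile normalization is (x - pre-offer) / other-window mean", {
  expect_equal(normalize_profile(15, pre_offer_mean = 5, other_mean = 10), 1)
  expect_equal(normalize_profile(rep(7, 3), 7, 2), rep(0, 3))
  expect_warning(out <- normalize_profile(5, 1, 0), "zero divisor")
  expect_null(out)
})

test_that("AUC matches enumeration and the Mann-Whitney oracle", {
  expect_equal(auc(c(3, 3, 3), c(3, 3, 3)), 0.5)
  expect_equal(auc(c(5, 6, 7), c(1, 2, 3)), 1.0)
  expect_equal(auc(c(2, 3), c(2, 5)), 0.375)
  expect_error(auc(numeric(0), 1), "non-empty")
  set.seed(81)
  for (i in 1:50) {
    x1 <- rpois(sample(2:12, 1), 5)
    x2 <- rpois(sample(2:12, 1), 6)
    u <- suppressWarnings(
      wilcox.test(x1, x2, exact = FALSE)$statistic)
    expect_equal(auc(x1, x2), unname(u) / (length(x1) * length(x2)),
                 tolerance = 1e-12)
    expect_equal(auc(x1, x2), 1 - auc(x2, x1), tolerance = 1e-12)
  }
})

test_that("the three ROC windows partition the first 750 ms after the offer", {
  w <- goodspace:::POST_OFFER_ROC
  expect_equal(w$start, c(0, 0.25, 0.5))
  expect_equal(w$end, c(0.25, 0.5, 0.75))
  expect_true(all(w$end[-3] == w$start[-1]))
})

test_that("choice probability averages AUC over eligible overt pairs", {
  cfg <- generator_config(seed = 82, trials_per_condition = 12L)
  s <- generate_session(cfg)
  labels <- label_cost_overt(s)
  expect_true(any(labels$label == "overt"))
  sl <- snr_slope(s, "chosen juice", snr = 3)
  sp <- generate_neuron(neuron_spec("cj", "chosen juice", 10, sl), s,
                        seed = 4)
  s$spikes <- sp
  cp <- cell_choice_probability(s, "cj", "post_offer_2", labels,
                                "chosen juice", "B")
  expect_gt(cp$n_pairs, 0L)
  expect_equal(cp$mean_auc, mean(cp$per_pair$auc))
  expect_gt(cp$mean_auc, 0.5)
  # a single eligible pair: the mean is that pair's AUC
  one <- labels[labels$label == "overt", ][1, ]
  labels1 <- labels
  labels1$label[!(labels1$qA == one$qA & labels1$qB == one$qB)] <-
    "insufficient"
  cp1 <- cell_choice_probability(s, "cj", "post_offer_2", labels1,
                                 "chosen juice", "B")
  expect_equal(cp1$n_pairs, 1L)
  expect_equal(cp1$mean_auc, cp1$per_pair$auc[1])
})

test_that("population AUC tests handle constants and small n", {
  res <- population_auc_test(rep(0.5, 10))
  expect_equal(res$mean_auc, 0.5)
  expect_equal(res$p, 1)
  expect_error(population_auc_test(c(0.5, 0.6)), "at least")
  res2 <- population_auc_test(c(0.7, 0.72, 0.68, 0.71))
  expect_lt(res2$p, 0.01)
})

test_that("grouped traces require enough trials per group and separate E/O", {
  cfg <- generator_config(seed = 83, trials_per_condition = 12L)
  s <- generate_session(cfg)
  labels <- label_cost_overt(s)
  sl <- snr_slope(s, "chosen juice", snr = 4)
  s$spikes <- generate_neuron(neuron_spec("cj", "chosen juice", 10, sl), s,
                              seed = 6)
  gt <- group_traces(s, "cj", labels, "chosen juice", "B")
  expect_true(gt$included)
  post <- gt$traces$offer_on
  sel <- post$Eo$time > 0.1 & post$Eo$time < 0.6
  expect_gt(mean(post$Eo$rate[sel]), mean(post$Oo$rate[sel]))
  expect_gt(mean(post$Ec$rate[sel]), mean(post$Oc$rate[sel]))
  # starving one group of trials excludes the cell
  lab_cov <- labels; lab_cov$label[lab_cov$label == "overt"] <- "insufficient"
  gt2 <- group_traces(s, "cj", lab_cov, "chosen juice", "B")
  expect_false(gt2$included)
})
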