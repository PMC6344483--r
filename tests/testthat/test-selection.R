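test_that("best-subset equals exhaustive enumeration on random instances", {
  set.seed(71)
  for (i in 1:40) {
    n_var <- sample(3:10, 1)
    m <- random_instance(sample(10:40, 1), n_var)
    w <- sample(epoch_windows("pre_target"), nrow(m), replace = TRUE)
    n_max <- min(4L, n_var)
    bs <- best_subset_selection(m, w, epoch = "pre_target", n_max = n_max)
    for (k in seq_len(n_max)) {
      oracle <- brute_force_best(m, k)
      expect_equal(bs$per_n$n_explained[k], oracle$cov)
      expect_equal(bs$per_n$sum_r2[k], oracle$s2, tolerance = 1e-9)
    }
    # coverage is non-decreasing in n
    expect_true(all(diff(bs$per_n$n_explained) >= 0))
  }
})

test_that("best-subset dominates the first n stepwise picks", {
  set.seed(72)
  for (i in 1:15) {
    m <- random_instance(30, 8)
    w <- sample(epoch_windows("pre_target"), nrow(m), replace = TRUE)
    sw <- stepwise_selection(m, w, epoch = "pre_target", stop_frac = 0)
    bs <- best_subset_selection(m, w, epoch = "pre_target",
                                n_max = max(1L, length(sw$selected)))
    for (n in seq_along(sw$selected)) {
      cov_sw <- sum(apply(m[, sw$selected[1:n], drop = FALSE] > 0, 1L, any))
      expect_gte(bs$per_n$n_explained[n], cov_sw)
    }
  }
})

test_that("stepwise is deterministic, monotone, and stops correctly", {
  set.seed(73)
  m <- random_instance(60, 8)
  w <- sample(epoch_windows("pre_target"), 60, replace = TRUE)
  s1 <- stepwise_selection(m, w)
  s2 <- stepwise_selection(m, w)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$trace, s2$trace)
  # best-fit score trace is monotone non-increasing
  expect_true(all(diff(s1$trace$best_fit_score) <= 0))
  # stop_frac = 0 runs until no response remains unaccounted
  s0 <- stepwise_selection(m, w, stop_frac = 0)
  expect_true(all(diff(s0$trace$best_fit_score) <= 0))
  keep <- w %in% epoch_windows("pre_target")
  explainable <- sum(apply(m[keep, , drop = FALSE] > 0, 1L, any))
  expect_equal(sum(s0$trace$n_new), explainable)
})

test_that("a single dominant variable is selected alone", {
  m <- matrix(0, 20, 5, dimnames = list(NULL, paste0("v", 1:5)))
  m[, 2] <- 0.8
  w <- rep("post_offer", 20)
  s <- stepwise_selection(m, w)
  expect_equal(s$selected, "v2")
  expect_equal(nrow(s$trace), 1L)
  # an empty response set selects nothing
  s_empty <- stepwise_selection(m[0, , drop = FALSE], character(0))
  expect_length(s_empty$selected, 0L)
})

test_that("explained-removal lets a sibling variable absorb responses", {
  # v1 best-fits half the responses and explains all of them; under
  # explained-removal v2 is never selected, under best-fit removal it is
  m <- matrix(0, 20, 2, dimnames = list(NULL, c("v1", "v2")))
  m[, "v1"] <- c(rep(0.9, 10), rep(0.5, 10))
  m[, "v2"] <- c(rep(0.4, 10), rep(0.8, 10))
  w <- rep("post_offer", 20)
  s_bf <- stepwise_selection(m, w, removal = "best_fit")
  expect_equal(sort(s_bf$selected), c("v1", "v2"))
  s_ex <- stepwise_selection(m, w, removal = "explained")
  expect_equal(s_ex$selected, "v1")
})

test_that("cells are classified by the largest summed effective R^2", {
  resp <- data.frame(neuron_id = rep(c("c1", "c2", "c3"), each = 2),
                     window = rep(c("post_offer", "post_target"), 3),
                     stringsAsFactors = FALSE)
  fams <- c("chosen cost", "chosen juice", "chosen value")
  r2c <- matrix(0, 6, 3, dimnames = list(NULL, fams))
  r2c[1:2, "chosen cost"] <- c(0.5, 0.4)       # c1: chosen cost only
  r2c[3:4, "chosen juice"] <- c(0.6, 0.7)      # c2: chosen juice
  r2c[3, "chosen value"] <- 0.2
  slope <- matrix(0, 6, 19,
                  dimnames = list(NULL, variable_catalog()$name))
  slope[3:4, "chosen juice"] <- -1             # higher rate for juice A
  slope[1:2, "chosen cost"] <- 1               # higher rate for low cost
  r2_19 <- matrix(0, 6, 19, dimnames = list(NULL, variable_catalog()$name))
  r2_19[cbind(1:4, match(c("chosen cost", "chosen cost", "chosen juice",
                           "chosen juice"), variable_catalog()$name))] <-
    c(0.5, 0.4, 0.6, 0.7)
  reg <- structure(list(responses = resp, slope = slope, r2_eff = r2_19),
                   class = "gs_regressions")
  cl <- classify_cells(reg, list(r2_eff = r2c), fams)
  expect_equal(cl$assigned[cl$neuron_id == "c1"], "chosen cost")
  expect_equal(cl$encoded_level[cl$neuron_id == "c1"], "low")
  expect_equal(cl$assigned[cl$neuron_id == "c2"], "chosen juice")
  expect_equal(cl$encoded_level[cl$neuron_id == "c2"], "A")
  expect_true(is.na(cl$assigned[cl$neuron_id == "c3"]))
})
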