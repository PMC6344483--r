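fit02 <- list(rho = 2.5, xi = 0.2)

test_that("catalog evaluators reproduce hand-computed values", {
  tr <- tiny_trials()
  s <- session(tr)$trials
  # trial 1: qA=1 qB=2, A low cost, B high cost, B chosen, offers A-L/B-R,
  # targets A-L/B-R
  ovA <- evaluate_variable("offer value A", s, fit02)
  ovB <- evaluate_variable("offer value B", s, fit02)
  expect_equal(ovA[1], 2.5 * 1 + 0.2)
  expect_equal(ovB[1], 2)                      # B high cost: no xi term
  expect_equal(ovB[2], 3 + 0.2)                # #B=3, B low cost: 3.2
  expect_equal(evaluate_variable("chosen juice", s, fit02), c(1, 0, 0, 1))
  expect_equal(evaluate_variable("chosen cost", s, fit02), c(0, 0, 1, 1))
  # offer value - is the high-cost offer's value
  expect_equal(evaluate_variable("offer value -", s, fit02)[1], 2)
  expect_equal(evaluate_variable("offer value +", s, fit02)[1], 2.7)
  # spatial values follow the sides
  expect_equal(evaluate_variable("offer value L", s, fit02)[1], ovA[1])
  expect_equal(evaluate_variable("offer value R", s, fit02)[1], ovB[1])
  expect_equal(evaluate_variable("spatial congruence", s, fit02),
               c(1, 1, 1, 1))
  expect_equal(evaluate_variable("chosen value", s, fit02)[1], ovB[1])
  expect_equal(evaluate_variable("chosen value", s, fit02)[2], ovA[2])
  expect_equal(evaluate_variable("cost of A", s, fit02), c(1, 0, 1, 0))
  expect_error(evaluate_variable("banana", s, fit02), "unknown variable")
})

test_that("variants remove exactly the determinant under test", {
  tr <- session(tiny_trials())$trials
  # cost-independent commodity value drops the xi term
  expect_equal(evaluate_variable("offer value A", tr, fit02, "independent"),
               2.5 * tr$qA)
  expect_equal(evaluate_variable("chosen value", tr, fit02, "independent")[1],
               tr$qB[1])
  # commodity-independent cost value uses raw quantities
  ovm <- evaluate_variable("offer value -", tr, fit02, "independent")
  expect_equal(ovm[1], tr$qB[1])               # B is high cost on trial 1
  expect_equal(ovm[2], tr$qA[2])
  # with xi = 0 the cost-affected and cost-independent variants coincide
  fit0 <- list(rho = 2.5, xi = 0)
  for (v in c("offer value A", "offer value B", "chosen value",
              "offer value L", "offer value target R"))
    expect_equal(evaluate_variable(v, tr, fit0, "affected"),
                 evaluate_variable(v, tr, fit0, "independent"))
  # binary variables are variant-invariant
  expect_equal(evaluate_variable("chosen juice", tr, fit02, "independent"),
               evaluate_variable("chosen juice", tr, fit02, "affected"))
})

test_that("the variable value matrix covers the catalog", {
  s <- small_session()
  m <- variable_value_matrix(s$trials, fit02)
  expect_equal(dim(m), c(nrow(s$trials), 19L))
  expect_equal(colnames(m), variable_catalog()$name)
  binaries <- variable_catalog()$name[c(3, 6, 9, 12, 13, 14, 15, 16, 17, 18)]
  expect_true(all(m[, binaries] %in% c(0, 1)))
})

test_that("simple regression matches the lm oracle on a fixed dataset", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2.1, 3.9, 6.2, 7.8, 10.1, 12.2)
  r <- regress_response(y, x, trial_types = factor(seq_along(x)))
  o <- summary(lm(y ~ x))
  expect_equal(r$slope, o$coefficients["x", "Estimate"], tolerance = 1e-10)
  expect_equal(r$p, o$coefficients["x", "Pr(>|t|)"], tolerance = 1e-10)
  expect_equal(r$r2_raw, o$r.squared, tolerance = 1e-10)
  expect_equal(r$r2_eff, o$r.squared, tolerance = 1e-10)
  # an exactly linear response has R^2 = 1
  rp <- regress_response(2 * x + 1, x, trial_types = factor(seq_along(x)))
  expect_equal(rp$r2_eff, 1)
  # a constant variable cannot explain anything
  rc <- regress_response(y, rep(1, 6), trial_types = factor(seq_along(x)))
  expect_true(rc$constant_x)
  expect_equal(rc$r2_eff, 0)
})

test_that("pure-noise regressions are explained at the nominal 5% rate", {
  set.seed(55)
  n_rep <- 400L
  hits <- vapply(seq_len(n_rep), function(i) {
    y <- rnorm(50)
    x <- rnorm(50)
    regress_response(y, x, trial_types = factor(1:50))$r2_eff > 0
  }, logical(1))
  band <- qbinom(c(0.005, 0.995), n_rep, 0.05)
  expect_gte(sum(hits), band[1])
  expect_lte(sum(hits), band[2])
})

test_that("collapsing credits the better component and best fit is the argmax", {
  m <- matrix(0, 2, 19, dimnames = list(NULL, variable_catalog()$name))
  m[1, "offer value A"] <- 0.3
  m[1, "offer value B"] <- 0.6
  m[2, "chosen value"] <- 0.4
  col <- collapse_r2(m)
  expect_equal(unname(col$r2_eff[1, "offer value (juice)"]), 0.6)
  expect_equal(unname(col$winner[1, "offer value (juice)"]), "offer value B")
  expect_true(is.na(col$winner[2, "offer value (juice)"]))
  expect_equal(unname(col$r2_eff[2, "chosen value"]), 0.4)
  bf <- best_fit_assignment(col$r2_eff)
  expect_equal(bf, c("offer value (juice)", "chosen value"))
  # all-zero rows are unassigned
  expect_true(is.na(best_fit_assignment(matrix(0, 1, 3,
    dimnames = list(NULL, c("a", "b", "c"))))))
})
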