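test_that("RMSEA point formula and degenerate cases", {
  expect_equal(rmsea(85, 85, 2543), 0)
  expect_equal(rmsea(50, 85, 2543), 0)
  # closed form: sqrt((chi2 - df) / (df (N-1)))
  expect_equal(rmsea(479, 85, 2543), sqrt((479 - 85) / (85 * 2542)))
  ci <- rmsea_ci90(479, 85, 2543)
  expect_lt(ci["lower"], rmsea(479, 85, 2543))
  expect_gt(ci["upper"], rmsea(479, 85, 2543))
})

test_that("baseline model: df and zero-covariance behaviour", {
  sp <- lst_spec("item_effects", 3)
  sim <- simulate_panel(sim_config(N = 400, seed = 81))
  f <- lst_fit(sp, sim, se = FALSE)
  bl <- baseline_fit(f)
  expect_equal(bl$df, 105)
  expect_gt(bl$chi2, chi_square(f)$chi2)  # correlated data: baseline is awful

  # exactly uncorrelated data: baseline chi2 is ~0
  set.seed(9)
  Z <- matrix(rnorm(200 * 15), 200, 15)
  Z <- scale(Z)  # unit variance
  Z <- Z %*% solve(chol(cov(Z) * 199 / 200))  # whiten: S = I exactly
  colnames(Z) <- observed_names(sp$design)
  fz <- suppressWarnings(lst_fit(sp, as.data.frame(Z), se = FALSE))
  expect_lt(baseline_fit(fz)$chi2, 1e-6)
})

test_that("CFI/TLI limits and SRMR hand values", {
  expect_equal(cfi(85, 85, 3000, 105), 1)
  expect_equal(cfi(3000, 105, 3000, 105), 0)
  expect_equal(tli(3000, 105, 3000, 105), 0)
  expect_error(tli(0, 0, 100, 10), "df")

  S <- matrix(c(1, .5, .5, 1), 2)
  Sh <- matrix(c(1, .4, .4, 1), 2)
  expect_equal(srmr(Sh, S), sqrt(0.01 / 3))
  expect_equal(srmr(S, S), 0)
  # invariant under common rescaling of the variables
  D <- diag(c(2, 2))
  expect_equal(srmr(D %*% Sh %*% D, D %*% S %*% D), srmr(Sh, S))
  expect_error(srmr(Sh, matrix(c(0, 0, 0, 1), 2)), "variance")
})

test_that("chi-square scale option and df consistency", {
  sp <- lst_spec("item_effects", 3)
  sim <- simulate_panel(sim_config(N = 300, seed = 91))
  f <- lst_fit(sp, sim, se = FALSE)
  csN <- chi_square(f, "N")
  csN1 <- chi_square(f, "N-1")
  expect_equal(csN$chi2 / csN1$chi2, 300 / 299)
  expect_equal(csN$df, count_df(sp))
  # perfect fit: feed the model its own implied moments via a 2-group trick
  expect_equal(chi_square(f)$p_value,
               pchisq(csN$chi2, csN$df, lower.tail = FALSE))
})

test_that("information criteria and likelihood-ratio test", {
  sim <- simulate_panel(sim_config(N = 500, seed = 101))
  f0 <- lst_fit(lst_spec("states_only", 3), sim, se = FALSE)
  f1 <- lst_fit(lst_spec("item_effects", 3), sim, se = FALSE)
  ic <- information_criteria(f1)
  expect_equal(ic$aic, -2 * f1$loglik + 2 * 50)
  expect_equal(ic$bic, -2 * f1$loglik + 50 * log(500))
  lr <- lr_test(f0, f1)
  expect_equal(lr$ddf, 18L)
  expect_gte(lr$stat, 0)
  # equivalent reparameterizations: zero statistic at zero ddf
  lr0 <- lr_test(f1, lst_fit(lst_spec("item_effects", 5), sim, se = FALSE))
  expect_equal(lr0$stat, 0, tolerance = 1e-4)
  expect_error(lr_test(f1, f0), "free parameters")
})

test_that("AIC prefers the item-effects model when item effects exist", {
  wins <- 0L
  for (i in 1:10) {
    sim <- simulate_panel(sim_config(N = 1000, seed = 110 + i))
    a0 <- information_criteria(
      lst_fit(lst_spec("states_only", 3), sim, se = FALSE))$aic
    a1 <- information_criteria(
      lst_fit(lst_spec("item_effects", 3), sim, se = FALSE))$aic
    wins <- wins + (a1 < a0)
  }
  expect_equal(wins, 10L)
})

test_that("threshold classifier reproduces the published cutoffs", {
  expect_equal(unname(classify_fit(.99, .98, .043, .019)["overall"]), "good")
  expect_equal(unname(classify_fit(.96, .955, .07, .06)["overall"]),
               "acceptable")
  cl <- classify_fit(.894, .892, .111, .060)
  expect_equal(unname(cl["overall"]), "poor")
  expect_equal(unname(cl["srmr"]), "acceptable")  # .06 is within .10
  expect_equal(unname(cl["rmsea"]), "poor")
})

test_that("fit indices are invariant to the reference item", {
  sim <- simulate_panel(sim_config(N = 700, seed = 131))
  i3 <- fit_indices(lst_fit(lst_spec("item_effects", 3), sim, se = FALSE))
  i5 <- fit_indices(lst_fit(lst_spec("item_effects", 5), sim, se = FALSE))
  for (fld in c("chi2", "rmsea", "srmr", "cfi", "tli", "aic", "bic"))
    expect_equal(i3[[fld]], i5[[fld]], tolerance = 1e-6)
})
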