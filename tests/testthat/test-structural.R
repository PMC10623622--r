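test_that("null outcome: no spurious explained variance", {
  base <- lst_spec("item_effects", 3)
  sim <- simulate_panel(sim_config(N = 5000, seed = 301))
  set.seed(302)
  sim$noise <- rnorm(nrow(sim), 2.2, 0.8)
  res <- fit_structural(structural_spec(base, "noise", "full"), sim,
                        se = FALSE)
  expect_true(res$converged)
  expect_lt(res$r2, 0.01)
})

test_that("a single-state effect is recovered with correct sign and R2", {
  base <- lst_spec("item_effects", 3)
  os <- outcome_spec("z", c(eta3 = -0.5), mean = 0, sd = 1, skew = 0)
  # beta_std = -.5 on eta3 alone gives R2_true = .25
  sim <- simulate_panel(sim_config(N = 5000, outcome_specs = list(os),
                                   seed = 311))
  res <- fit_structural(structural_spec(base, "z", "states"), sim,
                        se = FALSE)
  expect_gt(res$r2, 0.21)
  expect_lt(res$r2, 0.29)
  expect_lt(res$betas_std[["eta3"]], -0.3)
})

test_that("full-model R2 is reference-invariant; states-only R2 is not", {
  os <- default_outcome_specs()[[1]]
  sim <- simulate_panel(sim_config(N = 4000, outcome_specs = list(os),
                                   seed = 321))
  r3f <- fit_structural(structural_spec(lst_spec("item_effects", 3),
                                        "mhi", "full"), sim, se = FALSE)
  r5f <- fit_structural(structural_spec(lst_spec("item_effects", 5),
                                        "mhi", "full"), sim, se = FALSE)
  expect_lt(abs(r3f$r2 - r5f$r2), 1e-6)
  r3s <- fit_structural(structural_spec(lst_spec("item_effects", 3),
                                        "mhi", "states"), sim, se = FALSE)
  r5s <- fit_structural(structural_spec(lst_spec("item_effects", 5),
                                        "mhi", "states"), sim, se = FALSE)
  # the states mean different things under different references
  expect_gt(abs(r3s$r2 - r5s$r2), 0.01)
})

test_that("incremental variance: trivial zero and generator magnitudes", {
  base <- lst_spec("item_effects", 3)
  os <- default_outcome_specs()[[2]]  # physical-health-like, delta-loaded
  sim <- simulate_panel(sim_config(N = 4000, outcome_specs = list(os),
                                   seed = 331))
  red <- fit_structural(structural_spec(base, "phi_index", "states"), sim,
                        se = FALSE)
  ful <- fit_structural(structural_spec(base, "phi_index", "full"), sim,
                        se = FALSE)
  ci <- compare_increment(red, ful)
  expect_equal(ci$delta_r2, ful$r2 - red$r2)
  expect_gt(ci$delta_r2, 0.03)   # generator puts ~.08 on the item effects
  expect_equal(ci$lr$ddf, 4L)
  expect_lt(ci$lr$p_value, 0.01)
  # identical models: exactly zero increment
  ci0 <- compare_increment(ful, ful)
  expect_equal(ci0$delta_r2, 0)
  expect_error(compare_increment(ful, red), "nested")
})

test_that("structural parameter recovery at N = 2500", {
  base <- lst_spec("item_effects", 3)
  os <- default_outcome_specs()[[1]]
  os$skew <- 0  # exact linear-normal world for coefficient recovery
  sim <- simulate_panel(sim_config(N = 2500, outcome_specs = list(os),
                                   seed = 341))
  res <- fit_structural(structural_spec(base, "mhi", "full"), sim)
  expect_true(res$converged)
  # standardized coefficients close to the generating betas
  expect_lt(max(abs(res$betas_std - os$beta_std[names(res$betas_std)])),
            0.08)
  expect_false(res$collinearity)
})

test_that("composite builder averages available responses", {
  d <- data.frame(a = c(1, 2, NA), b = c(3, NA, NA), c = c(5, 4, NA))
  comp <- build_composite(d, c("a", "b", "c"))
  expect_equal(comp[1], 3)
  expect_equal(comp[2], 3)
  expect_true(is.nan(comp[3]))
  expect_error(build_composite(d, c("a", "x")), "not in data")
})

test_that("degenerate outcomes are rejected", {
  base <- lst_spec("item_effects", 3)
  sim <- simulate_panel(sim_config(N = 200, seed = 351))
  sim$const <- 1
  expect_error(fit_structural(structural_spec(base, "const"), sim),
               "constant")
  expect_error(fit_structural(structural_spec(base, "absent"), sim),
               "not present")
})
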