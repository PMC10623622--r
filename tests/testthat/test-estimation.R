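test_that("sample moments use the ML divisor and flag missing data", {
  d <- data.frame(a = c(0, 2), b = c(0, 2))
  sm <- sample_moments(d)
  expect_equal(unname(sm$ybar), c(1, 1))
  expect_equal(unname(sm$S), matrix(1, 2, 2))
  expect_equal(sm$N, 2L)
  expect_equal(unname(sample_moments(d[c(1, 1), ])$S), matrix(0, 2, 2))
  d$a[1] <- NA
  expect_error(sample_moments(d), "fiml")
})

test_that("ML discrepancy: zero at equality, closed form for p = 1", {
  sam <- list(ybar = 0.3, S = matrix(1, 1, 1), N = 10)
  expect_equal(fml_discrepancy(list(mu = 0.3, Sigma = matrix(1, 1, 1)), sam),
               0)
  expect_equal(fml_discrepancy(list(mu = 0.3, Sigma = matrix(2, 1, 1)), sam),
               log(2) + 1 / 2 - 1)
  # F >= 0 for arbitrary admissible moments
  set.seed(2)
  for (i in 1:5) {
    W <- matrix(rnorm(9), 3); S <- tcrossprod(W) + diag(3)
    W2 <- matrix(rnorm(9), 3); Sig <- tcrossprod(W2) + diag(3)
    F <- fml_discrepancy(list(mu = rnorm(3), Sigma = Sig),
                         list(ybar = rnorm(3), S = S))
    expect_gte(F, 0)
  }
})

test_that("-2 loglik equals N * F_ML plus the saturated constant", {
  sp <- lst_spec("item_effects", 3)
  sim <- simulate_panel(sim_config(N = 600, seed = 21))
  f <- lst_fit(sp, sim, se = FALSE)
  sm <- f$sample
  parts <- lstitem:::nat_parts(f$msp, f$estimates)
  Fml <- fml_discrepancy(list(mu = parts$mu, Sigma = parts$Sigma), sm)
  p <- f$msp$p
  const <- sm$N * (p * log(2 * pi) +
                     as.numeric(determinant(sm$S)$modulus) + p)
  expect_equal(-2 * f$loglik, sm$N * Fml + const, tolerance = 1e-10)
})

test_that("FIML reduces to complete-data ML and to row-wise densities", {
  sp <- lst_spec("item_effects", 3)
  sim <- simulate_panel(sim_config(N = 200, seed = 31))
  pr <- true_params_53()
  f_ml <- lst_fit(sp, sim, "ml", se = FALSE)
  f_fi <- lst_fit(sp, sim, "fiml", se = FALSE)
  expect_lt(abs(f_ml$loglik - f_fi$loglik), 1e-8 * abs(f_ml$loglik))

  # one extra row observed only on the first variable contributes its
  # univariate normal log-density
  im <- implied_moments(sp, pr)
  extra <- sim[1, ]; extra[1, ] <- NA; extra[1, 1] <- 5.1
  ll_base <- fiml_loglik(sp, pr, sim)
  ll_aug <- fiml_loglik(sp, pr, rbind(sim, extra))
  expect_equal(ll_aug - ll_base,
               dnorm(5.1, im$mu[1], sqrt(im$Sigma[1, 1]), log = TRUE),
               tolerance = 1e-8)

  allna <- sim[1, ]; allna[1, ] <- NA
  expect_error(fiml_loglik(sp, pr, rbind(sim, allna)), "observed")
})

test_that("ML recovers the generating parameters (single large sample)", {
  sp <- lst_spec("item_effects", 3)
  pr <- true_params_53()
  sim <- simulate_panel(sim_config(N = 5000, theta_true = pr, seed = 41))
  f <- lst_fit(sp, sim)
  expect_true(f$converged)
  se <- standard_errors(f)
  msp <- f$msp
  truth <- lstitem:::params_to_nat(msp, pr)
  z <- abs(f$estimates - truth) / se
  # nearly all free parameters within 3 SEs of truth
  expect_gte(mean(z < 3), 0.95)
})

test_that("likelihood is invariant to the reference item", {
  sim <- simulate_panel(sim_config(N = 800, seed = 51))
  f3 <- lst_fit(lst_spec("item_effects", 3), sim, se = FALSE)
  f5 <- lst_fit(lst_spec("item_effects", 5), sim, se = FALSE)
  expect_lt(abs(f3$loglik - f5$loglik), 1e-6 * abs(f3$loglik))
})

test_that("standard errors shrink like 1/sqrt(N) and omit fixed parameters", {
  sp <- lst_spec("item_effects", 3)
  pr <- true_params_53()
  sim <- simulate_panel(sim_config(N = 4000, theta_true = pr, seed = 61))
  f_all <- lst_fit(sp, sim)
  f_half <- lst_fit(sp, sim[1:2000, ])
  ratio <- standard_errors(f_all) / standard_errors(f_half)
  expect_equal(mean(ratio), 1 / sqrt(2), tolerance = 0.1)
  # only the q free parameters appear
  expect_equal(nrow(f_all$vcov), count_free_parameters(sp))
  expect_true(all(grepl("^(kappa|phi|theta)_", rownames(f_all$vcov))))
})

test_that("SEs are calibrated: empirical SD of estimates matches mean SE", {
  sp <- lst_spec("item_effects", 3)
  pr <- true_params_53()
  reps <- 100
  k1 <- numeric(reps); se1 <- numeric(reps)
  for (i in seq_len(reps)) {
    sim <- simulate_panel(sim_config(N = 500, theta_true = pr,
                                     seed = 7000 + i))
    f <- lst_fit(sp, sim)
    k1[i] <- f$estimates[["kappa_eta1"]]
    se1[i] <- standard_errors(f)[["kappa_eta1"]]
  }
  expect_equal(sd(k1), mean(se1), tolerance = 0.15)
})

test_that("listwise deletion mirrors a complete-case analysis", {
  sp <- lst_spec("item_effects", 3)
  sim <- simulate_panel(sim_config(N = 900, missing_rate = 0.25, seed = 71))
  fl <- lst_fit(sp, sim, "listwise", se = FALSE)
  complete <- sim[complete.cases(sim[, observed_names(sp$design)]), ]
  fc <- lst_fit(sp, complete, "ml", se = FALSE)
  expect_equal(fl$loglik, fc$loglik, tolerance = 1e-10)
  expect_equal(fl$N_used, nrow(complete))
  expect_error(lst_fit(sp, sim, "ml"), "fiml")
})
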