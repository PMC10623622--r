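test_that("default generating parameters reproduce the published latent moments", {
  pr <- default_true_parameters()
  tab <- published_latent_moments("2008-2010")
  expect_equal(unname(pr$kappa[1]), 5.565)
  expect_equal(unname(pr$kappa), unname(tab$means))
  expect_equal(unname(sqrt(diag(pr$Phi))), unname(tab$sds))
  expect_silent(chol(pr$Phi))
  # implied observed-item SDs inside the reported 1.08-1.63 range
  im <- implied_moments(pr$spec, pr)
  sds <- sqrt(diag(im$Sigma))
  expect_true(all(sds >= 1.08 & sds <= 1.63))
})

test_that("simulation is seed-deterministic and moment-faithful", {
  cfg <- sim_config(N = 300, outcome_specs = default_outcome_specs(),
                    missing_rate = 0.2, seed = 401)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a, b)
  c2 <- simulate_panel(sim_config(N = 300, seed = 402))
  expect_false(identical(a[, 1], c2[, 1]))
})

test_that("outcomes hit their configured scale and decouple when gamma = 0", {
  pr <- true_params_53()
  os_null <- outcome_spec("z0", c(eta1 = 0, delta5 = 0), 2.2, 0.82,
                          skew = 0)
  os_mhi <- default_outcome_specs()[[1]]
  sim <- simulate_panel(sim_config(N = 100000, theta_true = pr,
                                   outcome_specs = list(os_null, os_mhi),
                                   seed = 411))
  expect_equal(mean(sim$mhi), 2.20, tolerance = 0.01)
  expect_equal(sd(sim$mhi), 0.82, tolerance = 0.01)
  # right-skew transform produces right skew
  m3 <- mean(((sim$mhi - mean(sim$mhi)) / sd(sim$mhi))^3)
  expect_gt(m3, 0.5)
  # null outcome uncorrelated with every item
  cors <- cor(sim$z0, sim[, observed_names(panel_design())])
  expect_lt(max(abs(cors)), 0.02)
})

test_that("wave-level missingness: MCAR rate, never all waves", {
  d <- panel_design()
  sim <- simulate_panel(sim_config(N = 4000, seed = 421))
  simm <- inject_missingness(sim, 0.3, d, seed = 422)
  waves <- sapply(1:3, function(t)
    is.na(simm[[paste0("item1_w", t)]]))
  # whole waves go missing together
  for (t in 1:3) for (i in 2:5)
    expect_equal(is.na(simm[[paste0("item", i, "_w", t)]]), waves[, t])
  expect_equal(mean(waves), 0.3, tolerance = 0.03)
  expect_true(all(rowSums(waves) < 3))
  expect_error(inject_missingness(sim, 1.0, d), "rate")
})

test_that("discretized mode clips to the response scale", {
  sim <- simulate_panel(sim_config(N = 500, discretize = TRUE, seed = 431))
  Y <- as.matrix(sim[, observed_names(panel_design())])
  expect_true(all(Y == round(Y)))
  expect_gte(min(Y), 1)
  expect_lte(max(Y), 7)
})

test_that("generator round-trip: fit recovers the defaults within 3 SEs", {
  pr <- true_params_53()
  sim <- simulate_panel(sim_config(N = 5000, theta_true = pr, seed = 441))
  f <- lst_fit(lst_spec("item_effects", 3), sim)
  tab <- extract_latent_moments(f)
  se <- standard_errors(f)
  expect_true(all(abs(tab$means - pr$kappa) < 3.5 * se[1:7]))
  expect_lt(max(abs(tab$sds - sqrt(diag(pr$Phi)))), 0.05)
  expect_gt(min(tab$corr["eta1", "eta2"], tab$corr["eta2", "eta3"]), 0.70)
})
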