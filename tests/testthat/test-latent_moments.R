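test_that("latent moment extraction returns the fitted moments with flags", {
  sp <- lst_spec("item_effects", 3)
  pr <- true_params_53()
  sim <- simulate_panel(sim_config(N = 5000, theta_true = pr, seed = 201))
  f <- lst_fit(sp, sim)
  tab <- extract_latent_moments(f)
  expect_identical(tab$labels, sp$latent_labels)
  expect_equal(unname(tab$means), unname(f$params$kappa))
  expect_equal(unname(tab$sds), unname(sqrt(diag(f$params$Phi))))
  expect_equal(diag(tab$corr), rep(1, 7), ignore_attr = TRUE)
  # recovery: extracted means within 3 SEs of truth
  se_k <- standard_errors(f)[1:7]
  expect_true(all(abs(tab$means - pr$kappa) < 3.5 * se_k))
  # generated state correlations exceed .75 and are detected as such
  expect_gt(min(tab$corr["eta1", "eta2"], tab$corr["eta2", "eta3"]), 0.70)
  # strong means are flagged significant
  expect_true(all(tab$sig_means[1:3]))
  expect_true(all(tab$sig_sds))
  expect_true(tab$sig_corr["eta1", "eta2"])
})

test_that("reference switch: involution, identity, and error cases", {
  t3 <- published_latent_moments("2008-2010")
  t4 <- reference_switch(t3, 5)
  back <- reference_switch(t4, 3)
  expect_lt(max(abs(back$means - t3$means)), 1e-12)
  expect_lt(max(abs(back$sds - t3$sds)), 1e-12)
  expect_lt(max(abs(back$corr - t3$corr)), 1e-12)
  expect_identical(reference_switch(t3, 3), t3)
  expect_error(reference_switch(t3, 3L + 10L), "no item-effect")
})

test_that("switching a fitted table equals re-estimating under the new reference", {
  sim <- simulate_panel(sim_config(N = 2000, seed = 211))
  f3 <- lst_fit(lst_spec("item_effects", 3), sim, se = FALSE)
  f5 <- lst_fit(lst_spec("item_effects", 5), sim, se = FALSE)
  mapped <- reference_switch(extract_latent_moments(f3), 5)
  direct <- extract_latent_moments(f5)
  expect_lt(max(abs(mapped$means - direct$means)), 1e-4)
  expect_lt(max(abs(mapped$sds - direct$sds)), 1e-4)
  expect_lt(max(abs(mapped$corr - direct$corr)), 1e-4)
})

test_that("Wald flags: trivial cases and SE-based correlation inference", {
  sp <- lst_spec("item_effects", 3)
  pr <- true_params_53()
  sim <- simulate_panel(sim_config(N = 3000, theta_true = pr, seed = 221))
  f <- lst_fit(sp, sim)
  flags <- wald_flags(f, "correlations")
  expect_true(isSymmetric(flags))
  # a |z| > 10 mean is significant
  expect_true(wald_flags(f, "means")[["eta1"]])
  # near-zero generated correlation (eta1, delta5: r = .002) is usually
  # not flagged; strong one (eta1, eta2: r = .754) always is
  expect_true(flags["eta1", "eta2"])
  expect_false(flags["eta1", "delta5"])
  expect_error(wald_flags(lst_fit(sp, sim, se = FALSE)), "vcov|covariance")
})
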