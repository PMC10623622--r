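test_that("specs expose the right latent variables per variant and reference", {
  sp3 <- lst_spec("item_effects", 3)
  expect_identical(sp3$latent_labels,
                   c("eta1", "eta2", "eta3",
                     "delta1", "delta2", "delta4", "delta5"))
  sp5 <- lst_spec("item_effects", 5)
  expect_identical(sp5$latent_labels,
                   c("eta1", "eta2", "eta3",
                     "delta1", "delta2", "delta3", "delta4"))
  so <- lst_spec("states_only", 3)
  expect_identical(so$latent_labels, c("eta1", "eta2", "eta3"))
  expect_error(lst_spec("item_effects", 6), "1\\.\\.5")
  expect_error(panel_design(n_occasions = 2), "three occasions")
  expect_error(panel_design(n_items = 1), "two items")
})

test_that("loading matrix has the stated sparsity pattern", {
  d2 <- panel_design(n_items = 2)
  sp <- lst_spec("item_effects", 1, d2)
  L <- loading_matrix(sp)
  # observed row (item 2, occasion 1): state eta1 plus delta2
  expect_equal(unname(L["item2_w1", ]), c(1, 0, 0, 1))
  expect_equal(unname(L["item1_w2", ]), c(0, 1, 0, 0))

  sp53 <- lst_spec("item_effects", 3)
  L53 <- loading_matrix(sp53)
  d <- sp53$design
  for (t in 1:3) for (i in 1:5) {
    row <- L53[paste0("item", i, "_w", t), ]
    expect_equal(sum(row), if (i == 3) 1 else 2)
    expect_equal(unname(row[paste0("eta", t)]), 1)
  }

  so <- lst_spec("states_only", 3)
  lam <- c(0.8, 1.1, 1, 0.9, 1.2)
  Ls <- loading_matrix(so, lam)
  for (t in 1:3) for (i in 1:5) {
    row <- Ls[paste0("item", i, "_w", t), ]
    expect_equal(sum(row != 0), 1L)
    expect_equal(unname(row[t]), lam[i])
  }
  expect_error(loading_matrix(so, c(1, 1, 2, 1, 1)), "reference")
})

test_that("implied moments: identity and perfect-indicator limits", {
  sp <- lst_spec("item_effects", 3)
  pr <- lst_parameters(sp, kappa = rep(0, 7), Phi = diag(1e-8, 7),
                       theta = rep(1, 15))
  im <- implied_moments(sp, pr)
  expect_equal(unname(im$mu), rep(0, 15))
  expect_equal(unname(im$Sigma), diag(15), tolerance = 1e-6)

  # single state, unit loadings, tiny error: within-occasion block all ones
  so <- lst_spec("states_only", 1, panel_design(n_items = 3))
  pr2 <- lst_parameters(so, kappa = rep(0, 3), Phi = diag(3),
                        lambda = rep(1, 3), alpha = rep(0, 3),
                        theta = rep(1e-10, 9))
  Sg <- implied_moments(so, pr2)$Sigma
  expect_equal(unname(Sg[1:3, 1:3]), matrix(1, 3, 3), tolerance = 1e-8)
  expect_equal(unname(Sg[1:3, 4:6]), matrix(0, 3, 3), tolerance = 1e-8)
})

test_that("implied covariance matches simulated moments (generator oracle)", {
  sp <- lst_spec("item_effects", 3)
  pr <- true_params_53()
  im <- implied_moments(sp, pr)
  sim <- simulate_panel(sim_config(N = 500000, theta_true = pr, seed = 314))
  sm <- sample_moments(sim[, observed_names(sp$design)])
  expect_lt(max(abs(sm$S - im$Sigma)), 0.02)
  expect_lt(max(abs(sm$ybar - im$mu)), 0.01)
})

test_that("free-parameter counts and degrees of freedom", {
  expect_equal(count_free_parameters(lst_spec("states_only", 3)), 32L)
  expect_equal(count_df(lst_spec("states_only", 3)), 103L)
  expect_equal(count_free_parameters(lst_spec("item_effects", 3)), 50L)
  expect_equal(count_df(lst_spec("item_effects", 3)), 85L)
  d2 <- panel_design(n_items = 2)
  expect_equal(count_free_parameters(lst_spec("item_effects", 1, d2)), 20L)
  expect_equal(count_df(lst_spec("item_effects", 1, d2)), 7L)
  # the extended model is strictly less constrained, whatever the design
  for (I in c(2, 4, 7)) for (T_ in c(3, 4)) {
    d <- panel_design(I, T_)
    expect_gt(count_df(lst_spec("states_only", 1, d)),
              count_df(lst_spec("item_effects", 1, d)))
  }
})

test_that("implied Sigma is PD for random admissible parameters", {
  sp <- lst_spec("item_effects", 3)
  for (seed in 1:10) {
    pr <- random_params(sp, seed)
    im <- implied_moments(sp, pr)
    expect_silent(chol(im$Sigma))
    expect_equal(im$Sigma, t(im$Sigma))
  }
})

test_that("reference choice is a pure reparameterization of the moments", {
  sp3 <- lst_spec("item_effects", 3)
  for (seed in 1:10) {
    pr3 <- random_params(sp3, seed)
    pr5 <- switch_parameters(pr3, 5)
    im3 <- implied_moments(sp3, pr3)
    im5 <- implied_moments(pr5$spec, pr5)
    expect_lt(max(abs(im3$mu - im5$mu)), 1e-10)
    expect_lt(max(abs(im3$Sigma - im5$Sigma)), 1e-10)
  }
})

test_that("spec config serialization round-trips", {
  sp <- lst_spec("item_effects", 2,
                 panel_design(4, 3, item_labels = paste0("swl", 1:4)))
  path <- tempfile(fileext = ".cfg")
  write_lst_spec(sp, path)
  sp2 <- read_lst_spec(path)
  expect_equal(sp2$variant, sp$variant)
  expect_equal(sp2$reference_item, sp$reference_item)
  expect_equal(sp2$design$item_labels, sp$design$item_labels)
  expect_equal(sp2$latent_labels, sp$latent_labels)
})
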