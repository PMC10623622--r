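# Shared fixtures: all data are generated in code at test time.

# Random admissible parameter vector for a spec (deterministic given seed).
random_params <- function(spec, seed) {
  set.seed(seed)
  m <- spec$m
  W <- matrix(rnorm(m * (m + 2)), m)
  Phi <- tcrossprod(W) / (m + 2) + diag(0.1, m)
  I <- spec$design$n_items
  lambda <- rep(1, I); alpha <- rep(0, I)
  if (spec$variant == "states_only") {
    lambda[-spec$reference_item] <- runif(I - 1, 0.7, 1.3)
    alpha[-spec$reference_item] <- rnorm(I - 1, 0, 0.5)
  }
  lst_parameters(spec,
                 kappa = rnorm(m, 0, 1),
                 Phi = Phi,
                 lambda = lambda, alpha = alpha,
                 theta = runif(spec$p, 0.2, 1))
}

# Table-magnitude truth used across recovery tests.
true_params_53 <- function() default_true_parameters()
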